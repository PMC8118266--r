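# Pairwise ceRNA inference: candidate gene pairs must share a significant
# number of miRNA regulators (hypergeometric test), show strong positive
# partial correlation after removing each gene's own copy-number effect, and
# show joint negative Collective Regulation, with a bootstrap consensus on
# the two correlation statistics.

#' Upper-tail hypergeometric test for a shared-regulator overlap
#'
#' Probability of observing at least `overlap` shared elements between a set
#' of size |A| and a draw of size |B| from a universe of size |U|:
#' P(X >= overlap) with X ~ Hypergeometric(|U|, |A|, |B|).
#'
#' @param regulators_a,regulators_b Character vectors (regulator id sets).
#' @param universe Character vector; the regulator universe (all miRNAs in
#'   the final interaction table).
#' @return List with `overlap` (integer) and `p` (upper-tail probability).
#' @export
common_regulator_pvalue <- function(regulators_a, regulators_b, universe) {
  if (!length(universe)) abort("empty regulator universe")
  a <- unique(regulators_a); b <- unique(regulators_b); u <- unique(universe)
  if (length(setdiff(a, u)) || length(setdiff(b, u)))
    abort("regulator sets must be subsets of the universe")
  ov <- length(intersect(a, b))
  p <- phyper(ov - 1L, length(a), length(u) - length(a), length(b),
              lower.tail = FALSE)
  list(overlap = ov, p = p)
}

#' Regulator sets per gene
#'
#' @param table An `interaction_table`.
#' @return Named list mapping each target gene to its regulator id vector.
#' @export
regulator_sets <- function(table) {
  split(table$regulator, table$target)
}

#' Screen candidate gene pairs by common-regulator significance
#'
#' Enumerates all unordered candidate pairs and keeps those whose regulator
#' overlap is hypergeometrically significant (`p < alpha`) against the
#' universe of miRNAs in the interaction table. The overlap test runs on an
#' incidence-matrix cross product, so all pairs are screened before any
#' correlation is computed.
#'
#' @param candidates Character vector of candidate gene ids (each with at
#'   least one regulator in `table`).
#' @param table The final `interaction_table`.
#' @param alpha Significance cutoff (default 0.01).
#' @return data.frame with `gene_a`, `gene_b`, `n_common`, `hypergeom_p`.
#' @export
candidate_pair_screen <- function(candidates, table, alpha = 0.01) {
  candidates <- unique(candidates)
  sets <- regulator_sets(table)
  no_reg <- setdiff(candidates, names(sets))
  if (length(no_reg)) abort("candidate gene(s) without regulators: %s",
                            paste(utils::head(no_reg, 3), collapse = ", "))
  universe <- unique(table$regulator)
  inc <- matrix(0L, length(candidates), length(universe),
                dimnames = list(candidates, universe))
  sub <- table[table$target %in% candidates, , drop = FALSE]
  inc[cbind(sub$target, sub$regulator)] <- 1L
  ov <- tcrossprod(inc)                  # pairwise overlap counts
  sizes <- rowSums(inc)
  n <- length(candidates)
  if (n < 2L) return(data.frame(gene_a = character(), gene_b = character(),
                                n_common = integer(), hypergeom_p = numeric()))
  iu <- which(upper.tri(ov), arr.ind = TRUE)
  p <- phyper(ov[iu] - 1L, sizes[iu[, 1L]],
              length(universe) - sizes[iu[, 1L]], sizes[iu[, 2L]],
              lower.tail = FALSE)
  keep <- p < alpha
  data.frame(gene_a = candidates[iu[keep, 1L]],
             gene_b = candidates[iu[keep, 2L]],
             n_common = as.integer(ov[iu][keep]),
             hypergeom_p = p[keep],
             stringsAsFactors = FALSE)
}

# OLS residual of x on a single covariate c (intercept included); a constant
# covariate removes only the mean.
ols_residual <- function(x, covariate) {
  vc <- sum((covariate - mean(covariate))^2)
  beta <- if (vc == 0) 0 else sum((x - mean(x)) * (covariate - mean(covariate))) / vc
  x - mean(x) - beta * (covariate - mean(covariate))
}

#' Partial correlation between two genes excluding their copy-number effect
#'
#' Each expression vector is replaced by its residual after ordinary least
#' squares on that gene's own CNA vector (with intercept); the partial
#' correlation is the Pearson correlation of the two residual vectors. The
#' p-value uses t = rho * sqrt((n-4)/(1-rho^2)) on n - 4 degrees of freedom
#' (two fitted slopes consumed), two-sided.
#'
#' @param expr_a,expr_b Expression vectors (length n >= 5).
#' @param cna_a,cna_b Copy-number vectors for the same samples.
#' @return List with `rho` and `p`; `rho` is NA when a residual vector has
#'   zero variance (the caller drops such pairs).
#' @export
partial_correlation_excluding_cna <- function(expr_a, expr_b, cna_a, cna_b) {
  n <- length(expr_a)
  if (length(expr_b) != n || length(cna_a) != n || length(cna_b) != n)
    abort("all four vectors must have equal length")
  if (n < 5L) abort("need at least 5 samples for the partial correlation")
  ra <- ols_residual(expr_a, cna_a)
  rb <- ols_residual(expr_b, cna_b)
  rho <- safe_cor(ra, rb)
  if (is.na(rho)) return(list(rho = NA_real_, p = NA_real_))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 4) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tstat), df = n - 4))
}

#' Collective Regulation (CR) of a gene set
#'
#' Pearson correlation between the per-sample sum of Effective Regulation and
#' the per-sample sum of expression over the set:
#' \deqn{CR(S) = corr\big(\sum_{s \in S} ER(s), \sum_{s \in S} Exp(s)\big)}
#' Strongly negative values indicate that the set is jointly under miRNA
#' regulation. NA is returned when either summed vector is constant; callers
#' treat that as a failed condition.
#'
#' @param gene_set Character vector, at least 2 gene ids.
#' @param genes Gene expression matrix.
#' @param er ER matrix (same samples).
#' @return CR value in [-1, 1], or NA if undefined.
#' @export
collective_regulation <- function(gene_set, genes, er) {
  gene_set <- unique(gene_set)
  if (length(gene_set) < 2L) abort("collective regulation needs at least 2 genes")
  miss <- setdiff(gene_set, intersect(rownames(genes), rownames(er)))
  if (length(miss)) abort("gene(s) missing expression or ER: %s",
                          paste(utils::head(miss, 3), collapse = ", "))
  se <- colSums(er[gene_set, , drop = FALSE])
  sx <- colSums(genes[gene_set, , drop = FALSE])
  safe_cor(se, sx)
}

# Row-wise partial correlation for matched rows, with per-row OLS residuals
# against each row's own covariate.
rowwise_partial_cor <- function(XA, XB, CA, CB) {
  resid_rows <- function(X, C) {
    mx <- rowMeans(X); mc <- rowMeans(C)
    vc <- rowMeans(C * C) - mc * mc
    cxc <- rowMeans(X * C) - mx * mc
    beta <- ifelse(vc > 0, cxc / vc, 0)
    (X - mx) - beta * (C - mc)
  }
  rowwise_cor(resid_rows(XA, CA), resid_rows(XB, CB))
}

#' Filter screened pairs into a weighted ceRNA network
#'
#' A screened pair becomes an edge when, on the full data, its CNA-adjusted
#' partial correlation exceeds `partial_corr_min` with p-value below
#' `partial_p_max`, and its pairwise Collective Regulation is below `cr_max`;
#' and when, over the shared bootstrap resamples, both coefficient thresholds
#' (partial correlation and CR) hold in at least `min_pass_frac` of resamples
#' (the p-value is computed once, on the full data). Edge weights are the
#' surviving partial correlations min-max normalized onto
#' `[weight_floor, 1]`; if all survivors tie, every weight is 1.
#'
#' @param pairs data.frame from [candidate_pair_screen()].
#' @param genes Gene expression matrix.
#' @param cna CNA matrix (same genes present, same samples).
#' @param er ER matrix.
#' @param partial_corr_min,partial_p_max,cr_max Thresholds (defaults 0.55,
#'   0.01, -0.01).
#' @param consensus A [consensus_config()]; default 100 resamples at 0.99.
#' @param weight_floor Positive floor for normalized edge weights.
#' @return A `cerna_network`.
#' @export
pair_filter <- function(pairs, genes, cna, er,
                        partial_corr_min = 0.55, partial_p_max = 0.01,
                        cr_max = -0.01,
                        consensus = consensus_config(100L),
                        weight_floor = 0.01) {
  if (nrow(pairs) == 0L) abort("no screened pairs to filter")
  miss <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), rownames(cna))
  if (length(miss)) abort("gene(s) without CNA rows: %s",
                          paste(utils::head(miss, 3), collapse = ", "))
  n <- ncol(genes)
  XA <- genes[pairs$gene_a, , drop = FALSE]
  XB <- genes[pairs$gene_b, , drop = FALSE]
  CA <- cna[pairs$gene_a, , drop = FALSE]
  CB <- cna[pairs$gene_b, , drop = FALSE]
  EA <- er[pairs$gene_a, , drop = FALSE]
  EB <- er[pairs$gene_b, , drop = FALSE]

  rho <- rowwise_partial_cor(XA, XB, CA, CB)
  tstat <- rho * sqrt((n - 4) / pmax(1 - rho^2, .Machine$double.eps))
  pval <- 2 * pt(-abs(tstat), df = n - 4)
  pval[!is.na(rho) & abs(rho) >= 1] <- 0
  cr <- rowwise_cor(EA + EB, XA + XB)

  keep <- !is.na(rho) & rho > partial_corr_min & pval < partial_p_max &
    !is.na(cr) & cr < cr_max
  frac <- rep(NA_real_, nrow(pairs))
  if (any(keep) && consensus$n_resamples > 0L) {
    idx <- resample_indices(consensus, n)
    k <- which(keep)
    npass <- numeric(length(k))
    for (b in seq_len(nrow(idx))) {
      j <- idx[b, ]
      rb <- rowwise_partial_cor(XA[k, j, drop = FALSE], XB[k, j, drop = FALSE],
                                CA[k, j, drop = FALSE], CB[k, j, drop = FALSE])
      cb <- rowwise_cor(EA[k, j, drop = FALSE] + EB[k, j, drop = FALSE],
                        XA[k, j, drop = FALSE] + XB[k, j, drop = FALSE])
      ok <- !is.na(rb) & rb > partial_corr_min & !is.na(cb) & cb < cr_max
      npass <- npass + ok
    }
    frac[k] <- npass / nrow(idx)
    keep[k] <- frac[k] >= consensus$min_pass_frac
  } else if (any(keep)) {
    frac[keep] <- 1
  }
  if (!any(keep)) abort("no ceRNA pairs survive the pair filter")

  edges <- data.frame(gene_a = pairs$gene_a[keep], gene_b = pairs$gene_b[keep],
                      n_common = pairs$n_common[keep],
                      hypergeom_p = pairs$hypergeom_p[keep],
                      partial_corr = rho[keep], partial_corr_p = pval[keep],
                      cr = cr[keep], consensus_frac = frac[keep],
                      stringsAsFactors = FALSE)
  rng <- range(edges$partial_corr)
  # a spread below the numerical resolution of a correlation must not be
  # amplified into edge weights: treat it as a degenerate min-max (all ties)
  edges$weight <- if (rng[2] - rng[1] < 1e-8) rep(1, nrow(edges)) else
    weight_floor + (1 - weight_floor) * (edges$partial_corr - rng[1]) / (rng[2] - rng[1])
  cerna_network(edges)
}

#' Construct a ceRNA network from an edge table
#'
#' @param edges data.frame with at least `gene_a`, `gene_b`, `weight`
#'   (strictly positive); no self-loops or duplicate undirected edges.
#' @return List of class `cerna_network` with `nodes` and `edges`.
#' @export
cerna_network <- function(edges) {
  need <- c("gene_a", "gene_b", "weight")
  miss <- setdiff(need, names(edges))
  if (length(miss)) abort("edge table misses column(s): %s",
                          paste(miss, collapse = ", "))
  if (any(edges$gene_a == edges$gene_b)) abort("self-loops are not allowed")
  if (any(!is.finite(edges$weight)) || any(edges$weight <= 0))
    abort("edge weights must be finite and strictly positive")
  key <- ifelse(edges$gene_a < edges$gene_b,
                paste(edges$gene_a, edges$gene_b),
                paste(edges$gene_b, edges$gene_a))
  if (anyDuplicated(key)) abort("duplicate undirected edge(s)")
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
                 edges = edges),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat(sprintf("ceRNA network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# igraph view of a cerna_network (weights preserved).
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("gene_a", "gene_b")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE)
  ) -> g
  igraph::E(g)$weight <- net$edges$weight
  g
}

#' Write a ceRNA network edge list to TSV
#' @param net A `cerna_network`.
#' @param path Output path.
#' @export
write_cerna_network <- function(net, path) {
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
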