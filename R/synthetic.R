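# Seeded synthetic inputs with planted ceRNA structure. The generator
# emulates the four pipeline inputs (gene expression, miRNA expression,
# gene-centric CNA, miRNA-target binding table) at a desk scale:
#   * planted ceRNA sets: genes sharing a dedicated high-weight regulator set,
#     strongly repressed -> these are the ground-truth pairs;
#   * decoy co-regulated pairs: genuine but weaker miRNA co-regulation,
#     emulating the bulk of lower-confidence candidate edges that the
#     top-third retention after deconvolution is meant to prune;
#   * background genes with sparse weak regulators;
#   * filler records: annotation-only miRNA-target predictions with weak
#     scores and no expression effect, emulating the low-confidence tail of
#     sequence-based target predictions that the top-40% score cut removes.

#' Specification for a synthetic ceRNA dataset
#'
#' @param n_genes,n_mirnas,n_samples Dimensions of the dataset.
#' @param n_planted_pairs Number of planted (ground-truth) ceRNA pairs.
#' @param n_decoy_pairs Number of weaker co-regulated decoy pairs.
#' @param k_regulators Shared regulators per planted/decoy set (default 3).
#' @param repression_strength Base repression coefficient scale (default 0.9).
#' @param decoy_strength,background_strength Multipliers on
#'   `repression_strength` for decoy and background genes (defaults 0.7, 0.3).
#' @param cna_effect Coefficient of the gene's CNA on its expression (>= 0).
#' @param noise_sd Standard deviation of additive Gaussian expression noise.
#' @param filler_factor Annotation-only filler records per functional record
#'   (default 1.5, so functional records sit in the top 40% by score).
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 200L, n_mirnas = 30L, n_samples = 300L,
                           n_planted_pairs = 20L, n_decoy_pairs = 30L,
                           k_regulators = 3L,
                           repression_strength = 0.9,
                           decoy_strength = 0.7, background_strength = 0.3,
                           cna_effect = 0.8, noise_sd = 0.5,
                           filler_factor = 1.5, seed = 1L) {
  stopifnot(is_count(n_genes), is_count(n_mirnas), is_count(n_samples),
            is_count(n_planted_pairs), is_count(n_decoy_pairs),
            is_count(k_regulators))
  if (repression_strength <= 0) abort("repression_strength must be positive")
  if (cna_effect < 0 || noise_sd < 0) abort("cna_effect and noise_sd must be >= 0")
  if (2L * (n_planted_pairs + n_decoy_pairs) > n_genes)
    abort("n_genes too small for the planted and decoy pairs")
  if (k_regulators > n_mirnas)
    abort("infeasible: more planted regulators per set than miRNAs")
  structure(as.list(environment()), class = "synthetic_spec")
}

# Sample regulator sets of size k with pairwise overlap <= 1, so that only
# within-set gene pairs show a hypergeometrically significant overlap.
sample_regulator_sets <- function(n_sets, k, mirna_ids, max_tries = 5000L) {
  sets <- list()
  tries <- 0L
  while (length(sets) < n_sets) {
    cand <- sort(sample(mirna_ids, k))
    ok <- all(vapply(sets, function(s) length(intersect(s, cand)) <= 1L,
                     logical(1)))
    if (ok) sets[[length(sets) + 1L]] <- cand
    tries <- tries + 1L
    if (tries > max_tries)
      abort("infeasible: cannot place %d near-disjoint regulator sets over %d miRNAs",
            n_sets, length(mirna_ids))
  }
  sets
}

#' Generate a synthetic dataset with planted ceRNA structure
#'
#' miRNA expression is i.i.d. log-normal. Gene expression is
#' `baseline - sum(coef_r * Exp(r)) + cna_effect * CNA + noise`, truncated at
#' zero; the two genes of a planted or decoy pair share identical regulator
#' coefficients, so in the noiseless zero-CNA limit their expression vectors
#' are exactly affinely related. Planted binding scores are the most negative
#' in the table, so planted interactions survive the top-40% score cut by
#' construction.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `genes`, `mirnas`, `cna` (matrices), `table` (an
#'   `interaction_table`), `classes` (named RNA-class vector), and `truth`
#'   (with `pairs`, `planted_sets`, `decoy_sets`).
#' @export
generate_dataset <- function(spec) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stage_seed(spec$seed, "synth"))

  gene_ids <- sprintf("g%03d", seq_len(spec$n_genes))
  mir_ids <- sprintf("mir%02d", seq_len(spec$n_mirnas))
  sample_ids <- sprintf("s%03d", seq_len(spec$n_samples))

  n_pl <- spec$n_planted_pairs; n_dc <- spec$n_decoy_pairs
  planted_genes <- gene_ids[seq_len(2L * n_pl)]
  decoy_genes <- gene_ids[2L * n_pl + seq_len(2L * n_dc)]
  background_genes <- setdiff(gene_ids, c(planted_genes, decoy_genes))

  M <- matrix(rlnorm(spec$n_mirnas * spec$n_samples, meanlog = 1, sdlog = 0.3),
              spec$n_mirnas, spec$n_samples,
              dimnames = list(mir_ids, sample_ids))
  # the CNA matrix itself carries the effect scale, so cna_effect = 0 yields
  # a constant (all-zero) covariate and the partial correlation reduces to
  # the plain Pearson correlation
  CNA <- spec$cna_effect *
    matrix(rnorm(spec$n_genes * spec$n_samples),
           spec$n_genes, spec$n_samples,
           dimnames = list(gene_ids, sample_ids))
  classes <- setNames(sample(RNA_CLASSES, spec$n_genes, replace = TRUE,
                             prob = c(0.7, 0.2, 0.1)), gene_ids)

  sets <- sample_regulator_sets(n_pl + n_dc, spec$k_regulators, mir_ids)
  planted_sets <- sets[seq_len(n_pl)]
  decoy_sets <- if (n_dc) sets[n_pl + seq_len(n_dc)] else list()

  coefs <- matrix(0, spec$n_genes, spec$n_mirnas,
                  dimnames = list(gene_ids, mir_ids))
  reg <- data.frame(regulator = character(), target = character(),
                    raw_score = numeric(), stringsAsFactors = FALSE)
  add_records <- function(reg, target, mirs, scores) {
    rbind(reg, data.frame(regulator = mirs, target = target,
                          raw_score = scores, stringsAsFactors = FALSE))
  }

  for (i in seq_len(n_pl)) {
    mirs <- planted_sets[[i]]
    cf <- runif(length(mirs), 0.8, 1.0) * spec$repression_strength
    sc <- runif(length(mirs), -1.0, -0.8)
    for (g in planted_genes[c(2L * i - 1L, 2L * i)]) {
      coefs[g, mirs] <- cf
      reg <- add_records(reg, g, mirs, sc)
    }
  }
  for (i in seq_len(n_dc)) {
    mirs <- decoy_sets[[i]]
    cf <- runif(length(mirs), 0.8, 1.0) * spec$repression_strength * spec$decoy_strength
    sc <- runif(length(mirs), -0.7, -0.5)
    for (g in decoy_genes[c(2L * i - 1L, 2L * i)]) {
      coefs[g, mirs] <- cf
      reg <- add_records(reg, g, mirs, sc)
    }
  }
  for (g in background_genes) {
    # exactly one functional regulator: a single shared regulator is never a
    # hypergeometrically significant overlap, so background genes contribute
    # candidate genes but no spurious pairs
    mirs <- sample(mir_ids, 1L)
    cf <- runif(1L, 0.8, 1.0) * spec$repression_strength * spec$background_strength
    coefs[g, mirs] <- cf
    reg <- add_records(reg, g, mirs, runif(1L, -0.45, -0.3))
  }

  # annotation-only filler records (no expression effect)
  n_filler <- ceiling(spec$filler_factor * nrow(reg))
  have <- paste(reg$regulator, reg$target)
  fill_m <- character(0); fill_g <- character(0)
  while (length(fill_m) < n_filler) {
    need <- n_filler - length(fill_m)
    m <- sample(mir_ids, 2L * need, replace = TRUE)
    g <- sample(gene_ids, 2L * need, replace = TRUE)
    key <- paste(m, g)
    ok <- !(key %in% have) & !duplicated(key)
    fill_m <- c(fill_m, m[ok][seq_len(min(need, sum(ok)))])
    fill_g <- c(fill_g, g[ok][seq_len(min(need, sum(ok)))])
    have <- c(have, paste(fill_m, fill_g))
  }
  reg <- rbind(reg, data.frame(regulator = fill_m, target = fill_g,
                               raw_score = runif(n_filler, -0.25, -0.01),
                               stringsAsFactors = FALSE))

  baseline <- setNames(numeric(spec$n_genes), gene_ids)
  baseline[c(planted_genes, decoy_genes)] <-
    runif(length(planted_genes) + length(decoy_genes), 40, 50)
  baseline[background_genes] <- runif(length(background_genes), 5, 15)

  G <- baseline - coefs %*% M + CNA +
    matrix(rnorm(spec$n_genes * spec$n_samples, sd = spec$noise_sd),
           spec$n_genes, spec$n_samples)
  G <- pmax(G, 0)
  dimnames(G) <- list(gene_ids, sample_ids)

  table <- interaction_table(reg$regulator, reg$target, reg$raw_score,
                             classes[reg$target])
  pairs <- data.frame(
    gene_a = planted_genes[2L * seq_len(n_pl) - 1L],
    gene_b = planted_genes[2L * seq_len(n_pl)],
    stringsAsFactors = FALSE)
  list(genes = G, mirnas = M, cna = CNA, table = table, classes = classes,
       truth = list(pairs = pairs, planted_sets = planted_sets,
                    decoy_sets = decoy_sets,
                    decoy_pairs = data.frame(
                      gene_a = decoy_genes[2L * seq_len(n_dc) - 1L],
                      gene_b = decoy_genes[2L * seq_len(n_dc)],
                      stringsAsFactors = FALSE)))
}

#' Write a synthetic dataset to a directory as TSV files
#'
#' Emits `genes.tsv`, `mirnas.tsv`, `cna.tsv`, `interactions.tsv` and
#' `truth_pairs.tsv`.
#'
#' @param data Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(data$genes, file.path(dir, "genes.tsv"))
  write_expression_matrix(data$mirnas, file.path(dir, "mirnas.tsv"))
  write_expression_matrix(data$cna, file.path(dir, "cna.tsv"))
  write_interaction_table(data$table, file.path(dir, "interactions.tsv"))
  write.table(data$truth$pairs, file.path(dir, "truth_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# Canonical unordered-pair keys.
pair_keys <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}

# Gene-level pair set implied by a network: plain edges for a cerna_network;
# for a grouped network, within-group pairs plus the expansion of every edge
# into member-by-member gene pairs.
inferred_pair_keys <- function(net) {
  if (inherits(net, "cerna_network"))
    return(unique(pair_keys(net$edges$gene_a, net$edges$gene_b)))
  if (!inherits(net, "grouped_cerna_network"))
    abort("expected a cerna_network or grouped_cerna_network")
  keys <- character(0)
  for (g in net$groups) {
    m <- g$members
    if (length(m) >= 2L) {
      cmb <- utils::combn(m, 2L)
      keys <- c(keys, pair_keys(cmb[1L, ], cmb[2L, ]))
    }
  }
  expand <- function(node) {
    if (node %in% names(net$groups)) net$groups[[node]]$members else node
  }
  for (i in seq_len(nrow(net$edges))) {
    ma <- expand(net$edges$node_a[i]); mb <- expand(net$edges$node_b[i])
    grid <- expand.grid(a = ma, b = mb, stringsAsFactors = FALSE)
    keys <- c(keys, pair_keys(grid$a, grid$b))
  }
  unique(keys)
}

#' Precision and recall of planted-pair recovery
#'
#' A planted pair counts as recovered when it is an edge of the inferred
#' network or when both genes share a group. Precision is computed over the
#' inferred gene-level pair set (within-group pairs plus edges, group edges
#' expanded to member pairs); an empty inference has precision 1 by
#' convention.
#'
#' @param truth Truth component of [generate_dataset()] output (or any list
#'   with a `pairs` data.frame).
#' @param inferred A `cerna_network` or `grouped_cerna_network`.
#' @return List with `precision`, `recall`, `n_true`, `n_inferred`.
#' @export
score_recovery <- function(truth, inferred) {
  true_keys <- unique(pair_keys(truth$pairs$gene_a, truth$pairs$gene_b))
  inf_keys <- inferred_pair_keys(inferred)
  hit <- length(intersect(true_keys, inf_keys))
  list(precision = if (length(inf_keys)) hit / length(inf_keys) else 1,
       recall = if (length(true_keys)) hit / length(true_keys) else 1,
       n_true = length(true_keys), n_inferred = length(inf_keys))
}
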