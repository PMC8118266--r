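# miRNA-target interaction filtering: expression anticorrelation with
# bootstrap consensus, the per-sample Interaction Regulation (IR) statistic
# with an abundance cut, and the per-gene Effective Regulation (ER) statistic
# driving candidate-gene selection.

#' Filter miRNA-target interactions by expression anticorrelation
#'
#' miRNAs repress their targets, so a credible interaction should show
#' negative correlation between regulator and target expression. A record is
#' kept when the Pearson correlation is below `threshold` on the full data
#' and, under the bootstrap consensus, in at least `min_pass_frac` of
#' resamples of the samples (with replacement). Records whose regulator or
#' target expression is constant, and resamples with zero variance, count as
#' failures.
#'
#' @param table An `interaction_table`; every regulator/target must have an
#'   expression row.
#' @param mirnas,genes Expression matrices with aligned samples.
#' @param threshold Correlation cutoff (default -0.1).
#' @param consensus A [consensus_config()]; default 1000 resamples at 0.99.
#' @return The retained table with columns `corr` and `consensus_frac` added.
#' @export
expression_correlation_filter <- function(table, mirnas, genes,
                                          threshold = -0.1,
                                          consensus = consensus_config(1000L)) {
  if (nrow(table) == 0L) return(table)
  miss <- setdiff(table$regulator, rownames(mirnas))
  if (length(miss)) abort("regulator(s) without expression: %s",
                          paste(utils::head(miss, 3), collapse = ", "))
  miss <- setdiff(table$target, rownames(genes))
  if (length(miss)) abort("target(s) without expression: %s",
                          paste(utils::head(miss, 3), collapse = ", "))
  X <- mirnas[table$regulator, , drop = FALSE]
  Y <- genes[table$target, , drop = FALSE]
  r <- rowwise_cor(X, Y)
  keep <- !is.na(r) & r < threshold
  frac <- rep(NA_real_, nrow(table))
  if (any(keep)) {
    idx <- resample_indices(consensus, ncol(X))
    frac[keep] <- consensus_pass_fraction(X[keep, , drop = FALSE],
                                          Y[keep, , drop = FALSE],
                                          idx, threshold, lower = TRUE)
    keep[keep] <- frac[keep] >= consensus$min_pass_frac
  }
  out <- table[keep, , drop = FALSE]
  out$corr <- r[keep]
  out$consensus_frac <- frac[keep]
  rownames(out) <- NULL
  class(out) <- c("interaction_table", "data.frame")
  out
}

#' Interaction Regulation (IR): per-sample mutual abundance of an interaction
#'
#' For a regulator r with normalized binding weight w(r,t) on target t, and
#' expression Exp evaluated per sample,
#' \deqn{IR(r,t) = \frac{Exp(r)\,Exp(t)\,w_{rt}}{\sum_{j \in targets(r)} Exp(j)\,w_{rj}}
#'              \times \frac{Exp(t)\,Exp(r)\,w_{rt}}{\sum_{j \in regulators(t)} Exp(j)\,w_{jt}}}
#' The first factor measures how much of r's regulatory budget t commands;
#' the second how much of t's regulation r supplies. Denominator sums run
#' over the current table only. A zero denominator in a sample (all of r's
#' targets, or all of t's regulators, unexpressed) defines IR = 0 there.
#'
#' @param table An `interaction_table` with strictly positive `norm_weight`.
#' @param mirnas,genes Expression matrices with aligned samples.
#' @return List with `ir` (interactions x samples matrix, rows named
#'   `"regulator|target"`) and the `table` the rows refer to.
#' @export
compute_interaction_regulation <- function(table, mirnas, genes) {
  if (any(is.na(table$norm_weight)) || any(table$norm_weight <= 0))
    abort("norm_weight must be set and strictly positive (run normalize_binding_scores)")
  mir_ids <- unique(table$regulator)
  gene_ids <- unique(table$target)
  M <- mirnas[mir_ids, , drop = FALSE]
  G <- genes[gene_ids, , drop = FALSE]
  W <- matrix(0, length(mir_ids), length(gene_ids),
              dimnames = list(mir_ids, gene_ids))
  W[cbind(table$regulator, table$target)] <- table$norm_weight
  den_r <- W %*% G        # miRNA x samples: sum_j Exp(j) w_rj over r's targets
  den_t <- t(W) %*% M     # gene x samples:  sum_j Exp(j) w_jt over t's regulators
  num <- M[table$regulator, , drop = FALSE] * G[table$target, , drop = FALSE] *
    table$norm_weight
  d1 <- den_r[table$regulator, , drop = FALSE]
  d2 <- den_t[table$target, , drop = FALSE]
  ir <- matrix(0, nrow(table), ncol(M))
  ok <- d1 > 0 & d2 > 0
  ir[ok] <- num[ok]^2 / (d1[ok] * d2[ok])
  dimnames(ir) <- list(paste(table$regulator, table$target, sep = "|"),
                       colnames(M))
  list(ir = ir, table = table)
}

#' Keep interactions with sufficient expression abundance
#'
#' An interaction is retained when the `percentile` quantile (linear
#' interpolation between order statistics) of its natural-log IR vector is
#' strictly greater than `log_ir_threshold`. Samples with IR = 0 enter as
#' -Inf. The default threshold reproduces a third-quartile-of-IR calibration;
#' `recalibrate = TRUE` recomputes it as the third quartile of the current
#' dataset's log-IR values (finite entries only).
#'
#' @param table The `interaction_table` the IR rows refer to.
#' @param reg Output of [compute_interaction_regulation()].
#' @param log_ir_threshold Cutoff on log IR (default -4.89).
#' @param percentile Quantile of the per-interaction log-IR vector (default 0.80).
#' @param recalibrate Recompute the threshold from the data (default FALSE).
#' @return The retained table with column `log_ir_p` added.
#' @export
abundance_filter <- function(table, reg, log_ir_threshold = -4.89,
                             percentile = 0.80, recalibrate = FALSE) {
  if (nrow(table) != nrow(reg$ir)) abort("table and IR matrix are out of step")
  logir <- suppressWarnings(log(reg$ir))   # log(0) -> -Inf by design
  if (recalibrate) {
    fin <- logir[is.finite(logir)]
    if (!length(fin)) abort("no finite IR values to recalibrate the threshold")
    log_ir_threshold <- unname(quantile(fin, 0.75, type = 7))
  }
  p <- apply(logir, 1L, function(v) unname(quantile(v, percentile, type = 7,
                                                    names = FALSE)))
  keep <- is.finite(p) & p > log_ir_threshold
  out <- table[keep, , drop = FALSE]
  out$log_ir_p <- p[keep]
  rownames(out) <- NULL
  class(out) <- c("interaction_table", "data.frame")
  out
}

#' Effective Regulation (ER): total miRNA pressure on each gene
#'
#' For gene t and sample s,
#' \deqn{ER(t) = \sum_{r \in regulators(t)} Exp(r)\,
#'   \frac{w_{rt}}{\sum_{j \in targets(r)} w_{rj}}}
#' i.e. each regulator contributes its expression scaled by the share of its
#' binding budget spent on t. The inner ratio is invariant to rescaling all
#' of one miRNA's weights by a common factor. Genes are taken from the
#' targets present in `table`; a `gene_ids` argument may extend the result
#' with zero rows for regulator-free genes.
#'
#' @param table An `interaction_table` with strictly positive `norm_weight`.
#' @param mirnas miRNA expression matrix.
#' @param gene_ids Optional gene universe; genes without regulators get ER = 0.
#' @return Matrix genes x samples of ER values.
#' @export
compute_effective_regulation <- function(table, mirnas, gene_ids = NULL) {
  if (any(is.na(table$norm_weight)) || any(table$norm_weight <= 0))
    abort("norm_weight must be set and strictly positive")
  mir_ids <- unique(table$regulator)
  tgt_ids <- unique(table$target)
  if (is.null(gene_ids)) gene_ids <- tgt_ids
  M <- mirnas[mir_ids, , drop = FALSE]
  W <- matrix(0, length(mir_ids), length(tgt_ids),
              dimnames = list(mir_ids, tgt_ids))
  W[cbind(table$regulator, table$target)] <- table$norm_weight
  Wn <- W / rowSums(W)    # every present regulator has a positive row sum
  er_t <- t(Wn) %*% M     # targets x samples
  er <- matrix(0, length(gene_ids), ncol(M),
               dimnames = list(gene_ids, colnames(M)))
  common <- intersect(gene_ids, tgt_ids)
  er[common, ] <- er_t[common, , drop = FALSE]
  er
}

#' Select candidate genes by expression-vs-ER anticorrelation
#'
#' A gene under genuine miRNA control should show negative correlation
#' between its expression and its Effective Regulation. Genes pass when
#' Pearson corr(Exp, ER) < `threshold` on the full data and in at least
#' `min_pass_frac` of the shared resamples. Genes with constant expression or
#' constant ER (including regulator-free genes) are excluded.
#'
#' @param genes Gene expression matrix.
#' @param er ER matrix from [compute_effective_regulation()] (same samples).
#' @param threshold Correlation cutoff (default -0.01).
#' @param consensus A [consensus_config()]; default 1000 resamples at 0.99.
#' @return Character vector of candidate gene ids.
#' @export
filter_genes_by_effective_regulation <- function(genes, er, threshold = -0.01,
                                                 consensus = consensus_config(1000L)) {
  ids <- intersect(rownames(genes), rownames(er))
  if (!length(ids)) abort("no genes shared between expression and ER matrices")
  X <- genes[ids, , drop = FALSE]
  Y <- er[ids, , drop = FALSE]
  r <- rowwise_cor(X, Y)
  keep <- !is.na(r) & r < threshold
  if (any(keep)) {
    idx <- resample_indices(consensus, ncol(X))
    frac <- consensus_pass_fraction(X[keep, , drop = FALSE],
                                    Y[keep, , drop = FALSE],
                                    idx, threshold, lower = TRUE)
    keep[keep] <- frac >= consensus$min_pass_frac
  }
  out <- ids[keep]
  if (!length(out))
    abort("no candidate genes survive the effective-regulation filter")
  out
}
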