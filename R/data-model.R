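# Domain containers are deliberately plain: expression and copy-number data
# are numeric matrices (entities x samples, rownames/colnames set), the
# miRNA-target interaction table is a data.frame. Validators enforce the
# container invariants at the I/O boundary.

RNA_CLASSES <- c("mRNA", "lncRNA", "pseudogene")

#' Validate an expression or copy-number matrix
#'
#' Checks the container invariants: unique entity and sample identifiers,
#' positive dimensions, finite values, and (for expression data)
#' non-negativity.
#'
#' @param x Numeric matrix, entities x samples, with rownames and colnames.
#' @param kind One of `"gene"`, `"miRNA"` (non-negative expression) or
#'   `"cna"` (any finite real).
#' @return `x`, invisibly, after validation.
#' @export
validate_matrix <- function(x, kind = c("gene", "miRNA", "cna")) {
  kind <- match.arg(kind)
  if (!is.matrix(x) || !is.numeric(x)) abort("%s data must be a numeric matrix", kind)
  if (nrow(x) == 0L || ncol(x) == 0L) abort("%s matrix has a zero dimension", kind)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    abort("%s matrix must carry entity rownames and sample colnames", kind)
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup)) abort("duplicate %s entity id(s): %s", kind,
                         paste(unique(dup), collapse = ", "))
  dup <- colnames(x)[duplicated(colnames(x))]
  if (length(dup)) abort("duplicate sample id(s): %s", paste(unique(dup), collapse = ", "))
  if (any(!is.finite(x))) abort("%s matrix contains non-finite values", kind)
  if (kind != "cna" && any(x < 0)) abort("%s expression contains negative values", kind)
  invisible(x)
}

#' Read an expression or copy-number matrix from TSV
#'
#' Expects a tab-separated file with a header row of sample ids and a first
#' column of entity ids. Sample order is preserved; duplicate entity rows are
#' rejected by name.
#'
#' @param path Path to a TSV file.
#' @param kind `"gene"`, `"miRNA"` or `"cna"`; controls the non-negativity check.
#' @return A validated numeric matrix (entities x samples).
#' @export
read_expression_matrix <- function(path, kind = c("gene", "miRNA", "cna")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort("file not found: %s", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) abort("malformed matrix file (need id column + samples): %s", path)
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  nonnum <- !vapply(vals, is.numeric, logical(1))
  if (any(nonnum))
    abort("non-numeric cells in column(s): %s", paste(names(vals)[nonnum], collapse = ", "))
  m <- as.matrix(vals)
  rownames(m) <- ids
  validate_matrix(m, kind)
  m
}

#' Write an expression or copy-number matrix to TSV
#'
#' Inverse of [read_expression_matrix()]: first column `id`, one column per
#' sample, full numeric precision.
#'
#' @param x Numeric matrix with rownames/colnames.
#' @param path Output path.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a miRNA-target interaction table
#'
#' One record per (regulator, target) pair with the raw binding score (by the
#' weighted-context convention, more negative = stronger predicted binding),
#' the target's RNA class, and (after [normalize_binding_scores()]) a strictly
#' positive normalized weight. When the same pair occurs more than once (e.g.
#' multiple transcripts) the strongest (most negative) raw score is kept.
#'
#' @param regulator,target Character vectors of miRNA and gene ids.
#' @param raw_score Numeric binding scores (finite).
#' @param rna_class Character vector in `{"mRNA","lncRNA","pseudogene"}`.
#' @param norm_weight Optional normalized weights in (0, 1].
#' @return A data.frame of class `interaction_table`.
#' @export
interaction_table <- function(regulator, target, raw_score, rna_class,
                              norm_weight = NA_real_) {
  n <- length(regulator)
  if (length(target) != n || length(raw_score) != n || length(rna_class) != n)
    abort("interaction table columns must have equal length")
  if (any(!is.finite(raw_score))) abort("raw binding scores must be finite")
  bad <- setdiff(unique(rna_class), RNA_CLASSES)
  if (length(bad)) abort("unknown RNA class(es): %s", paste(bad, collapse = ", "))
  df <- data.frame(regulator = as.character(regulator),
                   target = as.character(target),
                   raw_score = as.numeric(raw_score),
                   rna_class = as.character(rna_class),
                   norm_weight = rep_len(as.numeric(norm_weight), n),
                   stringsAsFactors = FALSE)
  # collision rule: keep the strongest (most negative) score per pair
  o <- order(df$regulator, df$target, df$raw_score)
  df <- df[o, , drop = FALSE]
  df <- df[!duplicated(df[, c("regulator", "target")]), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("interaction_table", "data.frame")
  df
}

#' Read a miRNA-target interaction table from TSV
#'
#' Columns: `regulator`, `target`, `score`, `class` (and optionally
#' `norm_weight`).
#'
#' @param path Path to a TSV file.
#' @return An `interaction_table`.
#' @export
read_interaction_table <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("regulator", "target", "score", "class")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort("interaction file misses column(s): %s",
                          paste(miss, collapse = ", "))
  nw <- if ("norm_weight" %in% names(df)) df$norm_weight else NA_real_
  interaction_table(df$regulator, df$target, df$score, df$class, nw)
}

#' Write an interaction table to TSV
#' @param table An `interaction_table`.
#' @param path Output path.
#' @export
write_interaction_table <- function(table, path) {
  out <- data.frame(regulator = table$regulator, target = table$target,
                    score = table$raw_score, class = table$rna_class,
                    norm_weight = table$norm_weight, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align gene expression, miRNA expression and CNA on a common sample set
#'
#' Takes the intersection of sample ids once, up front, and orders all three
#' matrices identically.
#'
#' @param genes,mirnas,cna Matrices with sample colnames.
#' @return A list with aligned `genes`, `mirnas`, `cna`.
#' @export
align_samples <- function(genes, mirnas, cna) {
  common <- intersect(intersect(colnames(genes), colnames(mirnas)), colnames(cna))
  if (length(common) == 0L) abort("no common samples across the three matrices")
  list(genes = genes[, common, drop = FALSE],
       mirnas = mirnas[, common, drop = FALSE],
       cna = cna[, common, drop = FALSE])
}

#' Remove lowly expressed genes and miRNAs
#'
#' A gene is dropped when its expression is below `gene_thresh` (FPKM-like
#' units) in at least `frac` of samples; a miRNA is dropped when its
#' expression equals `mirna_zero` (RPM-like units) in at least `frac` of
#' samples. The two criteria are applied independently per data type.
#'
#' @param genes,mirnas Expression matrices sharing the sample set.
#' @param gene_thresh Gene expression threshold (default 1).
#' @param mirna_zero miRNA "unexpressed" value (default 0).
#' @param frac Minimum fraction of offending samples (default 0.15).
#' @return List with filtered `genes` and `mirnas`.
#' @export
filter_low_expression <- function(genes, mirnas, gene_thresh = 1,
                                  mirna_zero = 0, frac = 0.15) {
  if (!setequal(colnames(genes), colnames(mirnas)))
    abort("gene and miRNA matrices must share the sample set")
  keep_g <- rowMeans(genes < gene_thresh) < frac
  keep_m <- rowMeans(mirnas == mirna_zero) < frac
  if (!any(keep_g) || !any(keep_m))
    abort("low-expression filter removed every %s; lower gene_thresh/frac",
          if (!any(keep_g)) "gene" else "miRNA")
  list(genes = genes[keep_g, , drop = FALSE],
       mirnas = mirnas[keep_m, , drop = FALSE])
}

#' Keep the top fraction of interactions by binding score
#'
#' Records are ranked strongest (most negative raw score) first and the top
#' `ceiling(fraction * N)` kept, globally across RNA classes. All records tied
#' with the boundary score are kept, which makes the operation independent of
#' the input order.
#'
#' @param table An `interaction_table` with raw scores.
#' @param fraction Fraction in (0, 1] to retain (default 0.40).
#' @return The retained `interaction_table`.
#' @export
select_top_interactions <- function(table, fraction = 0.40) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    abort("fraction must be in (0, 1]")
  n <- nrow(table)
  if (n == 0L) return(table)
  k <- ceiling(fraction * n)
  cut <- sort(table$raw_score, partial = k)[k]
  out <- table[table$raw_score <= cut, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_table", "data.frame")
  out
}

#' Normalize binding scores into strictly positive interaction weights
#'
#' Raw binding-score distributions differ between mRNAs, lncRNAs and
#' pseudogenes, so scores are z-normalized per RNA class first (a class with
#' zero spread maps to z = 0). All z-scores are then rescaled into [-1, 1] by
#' dividing by the global maximum |z|, flipped so that stronger binding (more
#' negative raw score) gives a larger value, and min-max mapped onto
#' `[weight_floor, 1]`. The floor keeps every weight strictly positive because
#' downstream regulation statistics divide by weight sums.
#'
#' @param table An `interaction_table`.
#' @param weight_floor Smallest allowed weight (default 0.01).
#' @return The table with `norm_weight` set on every record.
#' @export
normalize_binding_scores <- function(table, weight_floor = 0.01) {
  if (nrow(table) == 0L) return(table)
  if (!is.numeric(weight_floor) || weight_floor <= 0 || weight_floor >= 1)
    abort("weight_floor must be in (0, 1)")
  z <- numeric(nrow(table))
  for (cl in unique(table$rna_class)) {
    i <- table$rna_class == cl
    s <- table$raw_score[i]
    sdv <- stats::sd(s)
    z[i] <- if (length(s) < 2L || sdv == 0) 0 else (s - mean(s)) / sdv
  }
  zmax <- max(abs(z))
  if (zmax == 0) {             # degenerate: indistinguishable binding strengths
    table$norm_weight <- 1
    return(table)
  }
  x <- -(z / zmax)             # stronger binding (negative z) -> larger value
  rng <- range(x)
  if (rng[1] == rng[2]) {
    table$norm_weight <- 1
  } else {
    table$norm_weight <- weight_floor +
      (1 - weight_floor) * (x - rng[1]) / (rng[2] - rng[1])
  }
  table
}

#' Restrict an interaction table to measured entities
#'
#' Drops records whose regulator or target has no expression row.
#'
#' @param table An `interaction_table`.
#' @param mirnas,genes Expression matrices.
#' @return The restricted table.
#' @export
restrict_to_measured <- function(table, mirnas, genes) {
  keep <- table$regulator %in% rownames(mirnas) & table$target %in% rownames(genes)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_table", "data.frame")
  out
}
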