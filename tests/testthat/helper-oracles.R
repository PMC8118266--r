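# Independent brute-force oracles: literal per-sample loop evaluations of the
# regulation statistics, kept deliberately naive and separate from the
# package's vectorized implementations.

# IR(r,t) per sample by explicit term-by-term summation.
brute_ir <- function(table, mirnas, genes) {
  ns <- ncol(mirnas)
  out <- matrix(0, nrow(table), ns)
  for (k in seq_len(nrow(table))) {
    r <- table$regulator[k]; t <- table$target[k]; w <- table$norm_weight[k]
    for (s in seq_len(ns)) {
      d1 <- 0
      for (j in which(table$regulator == r))
        d1 <- d1 + genes[table$target[j], s] * table$norm_weight[j]
      d2 <- 0
      for (j in which(table$target == t))
        d2 <- d2 + mirnas[table$regulator[j], s] * table$norm_weight[j]
      num <- mirnas[r, s] * genes[t, s] * w
      out[k, s] <- if (d1 > 0 && d2 > 0) (num / d1) * (num / d2) else 0
    }
  }
  dimnames(out) <- list(paste(table$regulator, table$target, sep = "|"),
                        colnames(mirnas))
  out
}

# ER(t) per sample by explicit double loop.
brute_er <- function(table, mirnas, gene_ids) {
  ns <- ncol(mirnas)
  out <- matrix(0, length(gene_ids), ns, dimnames = list(gene_ids, colnames(mirnas)))
  for (t in gene_ids) {
    for (s in seq_len(ns)) {
      val <- 0
      for (k in which(table$target == t)) {
        r <- table$regulator[k]
        wsum <- sum(table$norm_weight[table$regulator == r])
        val <- val + mirnas[r, s] * table$norm_weight[k] / wsum
      }
      out[t, s] <- val
    }
  }
  out
}

# CR(S) by literal formula evaluation.
brute_cr <- function(gene_set, genes, er) {
  se <- rep(0, ncol(genes)); sx <- rep(0, ncol(genes))
  for (g in gene_set) {
    se <- se + er[g, ]
    sx <- sx + genes[g, ]
  }
  suppressWarnings(stats::cor(se, sx))
}

# Exact hypergeometric upper tail by combinatorial sum.
brute_hyper_tail <- function(overlap, size_a, size_b, universe) {
  ks <- overlap:min(size_a, size_b)
  if (overlap <= 0) return(1)
  sum(choose(size_a, ks) * choose(universe - size_a, size_b - ks)) /
    choose(universe, size_b)
}

# Random small interaction system for oracle-equivalence checks.
random_toy_system <- function(seed, n_mirnas = 3, n_genes = 5, n_samples = 8,
                              density = 0.7) {
  set.seed(seed)
  mir_ids <- paste0("m", seq_len(n_mirnas))
  gene_ids <- paste0("g", seq_len(n_genes))
  M <- matrix(runif(n_mirnas * n_samples, 0, 5), n_mirnas,
              dimnames = list(mir_ids, paste0("s", seq_len(n_samples))))
  G <- matrix(runif(n_genes * n_samples, 0, 10), n_genes,
              dimnames = list(gene_ids, paste0("s", seq_len(n_samples))))
  pairs <- expand.grid(regulator = mir_ids, target = gene_ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[runif(nrow(pairs)) < density, , drop = FALSE]
  # every miRNA and gene keeps at least one record
  for (m in setdiff(mir_ids, pairs$regulator))
    pairs <- rbind(pairs, data.frame(regulator = m, target = sample(gene_ids, 1)))
  for (g in setdiff(gene_ids, pairs$target))
    pairs <- rbind(pairs, data.frame(regulator = sample(mir_ids, 1), target = g))
  tab <- interaction_table(pairs$regulator, pairs$target,
                           raw_score = -runif(nrow(pairs), 0.1, 1),
                           rna_class = sample(c("mRNA", "lncRNA", "pseudogene"),
                                              nrow(pairs), replace = TRUE))
  tab$norm_weight <- runif(nrow(tab), 0.05, 1)
  list(table = tab, mirnas = M, genes = G)
}

# Tiny expression matrix helper.
expr_mat <- function(values, entities, samples = NULL) {
  m <- matrix(values, nrow = length(entities), byrow = TRUE)
  rownames(m) <- entities
  colnames(m) <- if (is.null(samples)) paste0("s", seq_len(ncol(m))) else samples
  m
}

# Minimal one-class interaction table.
simple_table <- function(regulator, target, raw_score, norm_weight = NULL) {
  tab <- interaction_table(regulator, target, raw_score,
                           rep("mRNA", length(regulator)))
  if (!is.null(norm_weight)) tab$norm_weight <- norm_weight
  tab
}
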