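# End-to-end orchestration: data preparation -> miRNA-target filtering ->
# pairwise ceRNA inference -> network deconvolution -> group inference, with
# a per-stage count report and optional TSV outputs. Fully deterministic
# under a fixed master seed (per-stage substreams are derived from it).

#' Pipeline configuration
#'
#' All tunable thresholds with their default calibration. The consensus
#' resample counts (1000 for the miRNA-target stage, 100 for the pair stage,
#' both at a 0.99 pass fraction), the correlation cutoffs (-0.1 miRNA-target,
#' -0.01 expression-vs-ER and CR, 0.55 partial correlation at p < 0.01,
#' hypergeometric alpha 0.01), the abundance cut (80th percentile of log IR
#' above -4.89), the top-40% score cut, the top-third retention after
#' deconvolution, and the 0.90 group fractions are the method's standard
#' operating point. `log_ir_threshold` and `partial_corr_min` were originally
#' calibrated as data quartiles, so both can be recomputed from the data at
#' hand (`ir_recalibrate`, `partial_corr_recalibrate`).
#'
#' @param ... Named overrides of the defaults listed above.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    low_expr_gene_min = 1, low_expr_mirna_zero = 0, low_expr_frac = 0.15,
    top_score_fraction = 0.40, weight_floor = 0.01,
    mirna_corr_threshold = -0.1, mirna_consensus_n = 1000L,
    log_ir_threshold = -4.89, ir_percentile = 0.80, ir_recalibrate = FALSE,
    er_corr_threshold = -0.01, er_consensus_n = 1000L,
    hypergeom_alpha = 0.01,
    partial_corr_min = 0.55, partial_corr_recalibrate = FALSE,
    partial_p_max = 0.01, cr_max = -0.01, pair_consensus_n = 100L,
    consensus_min_pass = 0.99,
    max_direct_eig = 0.9, deconv_fraction = 1 / 3, drop_nonpositive = TRUE,
    walk_length = 4L, member_frac = 0.90, neighbor_frac = 0.90,
    group_max_iter = 10000L,
    seed = 1L,
    gene_expression = NULL, mirna_expression = NULL, cna = NULL,
    interactions = NULL, out_dir = NULL)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) abort("unknown config field(s): %s", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @return For `read_pipeline_config`, a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  writeLines(yaml::as.yaml(vals, precision = 15), path)
  invisible(path)
}

stage_fail <- function(stage, threshold_note) {
  function(e) abort("stage '%s' emptied its working set (%s): %s",
                    stage, threshold_note, conditionMessage(e))
}

#' Run the full ceRNA inference pipeline
#'
#' Executes, in order: sample alignment and low-expression filtering; the
#' top-fraction binding-score cut and per-class score normalization; the
#' expression-anticorrelation filter with bootstrap consensus; Interaction
#' Regulation abundance filtering; Effective Regulation candidate-gene
#' selection; the common-regulator hypergeometric screen; the partial
#' correlation / Collective Regulation pair filter with consensus; network
#' deconvolution with top-fraction retention; and Walktrap group inference
#' with integration. Deterministic for a fixed config (all randomness is
#' derived from `config$seed`). When `config$out_dir` is set, all
#' intermediate and final tables are written there as TSV.
#'
#' @param genes,mirnas,cna Input matrices (genes/miRNAs/CNA x samples).
#' @param table An `interaction_table` with raw binding scores.
#' @param config A [pipeline_config()].
#' @return List with `grouped_network`, `network` (pairwise, post
#'   deconvolution), `pre_deconvolution` network, `groups`, `iterations`,
#'   `candidate_genes`, `er`, `final_interactions`, and `stage_report`.
#' @export
run_pipeline <- function(genes, mirnas, cna, table, config = pipeline_config()) {
  validate_matrix(genes, "gene"); validate_matrix(mirnas, "miRNA")
  validate_matrix(cna, "cna")
  report <- list()
  note <- function(stage, n_interactions = NA, n_genes = NA, n_pairs = NA) {
    report[[length(report) + 1L]] <<- data.frame(
      stage = stage, n_interactions = n_interactions, n_genes = n_genes,
      n_pairs = n_pairs, stringsAsFactors = FALSE)
  }

  al <- align_samples(genes, mirnas, cna)
  fl <- tryCatch(
    filter_low_expression(al$genes, al$mirnas, config$low_expr_gene_min,
                          config$low_expr_mirna_zero, config$low_expr_frac),
    error = stage_fail("low_expression", sprintf("gene < %g or miRNA = %g in >= %g of samples",
      config$low_expr_gene_min, config$low_expr_mirna_zero, config$low_expr_frac)))
  genes <- fl$genes; mirnas <- fl$mirnas; cna <- al$cna
  tab <- restrict_to_measured(table, mirnas, genes)
  note("input", nrow(tab), nrow(genes))

  tab <- select_top_interactions(tab, config$top_score_fraction)
  tab <- normalize_binding_scores(tab, config$weight_floor)
  note("top_score", nrow(tab), length(unique(tab$target)))

  cons_m <- consensus_config(config$mirna_consensus_n, config$consensus_min_pass,
                             stage_seed(config$seed, "mirna_corr"))
  tab <- tryCatch(
    expression_correlation_filter(tab, mirnas, genes,
                                  config$mirna_corr_threshold, cons_m),
    error = stage_fail("correlation_filter",
                       sprintf("corr < %g", config$mirna_corr_threshold)))
  if (nrow(tab) == 0L)
    abort("stage 'correlation_filter' emptied its working set (corr < %g)",
          config$mirna_corr_threshold)
  note("correlation", nrow(tab), length(unique(tab$target)))

  ir <- compute_interaction_regulation(tab, mirnas, genes)
  tab <- abundance_filter(tab, ir, config$log_ir_threshold,
                          config$ir_percentile, config$ir_recalibrate)
  if (nrow(tab) == 0L)
    abort("stage 'abundance_filter' emptied its working set (P%g of log IR > %g)",
          100 * config$ir_percentile, config$log_ir_threshold)
  note("abundance", nrow(tab), length(unique(tab$target)))

  er <- compute_effective_regulation(tab, mirnas, rownames(genes))
  cons_e <- consensus_config(config$er_consensus_n, config$consensus_min_pass,
                             stage_seed(config$seed, "er_filter"))
  candidates <- tryCatch(
    filter_genes_by_effective_regulation(genes, er, config$er_corr_threshold,
                                         cons_e),
    error = stage_fail("er_filter", sprintf("corr(Exp, ER) < %g",
                                            config$er_corr_threshold)))
  candidates <- intersect(candidates, rownames(cna))  # pair stage needs CNA
  candidates <- intersect(candidates, unique(tab$target))
  note("candidates", n_genes = length(candidates))

  pairs <- candidate_pair_screen(candidates, tab, config$hypergeom_alpha)
  if (nrow(pairs) == 0L)
    abort("stage 'pair_screen' emptied its working set (hypergeometric p < %g)",
          config$hypergeom_alpha)
  note("common_regulator", n_pairs = nrow(pairs))

  pc_min <- config$partial_corr_min
  if (isTRUE(config$partial_corr_recalibrate)) {
    rho <- rowwise_partial_cor(genes[pairs$gene_a, , drop = FALSE],
                               genes[pairs$gene_b, , drop = FALSE],
                               cna[pairs$gene_a, , drop = FALSE],
                               cna[pairs$gene_b, , drop = FALSE])
    pos <- rho[!is.na(rho) & rho > 0]
    if (length(pos)) pc_min <- unname(quantile(pos, 0.75, type = 7))
  }
  cons_p <- consensus_config(config$pair_consensus_n, config$consensus_min_pass,
                             stage_seed(config$seed, "pair"))
  pre <- tryCatch(
    pair_filter(pairs, genes, cna, er, pc_min, config$partial_p_max,
                config$cr_max, cons_p, config$weight_floor),
    error = stage_fail("pair_filter",
                       sprintf("partial corr > %g (p < %g), CR < %g", pc_min,
                               config$partial_p_max, config$cr_max)))
  note("pair_filter", n_pairs = nrow(pre$edges))

  dec <- deconvolve_network(pre, config$max_direct_eig)
  net <- tryCatch(
    rank_and_retain_edges(dec, config$deconv_fraction, config$drop_nonpositive),
    error = stage_fail("deconvolution",
                       sprintf("top %.3g of positive direct scores",
                               config$deconv_fraction)))
  note("deconvolution", n_pairs = nrow(net$edges))

  ref <- refine_groups(net, genes, er, tab, config$walk_length,
                       config$member_frac, config$neighbor_frac,
                       pc_min, config$cr_max, config$group_max_iter)
  gnet <- integrate_groups(net, ref$groups, ref$iterations)
  note("groups", n_genes = length(gnet$individual_nodes),
       n_pairs = nrow(gnet$edges))

  report <- do.call(rbind, report)
  out <- list(grouped_network = gnet, network = net, pre_deconvolution = pre,
              groups = ref$groups, iterations = ref$iterations,
              candidate_genes = candidates, er = er,
              final_interactions = tab, stage_report = report,
              config = config)
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

#' Run the pipeline from files named in the configuration
#'
#' Reads the four inputs from `config$gene_expression`,
#' `config$mirna_expression`, `config$cna` and `config$interactions`, then
#' calls [run_pipeline()].
#'
#' @param config A [pipeline_config()] with the input paths set.
#' @return See [run_pipeline()].
#' @export
run_pipeline_files <- function(config) {
  for (f in c("gene_expression", "mirna_expression", "cna", "interactions"))
    if (is.null(config[[f]])) abort("config$%s is not set", f)
  run_pipeline(read_expression_matrix(config$gene_expression, "gene"),
               read_expression_matrix(config$mirna_expression, "miRNA"),
               read_expression_matrix(config$cna, "cna"),
               read_interaction_table(config$interactions),
               config)
}

write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_interaction_table(res$final_interactions,
                          file.path(dir, "interactions_final.tsv"))
  writeLines(res$candidate_genes, file.path(dir, "candidate_genes.txt"))
  write_cerna_network(res$pre_deconvolution, file.path(dir, "pairs_pre_deconvolution.tsv"))
  write_cerna_network(res$network, file.path(dir, "network.tsv"))
  write_grouped_network(res$grouped_network, file.path(dir, "grouped"))
  write.table(res$stage_report, file.path(dir, "stage_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_pipeline_config(res$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Log-log fit of the degree distribution
#'
#' Ordinary least squares of log10 P(k) on log10 k over the observed degrees
#' with positive probability. A clearly negative slope with high R-squared is
#' the usual scale-free diagnostic for regulatory networks.
#'
#' @param net A `cerna_network` or `grouped_cerna_network`.
#' @return List with `slope` and `r_squared`.
#' @export
degree_distribution_fit <- function(net) {
  ends <- if (inherits(net, "cerna_network"))
    c(net$edges$gene_a, net$edges$gene_b)
  else c(net$edges$node_a, net$edges$node_b)
  if (!length(ends)) abort("network has no edges")
  deg <- table(ends)
  pk <- table(factor(deg)) / length(deg)
  k <- as.numeric(names(pk))
  if (length(k) < 3L) abort("need at least 3 distinct degrees for the fit")
  x <- log10(k); y <- log10(as.numeric(pk))
  fit <- stats::lm.fit(cbind(1, x), y)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(fit$coefficients[2L]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1)
}

#' Hypergeometric overlap test between two gene lists
#'
#' Upper-tail probability of the observed overlap between two sets drawn from
#' a common universe; the same kernel as the common-regulator test, reused
#' for gene-list enrichment audits.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector.
#' @return Upper-tail p-value.
#' @export
list_overlap_test <- function(set_a, set_b, universe) {
  common_regulator_pvalue(set_a, set_b, universe)$p
}
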