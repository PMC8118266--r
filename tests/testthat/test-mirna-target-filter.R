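test_that("anticorrelation filter keeps negative, drops constant and weak records", {
  ns <- 30
  set.seed(11)
  base <- runif(ns, 1, 5)
  mirnas <- rbind(m_neg = base,
                  m_const = rep(2, ns),
                  m_weak = runif(ns, 1, 5))
  colnames(mirnas) <- paste0("s", 1:ns)
  # weak target: tiny negative loading drowned in noise (sample corr ~ -0.05)
  genes <- rbind(g_neg = 10 - base,
                 g_const = 10 - base,
                 g_weak = 5 - 0.05 * mirnas["m_weak", ] + runif(ns, 0, 3))
  colnames(genes) <- colnames(mirnas)
  tab <- simple_table(c("m_neg", "m_const", "m_weak"),
                      c("g_neg", "g_const", "g_weak"), rep(-0.5, 3))
  cons <- consensus_config(200L, 0.99, seed = 4L)
  out <- expression_correlation_filter(tab, mirnas, genes, -0.1, cons)
  expect_identical(out$regulator, "m_neg")
  expect_equal(out$corr, -1)
  expect_equal(out$consensus_frac, 1)
})

test_that("consensus pass fraction is reproduced by an independent seeded re-run", {
  ns <- 40
  set.seed(21)
  x <- runif(ns, 1, 6)
  y <- 8 - x + rnorm(ns, sd = 2.2)   # borderline negative correlation
  mirnas <- matrix(x, 1, dimnames = list("m1", paste0("s", 1:ns)))
  genes <- matrix(y, 1, dimnames = list("g1", paste0("s", 1:ns)))
  tab <- simple_table("m1", "g1", -0.5)
  cons <- consensus_config(300L, 0.5, seed = 99L)
  out <- expression_correlation_filter(tab, mirnas, genes, -0.1, cons)
  expect_equal(nrow(out), 1L)

  idx <- spongenet:::resample_indices(cons, ns)
  manual <- mean(vapply(seq_len(nrow(idx)), function(b) {
    xb <- x[idx[b, ]]; yb <- y[idx[b, ]]
    if (sd(xb) == 0 || sd(yb) == 0) return(FALSE)
    cor(xb, yb) < -0.1
  }, logical(1)))
  expect_equal(out$consensus_frac, manual)
})

test_that("interaction regulation collapses correctly on a single edge", {
  mirnas <- expr_mat(c(2, 0, 4), "m1")
  genes <- expr_mat(c(3, 5, 7), "g1")
  tab <- simple_table("m1", "g1", -0.5, norm_weight = 0.37)
  ir <- compute_interaction_regulation(tab, mirnas, genes)$ir
  # both fractions collapse: IR = Exp(r) * Exp(t); zero expression gives 0
  expect_equal(unname(ir[1, ]), c(2 * 3, 0, 4 * 7))
})

test_that("interaction regulation matches the brute-force per-sample oracle", {
  for (seed in 1:8) {
    sys <- random_toy_system(seed, n_mirnas = sample(2:5, 1),
                             n_genes = sample(3:10, 1),
                             n_samples = sample(4:20, 1))
    ir <- compute_interaction_regulation(sys$table, sys$mirnas, sys$genes)$ir
    expect_equal(ir, brute_ir(sys$table, sys$mirnas, sys$genes),
                 tolerance = 1e-10)
  }
})

test_that("abundance filter uses the linear-interpolation percentile of log IR", {
  ns <- 10
  mirnas <- expr_mat(rep(1, 3 * ns), c("mA", "mB", "mC"))
  genes <- expr_mat(rep(1, 3 * ns), c("gA", "gB", "gC"))
  tab <- simple_table(c("mA", "mB", "mC"), c("gA", "gB", "gC"), rep(-0.5, 3),
                      norm_weight = rep(1, 3))
  reg <- compute_interaction_regulation(tab, mirnas, genes)
  # constant IR vectors at chosen levels
  reg$ir[1, ] <- exp(-4)                       # percentile -4    > -4.89 kept
  reg$ir[2, ] <- exp(-5)                       # percentile -5   <= -4.89 removed
  reg$ir[3, ] <- exp(c(rep(-5, 8), rep(-1, 2)))  # p80 = -5 + 0.2*4 = -4.2 kept
  out <- abundance_filter(tab, reg)
  expect_setequal(out$regulator, c("mA", "mC"))
  expect_equal(out$log_ir_p[out$regulator == "mC"], -4.2)
})

test_that("IR zero in a sample propagates as -Inf and fails high percentiles", {
  mirnas <- expr_mat(rep(1, 5), "m1")
  genes <- expr_mat(rep(1, 5), "g1")
  tab <- simple_table("m1", "g1", -0.5, norm_weight = 1)
  reg <- compute_interaction_regulation(tab, mirnas, genes)
  # 80th percentile interpolates from an -Inf order statistic -> rejected
  reg$ir[1, ] <- c(0, 0, 0, 0, 1)
  expect_equal(nrow(abundance_filter(tab, reg)), 0L)
  # but three zeros in five samples leave the 80th percentile finite -> kept
  reg$ir[1, ] <- c(0, 0, 0, 1, 1)
  expect_equal(nrow(abundance_filter(tab, reg)), 1L)
})

test_that("effective regulation collapses on single edges and splits weights", {
  mirnas <- expr_mat(c(2, 5, 1), "m1")
  # single target: ER(t) = Exp(r)
  tab1 <- simple_table("m1", "g1", -0.5, norm_weight = 0.42)
  er1 <- compute_effective_regulation(tab1, mirnas)
  expect_equal(unname(er1["g1", ]), c(2, 5, 1))
  # two targets with equal weights: each gets half the regulator's expression
  tab2 <- simple_table(c("m1", "m1"), c("g1", "g2"), c(-0.5, -0.5),
                       norm_weight = c(0.5, 0.5))
  er2 <- compute_effective_regulation(tab2, mirnas)
  expect_equal(unname(er2["g1", ]), 0.5 * c(2, 5, 1))
  # genes outside the table get ER identically zero
  er3 <- compute_effective_regulation(tab2, mirnas, gene_ids = c("g1", "g2", "g9"))
  expect_equal(unname(er3["g9", ]), rep(0, 3))
})

test_that("effective regulation matches the brute-force oracle and is scale-invariant", {
  for (seed in 11:16) {
    sys <- random_toy_system(seed, n_mirnas = sample(2:5, 1),
                             n_genes = sample(3:10, 1),
                             n_samples = sample(4:20, 1))
    gene_ids <- unique(sys$table$target)
    er <- compute_effective_regulation(sys$table, sys$mirnas)
    expect_equal(er[gene_ids, ], brute_er(sys$table, sys$mirnas, gene_ids),
                 tolerance = 1e-10)
    expect_true(all(er >= 0))
    # rescaling one miRNA's weights by a common factor leaves ER unchanged
    tab2 <- sys$table
    m <- tab2$regulator[1]
    tab2$norm_weight[tab2$regulator == m] <- 3.7 * tab2$norm_weight[tab2$regulator == m]
    expect_equal(compute_effective_regulation(tab2, sys$mirnas), er,
                 tolerance = 1e-12)
  }
})

test_that("candidate-gene filter keeps anticorrelated, excludes constant ER", {
  ns <- 25
  set.seed(31)
  e1 <- runif(ns, 1, 9)
  genes <- rbind(g_keep = e1, g_const = runif(ns, 1, 9), g_weak = runif(ns, 1, 9))
  colnames(genes) <- paste0("s", 1:ns)
  er <- rbind(g_keep = -e1 + 10, g_const = rep(2, ns),
              g_weak = -0.02 * genes["g_weak", ] + rnorm(ns, sd = 2))
  colnames(er) <- colnames(genes)
  cons <- consensus_config(200L, 0.99, seed = 5L)
  out <- filter_genes_by_effective_regulation(genes, er, -0.01, cons)
  expect_identical(out, "g_keep")
  # idempotence on the surviving set
  out2 <- filter_genes_by_effective_regulation(
    genes[out, , drop = FALSE], er[out, , drop = FALSE], -0.01, cons)
  expect_identical(out2, out)
})

test_that("filters are monotone: outputs are subsets of inputs", {
  sys <- random_toy_system(77, n_mirnas = 4, n_genes = 8, n_samples = 15)
  cons <- consensus_config(50L, 0.9, seed = 2L)
  out <- expression_correlation_filter(sys$table, sys$mirnas, sys$genes,
                                       0.5, cons)  # lax threshold
  expect_true(all(paste(out$regulator, out$target) %in%
                    paste(sys$table$regulator, sys$table$target)))
  reg <- compute_interaction_regulation(sys$table, sys$mirnas, sys$genes)
  ab <- abundance_filter(sys$table, reg, log_ir_threshold = -20)
  expect_true(all(paste(ab$regulator, ab$target) %in%
                    paste(sys$table$regulator, sys$table$target)))
  # applying the abundance filter twice equals applying it once
  reg2 <- compute_interaction_regulation(ab, sys$mirnas, sys$genes)
  expect_equal(nrow(abundance_filter(ab, reg2, log_ir_threshold = -20)), nrow(ab))
})
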