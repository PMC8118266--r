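# shared builders -----------------------------------------------------------

triangle_edges <- function(ids, w = 1) {
  data.frame(gene_a = ids[c(1, 1, 2)], gene_b = ids[c(2, 3, 3)], weight = w,
             stringsAsFactors = FALSE)
}

# expression/ER matrices where `members` follow one latent signal and their
# summed ER anticorrelates with summed expression
coherent_group_data <- function(members, others, ns = 40, seed = 1,
                                noise = 0.3) {
  set.seed(seed)
  u <- runif(ns, 1, 5)
  ids <- c(members, others)
  genes <- matrix(runif(length(ids) * ns, 1, 8), length(ids),
                  dimnames = list(ids, paste0("s", 1:ns)))
  er <- matrix(runif(length(ids) * ns, 0, 2), length(ids),
               dimnames = dimnames(genes))
  for (g in members) {
    genes[g, ] <- u + rnorm(ns, sd = noise)
    er[g, ] <- -u / length(members) + rnorm(ns, sd = 0.05)
  }
  list(genes = genes, er = er, u = u)
}

test_that("walktrap partition separates disconnected communities", {
  net <- cerna_network(rbind(triangle_edges(c("a1", "a2", "a3")),
                             triangle_edges(c("b1", "b2", "b3"))))
  parts <- detect_communities(net)
  expect_length(parts, 2L)
  expect_setequal(vapply(parts, function(p) paste(sort(p), collapse = ","), ""),
                  c("a1,a2,a3", "b1,b2,b3"))
})

test_that("walktrap partition splits a barbell at the bridge", {
  cl <- function(ids) {
    cmb <- t(combn(ids, 2))
    data.frame(gene_a = cmb[, 1], gene_b = cmb[, 2], weight = 1,
               stringsAsFactors = FALSE)
  }
  left <- paste0("L", 1:10); right <- paste0("R", 1:10)
  edges <- rbind(cl(left), cl(right),
                 data.frame(gene_a = "L1", gene_b = "R1", weight = 1))
  parts <- detect_communities(cerna_network(edges))
  expect_length(parts, 2L)
  expect_setequal(vapply(parts, function(p) paste(sort(p), collapse = ","), ""),
                  c(paste(sort(left), collapse = ","),
                    paste(sort(right), collapse = ",")))
})

test_that("group conditions pass on a coherent group with no neighbors", {
  members <- c("g1", "g2", "g3")
  d <- coherent_group_data(members, character(), seed = 2)
  net <- cerna_network(triangle_edges(members))
  tab <- simple_table(rep("mC", 3), members, rep(-0.5, 3), norm_weight = 1)
  ev <- evaluate_group(members, net, d$genes, d$er, tab)
  expect_true(ev$common_regulator_ok)   # all share mC
  expect_true(ev$regulation_ok)         # joint CR below every member's own corr
  expect_true(ev$compatibility_ok)      # vacuous: no neighbors
  expect_true(ev$valid)
  expect_lt(ev$group_cr, -0.9)
  expect_true(all(ev$group_cr < ev$member_corr))
})

test_that("pairwise-disjoint regulator sets fail the common-regulator condition", {
  members <- c("g1", "g2", "g3")
  d <- coherent_group_data(members, character(), seed = 3)
  net <- cerna_network(triangle_edges(members))
  tab <- simple_table(c("m1", "m2", "m3"), members, rep(-0.5, 3), norm_weight = 1)
  ev <- evaluate_group(members, net, d$genes, d$er, tab)
  expect_false(ev$common_regulator_ok)
  expect_false(ev$valid)
})

test_that("compatibility fraction equals per-neighbor enumeration", {
  members <- c("g1", "g2")
  nbrs <- paste0("n", 1:10)
  d <- coherent_group_data(members, nbrs, seed = 4, noise = 0.1)
  # 8 compatible neighbors: shadow the member signal; 2 incompatible: flat ER
  # pattern plus expression orthogonal to the members
  for (k in 1:8) {
    d$genes[nbrs[k], ] <- d$u + rnorm(ncol(d$genes), sd = 0.1)
    d$er[nbrs[k], ] <- -d$u + rnorm(ncol(d$genes), sd = 0.05)
  }
  for (k in 9:10) {
    d$genes[nbrs[k], ] <- 50 + rnorm(ncol(d$genes), sd = 0.01)
    d$er[nbrs[k], ] <- 60 + d$u   # pushes CR(S + n) positive
  }
  edges <- rbind(data.frame(gene_a = "g1", gene_b = "g2", weight = 1),
                 data.frame(gene_a = "g1", gene_b = nbrs, weight = 0.5))
  net <- cerna_network(edges)
  tab <- simple_table(c("mC", "mC", rep("mC", 8), "mX", "mY"),
                      c(members, nbrs), rep(-0.5, 12), norm_weight = 1)
  ev <- evaluate_group(members, net, d$genes, d$er, tab)
  expect_equal(ev$neighbor_frac, 0.8)
  expect_false(ev$compatibility_ok)

  # enumeration oracle: recount two-of-three per neighbor by hand
  sum_expr <- colSums(d$genes[members, ])
  manual <- vapply(nbrs, function(nb) {
    c1 <- nb %in% tab$target[tab$regulator == "mC"]
    c2 <- cor(sum_expr, d$genes[nb, ]) > 0.55
    crn <- cor(colSums(d$er[c(members, nb), ]), colSums(d$genes[c(members, nb), ]))
    c3 <- !is.na(crn) && crn < -0.01
    sum(c(c1, c2, c3)) >= 2
  }, logical(1))
  expect_equal(ev$neighbor_frac, mean(manual))
})

test_that("refinement splits a merged community into its valid blocks", {
  tri_a <- c("a1", "a2", "a3"); tri_b <- c("b1", "b2", "b3")
  clique <- paste0("c", 1:8)
  cmb <- t(combn(clique, 2))
  edges <- rbind(triangle_edges(tri_a), triangle_edges(tri_b),
                 data.frame(gene_a = "a1", gene_b = "b1", weight = 1),
                 data.frame(gene_a = cmb[, 1], gene_b = cmb[, 2], weight = 1))
  net <- cerna_network(edges)
  d <- coherent_group_data(c(tri_a, tri_b), clique, seed = 5, noise = 0.25)
  # regulator design: triangles share mA / mB respectively (bridge gene b1
  # carries both), the whole prism shares nothing; clique genes are disjoint
  tab <- simple_table(
    c(rep("mA", 3), "mA", rep("mB", 3), paste0("mc", 1:8)),
    c(tri_a, "b1", tri_b, clique),
    rep(-0.5, 15), norm_weight = 1)
  res <- refine_groups(net, d$genes, d$er, tab)
  got <- lapply(res$groups, function(g) sort(g$members))
  expect_length(res$groups, 2L)
  expect_setequal(vapply(got, paste, "", collapse = ","),
                  c("a1,a2,a3", "b1,b2,b3"))
  expect_setequal(res$individual_nodes, clique)
  # full pass + prism re-split + clique re-split
  expect_equal(res$iterations, 3L)
  # every emitted group has >= 2 members and a nonempty common-regulator set
  for (g in res$groups) {
    expect_gte(length(g$members), 2L)
    expect_gt(length(g$common_regulators), 0L)
  }
  # disjointness: groups and individual nodes partition the node set
  all_members <- unlist(lapply(res$groups, `[[`, "members"))
  expect_setequal(c(all_members, res$individual_nodes), net$nodes)
  expect_equal(anyDuplicated(all_members), 0L)
})

test_that("an invalid two-gene community dissolves into individual nodes", {
  net <- cerna_network(data.frame(gene_a = "g1", gene_b = "g2", weight = 1))
  d <- coherent_group_data(character(), c("g1", "g2"), seed = 6)
  tab <- simple_table(c("m1", "m2"), c("g1", "g2"), rep(-0.5, 2), norm_weight = 1)
  res <- refine_groups(net, d$genes, d$er, tab)
  expect_length(res$groups, 0L)
  expect_setequal(res$individual_nodes, c("g1", "g2"))
  expect_equal(res$iterations, 1L)
})

test_that("a fully valid first pass finishes in one iteration", {
  members <- c("g1", "g2", "g3")
  d <- coherent_group_data(members, character(), seed = 7)
  net <- cerna_network(triangle_edges(members))
  tab <- simple_table(rep("mC", 3), members, rep(-0.5, 3), norm_weight = 1)
  res <- refine_groups(net, d$genes, d$er, tab)
  expect_length(res$groups, 1L)
  expect_equal(res$iterations, 1L)
})

test_that("group integration absorbs intra-group edges and rewires neighbors", {
  net <- cerna_network(data.frame(gene_a = c("g1", "g1"),
                                  gene_b = c("g2", "n"),
                                  weight = c(0.9, 0.4)))
  grp <- structure(list(members = c("g1", "g2"), common_regulators = "mC",
                        group_cr = -0.8), class = "cerna_group")
  gnet <- integrate_groups(net, list(grp))
  expect_setequal(gnet$individual_nodes, "n")
  expect_equal(nrow(gnet$edges), 1L)
  expect_setequal(c(gnet$edges$node_a, gnet$edges$node_b), c("G1", "n"))
  expect_equal(gnet$edges$weight, 0.4)

  # group with only intra-group edges becomes an isolated group node
  net2 <- cerna_network(data.frame(gene_a = "g1", gene_b = "g2", weight = 1))
  gnet2 <- integrate_groups(net2, list(grp))
  expect_equal(nrow(gnet2$edges), 0L)
  expect_length(gnet2$individual_nodes, 0L)
  expect_length(gnet2$groups, 1L)

  # group-group edges take the maximum absorbed weight
  net3 <- cerna_network(data.frame(gene_a = c("g1", "g3", "g1", "g2"),
                                   gene_b = c("g2", "g4", "g3", "g4"),
                                   weight = c(1, 1, 0.3, 0.6)))
  grp2 <- structure(list(members = c("g3", "g4"), common_regulators = "mD",
                         group_cr = -0.7), class = "cerna_group")
  gnet3 <- integrate_groups(net3, list(grp, grp2))
  expect_equal(nrow(gnet3$edges), 1L)
  expect_equal(gnet3$edges$weight, 0.6)
  expect_setequal(gnet3$edges$kind_a, "group")

  # overlapping groups are rejected
  bad <- structure(list(members = c("g2", "g3"), common_regulators = "mE",
                        group_cr = -0.5), class = "cerna_group")
  expect_error(integrate_groups(net3, list(grp, bad)), "disjoint")
})
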