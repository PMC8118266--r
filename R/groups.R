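# ceRNA group inference: Walktrap communities on the weighted pairwise
# network, validated against three conditions (shared regulator, stronger
# collective regulation than the members individually, compatibility with the
# surrounding network), with iterative splitting of failing communities.

#' Detect communities on a weighted ceRNA network
#'
#' Runs Walktrap (short random walks agglomerated at the modularity-optimal
#' cut) on the weighted graph. Deterministic for a fixed input.
#'
#' @param net A `cerna_network`.
#' @param walk_length Random-walk length (default 4).
#' @return List of character vectors, one per community (a partition of the
#'   node set); empty list for an empty network.
#' @export
detect_communities <- function(net, walk_length = 4L) {
  if (length(net$nodes) == 0L) return(list())
  g <- as_igraph(net)
  walktrap_partition(g, walk_length)
}

# Walktrap partition of an igraph object; singleton components included.
walktrap_partition <- function(g, walk_length) {
  if (igraph::vcount(g) == 0L) return(list())
  if (igraph::ecount(g) == 0L)
    return(as.list(igraph::V(g)$name))
  wt <- igraph::cluster_walktrap(g, weights = igraph::E(g)$weight,
                                 steps = walk_length)
  memb <- igraph::membership(wt)
  unname(split(names(memb), memb))
}

#' Evaluate the three ceRNA group conditions
#'
#' For a candidate group S on the pairwise network:
#' \enumerate{
#'   \item \emph{Common regulator}: the intersection of all members' regulator
#'     sets is nonempty.
#'   \item \emph{Strong regulation effect}: the group's Collective Regulation
#'     CR(S) is strictly below corr(Exp(g), ER(g)) for at least `member_frac`
#'     of the members, and the mean of corr(Exp(g), ER(g)) - CR(S) over
#'     members is positive (the group is more strongly regulated jointly than
#'     its members are individually).
#'   \item \emph{Network compatibility}: every gene outside S adjacent to a
#'     member is a neighbor; at least `neighbor_frac` of neighbors must
#'     satisfy two of: (i) a shared regulator with the group's common set,
#'     (ii) Pearson correlation between the summed member expression and the
#'     neighbor's expression above `pearson_min`, (iii) CR(S + neighbor)
#'     below `cr_max`. Vacuously true with no neighbors.
#' }
#' Undefined correlations count as condition failures.
#'
#' @param members Character vector of member gene ids (>= 2).
#' @param net The pairwise `cerna_network`.
#' @param genes Gene expression matrix.
#' @param er ER matrix.
#' @param table The final `interaction_table` (regulator sets).
#' @param member_frac,neighbor_frac Required fractions (defaults 0.90).
#' @param pearson_min Threshold for neighbor sub-condition (ii) (default 0.55).
#' @param cr_max Threshold for CR-based conditions (default -0.01).
#' @return List of class `cerna_group`: `members`, `common_regulators`,
#'   `group_cr`, and logicals `common_regulator_ok`, `regulation_ok`,
#'   `compatibility_ok`, `valid`.
#' @export
evaluate_group <- function(members, net, genes, er, table,
                           member_frac = 0.90, neighbor_frac = 0.90,
                           pearson_min = 0.55, cr_max = -0.01) {
  members <- unique(members)
  if (length(members) < 2L) abort("a ceRNA group needs at least 2 members")
  miss <- setdiff(members, net$nodes)
  if (length(miss)) abort("group member(s) not in the network: %s",
                          paste(utils::head(miss, 3), collapse = ", "))
  sets <- regulator_sets(table)
  common <- Reduce(intersect, lapply(members, function(g)
    unique(sets[[g]] %||% character())))
  cond1 <- length(common) > 0L

  group_cr <- collective_regulation(members, genes, er)
  mcorr <- vapply(members, function(g)
    safe_cor(genes[g, ], er[g, ]), numeric(1))
  if (is.na(group_cr)) {
    cond2 <- FALSE
  } else {
    stronger <- !is.na(mcorr) & group_cr < mcorr
    diffs <- mcorr - group_cr
    cond2 <- mean(stronger) >= member_frac &&
      !all(is.na(diffs)) && mean(diffs, na.rm = TRUE) > 0
  }

  e <- net$edges
  touch <- e$gene_a %in% members | e$gene_b %in% members
  nbrs <- setdiff(unique(c(e$gene_a[touch], e$gene_b[touch])), members)
  if (length(nbrs) == 0L) {
    cond3 <- TRUE
    nb_frac <- NA_real_
  } else {
    sum_expr <- colSums(genes[members, , drop = FALSE])
    npass <- vapply(nbrs, function(nb) {
      c1 <- length(intersect(common, unique(sets[[nb]] %||% character()))) > 0L
      r <- safe_cor(sum_expr, genes[nb, ])
      c2 <- !is.na(r) && r > pearson_min
      crn <- if (nb %in% rownames(er)) collective_regulation(c(members, nb), genes, er)
             else NA_real_
      c3 <- !is.na(crn) && crn < cr_max
      sum(c(c1, c2, c3)) >= 2L
    }, logical(1))
    nb_frac <- mean(npass)
    cond3 <- nb_frac >= neighbor_frac
  }

  structure(list(members = members, common_regulators = common,
                 group_cr = group_cr, member_corr = mcorr,
                 neighbor_frac = nb_frac,
                 common_regulator_ok = cond1, regulation_ok = cond2,
                 compatibility_ok = cond3,
                 valid = cond1 && cond2 && cond3),
            class = "cerna_group")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Iteratively refine Walktrap communities into valid ceRNA groups
#'
#' Worklist algorithm: Walktrap partitions the full network once; every
#' community of two or more genes is evaluated against the three group
#' conditions. Valid communities become groups. An invalid community is
#' re-split by running Walktrap on its induced subgraph and the parts
#' re-enter the worklist; two-gene communities, single-gene parts, and
#' communities whose re-split returns them unchanged dissolve into individual
#' nodes. `iterations` counts community-detection invocations; every split
#' strictly decreases the set size, so the algorithm terminates in fewer than
#' 2 |V| invocations.
#'
#' @param net The pairwise `cerna_network`.
#' @param genes,er,table Data for [evaluate_group()].
#' @param walk_length Walktrap walk length (default 4).
#' @param member_frac,neighbor_frac,pearson_min,cr_max Group-condition
#'   parameters, see [evaluate_group()].
#' @param max_iter Hard cap on community-detection invocations.
#' @return List with `groups` (valid `cerna_group`s), `iterations`, and
#'   `individual_nodes`.
#' @export
refine_groups <- function(net, genes, er, table, walk_length = 4L,
                          member_frac = 0.90, neighbor_frac = 0.90,
                          pearson_min = 0.55, cr_max = -0.01,
                          max_iter = 10000L) {
  g <- as_igraph(net)
  iterations <- 1L
  worklist <- walktrap_partition(g, walk_length)
  groups <- list()
  while (length(worklist)) {
    members <- worklist[[1L]]
    worklist <- worklist[-1L]
    if (length(members) < 2L) next          # dissolves to an individual node
    ev <- evaluate_group(members, net, genes, er, table,
                         member_frac = member_frac,
                         neighbor_frac = neighbor_frac,
                         pearson_min = pearson_min, cr_max = cr_max)
    if (ev$valid) {
      groups[[length(groups) + 1L]] <- ev
      next
    }
    if (length(members) == 2L) next         # cannot split further; dissolve
    if (iterations >= max_iter)
      abort("group refinement exceeded %d community-detection invocations", max_iter)
    sub <- igraph::induced_subgraph(g, members)
    parts <- walktrap_partition(sub, walk_length)
    iterations <- iterations + 1L
    if (length(parts) == 1L) next           # unsplittable; dissolve
    worklist <- c(worklist, parts)
  }
  grouped <- unlist(lapply(groups, `[[`, "members"))
  list(groups = groups, iterations = iterations,
       individual_nodes = setdiff(net$nodes, grouped))
}

#' Integrate validated groups into the network
#'
#' Each group collapses to a single node: intra-group edges are absorbed, and
#' for every outside node adjacent to at least one member a single edge to
#' the group node is created with weight equal to the maximum absorbed edge
#' weight (group-group edges arise the same way). Member genes disappear as
#' individual nodes.
#'
#' @param net The pairwise `cerna_network`.
#' @param groups List of valid, disjoint `cerna_group` objects.
#' @param iterations Optional Walktrap invocation count to record.
#' @return List of class `grouped_cerna_network` with `individual_nodes`,
#'   `groups` (named `G1`, `G2`, ...), `edges` (columns `node_a`, `node_b`,
#'   `kind_a`, `kind_b`, `weight`), and `walktrap_iterations`.
#' @export
integrate_groups <- function(net, groups, iterations = NA_integer_) {
  members_all <- unlist(lapply(groups, `[[`, "members"))
  if (anyDuplicated(members_all)) abort("groups must be disjoint")
  if (length(setdiff(members_all, net$nodes)))
    abort("group members must be network nodes")
  gid <- if (length(groups)) paste0("G", seq_along(groups)) else character()
  names(groups) <- gid
  node_map <- setNames(net$nodes, net$nodes)
  for (i in seq_along(groups)) node_map[groups[[i]]$members] <- gid[i]

  e <- net$edges
  a <- unname(node_map[e$gene_a]); b <- unname(node_map[e$gene_b])
  keep <- a != b                              # intra-group edges absorbed
  a <- a[keep]; b <- b[keep]; w <- e$weight[keep]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(a, b, sep = "\r")
  if (length(key)) {
    wmax <- tapply(w, key, max)
    parts <- strsplit(names(wmax), "\r", fixed = TRUE)
    edges <- data.frame(node_a = vapply(parts, `[`, "", 1L),
                        node_b = vapply(parts, `[`, "", 2L),
                        weight = as.numeric(wmax), stringsAsFactors = FALSE)
    edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(node_a = character(), node_b = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  kind <- function(x) ifelse(x %in% gid, "group", "gene")
  edges$kind_a <- kind(edges$node_a)
  edges$kind_b <- kind(edges$node_b)
  structure(list(individual_nodes = setdiff(net$nodes, members_all),
                 groups = groups, edges = edges,
                 walktrap_iterations = iterations),
            class = "grouped_cerna_network")
}

#' @export
print.grouped_cerna_network <- function(x, ...) {
  cat(sprintf("grouped ceRNA network: %d individual genes + %d groups, %d edges\n",
              length(x$individual_nodes), length(x$groups), nrow(x$edges)))
  invisible(x)
}

#' Write groups and the grouped network to TSV
#'
#' `<path_prefix>_groups.tsv` holds one row per group (members and common
#' regulators comma-separated, group CR); `<path_prefix>_edges.tsv` holds the
#' grouped edge list with node-kind columns.
#'
#' @param gnet A `grouped_cerna_network`.
#' @param path_prefix Output path prefix.
#' @export
write_grouped_network <- function(gnet, path_prefix) {
  groups_df <- data.frame(
    group_id = names(gnet$groups),
    members = vapply(gnet$groups, function(g) paste(g$members, collapse = ","), ""),
    common_regulators = vapply(gnet$groups, function(g)
      paste(g$common_regulators, collapse = ","), ""),
    group_cr = vapply(gnet$groups, `[[`, numeric(1), "group_cr"),
    stringsAsFactors = FALSE)
  write.table(groups_df, paste0(path_prefix, "_groups.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(gnet$edges, paste0(path_prefix, "_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path_prefix)
}
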