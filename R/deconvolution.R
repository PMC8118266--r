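# Network deconvolution: two genes with many common ceRNA partners show
# inflated (amplified) correlation, so the observed network is treated as
# direct effects plus all transitive closures, G_obs = G_dir + G_dir^2 + ...,
# and inverted in closed form through the eigendecomposition.

#' Deconvolve a ceRNA network into direct-edge scores
#'
#' Builds the symmetric weighted adjacency matrix of the network and applies
#' the closed-form deconvolution: with eigendecomposition G = V L V', each
#' eigenvalue is mapped to `beta * l / (1 + beta * l)`, where the scaling
#' `beta > 0` is the largest value keeping every mapped eigenvalue within
#' `max_direct_eig` in absolute value (which also keeps the series
#' convergent). The direct-score matrix is V diag(mapped) V'. Only entries at
#' observed edge positions are used downstream; no new edges are introduced.
#'
#' @param net A `cerna_network` with weights in (0, 1].
#' @param max_direct_eig Spectral bound on the direct matrix (default 0.9).
#' @return List of class `deconvolution_result` with `direct_scores`
#'   (symmetric matrix over nodes), `beta`, and `edges` (the input edge table
#'   with a `direct_score` column).
#' @export
deconvolve_network <- function(net, max_direct_eig = 0.9) {
  if (!is.numeric(max_direct_eig) || max_direct_eig <= 0 || max_direct_eig >= 1)
    abort("max_direct_eig must be in (0, 1)")
  nodes <- net$nodes
  G <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  G[cbind(net$edges$gene_a, net$edges$gene_b)] <- net$edges$weight
  G <- G + t(G)
  if (any(!is.finite(G))) abort("adjacency contains non-finite weights")
  eg <- eigen(G, symmetric = TRUE)
  lam <- eg$values
  lmax <- max(lam); lmin <- min(lam)
  d <- max_direct_eig
  # beta*l/(1+beta*l) <= d for l = lmax  and  >= -d for l = lmin
  cand <- c(if (lmax > 0) d / ((1 - d) * lmax),
            if (lmin < 0) -d / ((1 + d) * lmin))
  if (!length(cand)) {                       # zero matrix
    D <- G
    beta <- 1
  } else {
    beta <- min(cand)
    ldir <- beta * lam / (1 + beta * lam)
    D <- eg$vectors %*% (ldir * t(eg$vectors))
    D <- (D + t(D)) / 2
    dimnames(D) <- dimnames(G)
  }
  edges <- net$edges
  edges$direct_score <- D[cbind(edges$gene_a, edges$gene_b)]
  structure(list(direct_scores = D, beta = beta, edges = edges),
            class = "deconvolution_result")
}

#' Retain the top fraction of deconvolved edges
#'
#' Observed edges are ranked by direct score, descending. Edges with
#' non-positive direct scores are dropped first (by default); of the
#' remainder, the top `ceiling(fraction * E)` are kept, with boundary ties
#' kept. Nodes left without edges are removed from the network.
#'
#' @param result A `deconvolution_result`.
#' @param fraction Fraction of (positive-scored) edges to keep (default 1/3).
#' @param drop_nonpositive Drop edges with direct score <= 0 before ranking
#'   (default TRUE).
#' @return A `cerna_network` of retained edges (with `direct_score` column).
#' @export
rank_and_retain_edges <- function(result, fraction = 1 / 3,
                                  drop_nonpositive = TRUE) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    abort("fraction must be in (0, 1]")
  edges <- result$edges
  if (drop_nonpositive) edges <- edges[edges$direct_score > 0, , drop = FALSE]
  if (nrow(edges) == 0L) abort("no edges with positive direct score remain")
  k <- ceiling(fraction * nrow(edges))
  cut <- -sort(-edges$direct_score, partial = k)[k]
  # boundary ties are kept; the tolerance makes tie detection robust to
  # eigendecomposition rounding between otherwise identical edges
  tol <- 1e-8 * max(abs(edges$direct_score))
  keep <- edges[edges$direct_score >= cut - tol, , drop = FALSE]
  cerna_network(keep)
}
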