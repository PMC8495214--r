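#' Configuration for the explicit centrality feature block
#'
#' The canonical schema carries 12 centrality measures spanning the
#' degree, shortest-path, spectral, flow and core families: degree
#' centrality, betweenness, closeness, harmonic closeness, eigenvector,
#' PageRank, Katz, load, subgraph centrality, current-flow closeness
#' (information centrality), current-flow betweenness, and coreness
#' (k-core number). All are computed on the unweighted topology; edge
#' weights enter the feature matrix only through the weighted degree and
#' the weighted recursive features.
#'
#' @param centralities ordered character vector of measure names; the
#'   canonical list of 12 by default.
#' @param tolerance convergence tolerance for iterative measures.
#' @param max_iter iteration cap for iterative measures.
#' @param damping PageRank damping factor.
#' @param katz_alpha Katz attenuation factor (must stay below the
#'   reciprocal spectral radius of the adjacency matrix).
#' @param max_clique_nodes node-count guard for maximal-clique
#'   enumeration, which is exponential in the worst case.
#' @return list of class `centrality_config`.
#' @export
centrality_config <- function(centralities = c(
                                "cent_degree", "cent_betweenness", "cent_closeness",
                                "cent_harmonic", "cent_eigenvector", "cent_pagerank",
                                "cent_katz", "cent_load", "cent_subgraph",
                                "cent_info_closeness", "cent_cf_betweenness",
                                "cent_coreness"),
                              tolerance = 1e-8, max_iter = 1000L,
                              damping = 0.85, katz_alpha = 0.005,
                              max_clique_nodes = 50000L) {
  structure(list(centralities = centralities, tolerance = tolerance,
                 max_iter = as.integer(max_iter), damping = damping,
                 katz_alpha = katz_alpha,
                 max_clique_nodes = as.integer(max_clique_nodes)),
            class = "centrality_config")
}

# unweighted simple graph for topology-based measures
.topology <- function(net) {
  g <- as_igraph(net)
  igraph::delete_edge_attr(g, "weight")
}

# Katz centrality: x = (I - alpha A)^{-1} 1, scaled to unit 2-norm
.katz_centrality <- function(A, alpha) {
  n <- nrow(A)
  x <- tryCatch(
    as.numeric(Matrix::solve(Matrix::Diagonal(n) - alpha * A, rep(1, n))),
    error = function(e) stop(sprintf("katz centrality failed on %d nodes: %s",
                                     n, conditionMessage(e))))
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("katz centrality did not converge (attenuation %g too large for %d nodes)",
                 alpha, n))
  }
  x / sqrt(sum(x^2))
}

# Load centrality (Goh/Newman): unit packets from every source split
# evenly among shortest-path predecessors; no flow enters the source.
# Normalized by (n-1)(n-2) over ordered pairs.
.load_centrality <- function(nbrs, n) {
  if (n < 3) return(numeric(n))
  load <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n); dist[s] <- 0L
    frontier <- s; visited <- s; d <- 0L
    while (length(frontier)) {
      nxt <- unique(unlist(nbrs[frontier], use.names = FALSE))
      nxt <- nxt[is.na(dist[nxt])]
      if (!length(nxt)) break
      d <- d + 1L
      dist[nxt] <- d
      visited <- c(visited, nxt)
      frontier <- nxt
    }
    b <- rep(1, n)
    for (v in rev(visited)) {
      if (v == s) next
      nb <- nbrs[[v]]
      preds <- nb[dist[nb] == (dist[v] - 1L)]
      preds <- preds[!is.na(preds)]
      share <- b[v] / length(preds)
      preds <- preds[preds != s]
      if (length(preds)) b[preds] <- b[preds] + share
    }
    reach <- which(!is.na(dist))
    reach <- reach[reach != s]
    load[reach] <- load[reach] + b[reach] - 1
  }
  load / ((n - 1) * (n - 2))
}

# Current-flow measures on one connected component, from the inverse of
# (L + J/n): potentials differ from the Laplacian pseudoinverse only by a
# constant that cancels in every formula used here.
.current_flow_component <- function(A_comp) {
  nc <- nrow(A_comp)
  info <- numeric(nc); cfb <- numeric(nc)
  if (nc == 1) return(list(info = info, cfb = cfb))
  L <- diag(Matrix::rowSums(A_comp)) - as.matrix(A_comp)
  C <- solve(L + 1 / nc)
  # information centrality = (nc-1) / sum of effective resistances
  res_sum <- nc * diag(C) + sum(diag(C)) - 2 * rowSums(C)
  info <- (nc - 1) / res_sum
  if (nc >= 3) {
    eidx <- which(as.matrix(A_comp) != 0 & upper.tri(A_comp), arr.ind = TRUE)
    P <- numeric(nc); Q <- numeric(nc)
    for (k in seq_len(nrow(eidx))) {
      i <- eidx[k, 1]; j <- eidx[k, 2]
      d <- C[i, ] - C[j, ]
      x <- sort(d)
      S <- sum((2 * seq_len(nc) - nc - 1) * x)  # sum over pairs of |d_s - d_t|
      P[i] <- P[i] + S / 2; P[j] <- P[j] + S / 2
      Q[i] <- Q[i] + sum(abs(d[i] - d[-i])) / 2
      Q[j] <- Q[j] + sum(abs(d[j] - d[-j])) / 2
    }
    cfb <- (P - Q) / ((nc - 1) * (nc - 2) / 2)
  }
  list(info = info, cfb = cfb)
}

#' Per-node centrality suite
#'
#' Computes the 12-column canonical centrality block on the unweighted
#' topology. Measures that are only defined within a connected component
#' (closeness, eigenvector, current-flow measures) are computed per
#' component with component-size normalization, so every value is finite
#' even on disconnected graphs; isolated nodes score zero throughout.
#'
#' @param net an `interactome`.
#' @param cfg a [centrality_config()].
#' @return numeric matrix, rows = nodes, 12 named columns in canonical
#'   order.
#' @export
centrality_suite <- function(net, cfg = centrality_config()) {
  stopifnot(inherits(net, "interactome"), length(net$nodes) >= 1)
  g <- .topology(net)
  n <- igraph::vcount(g)
  A <- .adjacency(net)$A
  deg <- Matrix::rowSums(A)
  comp <- igraph::components(g)$membership

  out <- matrix(0, n, 12,
                dimnames = list(net$nodes, centrality_config()$centralities))
  out[, "cent_degree"] <- if (n > 1) deg / (n - 1) else 0
  out[, "cent_betweenness"] <- if (n > 2) {
    igraph::betweenness(g, weights = NA, normalized = TRUE)
  } else 0
  # closeness/harmonic within components, component-size normalization
  harm <- igraph::harmonic_centrality(g, weights = NA, normalized = FALSE)
  out[, "cent_harmonic"] <- if (n > 1) harm / (n - 1) else 0
  for (cc in unique(comp)) {
    v <- which(comp == cc); nc <- length(v)
    if (nc == 1) next
    sg <- igraph::induced_subgraph(g, v)
    dsum <- Matrix::rowSums(igraph::distances(sg, weights = NA))
    out[v, "cent_closeness"] <- (nc - 1) / dsum
    ev <- igraph::eigen_centrality(sg, weights = NA,
                                   options = list(maxiter = cfg$max_iter,
                                                  tol = cfg$tolerance))$vector
    out[v, "cent_eigenvector"] <- ev
    cf <- .current_flow_component(A[v, v, drop = FALSE])
    out[v, "cent_info_closeness"] <- cf$info
    out[v, "cent_cf_betweenness"] <- cf$cfb
  }
  out[, "cent_pagerank"] <- igraph::page_rank(g, weights = NA,
                                              damping = cfg$damping)$vector
  out[, "cent_katz"] <- .katz_centrality(A, cfg$katz_alpha)
  nbrs <- igraph::adjacent_vertices(g, igraph::V(g))
  nbrs <- lapply(nbrs, as.integer)
  out[, "cent_load"] <- .load_centrality(nbrs, n)
  out[, "cent_subgraph"] <- igraph::subgraph_centrality(g, diag = FALSE)
  out[, "cent_coreness"] <- igraph::coreness(g)
  out[, cfg$centralities[cfg$centralities %in% colnames(out)], drop = FALSE]
}

#' Per-node clique number
#'
#' For every node, the size of the largest maximal clique that contains
#' it. Uses maximal-clique enumeration, which is exponential in the worst
#' case; graphs above `max_nodes` raise an error rather than hang.
#'
#' @param net an `interactome`.
#' @param max_nodes node-count guard (default 50000).
#' @return named numeric vector over nodes (isolated node: 1).
#' @export
clique_number_per_node <- function(net, max_nodes = 50000L) {
  if (length(net$nodes) > max_nodes) {
    stop(sprintf("clique enumeration refused on %d nodes (guard: %d)",
                 length(net$nodes), max_nodes))
  }
  g <- .topology(net)
  res <- rep(1, igraph::vcount(g))
  for (cl in igraph::max_cliques(g)) {
    i <- as.integer(cl)
    res[i] <- pmax(res[i], length(i))
  }
  names(res) <- net$nodes
  res
}

#' Clustering coefficient, biconnected-component membership, weighted degree
#'
#' Three explicit structural columns: the unweighted local clustering
#' coefficient (0 for nodes of degree < 2), the number of biconnected
#' components (blocks) the node belongs to (articulation points > 1,
#' isolated nodes 0), and the weighted degree (sum of incident edge
#' weights).
#'
#' @param net an `interactome`.
#' @return numeric matrix with columns `clustering_coef`, `biconn_count`,
#'   `weighted_degree`.
#' @export
clustering_and_structure <- function(net) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[!is.finite(cc)] <- 0
  bc <- igraph::biconnected_components(g)
  counts <- numeric(n)
  for (blk in bc$components) {
    i <- as.integer(blk)
    counts[i] <- counts[i] + 1
  }
  wdeg <- igraph::strength(g)
  out <- cbind(clustering_coef = cc, biconn_count = counts,
               weighted_degree = as.numeric(wdeg))
  rownames(out) <- net$nodes
  out
}

#' The 16-column explicit graph-feature block
#'
#' Canonical order: the 12 centralities of [centrality_suite()], then
#' clique number, clustering coefficient, biconnected-component count and
#' weighted degree.
#'
#' @param net an `interactome`.
#' @param cfg a [centrality_config()].
#' @return numeric matrix, rows = nodes, 16 named columns.
#' @export
explicit_features <- function(net, cfg = centrality_config()) {
  cs <- centrality_suite(net, cfg)
  cl <- clique_number_per_node(net, max_nodes = cfg$max_clique_nodes)
  st <- clustering_and_structure(net)
  cbind(cs, clique_number = cl, st)
}

#' Assemble the canonical 283-column feature matrix
#'
#' Horizontally concatenates the recursive (ReFeX) block and the explicit
#' graph-feature block, recursive block first. Both blocks must index the
#' same genes.
#'
#' @param refex_block matrix from [refex()] (canonically 267 columns).
#' @param explicit_block matrix from [explicit_features()] (16 columns).
#' @return numeric matrix over the shared genes, canonically 283 columns.
#' @export
assemble_feature_matrix <- function(refex_block, explicit_block) {
  a <- rownames(refex_block); b <- rownames(explicit_block)
  if (!setequal(a, b)) {
    diff <- c(setdiff(a, b), setdiff(b, a))
    stop(sprintf("gene sets differ between blocks; symmetric difference: %s",
                 paste(utils::head(diff, 10), collapse = ", ")))
  }
  out <- cbind(refex_block, explicit_block[a, , drop = FALSE])
  attr(out, "generation") <- NULL
  out
}

#' Extract the full canonical feature matrix of an interactome
#'
#' Convenience wrapper running [refex()] and [explicit_features()] and
#' assembling the canonical 283-column (267 + 16) per-gene matrix.
#'
#' @param net an `interactome`.
#' @param refex_cfg a [refex_config()].
#' @param centrality_cfg a [centrality_config()].
#' @return numeric matrix, rows = genes, 283 named columns.
#' @export
extract_features <- function(net, refex_cfg = refex_config(),
                             centrality_cfg = centrality_config()) {
  assemble_feature_matrix(refex(net, refex_cfg),
                          explicit_features(net, centrality_cfg))
}
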