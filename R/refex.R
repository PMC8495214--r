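#' Configuration for recursive structural feature extraction
#'
#' Controls the ReFeX-style recursion: base local/egonet features are
#' repeatedly augmented with neighbor aggregates; feature blow-up is
#' controlled either by truncation to a fixed canonical width (schema
#' mode) or by vertical logarithmic binning plus correlation pruning
#' (research mode).
#'
#' @param bin_fraction fraction `p` of remaining values assigned to each
#'   successive vertical bin, in `(0, 1)` (default 0.5).
#' @param similarity_threshold non-negative integer `s`: two binned
#'   features are "similar" when their bins differ by at most `s` on every
#'   node (default 0, i.e. identical binning).
#' @param aggregators ordered subset of `c("sum", "mean")` applied over
#'   each node's neighbors at every recursion (default both).
#' @param max_iterations maximum recursion depth (default 4).
#' @param target_width canonical number of output columns in schema mode
#'   (default 267).
#' @param prune `FALSE` for schema mode (fixed, input-independent column
#'   set truncated to `target_width`); `TRUE` for research mode
#'   (bin-and-prune each generation; width is data dependent).
#' @return list of class `refex_config`.
#' @export
refex_config <- function(bin_fraction = 0.5, similarity_threshold = 0L,
                         aggregators = c("sum", "mean"), max_iterations = 4L,
                         target_width = 267L, prune = FALSE) {
  stopifnot(bin_fraction > 0, bin_fraction < 1,
            similarity_threshold >= 0,
            length(aggregators) >= 1, all(aggregators %in% c("sum", "mean")),
            max_iterations >= 1, target_width >= 1)
  structure(list(bin_fraction = bin_fraction,
                 similarity_threshold = as.integer(similarity_threshold),
                 aggregators = aggregators,
                 max_iterations = as.integer(max_iterations),
                 target_width = as.integer(target_width),
                 prune = isTRUE(prune)),
            class = "refex_config")
}

# sparse binary and weighted adjacency of an interactome, node order fixed
.adjacency <- function(net) {
  n <- length(net$nodes)
  i <- match(net$edges$from, net$nodes)
  j <- match(net$edges$to, net$nodes)
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = rep(net$edges$weight, 2), dims = c(n, n),
                            dimnames = list(net$nodes, net$nodes))
  A <- W
  if (length(A@x)) A@x <- rep(1, length(A@x))
  list(A = A, W = W)
}

#' Base local and egonet features
#'
#' The six per-node features at recursion depth zero: degree, weighted
#' degree (sum of incident edge weights), egonet internal edge count
#' (edges with both endpoints inside `{v} U N(v)`), egonet boundary edge
#' count (edges with exactly one endpoint inside the egonet), and the
#' weighted variants of the two egonet counts. An isolated node scores
#' zero on all six.
#'
#' @param net an `interactome`.
#' @return numeric matrix, one row per node (rownames = node ids), columns
#'   `degree`, `wdegree`, `ego_within`, `ego_out`, `w_ego_within`,
#'   `w_ego_out`, with attribute `generation = rep(0, 6)`.
#' @export
base_features <- function(net) {
  stopifnot(inherits(net, "interactome"), length(net$nodes) >= 1)
  ad <- .adjacency(net)
  A <- ad$A; W <- ad$W
  deg <- Matrix::rowSums(A)
  wdeg <- Matrix::rowSums(W)
  # edges inside ego(v) = deg(v) + #triangles through v; weighted variant
  # counts the opposite edge's weight: (A W A)_vv / 2
  AW <- A %*% W
  tri_w <- Matrix::rowSums(AW * A) / 2
  tri <- Matrix::rowSums((A %*% A) * A) / 2
  ego_within <- deg + tri
  w_ego_within <- wdeg + tri_w
  # endpoint sum over ego minus twice the internal edges
  ego_out <- deg + as.numeric(A %*% deg) - 2 * ego_within
  w_ego_out <- wdeg + as.numeric(A %*% wdeg) - 2 * w_ego_within
  fm <- cbind(degree = deg, wdegree = wdeg, ego_within = ego_within,
              ego_out = ego_out, w_ego_within = w_ego_within,
              w_ego_out = w_ego_out)
  rownames(fm) <- net$nodes
  attr(fm, "generation") <- rep(0L, ncol(fm))
  fm
}

#' Append recursive neighbor aggregates to a feature matrix
#'
#' At each iteration and for every column of the previous generation's
#' cumulative matrix, appends its sum and/or mean over each node's
#' neighbors (the mean over an empty neighborhood is 0, keeping the matrix
#' free of missing values). With both aggregators the cumulative width
#' after `g` iterations over a 6-column base is `6 * 3^g`. Within a
#' generation, columns are ordered parent-feature-major, aggregator-minor;
#' a child of parent `P` born at iteration `g` is named `P.s<g>` (sum) or
#' `P.m<g>` (mean), so names stay unique even though re-aggregating a
#' column from an older generation reproduces its earlier child by value
#' (such redundancy keeps the canonical enumeration input-independent;
#' research-mode pruning removes it).
#'
#' @param fm feature matrix whose rows match `net$nodes`.
#' @param net an `interactome`.
#' @param aggregators ordered subset of `c("sum", "mean")`.
#' @param iterations non-negative recursion count.
#' @return the augmented matrix with updated `generation` attribute.
#' @export
recursive_aggregate <- function(fm, net, aggregators = c("sum", "mean"),
                                iterations = 1L) {
  stopifnot(identical(rownames(fm), net$nodes))
  if (iterations < 0) stop("iterations must be non-negative")
  if (iterations == 0) return(fm)
  A <- .adjacency(net)$A
  deg <- Matrix::rowSums(A)
  inv_deg <- ifelse(deg > 0, 1 / deg, 0)
  gen <- attr(fm, "generation")
  if (is.null(gen)) gen <- rep(0L, ncol(fm))
  for (g in seq_len(iterations)) {
    prev <- fm
    newgen <- max(gen) + 1L
    agg <- list()
    if ("sum" %in% aggregators) {
      S <- as.matrix(A %*% prev)
      colnames(S) <- sprintf("%s.s%d", colnames(prev), newgen)
      agg$sum <- S
    }
    if ("mean" %in% aggregators) {
      M <- as.matrix(A %*% prev) * inv_deg
      colnames(M) <- sprintf("%s.m%d", colnames(prev), newgen)
      agg$mean <- M
    }
    k <- length(agg)
    block <- matrix(0, nrow(prev), ncol(prev) * k,
                    dimnames = list(rownames(prev), character(ncol(prev) * k)))
    # parent-major, aggregator-minor column order
    for (a in seq_len(k)) {
      idx <- seq(a, by = k, length.out = ncol(prev))
      block[, idx] <- agg[[match(aggregators[a], names(agg))]]
      colnames(block)[idx] <- colnames(agg[[match(aggregators[a], names(agg))]])
    }
    fm <- cbind(fm, block)
    gen <- c(gen, rep(newgen, ncol(block)))
  }
  attr(fm, "generation") <- gen
  fm
}

#' Vertical logarithmic binning
#'
#' Rank-based discretization: the `ceiling(p * remaining)` smallest
#' unassigned values receive the current bin, then the rule recurses on
#' the remainder with the next bin. Tied values always share a bin (the
#' current bin extends past its nominal cut when the cut would split a
#' tie), so the output depends only on the ordering of the input.
#'
#' @param values numeric vector.
#' @param p bin fraction in `(0, 1)`.
#' @return integer vector of bin indices (0-based), same length as
#'   `values`; empty input gives an empty output.
#' @export
vertical_log_bin <- function(values, p = 0.5) {
  stopifnot(p > 0, p < 1)
  n <- length(values)
  if (!n) return(integer(0))
  o <- order(values)
  sorted <- values[o]
  bins_sorted <- integer(n)
  pos <- 1L; bin <- 0L
  while (pos <= n) {
    remaining <- n - pos + 1L
    take <- ceiling(p * remaining)
    end <- pos + take - 1L
    # extend the bin over a tie straddling the cut
    while (end < n && sorted[end + 1L] == sorted[end]) end <- end + 1L
    bins_sorted[pos:end] <- bin
    pos <- end + 1L
    bin <- bin + 1L
  }
  bins <- integer(n)
  bins[o] <- bins_sorted
  bins
}

#' Prune near-duplicate binned features
#'
#' Builds a feature graph connecting features `i`, `j` whenever their bins
#' differ by at most `s` on every node, then retains a single
#' representative per connected component: the earliest feature in the
#' deterministic generation order (ties broken lexicographically by name).
#' Transitively similar features are merged even when the endpoints of the
#' chain differ by more than `s`.
#'
#' @param fm_binned integer matrix of binned features (columns named).
#' @param s similarity threshold (non-negative integer).
#' @param generation optional integer vector (one per column) used for the
#'   earliest-generation tie-break; defaults to column position.
#' @return character vector of retained column names, in original order.
#' @export
prune_correlated <- function(fm_binned, s = 0L, generation = NULL) {
  m <- ncol(fm_binned)
  if (m == 0) return(character(0))
  if (is.null(generation)) generation <- attr(fm_binned, "generation")
  if (is.null(generation)) generation <- seq_len(m)
  nms <- colnames(fm_binned)
  pairs <- which(upper.tri(matrix(TRUE, m, m)), arr.ind = TRUE)
  if (nrow(pairs)) {
    sim <- vapply(seq_len(nrow(pairs)), function(k) {
      max(abs(fm_binned[, pairs[k, 1]] - fm_binned[, pairs[k, 2]])) <= s
    }, logical(1))
    pairs <- pairs[sim, , drop = FALSE]
  }
  g <- igraph::graph_from_edgelist(cbind(pairs[, 1], pairs[, 2]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, m - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  keep <- logical(m)
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    o <- order(generation[members], members, nms[members])
    keep[members[o[1]]] <- TRUE
  }
  nms[keep]
}

#' Recursive feature extraction (ReFeX style)
#'
#' Computes the recursive structural feature block for every node of an
#' interactome. In the default schema mode the recursion runs to the first
#' depth whose cumulative width reaches `target_width` and the first
#' `target_width` columns are kept in canonical order, so every input
#' graph yields the same 267 deterministically named columns -- the fixed
#' schema required for training across organisms. In research mode
#' (`prune = TRUE`) each generation is binned ([vertical_log_bin()]) and
#' pruned ([prune_correlated()]) and the recursion stops when no new
#' feature survives; the retained set is data dependent.
#'
#' @param net an `interactome`.
#' @param cfg a [refex_config()].
#' @return numeric feature matrix (rows = nodes). Schema mode: exactly
#'   `cfg$target_width` columns, identical names for every input.
#' @export
refex <- function(net, cfg = refex_config()) {
  stopifnot(inherits(net, "interactome"))
  fm <- base_features(net)
  if (cfg$target_width < ncol(fm)) {
    stop(sprintf("target_width (%d) below the %d base features",
                 cfg$target_width, ncol(fm)))
  }
  if (!cfg$prune) {
    g <- 0L
    while (ncol(fm) < cfg$target_width) {
      if (g >= cfg$max_iterations) {
        stop(sprintf("target_width %d unreachable within %d iterations (width %d)",
                     cfg$target_width, cfg$max_iterations, ncol(fm)))
      }
      fm <- recursive_aggregate(fm, net, cfg$aggregators, 1L)
      g <- g + 1L
    }
    gen <- attr(fm, "generation")
    out <- fm[, seq_len(cfg$target_width), drop = FALSE]
    attr(out, "generation") <- gen[seq_len(cfg$target_width)]
    return(out)
  }
  # research mode: aggregate -> bin -> prune per generation
  bin_all <- function(m) {
    b <- apply(m, 2, vertical_log_bin, p = cfg$bin_fraction)
    if (is.null(dim(b))) b <- matrix(b, nrow = nrow(m), dimnames = dimnames(m))
    b
  }
  gen <- attr(fm, "generation")
  retained <- prune_correlated(structure(bin_all(fm), dimnames = dimnames(fm)),
                               s = cfg$similarity_threshold, generation = gen)
  fm <- fm[, retained, drop = FALSE]
  attr(fm, "generation") <- rep(0L, length(retained))
  for (g in seq_len(cfg$max_iterations)) {
    before <- colnames(fm)
    fm2 <- recursive_aggregate(fm, net, cfg$aggregators, 1L)
    gen2 <- attr(fm2, "generation")
    binned <- bin_all(fm2)
    attr(binned, "generation") <- gen2
    retained <- prune_correlated(binned, s = cfg$similarity_threshold,
                                 generation = gen2)
    keep <- match(retained, colnames(fm2))
    fm <- fm2[, sort(keep), drop = FALSE]
    attr(fm, "generation") <- gen2[sort(keep)]
    if (!length(setdiff(colnames(fm), before))) break
  }
  fm
}
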