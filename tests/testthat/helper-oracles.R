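# Small fixture graphs and brute-force oracles, independent of the
# package's computation paths.

make_net <- function(from, to, weight = 1, taxon_id = "test") {
  interactome(data.frame(from = from, to = to, weight = weight,
                         stringsAsFactors = FALSE), taxon_id = taxon_id)
}

triangle_net <- function() make_net(c("a", "b", "c"), c("b", "c", "a"), 0.5)
star_net <- function(k = 4) make_net(rep("c0", k), paste0("l", seq_len(k)))
path_net <- function() make_net(c("a", "b"), c("b", "c"))
complete_net <- function(k = 4) {
  p <- t(utils::combn(paste0("v", seq_len(k)), 2))
  make_net(p[, 1], p[, 2])
}
cycle_net <- function(k = 5) {
  v <- paste0("v", seq_len(k))
  make_net(v, c(v[-1], v[1]))
}

# Erdos-Renyi style random interactome (guaranteed >= 1 edge)
rand_net <- function(n, p = 0.4, seed = 1) {
  pairs <- t(utils::combn(sprintf("n%02d", seq_len(n)), 2))
  keep <- withr::with_seed(seed, stats::runif(nrow(pairs)) < p)
  if (!any(keep)) keep[1] <- TRUE
  w <- withr::with_seed(seed + 1, sample(150:999, sum(keep), TRUE)) / 1000
  interactome(data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                         weight = w, stringsAsFactors = FALSE),
              nodes = sprintf("n%02d", seq_len(n)))
}

# AUROC by exhaustive positive-negative pair counting
auroc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Betweenness by exhaustive simple-path enumeration (pure R, <= 8 nodes):
# for every pair, list all simple paths, keep the shortest, and count the
# fraction passing through each interior node.
brute_betweenness <- function(net, normalized = TRUE) {
  nodes <- net$nodes
  n <- length(nodes)
  adj <- lapply(nodes, function(v) {
    c(net$edges$to[net$edges$from == v], net$edges$from[net$edges$to == v])
  })
  names(adj) <- nodes
  all_paths <- function(s, t) {
    out <- list()
    grow <- function(path) {
      last <- path[length(path)]
      if (last == t) { out[[length(out) + 1]] <<- path; return() }
      for (nb in adj[[last]]) if (!nb %in% path) grow(c(path, nb))
    }
    grow(s)
    out
  }
  b <- stats::setNames(numeric(n), nodes)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    paths <- all_paths(nodes[i], nodes[j])
    if (!length(paths)) next
    len <- vapply(paths, length, integer(1))
    sp <- paths[len == min(len)]
    for (pth in sp) {
      interior <- pth[-c(1, length(pth))]
      b[interior] <- b[interior] + 1 / length(sp)
    }
  }
  if (normalized && n > 2) b <- b / ((n - 1) * (n - 2) / 2)
  b
}

# Egonet edge counts by direct edge-subset enumeration
brute_ego_counts <- function(net, v) {
  ego <- c(v, union(net$edges$to[net$edges$from == v],
                    net$edges$from[net$edges$to == v]))
  inside_from <- net$edges$from %in% ego
  inside_to <- net$edges$to %in% ego
  within <- inside_from & inside_to
  boundary <- xor(inside_from, inside_to)
  list(within = sum(within), boundary = sum(boundary),
       w_within = sum(net$edges$weight[within]),
       w_boundary = sum(net$edges$weight[boundary]))
}
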