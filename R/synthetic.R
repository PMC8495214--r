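#' Configuration for a synthetic organism cohort
#'
#' Describes a cohort of synthetic interactomes with planted,
#' centrality-correlated essentiality, emulating the shape of real
#' training data: heavy-tailed degree distributions (preferential
#' attachment), integer association confidences in `[150, 999]`, and a
#' target essential-gene prevalence of about 10.5% -- the imbalance of a
#' DEG-labelled bacterial training cohort (~8,750 essential among ~83,250
#' genes). Essentiality probability increases with latent centrality via
#' a logistic model on standardized log-degree and betweenness.
#'
#' @param n_organisms number of organisms in the cohort (default 6).
#' @param n_nodes genes per organism (default 800).
#' @param m preferential-attachment parameter: edges added per new node
#'   (default 4, mean degree ~8).
#' @param prevalence target essential prevalence `pi` in `(0,1)`
#'   (default 0.105).
#' @param beta_degree logistic effect of standardized log-degree
#'   (default 2).
#' @param beta_betweenness logistic effect of standardized betweenness
#'   (default 1).
#' @param seed master seed; each organism derives its own sub-seed.
#' @param score_range integer confidence range for edges
#'   (default `c(150, 999)`).
#' @return list of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(n_organisms = 6L, n_nodes = 800L, m = 4L,
                                    prevalence = 0.105, beta_degree = 2,
                                    beta_betweenness = 1, seed = 1L,
                                    score_range = c(150L, 999L)) {
  stopifnot(prevalence > 0, prevalence < 1, n_nodes > m, m >= 1,
            n_organisms >= 1, score_range[1] >= 1, score_range[2] <= 1000,
            score_range[1] <= score_range[2])
  structure(list(n_organisms = as.integer(n_organisms),
                 n_nodes = as.integer(n_nodes), m = as.integer(m),
                 prevalence = prevalence, beta_degree = beta_degree,
                 beta_betweenness = beta_betweenness, seed = as.integer(seed),
                 score_range = as.integer(score_range)),
            class = "synthetic_cohort_config")
}

.org_seed <- function(cfg, organism_index, stage = 0L) {
  # keep derived seeds well inside 32-bit integer range
  (cfg$seed %% 100000L) * 10000L + organism_index * 10L + stage
}

#' Generate one synthetic interactome
#'
#' Undirected preferential-attachment graph over `n_nodes` genes named
#' `synth<idx>.g<k>`, with integer edge confidences drawn uniformly from
#' `score_range` (weights = confidence/1000). Deterministic given
#' `(cfg$seed, organism_index)`. With attachment parameter `m` the graph
#' is simple, so early nodes attach with fewer edges while fewer than `m`
#' targets exist; the edge count is
#' `m * (m - 1) / 2 + (n_nodes - m) * m` (e.g. 197 for 100 nodes, m = 2;
#' `n_nodes - 1`, a tree, for m = 1).
#'
#' @param cfg a [synthetic_cohort_config()].
#' @param organism_index 1-based organism index within the cohort.
#' @return an [interactome()] with taxon id `synth<idx>`.
#' @export
generate_interactome <- function(cfg, organism_index = 1L) {
  tag <- sprintf("synth%d", organism_index)
  withr::with_seed(.org_seed(cfg, organism_index, 0L), {
    g <- igraph::sample_pa(cfg$n_nodes, m = cfg$m, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    score <- sample(seq(cfg$score_range[1], cfg$score_range[2]),
                    nrow(el), replace = TRUE)
  })
  ids <- sprintf("%s.g%d", tag, seq_len(cfg$n_nodes))
  interactome(data.frame(from = ids[el[, 1]], to = ids[el[, 2]],
                         weight = score / 1000, stringsAsFactors = FALSE),
              taxon_id = tag, nodes = ids,
              name = sprintf("synthetic organism %d", organism_index))
}

# solve the logistic intercept so mean(plogis(alpha + eta)) = pi
.solve_intercept <- function(eta, pi, tol = 1e-9) {
  f <- function(a) mean(stats::plogis(a + eta)) - pi
  lo <- -50; hi <- 50
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Plant essentiality labels on a synthetic interactome
#'
#' Per-gene essentiality is Bernoulli with
#' `p = logistic(alpha + beta_deg * z_logdeg + beta_btw * z_btw)`, where
#' the `z` are the standardized log-degree (`log1p`) and standardized
#' betweenness, and the intercept `alpha` is solved by bisection so the
#' expected prevalence over the realized node set equals `prevalence`.
#' Draws are seeded per `(cfg$seed, organism_index)`.
#'
#' @param net an `interactome` (typically from [generate_interactome()]).
#' @param cfg a [synthetic_cohort_config()].
#' @param organism_index index used only for seed derivation.
#' @return a [label_set()] with version tag `"synthetic"`; the underlying
#'   truth probabilities are attached as attribute `"truth"` (named
#'   vector).
#' @export
plant_labels <- function(net, cfg, organism_index = 1L) {
  g <- .topology(net)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, weights = NA, normalized = TRUE)
  z <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  eta <- cfg$beta_degree * z(log1p(deg)) + cfg$beta_betweenness * z(btw)
  alpha <- .solve_intercept(eta, cfg$prevalence)
  p <- stats::plogis(alpha + eta)
  ess <- withr::with_seed(.org_seed(cfg, organism_index, 1L),
                          stats::runif(length(p)) < p)
  out <- label_set(net$nodes[ess], net$nodes, organism = net$taxon_id,
                   version_tag = "synthetic")
  names(p) <- net$nodes
  attr(out, "truth") <- p
  out
}

#' Generate a full in-memory synthetic cohort
#'
#' @param cfg a [synthetic_cohort_config()].
#' @return named list (one element per organism tag) of lists with
#'   elements `net` and `labels`.
#' @export
generate_cohort <- function(cfg) {
  out <- list()
  for (i in seq_len(cfg$n_organisms)) {
    net <- generate_interactome(cfg, i)
    labels <- plant_labels(net, cfg, i)
    out[[net$taxon_id]] <- list(net = net, labels = labels)
  }
  out
}

#' Write a synthetic cohort to disk
#'
#' Per organism: a STRING-dialect links file, a one-id-per-line label
#' file, and a truth CSV of the underlying essentiality probabilities;
#' plus one JSON manifest of the full configuration. Every emitted file
#' is a valid input to [read_string_links()] / [read_labels()], and
#' re-running with the same configuration regenerates identical files.
#'
#' @param cfg a [synthetic_cohort_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list of per-organism file paths.
#' @export
write_cohort <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (i in seq_len(cfg$n_organisms)) {
    net <- generate_interactome(cfg, i)
    labels <- plant_labels(net, cfg, i)
    tag <- net$taxon_id
    links <- file.path(out_dir, sprintf("%s.links.txt", tag))
    labf <- file.path(out_dir, sprintf("%s.labels.txt", tag))
    truth <- file.path(out_dir, sprintf("%s.truth.csv", tag))
    write_string_links(net, links)
    writeLines(c(sprintf("# planted essential genes of %s", tag),
                 labels$essential), labf)
    tp <- attr(labels, "truth")
    utils::write.csv(data.frame(gene_id = names(tp),
                                essential_probability = unname(tp)),
                     truth, row.names = FALSE, quote = FALSE)
    paths[[tag]] <- list(links = links, labels = labf, truth = truth)
  }
  jsonlite::write_json(c(unclass(cfg), list(organisms = names(paths))),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
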