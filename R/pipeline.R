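#' Resolved pipeline run configuration
#'
#' Bundles every path and sub-configuration of a pipeline run. A fully
#' resolved copy is serialized as JSON alongside every output directory
#' so any result can be regenerated from its provenance.
#'
#' @param networks_dir directory of STRING-dialect links files
#'   (`<organism>.links.txt[.gz]` or any `*.txt[.gz]`).
#' @param labels_dir directory of label files named `<organism>.labels.txt`.
#' @param annotations_path optional offline annotation TSV (or `NULL`).
#' @param out_dir output directory.
#' @param refex a [refex_config()].
#' @param centrality a [centrality_config()].
#' @param model a [model_config()].
#' @param min_score minimum STRING combined_score when reading networks.
#' @param threshold essentiality probability cutoff for reporting.
#' @param seed master seed (propagated into the model config).
#' @param version_tag label-source tag recorded in provenance.
#' @param cache_dir directory for cached feature matrices (defaults to
#'   `<out_dir>/cache`); extraction dominates runtime and LOSO reuses
#'   features many times, so features are cached keyed by the content
#'   hash of the network file plus the feature configuration.
#' @return list of class `run_config`.
#' @export
run_config <- function(networks_dir, labels_dir, annotations_path = NULL,
                       out_dir = "netess_out", refex = refex_config(),
                       centrality = centrality_config(),
                       model = model_config(), min_score = 0L,
                       threshold = 0.70, seed = 1L, version_tag = "NA",
                       cache_dir = NULL) {
  model$seed <- as.integer(seed)
  structure(list(networks_dir = networks_dir, labels_dir = labels_dir,
                 annotations_path = annotations_path, out_dir = out_dir,
                 refex = refex, centrality = centrality, model = model,
                 min_score = as.integer(min_score), threshold = threshold,
                 seed = as.integer(seed), version_tag = version_tag,
                 cache_dir = if (is.null(cache_dir)) file.path(out_dir, "cache")
                             else cache_dir),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Scalar fields of the YAML map onto [run_config()] arguments; nested
#' maps `refex`, `centrality`, `model` override the corresponding
#' sub-configuration defaults.
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sub <- function(name, ctor) {
    if (is.null(y[[name]])) ctor() else do.call(ctor, y[[name]])
  }
  args <- y[setdiff(names(y), c("refex", "centrality", "model"))]
  do.call(run_config, c(args, list(refex = sub("refex", refex_config),
                                   centrality = sub("centrality", centrality_config),
                                   model = sub("model", model_config))))
}

.config_fingerprint <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(list(refex = unclass(config$refex),
                                   centrality = unclass(config$centrality),
                                   min_score = config$min_score),
                              auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.discover_organisms <- function(config) {
  nets <- list.files(config$networks_dir,
                     pattern = "\\.(links\\.)?txt(\\.gz)?$", full.names = TRUE)
  nets <- nets[!grepl("\\.labels\\.txt$", nets)]
  if (!length(nets)) stop(sprintf("no network files found in '%s'",
                                  config$networks_dir))
  orgs <- sub("\\.(links\\.)?txt(\\.gz)?$", "", basename(nets))
  data.frame(organism = orgs, network = nets,
             labels = file.path(config$labels_dir,
                                paste0(orgs, ".labels.txt")),
             stringsAsFactors = FALSE)
}

# feature extraction with a content-hash cache
.features_cached <- function(net_path, config, log = message) {
  dir.create(config$cache_dir, recursive = TRUE, showWarnings = FALSE)
  key <- paste0(unname(tools::md5sum(net_path)), "-",
                substr(.config_fingerprint(config), 1, 8))
  cache <- file.path(config$cache_dir, paste0(key, ".features.csv"))
  if (file.exists(cache)) {
    fm <- as.matrix(utils::read.csv(cache, row.names = 1, check.names = FALSE))
    log(sprintf("features: cache hit for %s (%d genes x %d features)",
                basename(net_path), nrow(fm), ncol(fm)))
    return(fm)
  }
  net <- read_string_links(net_path, min_score = config$min_score)
  log(sprintf("extract: %s -> %d genes, %d edges", basename(net_path),
              n_nodes(net), n_edges(net)))
  fm <- extract_features(net, config$refex, config$centrality)
  utils::write.csv(as.data.frame(fm), cache, row.names = TRUE)
  log(sprintf("features: %d genes x %d features cached", nrow(fm), ncol(fm)))
  fm
}

.load_cohort <- function(config, log = message) {
  plan <- .discover_organisms(config)
  cohort <- list()
  for (i in seq_len(nrow(plan))) {
    fm <- .features_cached(plan$network[i], config, log)
    if (!file.exists(plan$labels[i])) {
      stop(sprintf("missing labels file: '%s'", plan$labels[i]))
    }
    labels <- read_labels(plan$labels[i], rownames(fm),
                          organism = plan$organism[i],
                          version_tag = config$version_tag)
    cohort[[plan$organism[i]]] <- list(features = fm, labels = labels)
  }
  cohort
}

.write_provenance <- function(config, out_dir) {
  jsonlite::write_json(
    lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x),
    file.path(out_dir, "run_config.json"), auto_unbox = TRUE, pretty = TRUE,
    null = "null")
}

#' Run the full prediction pipeline
#'
#' Stages in order: feature extraction (cached), ensemble training on all
#' organisms, per-organism probability prediction, and report generation
#' (prediction CSVs with the >= 70% essentiality rule). The resolved
#' configuration is written to the output directory; reruns with an
#' identical configuration and seed produce byte-identical outputs.
#'
#' @param config a [run_config()].
#' @param log logging callback taking one string (default [message()];
#'   pass `function(...) {}` to silence).
#' @return invisibly, a list with the `ess_ensemble`, the per-organism
#'   probability vectors, and the written CSV paths.
#' @export
run_pipeline <- function(config, log = message) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- .load_cohort(config, log)
  feats <- do.call(rbind, lapply(cohort, function(el) el$features))
  ess <- unlist(lapply(cohort, function(el) el$labels$essential),
                use.names = FALSE)
  uni <- unlist(lapply(cohort, function(el) el$labels$universe),
                use.names = FALSE)
  labels <- label_set(ess, uni,
                      organism = paste(names(cohort), collapse = "+"),
                      version_tag = config$version_tag)
  log(sprintf("train: %d organisms, %d genes (%d essential), %d features",
              length(cohort), length(uni), length(ess), ncol(feats)))
  ens <- ess_train(feats, labels, config$model)
  save_ensemble(ens, file.path(config$out_dir, "ensemble"))
  annotations <- if (!is.null(config$annotations_path)) {
    read_annotations(config$annotations_path)
  }
  probs <- list(); csvs <- character(0)
  for (org in names(cohort)) {
    p <- predict(ens, cohort[[org]]$features)
    probs[[org]] <- p
    tab <- classify_and_score(p, threshold = config$threshold)
    path <- file.path(config$out_dir, sprintf("%s.predictions.csv", org))
    write_predictions_csv(tab, annotations, path)
    log(sprintf("report: %s -> %d/%d genes at score >= %.1f", org,
                nrow(tab), length(p), config$threshold * 100))
    csvs[org] <- path
  }
  .write_provenance(config, config$out_dir)
  invisible(list(ensemble = ens, probabilities = probs, predictions = csvs))
}

#' Leave-one-species-out evaluation over a directory cohort
#'
#' Convenience wrapper: loads networks and labels per [run_config()],
#' extracts (cached) features, and runs [loso()]. The result table and
#' the resolved configuration are written to the output directory.
#'
#' @param config a [run_config()].
#' @param log logging callback.
#' @return the [loso_result()].
#' @export
run_loso <- function(config, log = message) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- .load_cohort(config, log)
  res <- loso(cohort, config$model)
  counts <- lapply(cohort, function(el)
    c(length(el$labels$essential),
      length(el$labels$universe) - length(el$labels$essential)))
  write_loso_csv(res, file.path(config$out_dir, "loso_auroc.csv"),
                 class_counts = counts)
  .write_provenance(config, config$out_dir)
  log(sprintf("loso: mean AUROC %.3f over %d organisms", res$mean,
              length(res$aurocs)))
  res
}
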