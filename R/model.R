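#' Random-forest ensemble configuration
#'
#' Hyperparameters of the imbalance-aware ensemble: `n_folds` disjoint
#' undersampled negative chunks, one forest per chunk. Defaults follow the
#' grid-search optimum reported for this model family: 150 trees,
#' entropy criterion, sqrt features per split, 10 folds.
#'
#' @param n_trees trees per member forest (default 150).
#' @param criterion split criterion, `"entropy"` or `"gini"`. Recorded in
#'   the ensemble provenance; the ranger backend fits with the Gini
#'   impurity in both cases (it implements no information-gain split), a
#'   substitution that is immaterial for forest quality in practice.
#' @param max_features features considered per split: `"sqrt"`, `"log2"`
#'   or `"all"`.
#' @param n_folds number of undersampled negative folds (default 10).
#' @param seed integer seed governing undersampling and tree growth.
#' @param cap_negatives optionally cap each negative chunk at the number
#'   of positives (default `FALSE`).
#' @param check_schema require the canonical 283-column schema at
#'   training time (default `TRUE`; disable for research-mode feature
#'   sets).
#' @return list of class `model_config`.
#' @export
model_config <- function(n_trees = 150L, criterion = c("entropy", "gini"),
                         max_features = c("sqrt", "log2", "all"),
                         n_folds = 10L, seed = 1L, cap_negatives = FALSE,
                         check_schema = TRUE) {
  criterion <- match.arg(criterion)
  max_features <- match.arg(max_features)
  stopifnot(n_trees >= 1, n_folds >= 1)
  structure(list(n_trees = as.integer(n_trees), criterion = criterion,
                 max_features = max_features, n_folds = as.integer(n_folds),
                 seed = as.integer(seed), cap_negatives = isTRUE(cap_negatives),
                 check_schema = isTRUE(check_schema)),
            class = "model_config")
}

.mtry_for <- function(rule, p) {
  switch(rule,
         sqrt = max(1L, floor(sqrt(p))),
         log2 = max(1L, floor(log2(p))),
         all = p)
}

#' Undersampled training folds with full negative coverage
#'
#' Shuffles the negatives with a seeded RNG and partitions them into
#' `n_folds` disjoint chunks whose sizes differ by at most one; fold `k`'s
#' training set is all positives plus chunk `k`. Every negative therefore
#' appears in exactly one fold, guaranteeing that all negative labels are
#' seen at least once across the ensemble.
#'
#' @param positives character vector of positive (essential) gene ids;
#'   must be non-empty.
#' @param negatives character vector of negative gene ids.
#' @param n_folds number of chunks; must not exceed `length(negatives)`.
#' @param seed integer seed for the shuffle.
#' @param cap_negatives cap each chunk at `length(positives)` genes?
#' @return list of `n_folds` lists, each with elements `positives` and
#'   `negatives`.
#' @export
undersample_folds <- function(positives, negatives, n_folds = 10L, seed = 1L,
                              cap_negatives = FALSE) {
  if (!length(positives)) stop("no positive labels: cannot build training folds")
  if (n_folds > length(negatives)) {
    stop(sprintf("n_folds (%d) exceeds the number of negatives (%d)",
                 n_folds, length(negatives)))
  }
  shuffled <- withr::with_seed(seed, sample(negatives))
  sizes <- rep(length(negatives) %/% n_folds, n_folds)
  extra <- length(negatives) %% n_folds
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  lapply(seq_len(n_folds), function(k) {
    neg <- shuffled[starts[k]:ends[k]]
    if (cap_negatives && length(neg) > length(positives)) {
      neg <- neg[seq_along(positives)]
    }
    list(positives = positives, negatives = neg)
  })
}

#' Fit the imbalance-aware random-forest ensemble
#'
#' The central fitting function. Builds the undersampled folds with
#' [undersample_folds()] and fits one probability forest per fold; the
#' ensemble's prediction is the arithmetic mean of the member forests'
#' probabilities ([predict.ess_ensemble()]). The feature schema (ordered
#' column names) is stored and enforced at prediction time.
#'
#' @param features numeric matrix, rows = genes (rownames required),
#'   canonically 283 columns.
#' @param labels a [label_set()] whose universe is covered by the feature
#'   rows.
#' @param cfg a [model_config()].
#' @return object of class `ess_ensemble`: list with `forests`, `schema`,
#'   `config` and `provenance` (organisms, label version, seed, class
#'   counts).
#' @export
ess_train <- function(features, labels, cfg = model_config()) {
  stopifnot(is.matrix(features), !is.null(rownames(features)))
  if (!all(labels$universe %in% rownames(features))) {
    stop("label universe contains genes absent from the feature matrix")
  }
  if (cfg$check_schema && ncol(features) != 283) {
    stop(sprintf(
      "feature matrix has %d columns; the canonical schema has 283 (set check_schema = FALSE for research-mode features)",
      ncol(features)))
  }
  pos <- intersect(labels$essential, labels$universe)
  neg <- nonessential(labels)
  if (!length(pos)) stop("no positive labels: cannot train")
  if (!length(neg)) stop("no negative labels: cannot train")
  folds <- undersample_folds(pos, neg, n_folds = cfg$n_folds, seed = cfg$seed,
                             cap_negatives = cfg$cap_negatives)
  mtry <- .mtry_for(cfg$max_features, ncol(features))
  forests <- lapply(seq_along(folds), function(k) {
    ids <- c(folds[[k]]$positives, folds[[k]]$negatives)
    y <- factor(c(rep("essential", length(folds[[k]]$positives)),
                  rep("nonessential", length(folds[[k]]$negatives))),
                levels = c("nonessential", "essential"))
    x <- as.data.frame(features[ids, , drop = FALSE])
    ranger::ranger(x = x, y = y, num.trees = cfg$n_trees, mtry = mtry,
                   probability = TRUE, num.threads = 1L,
                   seed = cfg$seed + k,
                   respect.unordered.factors = "order")
  })
  structure(list(forests = forests,
                 schema = colnames(features),
                 config = cfg,
                 provenance = list(
                   organisms = labels$organism,
                   version_tag = labels$version_tag,
                   seed = cfg$seed,
                   n_positive = length(pos), n_negative = length(neg))),
            class = "ess_ensemble")
}

#' @export
print.ess_ensemble <- function(x, ...) {
  cat(sprintf(
    "<ess_ensemble> %d forests x %d trees (%s, %s), %d-feature schema\n",
    length(x$forests), x$config$n_trees, x$config$criterion,
    x$config$max_features, length(x$schema)))
  cat(sprintf("  trained on %s [%s]: %d essential / %d non-essential, seed %d\n",
              paste(x$provenance$organisms, collapse = "+"),
              x$provenance$version_tag, x$provenance$n_positive,
              x$provenance$n_negative, x$provenance$seed))
  invisible(x)
}

#' @export
summary.ess_ensemble <- function(object, ...) {
  oob <- vapply(object$forests, function(f) f$prediction.error, numeric(1))
  out <- list(n_forests = length(object$forests), config = object$config,
              provenance = object$provenance, oob_brier = oob)
  class(out) <- "summary.ess_ensemble"
  out
}

#' @export
print.summary.ess_ensemble <- function(x, ...) {
  cat(sprintf("<ess_ensemble> %d member forests; per-fold OOB Brier score:\n",
              x$n_forests))
  print(round(x$oob_brier, 4))
  invisible(x)
}

#' Predict essentiality probabilities
#'
#' The ensemble probability of a gene being essential is the arithmetic
#' mean of the member forests' probabilities; it always lies within the
#' member range and in `[0, 1]`.
#'
#' @param object an `ess_ensemble`.
#' @param features numeric matrix whose columns match the training schema
#'   exactly (order included); rownames are gene ids.
#' @param ... unused.
#' @return named numeric vector of probabilities in `[0, 1]`.
#' @export
predict.ess_ensemble <- function(object, features, ...) {
  stopifnot(is.matrix(features))
  if (!identical(colnames(features), object$schema)) {
    missing <- setdiff(object$schema, colnames(features))
    extra <- setdiff(colnames(features), object$schema)
    if (length(missing) || length(extra)) {
      stop(sprintf("feature schema mismatch; missing: [%s]; extra: [%s]",
                   paste(utils::head(missing, 5), collapse = ", "),
                   paste(utils::head(extra, 5), collapse = ", ")))
    }
    stop("feature columns are out of canonical order")
  }
  x <- as.data.frame(features)
  probs <- vapply(object$forests, function(f) {
    stats::predict(f, data = x, num.threads = 1L)$predictions[, "essential"]
  }, numeric(nrow(features)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  p <- rowMeans(probs)
  names(p) <- rownames(features)
  p
}

#' Exhaustive hyperparameter grid search
#'
#' Evaluates every combination of the supplied hyperparameter lists by
#' stratified k-fold cross-validated AUROC (an ensemble is trained on
#' each fold's training part and scored on the held-out part; fold AUROCs
#' are averaged). Ties are broken deterministically in favor of the first
#' configuration in grid enumeration order.
#'
#' @param features feature matrix (rownames = genes).
#' @param labels a [label_set()].
#' @param grid named list of vectors over any of `n_trees`, `criterion`,
#'   `max_features`; non-empty.
#' @param n_folds cross-validation folds (default 10; also used as the
#'   undersampling fold count of each candidate).
#' @param seed integer seed.
#' @param check_schema passed to [model_config()].
#' @return list with `best` (a [model_config()]) and `scores` (data.frame
#'   of one row per configuration with its mean CV AUROC).
#' @export
grid_search <- function(features, labels, grid, n_folds = 10L, seed = 1L,
                        check_schema = TRUE) {
  if (!length(grid)) stop("empty hyperparameter grid")
  combos <- expand.grid(grid, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  pos <- labels$essential
  neg <- nonessential(labels)
  if (!length(pos) || !length(neg)) stop("grid_search needs both classes")
  k <- min(n_folds, length(pos), length(neg))
  fold_of <- function(ids, off) {
    s <- withr::with_seed(seed + off, sample(ids))
    split(s, rep_len(seq_len(k), length(s)))
  }
  pf <- fold_of(pos, 0L); nf <- fold_of(neg, 1L)
  scores <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    args <- as.list(combos[i, , drop = FALSE])
    fold_auc <- vapply(seq_len(k), function(j) {
      test_ids <- c(pf[[j]], nf[[j]])
      train_ls <- label_set(setdiff(pos, pf[[j]]),
                            setdiff(labels$universe, test_ids),
                            organism = labels$organism,
                            version_tag = labels$version_tag)
      cfg <- do.call(model_config,
                     c(args, list(n_folds = min(n_folds, length(nonessential(train_ls))),
                                  seed = seed, check_schema = check_schema)))
      ens <- ess_train(features, train_ls, cfg)
      p <- predict(ens, features[test_ids, , drop = FALSE])
      auroc(p, as.integer(test_ids %in% pos))
    }, numeric(1))
    scores[i] <- mean(fold_auc)
  }
  best_i <- which.max(scores)  # first maximum wins
  best <- do.call(model_config,
                  c(as.list(combos[best_i, , drop = FALSE]),
                    list(n_folds = n_folds, seed = seed,
                         check_schema = check_schema)))
  list(best = best, scores = cbind(combos, cv_auroc = scores))
}

#' Persist a trained ensemble to a directory
#'
#' Writes one model artifact per member forest plus a JSON manifest
#' carrying the feature schema, configuration, and training provenance.
#'
#' @param ens an `ess_ensemble`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_ensemble <- function(ens, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(ens$forests)) {
    saveRDS(ens$forests[[k]], file.path(dir, sprintf("forest_%02d.rds", k)))
  }
  manifest <- list(schema = ens$schema,
                   config = unclass(ens$config),
                   provenance = ens$provenance,
                   n_forests = length(ens$forests))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load a persisted ensemble
#'
#' @param dir directory written by [save_ensemble()].
#' @return an `ess_ensemble`.
#' @export
load_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^forest_\\d+\\.rds$",
                           full.names = TRUE))
  if (length(files) != manifest$n_forests) {
    stop(sprintf("expected %d forest artifacts, found %d",
                 manifest$n_forests, length(files)))
  }
  cfg <- do.call(model_config, manifest$config[
    c("n_trees", "criterion", "max_features", "n_folds", "seed",
      "cap_negatives", "check_schema")])
  structure(list(forests = lapply(files, readRDS),
                 schema = manifest$schema, config = cfg,
                 provenance = manifest$provenance),
            class = "ess_ensemble")
}
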