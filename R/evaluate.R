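#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney formulation with midrank tie handling:
#' `AUROC = P(score_pos > score_neg) + 0.5 * P(score_pos == score_neg)`
#' over random positive-negative pairs. Invariant under strictly
#' increasing transforms of the scores.
#'
#' @param scores numeric vector of predicted scores.
#' @param labels binary vector (0/1 or logical) of the same length; must
#'   contain both classes.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUROC undefined: labels contain a single class")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Construct a LOSO result
#'
#' Container for per-organism leave-one-species-out AUROCs. Can be built
#' directly from a named vector (e.g. to re-analyze a published score
#' table) or by [loso()].
#'
#' @param aurocs named numeric vector, one AUROC in `[0,1]` per organism.
#' @param version_tag label-source version the scores were computed under.
#' @param skipped character vector of organisms excluded (single-class
#'   labels).
#' @param provenance optional list (config, seed).
#' @return object of class `loso_result` with fields `aurocs`, `mean`,
#'   `version_tag`, `skipped`, `provenance`.
#' @export
loso_result <- function(aurocs, version_tag = "NA", skipped = character(0),
                        provenance = list()) {
  stopifnot(is.numeric(aurocs), !is.null(names(aurocs)),
            all(aurocs >= 0 & aurocs <= 1))
  structure(list(aurocs = aurocs, mean = mean(aurocs),
                 version_tag = version_tag, skipped = skipped,
                 provenance = provenance),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, digits = 3, ...) {
  cat(sprintf("<loso_result> [%s] %d organisms, mean AUROC %.*f\n",
              x$version_tag, length(x$aurocs), digits, x$mean))
  print(round(x$aurocs, digits))
  if (length(x$skipped)) {
    cat(sprintf("  skipped (single-class labels): %s\n",
                paste(x$skipped, collapse = ", ")))
  }
  invisible(x)
}

#' Leave-one-species-out evaluation
#'
#' For each organism of the cohort, trains the ensemble on all other
#' organisms' genes (pooled features and labels) and computes the AUROC
#' of its predictions on the held-out organism. Organisms whose labels
#' contain a single class are skipped with a warning and excluded from
#' the cohort mean. The held-out organism never contributes training
#' rows; its absence is recorded in each fit's provenance.
#'
#' @param cohort named list; each element a list with `features` (matrix,
#'   shared schema) and `labels` (a [label_set()]). Cohort size >= 2.
#' @param cfg a [model_config()].
#' @return a [loso_result()].
#' @export
loso <- function(cohort, cfg = model_config()) {
  stopifnot(length(cohort) >= 2, !is.null(names(cohort)))
  schema <- colnames(cohort[[1]]$features)
  for (el in cohort) {
    if (!identical(colnames(el$features), schema)) {
      stop("cohort feature matrices do not share one schema")
    }
  }
  res <- numeric(0); skipped <- character(0); fits <- list()
  for (org in names(cohort)) {
    held <- cohort[[org]]
    y <- as.integer(held$labels$universe %in% held$labels$essential)
    if (length(unique(y)) < 2) {
      warning(sprintf("organism '%s' has single-class labels; skipped", org))
      skipped <- c(skipped, org)
      next
    }
    rest <- cohort[names(cohort) != org]
    feats <- do.call(rbind, lapply(rest, function(el) el$features))
    ess <- unlist(lapply(rest, function(el) el$labels$essential),
                  use.names = FALSE)
    uni <- unlist(lapply(rest, function(el) el$labels$universe),
                  use.names = FALSE)
    train_labels <- label_set(ess, uni,
                              organism = paste(names(rest), collapse = "+"),
                              version_tag = held$labels$version_tag)
    ens <- ess_train(feats, train_labels, cfg)
    p <- predict(ens, held$features[held$labels$universe, , drop = FALSE])
    res[org] <- auroc(p, y)
    fits[[org]] <- ens$provenance
  }
  if (!length(res)) stop("no organism of the cohort was evaluable")
  loso_result(res, version_tag = cohort[[1]]$labels$version_tag,
              skipped = skipped,
              provenance = list(config = unclass(cfg), fits = fits))
}

#' Compare two LOSO results organism by organism
#'
#' Reports per-organism AUROC differences (B minus A), their mean (in
#' AUROC points and as a rounded percentage), and both a paired t-test
#' and a Welch two-sample t-test. With zero-variance differences the
#' paired test is degenerate; it is then flagged and its p-value reported
#' as `NA`.
#'
#' @param resA,resB two [loso_result()] objects over the same organisms
#'   (e.g. scores under DEG10 vs DEG15 labels).
#' @return list of class `loso_comparison`: `diffs`, `mean_diff`,
#'   `mean_diff_percent` (rounded to integer percent), `paired` and
#'   `welch` htest-like summaries, `degenerate` flag.
#' @export
compare_label_versions <- function(resA, resB) {
  a <- resA$aurocs; b <- resB$aurocs
  if (!setequal(names(a), names(b))) {
    stop("organism sets differ between the two results")
  }
  b <- b[names(a)]
  d <- b - a
  degenerate <- length(d) < 2 || isTRUE(all.equal(unname(stats::var(d)), 0))
  paired <- if (degenerate) {
    list(p.value = NA_real_, statistic = NA_real_,
         note = "zero-variance differences: no paired test possible")
  } else {
    t <- stats::t.test(b, a, paired = TRUE)
    list(p.value = t$p.value, statistic = unname(t$statistic))
  }
  welch <- if (length(a) < 2 ||
               (stats::var(a) == 0 && stats::var(b) == 0)) {
    list(p.value = NA_real_, statistic = NA_real_,
         note = "zero variance in both samples")
  } else {
    t <- stats::t.test(b, a, paired = FALSE)
    list(p.value = t$p.value, statistic = unname(t$statistic))
  }
  structure(list(diffs = d, mean_diff = mean(d),
                 mean_diff_percent = round(mean(d) * 100),
                 paired = paired, welch = welch,
                 degenerate = degenerate,
                 versions = c(resA$version_tag, resB$version_tag)),
            class = "loso_comparison")
}

#' @export
print.loso_comparison <- function(x, ...) {
  cat(sprintf("<loso_comparison> %s -> %s over %d organisms\n",
              x$versions[1], x$versions[2], length(x$diffs)))
  cat(sprintf("  mean AUROC difference: %+0.4f (%+d%%)\n",
              x$mean_diff, x$mean_diff_percent))
  if (x$degenerate) {
    cat("  paired test degenerate (no difference variance)\n")
  } else {
    cat(sprintf("  paired t-test p = %.3g; Welch t-test p = %.3g\n",
                x$paired$p.value, x$welch$p.value))
  }
  invisible(x)
}

#' Published LOSO AUROC benchmark table
#'
#' The per-organism leave-one-species-out AUROC scores of the NetGenes
#' model for 34 bacterial organisms under the DEG10 and DEG15 label
#' versions, as printed in the resource's benchmark table. The 27
#' organisms of the core training cohort carry `core = TRUE`; the seven
#' organisms added with DEG15 carry `core = FALSE`.
#'
#' @return data.frame with columns `organism`, `deg10`, `deg15`, `core`.
#' @export
deg_benchmark_table <- function() {
  path <- system.file("extdata", "loso_auroc_deg10_deg15.tsv",
                      package = "netess", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$core <- as.logical(df$core)
  df
}

#' Serialize a LOSO result as CSV
#'
#' One row per organism: `organism, auroc, n_pos, n_neg, version_tag`
#' (class counts filled when known from provenance, else `NA`).
#'
#' @param res a [loso_result()].
#' @param path output path.
#' @param class_counts optional named list organism -> c(n_pos, n_neg).
#' @return `path`, invisibly.
#' @export
write_loso_csv <- function(res, path, class_counts = NULL) {
  orgs <- names(res$aurocs)
  np <- nn <- rep(NA_integer_, length(orgs))
  if (!is.null(class_counts)) {
    for (i in seq_along(orgs)) {
      cc <- class_counts[[orgs[i]]]
      if (!is.null(cc)) { np[i] <- cc[1]; nn[i] <- cc[2] }
    }
  }
  utils::write.csv(
    data.frame(organism = orgs, auroc = unname(res$aurocs),
               n_pos = np, n_neg = nn, version_tag = res$version_tag,
               stringsAsFactors = FALSE),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
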