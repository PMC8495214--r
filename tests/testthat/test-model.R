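# small feature matrix with one informative column; genes g1.. with the
# first n_pos essential
toy_features <- function(n, n_pos, seed = 1, p = 283, signal = 3) {
  ids <- sprintf("g%03d", seq_len(n))
  y <- c(rep(1, n_pos), rep(0, n - n_pos))
  fm <- withr::with_seed(seed, matrix(stats::rnorm(n * p), n, p))
  fm[, 1] <- fm[, 1] + signal * y
  rownames(fm) <- ids
  colnames(fm) <- sprintf("f%03d", seq_len(p))
  list(features = fm,
       labels = label_set(ids[y == 1], ids, organism = "toy",
                          version_tag = "synthetic"))
}

test_that("undersampled folds cover all negatives exactly once in near-equal chunks", {
  pos <- sprintf("p%02d", 1:5)
  neg <- sprintf("n%02d", 1:20)
  folds <- undersample_folds(pos, neg, n_folds = 10, seed = 3)
  expect_length(folds, 10)
  chunks <- lapply(folds, `[[`, "negatives")
  expect_equal(sort(unlist(chunks)), sort(neg))       # coverage
  expect_equal(lengths(chunks), rep(2L, 10))
  expect_true(all(vapply(folds, function(f) identical(f$positives, pos),
                         logical(1))))

  # 23 negatives over 10 folds: sizes {3,3,3,2,...}
  folds23 <- undersample_folds(pos, sprintf("n%02d", 1:23), 10, seed = 3)
  expect_equal(sort(lengths(lapply(folds23, `[[`, "negatives")),
                    decreasing = TRUE),
               c(3L, 3L, 3L, rep(2L, 7)))
  expect_equal(sort(unlist(lapply(folds23, `[[`, "negatives"))),
               sprintf("n%02d", 1:23))
  # pairwise disjoint
  expect_false(any(duplicated(unlist(lapply(folds23, `[[`, "negatives")))))

  f1 <- undersample_folds(pos, neg[1:5], 1, seed = 1)
  expect_length(f1, 1)
  expect_length(f1[[1]]$negatives, 5)

  expect_error(undersample_folds(character(0), neg, 10, 1), "no positive")
  expect_error(undersample_folds(pos, neg[1:3], 10, 1), "exceeds")
})

test_that("training is deterministic, schema-guarded, and separates separable data", {
  toy <- toy_features(120, 20, seed = 5)
  cfg <- model_config(n_trees = 60, n_folds = 4, seed = 11,
                      check_schema = TRUE)
  ens <- ess_train(toy$features, toy$labels, cfg)
  expect_s3_class(ens, "ess_ensemble")
  expect_length(ens$forests, 4)
  p1 <- predict(ens, toy$features)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # training-set separation of a linearly separable signal
  y <- as.integer(toy$labels$universe %in% toy$labels$essential)
  expect_equal(auroc(p1[toy$labels$universe], y), 1.0, tolerance = 0.01)

  # same inputs + same seed -> identical probabilities
  ens2 <- ess_train(toy$features, toy$labels, cfg)
  expect_identical(predict(ens2, toy$features), p1)

  # schema width enforced in canonical mode
  narrow <- toy$features[, 1:50]
  expect_error(ess_train(narrow, toy$labels, model_config()), "283")
  expect_silent(ess_train(narrow, toy$labels,
                          model_config(n_trees = 10, n_folds = 2,
                                       check_schema = FALSE)))

  empty <- label_set(character(0), rownames(toy$features))
  expect_error(ess_train(toy$features, empty, cfg), "no positive")
})

test_that("ensemble probabilities are the mean of member forests, schema enforced", {
  toy <- toy_features(80, 15, seed = 7)
  cfg <- model_config(n_trees = 40, n_folds = 3, seed = 2)
  ens <- ess_train(toy$features, toy$labels, cfg)
  member <- vapply(ens$forests, function(f) {
    stats::predict(f, data = as.data.frame(toy$features),
                   num.threads = 1)$predictions[, "essential"]
  }, numeric(nrow(toy$features)))
  p <- predict(ens, toy$features)
  expect_equal(unname(p), unname(rowMeans(member)))
  expect_true(all(p >= apply(member, 1, min) - 1e-12))
  expect_true(all(p <= apply(member, 1, max) + 1e-12))

  # permuting rows permutes probabilities identically
  perm <- rev(seq_len(nrow(toy$features)))
  expect_equal(predict(ens, toy$features[perm, ]), p[perm])

  # mismatched schema errors name the offending columns
  bad <- toy$features
  colnames(bad)[1] <- "zzz"
  expect_error(predict(ens, bad), "missing.*f001|f001")
  expect_error(predict(ens, toy$features[, rev(colnames(toy$features))]),
               "order")
})

test_that("grid search is exhaustive with a deterministic winner", {
  toy <- toy_features(90, 18, seed = 9, p = 40)
  gs <- grid_search(toy$features, toy$labels,
                    grid = list(n_trees = c(5L, 60L)),
                    n_folds = 3, seed = 4, check_schema = FALSE)
  expect_equal(nrow(gs$scores), 2)
  expect_s3_class(gs$best, "model_config")
  # strongly structured data: the larger forest does not score worse
  expect_gte(gs$scores$cv_auroc[2], gs$scores$cv_auroc[1] - 0.02)

  one <- grid_search(toy$features, toy$labels, grid = list(n_trees = 25L),
                     n_folds = 2, seed = 4, check_schema = FALSE)
  expect_equal(one$best$n_trees, 25L)
  grid2 <- list(n_trees = c(10L, 20L), max_features = c("sqrt", "log2"))
  gs2 <- grid_search(toy$features, toy$labels, grid = grid2, n_folds = 2,
                     seed = 4, check_schema = FALSE)
  expect_equal(nrow(gs2$scores), 4)  # product of grid dimensions
})

test_that("ensembles persist to a directory and reload identically", {
  toy <- toy_features(60, 12, seed = 3)
  cfg <- model_config(n_trees = 25, n_folds = 2, seed = 8)
  ens <- ess_train(toy$features, toy$labels, cfg)
  dir <- withr::local_tempdir()
  save_ensemble(ens, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- load_ensemble(dir)
  expect_identical(back$schema, ens$schema)
  expect_equal(predict(back, toy$features), predict(ens, toy$features))
})
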