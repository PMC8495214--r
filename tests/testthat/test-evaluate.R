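test_that("auroc matches fixtures and fails on single-class labels", {
  expect_equal(auroc(c(0.9, 0.1), c(1, 0)), 1.0)
  expect_equal(auroc(c(0.5, 0.5, 0.5, 0.5), c(1, 1, 0, 0)), 0.5)
  expect_equal(auroc(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_error(auroc(c(0.1, 0.9), c(1, 1)), "single class")
})

test_that("auroc agrees with exhaustive pair counting on random small inputs", {
  for (seed in 1:40) {
    n <- withr::with_seed(seed, sample(4:12, 1))
    repeat {
      labels <- withr::with_seed(seed + 100, stats::rbinom(n, 1, 0.5))
      if (length(unique(labels)) == 2) break
      seed <- seed + 1000
    }
    scores <- withr::with_seed(seed + 200,
                               sample(seq(0, 1, 0.25), n, replace = TRUE))
    expect_equal(auroc(scores, labels), auroc_pairs(scores, labels))
  }
})

test_that("auroc respects complement symmetry and monotone invariance", {
  for (seed in 1:10) {
    scores <- withr::with_seed(seed, stats::rnorm(30))
    labels <- withr::with_seed(seed + 50, stats::rbinom(30, 1, 0.4))
    if (length(unique(labels)) < 2) next
    a <- auroc(scores, labels)
    expect_equal(a + auroc(scores, 1 - labels), 1)
    expect_equal(auroc(exp(scores), labels), a)
    expect_equal(auroc(scores * 100 - 3, labels), a)
  }
})

test_that("the published benchmark table reproduces its printed summaries", {
  tab <- deg_benchmark_table()
  expect_equal(nrow(tab), 34)
  expect_equal(sum(tab$core), 27)
  core <- loso_result(stats::setNames(tab$deg10[tab$core],
                                      tab$organism[tab$core]),
                      version_tag = "DEG10")
  expect_equal(round(core$mean, 2), 0.77)
})

test_that("label-version comparison reports differences and both t-tests", {
  tab <- deg_benchmark_table()
  r10 <- loso_result(stats::setNames(tab$deg10, tab$organism), "DEG10")
  r15 <- loso_result(stats::setNames(tab$deg15, tab$organism), "DEG15")
  cmp <- compare_label_versions(r10, r15)
  expect_equal(cmp$mean_diff_percent, 4)
  expect_false(cmp$degenerate)
  expect_true(is.finite(cmp$paired$p.value))
  expect_true(is.finite(cmp$welch$p.value))

  # identical results: no difference, degenerate paired test flagged
  same <- compare_label_versions(r10, r10)
  expect_equal(same$mean_diff, 0)
  expect_true(same$degenerate)
  expect_true(is.na(same$paired$p.value))

  # constant +0.1 shift: mean difference exact, paired test degenerate
  keep <- tab$deg10 + 0.1 <= 1
  cmp2 <- compare_label_versions(
    loso_result(stats::setNames(tab$deg10[keep], tab$organism[keep]), "a"),
    loso_result(stats::setNames(tab$deg10[keep] + 0.1, tab$organism[keep]), "b"))
  expect_equal(cmp2$mean_diff, 0.1)
  expect_true(cmp2$degenerate)

  r_sub <- loso_result(stats::setNames(tab$deg15[1:5], tab$organism[1:5]), "x")
  expect_error(compare_label_versions(r10, r_sub), "organism sets differ")
})

test_that("loso trains without the held-out organism and skips single-class ones", {
  cfg <- synthetic_cohort_config(n_organisms = 3, n_nodes = 120, m = 2,
                                 beta_degree = 2.5, seed = 31)
  cohort <- generate_cohort(cfg)
  cohort <- lapply(cohort, function(el)
    list(features = extract_features(el$net), labels = el$labels))
  mc <- model_config(n_trees = 30, n_folds = 3, seed = 31)
  res <- loso(cohort, mc)
  expect_s3_class(res, "loso_result")
  expect_setequal(names(res$aurocs), names(cohort))
  expect_equal(res$mean, mean(res$aurocs))
  # provenance: the held-out organism never appears among the training orgs
  for (org in names(res$provenance$fits)) {
    trained_on <- res$provenance$fits[[org]]$organisms
    expect_false(grepl(org, trained_on, fixed = TRUE))
  }

  # an all-negative organism is skipped with a warning, excluded from mean
  broken <- cohort
  broken$synth1$labels <- label_set(character(0),
                                    broken$synth1$labels$universe,
                                    organism = "synth1")
  expect_warning(res2 <- loso(broken, mc), "single-class")
  expect_equal(res2$skipped, "synth1")
  expect_setequal(names(res2$aurocs), c("synth2", "synth3"))
})

test_that("loso results serialize to the benchmark CSV layout", {
  res <- loso_result(c(orgA = 0.8, orgB = 0.7), version_tag = "DEG10")
  f <- withr::local_tempfile(fileext = ".csv")
  write_loso_csv(res, f, class_counts = list(orgA = c(10, 90)))
  df <- utils::read.csv(f)
  expect_equal(names(df), c("organism", "auroc", "n_pos", "n_neg",
                            "version_tag"))
  expect_equal(df$auroc, c(0.8, 0.7))
  expect_equal(df$n_pos[1], 10)
  expect_true(is.na(df$n_neg[2]))
})
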