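test_that("base features match hand-enumerated egonet counts on fixtures", {
  tri <- base_features(triangle_net())
  expect_equal(unname(tri[, "degree"]), rep(2, 3))
  expect_equal(unname(tri[, "ego_within"]), rep(3, 3))  # egonet = whole K3
  expect_equal(unname(tri[, "ego_out"]), rep(0, 3))

  st <- base_features(star_net(4))
  expect_equal(st["c0", "ego_within"], 4)
  expect_equal(st["c0", "ego_out"], 0)
  expect_equal(unname(st[paste0("l", 1:4), "degree"]), rep(1, 4))
  expect_equal(unname(st[paste0("l", 1:4), "ego_within"]), rep(1, 4))
  expect_equal(unname(st[paste0("l", 1:4), "ego_out"]), rep(3, 4))

  iso <- interactome(data.frame(from = "a", to = "b", weight = 1),
                     nodes = c("a", "b", "z"))
  expect_equal(unname(base_features(iso)["z", ]), rep(0, 6))
})

test_that("base egonet features agree with an edge-subset enumeration oracle", {
  for (seed in 1:5) {
    net <- rand_net(7, p = 0.45, seed = seed)
    fm <- base_features(net)
    for (v in net$nodes) {
      o <- brute_ego_counts(net, v)
      expect_equal(fm[v, "ego_within"], o$within, ignore_attr = TRUE)
      expect_equal(fm[v, "ego_out"], o$boundary, ignore_attr = TRUE)
      expect_equal(fm[v, "w_ego_within"], o$w_within, ignore_attr = TRUE)
      expect_equal(fm[v, "w_ego_out"], o$w_boundary, ignore_attr = TRUE)
    }
  }
})

test_that("recursive aggregation computes neighbor sums/means and the 6*3^g width", {
  p3 <- path_net()
  fm <- base_features(p3)
  r1 <- recursive_aggregate(fm, p3, iterations = 1)
  expect_equal(unname(r1[c("a", "b", "c"), "degree.s1"]), c(2, 2, 2))
  expect_equal(unname(r1[c("a", "b", "c"), "degree.m1"]), c(2, 1, 2))
  for (g in 0:3) {
    expect_equal(ncol(recursive_aggregate(fm, p3, iterations = g)), 6 * 3^g)
  }
  expect_error(recursive_aggregate(fm, p3, iterations = -1), "non-negative")

  # empty-neighborhood convention: every aggregate of an isolated node is 0
  iso <- interactome(data.frame(from = "a", to = "b", weight = 1),
                     nodes = c("a", "b", "z"))
  r2 <- recursive_aggregate(base_features(iso), iso, iterations = 2)
  expect_equal(unname(r2["z", ]), rep(0, ncol(r2)))
  expect_false(anyNA(r2))
})

test_that("vertical binning follows the recursive rank rule and respects ties", {
  expect_equal(vertical_log_bin(1:8, 0.5), c(0, 0, 0, 0, 1, 1, 2, 3))
  expect_equal(vertical_log_bin(8:1, 0.5), c(3, 2, 1, 1, 0, 0, 0, 0))
  expect_equal(vertical_log_bin(rep(3.7, 9), 0.5), rep(0L, 9))
  expect_equal(vertical_log_bin(numeric(0), 0.5), integer(0))
  # ties extend the current bin past the nominal cut
  expect_equal(vertical_log_bin(c(1, 1, 1, 2), 0.5), c(0, 0, 0, 1))
})

test_that("binning is invariant under strictly increasing transforms", {
  for (seed in 1:10) {
    x <- withr::with_seed(seed, stats::rnorm(25))
    for (p in c(0.3, 0.5, 0.7)) {
      ref <- vertical_log_bin(x, p)
      expect_identical(vertical_log_bin(exp(x), p), ref)
      expect_identical(vertical_log_bin(5 * x - 2, p), ref)
      expect_identical(vertical_log_bin(rank(x, ties.method = "average"), p), ref)
    }
  }
})

test_that("correlation pruning keeps one representative per similarity component", {
  b <- cbind(f1 = c(0L, 1L, 2L), f2 = c(0L, 1L, 2L), f3 = c(0L, 1L, 3L))
  expect_setequal(prune_correlated(b, s = 0), c("f1", "f3"))
  # transitive merge: A~B (s=1) and B~C but A!~C -> one survivor
  b2 <- cbind(A = c(0L, 0L), B = c(1L, 1L), C = c(2L, 2L))
  expect_identical(prune_correlated(b2, s = 1), "A")
  expect_setequal(prune_correlated(b2, s = 0), c("A", "B", "C"))
  # earliest generation order wins within a component
  b3 <- cbind(late = c(0L, 1L), early = c(0L, 1L))
  expect_identical(prune_correlated(b3, s = 0, generation = c(2L, 1L)), "early")
})

test_that("pruning is idempotent", {
  for (seed in 1:5) {
    m <- withr::with_seed(seed, matrix(sample(0L:2L, 40, TRUE), 5, 8,
                                       dimnames = list(NULL, paste0("f", 1:8))))
    kept <- prune_correlated(m, s = 0)
    again <- prune_correlated(m[, kept, drop = FALSE], s = 0)
    expect_identical(again, kept)
  }
})

test_that("schema-mode refex yields the canonical fixed-width block on any graph", {
  nets <- list(triangle_net(), star_net(4), rand_net(12, 0.3, seed = 3),
               cycle_net(5))
  names_ref <- NULL
  for (net in nets) {
    fm <- refex(net)
    expect_equal(ncol(fm), 267)
    expect_equal(nrow(fm), length(net$nodes))
    expect_false(anyNA(fm))
    expect_false(anyDuplicated(colnames(fm)) > 0)
    if (is.null(names_ref)) names_ref <- colnames(fm)
    expect_identical(colnames(fm), names_ref)  # input-independent schema
  }
  expect_equal(ncol(refex(nets[[1]], refex_config(target_width = 6))), 6)
  expect_error(refex(nets[[1]], refex_config(target_width = 1000,
                                             max_iterations = 2)),
               "unreachable")
})

test_that("refex is deterministic and permutation-equivariant", {
  net <- rand_net(10, 0.4, seed = 9)
  a <- refex(net); b <- refex(net)
  expect_identical(a, b)
  # relabeling nodes permutes rows only
  perm <- stats::setNames(sprintf("z%02d", seq_along(net$nodes)), net$nodes)
  e2 <- net$edges
  e2$from <- unname(perm[e2$from]); e2$to <- unname(perm[e2$to])
  net2 <- interactome(e2, nodes = unname(perm[net$nodes]))
  c2 <- refex(net2)
  expect_equal(unname(c2[unname(perm[rownames(a)]), ]), unname(a),
               ignore_attr = TRUE)
})

test_that("research-mode refex collapses node-transitive graphs and is prune-stable", {
  fm <- refex(cycle_net(5), refex_config(prune = TRUE))
  # every node is structurally identical: each column is constant,
  # so a single feature survives
  expect_equal(ncol(fm), 1)
  binned <- apply(fm, 2, vertical_log_bin, p = 0.5)
  if (is.null(dim(binned))) binned <- matrix(binned, ncol = 1,
                                             dimnames = dimnames(fm))
  expect_identical(prune_correlated(binned, s = 0), colnames(fm))

  fm2 <- refex(rand_net(9, 0.4, seed = 5), refex_config(prune = TRUE))
  expect_true(ncol(fm2) >= 1)
  expect_false(anyNA(fm2))
})
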