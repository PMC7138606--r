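test_that("Mann-Whitney exact branch: worked examples", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 2 / 6, tolerance = 1e-12)
  expect_identical(r$method, "exact")
  # identical multisets: central U, p = 1
  r2 <- mann_whitney_u(c(3, 1, 2), c(2, 3, 1))
  expect_equal(r2$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "empty")
})

test_that("Mann-Whitney exact branch equals the enumeration oracle", {
  set.seed(17)
  for (i in 1:50) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    # integer draws so ties occur often
    x <- sample(1:6, n, replace = TRUE); y <- sample(1:6, m, replace = TRUE)
    mine <- mann_whitney_u(x, y)
    oracle <- mw_enumerate(x, y)
    expect_equal(mine$U, oracle$U)
    expect_equal(mine$p_value, oracle$p_value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney normal branch tracks the exact branch near n+m=12", {
  set.seed(23)
  x <- rnorm(8); y <- rnorm(8, 1)
  appr <- mann_whitney_u(x, y)
  expect_identical(appr$method, "normal")
  ref <- suppressWarnings(stats::wilcox.test(x, y))
  expect_equal(appr$U, unname(ref$statistic))
  expect_lt(abs(appr$p_value - ref$p.value), 0.05)
})

test_that("nested permutation test: effect detection and degenerate cases", {
  # strong separation with 6 individuals per group: p near its lower bound
  d <- make_nested(c(107, 187), n_ind = 6, seed = 41)
  r <- nested_group_test(d, n_perm = 999, seed = 1)
  expect_lt(r$p_value, 0.01)
  expect_true(all(r$variance_components >= 0))
  # identical data in both groups: p ~ 1
  set.seed(42)
  v <- 150 + rnorm(60, 0, 14)
  copy <- nested_dataset(rep(v, 2), rep(c("a", "b"), each = 60),
                         rep(rep(1:3, each = 20), 2),
                         rep(rep(1:4, 15), 2))
  rc <- nested_group_test(copy, n_perm = 499, seed = 2, varcomp = "none")
  expect_gt(rc$p_value, 0.9)
  # a single-individual group is confounded and refused
  d1 <- nested_dataset(rnorm(20), rep(c("a", "b"), each = 10),
                       c(rep(1, 10), rep(1, 5), rep(2, 5)),
                       rep(1:2, 10))
  expect_error(nested_group_test(d1), ">= 2 individuals")
})

test_that("REML variance components recover generating values on average", {
  # identifiable design: components well above zero; mean estimate over
  # replicates within 30% relative error of the generating value
  truth <- c(individual = 100, scale = 64, residual = 196)
  est <- t(vapply(1:60, function(i) {
    d <- make_nested(c(150, 190), n_ind = 3, sd_ind = 10, sd_scale = 8,
                     sd_point = 14, seed = 400 + i)
    nested_group_test(d, n_perm = 9, seed = i)$variance_components
  }, numeric(3)))
  expect_true(all(est >= 0))
  expect_true(all(abs(colMeans(est) / truth - 1) < 0.3))
})

test_that("pairwise post-hoc: separation, identity, and adjustment order", {
  # five well-separated groups: all adjusted p below 0.001
  d <- make_nested(c(100, 130, 165, 200, 240) * 3, n_ind = 4, sd_ind = 5,
                   sd_scale = 5, sd_point = 14, seed = 51)
  r <- pairwise_posthoc(d)
  expect_true(all(r$pairs$adj_p < 0.001))
  expect_true(all(r$pairs$adj_p >= r$pairs$raw_p))
  # adjusted p monotone in raw p
  o <- order(r$pairs$raw_p)
  expect_true(all(diff(r$pairs$adj_p[o]) >= -1e-12))
  # two identical groups among three
  set.seed(52)
  base <- rnorm(4, 150, 5)
  d2 <- nested_dataset(
    c(rep(base, each = 10), rep(base, each = 10), rnorm(40, 400, 5)),
    rep(c("a", "b", "c"), each = 40),
    rep(rep(1:4, each = 10), 3), rep(rep(1:2, 20), 3))
  r2 <- pairwise_posthoc(d2)
  ab <- r2$adjusted["a", "b"]
  expect_gt(ab, 0.5)
  expect_lt(r2$adjusted["a", "c"], 0.01)
  expect_error(pairwise_posthoc(make_nested(c(1, 2))), ">= 3 groups")
})

test_that("natural-breaks grouping cuts at the largest gaps", {
  g <- natural_breaks_grouping(c(1, 1.1, 1.2, 5, 5.1), k = 2)
  expect_identical(g$groups_thickness, c(1L, 1L, 1L, 2L, 2L))
  expect_gt(g$breaks_thickness, 1.2); expect_lt(g$breaks_thickness, 5)
  # k = n: every specimen its own group
  gn <- natural_breaks_grouping(c(3, 1, 2), k = 3)
  expect_identical(sort(gn$groups_thickness), 1:3)
  expect_error(natural_breaks_grouping(1:3, k = 4), "exceed")
  # agreement flag: coincident metrics agree, shuffled ones conflict
  th <- c(100, 101, 200, 201, 300, 301)
  g2 <- natural_breaks_grouping(th, wav = th * 2 + 5, k = 3)
  expect_true(g2$agreement)
  g3 <- natural_breaks_grouping(th, wav = c(1, 9, 2, 10, 3, 11), k = 3)
  expect_false(g3$agreement)
})

test_that("planted thickness clusters are recovered across seeds", {
  centers <- c(100, 130, 165, 200, 240)
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    truth <- rep(1:5, each = 4)
    v <- centers[truth] + rnorm(20, 0, 3)
    g <- natural_breaks_grouping(v, k = 5)
    all(tapply(g$groups_thickness, truth, function(x) length(unique(x)) == 1)) &&
      length(unique(g$groups_thickness)) == 5
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
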