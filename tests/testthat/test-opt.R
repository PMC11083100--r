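test_that("beta log ratio matches closed forms and a numerical Beta oracle", {
  expect_equal(beta_log_ratio(0, 0), 0)
  # B(1.5, 1.5) = pi/8, B(0.5, 0.5) = pi
  expect_equal(exp(beta_log_ratio(1, 1)), 0.125, tolerance = 1e-12)
  expect_equal(exp(beta_log_ratio(1, 1)),
               numeric_beta(1.5, 1.5) / numeric_beta(0.5, 0.5),
               tolerance = 1e-8)
  # B(2.5, 0.5) = 0.375 * pi
  expect_equal(exp(beta_log_ratio(2, 0)), 0.375, tolerance = 1e-12)
  expect_equal(exp(beta_log_ratio(2, 0)),
               numeric_beta(2.5, 0.5) / numeric_beta(0.5, 0.5),
               tolerance = 1e-8)
  # fractional (censored) counts go through the same Gamma identities
  expect_equal(exp(beta_log_ratio(0.7, 1.3)),
               numeric_beta(1.2, 1.8) / numeric_beta(0.5, 0.5),
               tolerance = 1e-8)
  expect_error(beta_log_ratio(-1, 0), "nonnegative")
})

test_that("uniform-component log likelihood has its closed form", {
  sq <- region(0, 1, 0, 1)
  expect_equal(log_phi0(sq, 0), 0)
  expect_equal(log_phi0(sq, 5), 0)
  expect_equal(log_phi0(region(0, 2, 0, 1), 3), -3 * log(2))
})

test_that("region construction validates bounds", {
  expect_error(region(1, 1, 0, 1), "lo < hi")
  expect_error(region(0, 1, 2, 1), "lo < hi")
  expect_equal(region_area(region(0, 2, 0, 3)), 6)
})

test_that("recursion log likelihood equals the brute-force expansion", {
  set.seed(11)
  for (np in c(1, 2, 5, 8)) {
    for (dep in 1:3) {
      pts <- cbind(runif(np), runif(np))
      tree <- build_opt(pts, root = region(0, 1, 0, 1),
                        config = opt_config(max_depth = dep))
      expect_equal(opt_log_phi(tree),
                   brute_log_phi(pts, 0, 1, 0, 1, 0, 0, dep),
                   tolerance = 1e-9)
    }
  }
  # non-unit, non-square root region
  pts <- cbind(runif(6, 1, 5), runif(6, 0, 2))
  tree <- build_opt(pts, root = region(1, 5, 0, 2),
                    config = opt_config(max_depth = 3))
  expect_equal(opt_log_phi(tree), brute_log_phi(pts, 1, 5, 0, 2, 0, 0, 3),
               tolerance = 1e-9)
})

test_that("a forced stop reduces the root likelihood to the uniform term", {
  set.seed(2)
  pts <- cbind(runif(5), runif(5))
  # min_count above n makes the root terminal
  tree <- build_opt(pts, root = region(0, 1, 0, 1),
                    config = opt_config(max_depth = 4, min_count = 10))
  expect_equal(opt_log_phi(tree), 0)  # area 1, so log Phi0 = 0
  expect_true(tree$terminal[tree$d1 == 0 & tree$d2 == 0])
})

test_that("the recursion treats the two axes symmetrically", {
  set.seed(3)
  pts <- cbind(runif(10), runif(10))
  cfg <- opt_config(max_depth = 4)
  t1 <- build_opt(pts, root = region(0, 1, 0, 1), config = cfg)
  t2 <- build_opt(pts[, 2:1], root = region(0, 1, 0, 1), config = cfg)
  expect_equal(opt_log_phi(t1), opt_log_phi(t2), tolerance = 1e-12)
})

test_that("child expected counts sum to the parent along each axis", {
  set.seed(4)
  x <- cbind(runif(60), runif(60))
  delta <- matrix(rbinom(120, 1, 0.7), 60, 2)
  d <- em_estimate(x, delta, root = region(0, 1, 0, 1),
                   config = opt_config(max_depth = 5))
  tree <- build_opt(d$counts, root = region(0, 1, 0, 1),
                    config = opt_config(max_depth = 5), counts = TRUE)
  key <- function(d1, i1, d2, i2) paste(d1, i1, d2, i2)
  n_of <- setNames(tree$n, key(tree$d1, tree$i1, tree$d2, tree$i2))
  D <- 5
  int1 <- tree[!tree$terminal & tree$d1 < D, ]  # nodes split along axis 1
  ax1 <- n_of[key(int1$d1 + 1, 2 * int1$i1, int1$d2, int1$i2)] +
    n_of[key(int1$d1 + 1, 2 * int1$i1 + 1, int1$d2, int1$i2)]
  expect_lt(max(abs(ax1 - int1$n)), 1e-9)
  int2 <- tree[!tree$terminal & tree$d2 < D, ]
  ax2 <- n_of[key(int2$d1, int2$i1, int2$d2 + 1, 2 * int2$i2)] +
    n_of[key(int2$d1, int2$i1, int2$d2 + 1, 2 * int2$i2 + 1)]
  expect_lt(max(abs(ax2 - int2$n)), 1e-9)
})

test_that("a tree stopped at the root yields the uniform density", {
  set.seed(5)
  pts <- cbind(runif(5, 0, 2), runif(5, 0, 2))
  tree <- build_opt(pts, root = region(0, 2, 0, 2),
                    config = opt_config(max_depth = 3, min_count = 10))
  d <- density_from_tree(tree)
  expect_equal(max(abs(d$density - 0.25)), 0, tolerance = 1e-12)
  expect_equal(density_integral(d), 1, tolerance = 1e-9)
})

test_that("the posterior-mean cascade matches a direct recursion oracle", {
  set.seed(14)
  for (case in 1:4) {
    dep <- sample(1:3, 1)
    np <- sample(3:8, 1)
    pts <- cbind(runif(np), runif(np))
    tree <- build_opt(pts, root = region(0, 1, 0, 1),
                      config = opt_config(max_depth = dep))
    d <- density_from_tree(tree)
    m <- 2^dep
    got <- d$density / m^2             # density values -> cell masses
    want <- brute_mass(pts, 0, 1, 0, 1, 0, 0, dep)
    expect_equal(got, want, tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(sum(got), 1, tolerance = 1e-9)
  }
})

test_that("density mass concentrates where the samples are", {
  set.seed(6)
  pts <- cbind(runif(200, 0, 0.5), runif(200, 0, 0.5))
  d <- em_estimate(pts, matrix(1, 200, 2), root = region(0, 1, 0, 1),
                   config = opt_config(max_depth = 6))
  qmass <- function(a1, b1, a2, b2) {
    idx1 <- d$breaks1[-length(d$breaks1)] >= a1 & d$breaks1[-1] <= b1
    idx2 <- d$breaks2[-length(d$breaks2)] >= a2 & d$breaks2[-1] <= b2
    sum(d$density[idx1, idx2]) * diff(d$breaks1)[1] * diff(d$breaks2)[1]
  }
  target <- qmass(0, 0.5, 0, 0.5)
  expect_gt(target, qmass(0.5, 1, 0, 0.5))
  expect_gt(target, qmass(0, 0.5, 0.5, 1))
  expect_gt(target, qmass(0.5, 1, 0.5, 1))
  expect_gt(target, 0.9)
})

test_that("expected count is the indicator for fully observed samples", {
  set.seed(7)
  d <- em_estimate(cbind(runif(50), runif(50)), matrix(1, 50, 2),
                   root = region(0, 1, 0, 1),
                   config = opt_config(max_depth = 4))
  r <- region(0, 0.5, 0, 0.5)
  expect_equal(expected_count(r, c(0.2, 0.2), c(1, 1), d), 1)
  expect_equal(expected_count(r, c(0.7, 0.2), c(1, 1), d), 0)
})

test_that("tail conditioning excludes regions below the censoring time", {
  set.seed(8)
  d <- em_estimate(cbind(runif(50, 0, 10), runif(50, 0, 10)),
                   matrix(1, 50, 2), root = region(0, 10, 0, 10),
                   config = opt_config(max_depth = 4))
  # censored at x1 = 5: a region entirely below t1 = 5 has probability 0
  expect_equal(expected_count(region(0, 5, 0, 10), c(5, 2), c(0, 1), d), 0)
  # probabilities over a partition of the conditioning set sum to one
  p_lo <- expected_count(region(5, 10, 0, 10), c(5, 3), c(0, 1), d)
  expect_equal(p_lo, 1, tolerance = 1e-9)
})

test_that("without censoring the EM reduces to a single OPT pass", {
  set.seed(9)
  x <- cbind(runif(80), runif(80))
  cfg <- opt_config(max_depth = 5)
  d <- em_estimate(x, matrix(1, 80, 2), root = region(0, 1, 0, 1),
                   config = cfg)
  tree <- build_opt(x, root = region(0, 1, 0, 1), config = cfg)
  expect_identical(as.vector(d$counts), as.vector(attr(tree, "counts")))
  single <- density_from_tree(tree)
  expect_identical(as.vector(d$density), as.vector(single$density))
  expect_true(d$converged)
  expect_identical(d$iterations, 1L)
})

test_that("samples censored at the origin leave the density uniform", {
  n <- 20
  x <- matrix(0, n, 2)
  delta <- matrix(0L, n, 2)
  d <- em_estimate(x, delta, root = region(0, 1, 0, 1),
                   config = opt_config(max_depth = 4))
  expect_equal(max(abs(d$density - 1)), 0, tolerance = 1e-9)
  expect_true(d$converged)
})

test_that("every fitted density integrates to one", {
  set.seed(10)
  for (k in 1:20) {
    n <- sample(10:80, 1)
    x <- cbind(runif(n, 0, 5), runif(n, 0, 5))
    delta <- matrix(rbinom(2 * n, 1, runif(1, 0.3, 1)), n, 2)
    d <- suppressWarnings(
      em_estimate(x, delta, root = region(0, 5, 0, 5),
                  config = opt_config(max_depth = sample(2:5, 1))))
    expect_equal(density_integral(d), 1, tolerance = 1e-6)
  }
})

test_that("the estimate tightens around uniform as n grows", {
  # uncensored uniform data: sup deviation from the flat density should
  # shrink when the sample size doubles, for most seeds
  wins <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    cfg <- opt_config(max_depth = 5)
    d1 <- em_estimate(cbind(runif(2000), runif(2000)), matrix(1, 2000, 2),
                      root = region(0, 1, 0, 1), config = cfg)
    d2 <- em_estimate(cbind(runif(4000), runif(4000)), matrix(1, 4000, 2),
                      root = region(0, 1, 0, 1), config = cfg)
    if (max(abs(d2$density - 1)) < max(abs(d1$density - 1))) wins <- wins + 1
  }
  expect_gte(wins, 6)
})

test_that("non-convergence is reported with a warning, not an error", {
  set.seed(12)
  x <- cbind(runif(100), runif(100))
  delta <- matrix(rbinom(200, 1, 0.4), 100, 2)
  expect_warning(
    d <- em_estimate(x, delta, root = region(0, 1, 0, 1),
                     config = opt_config(max_depth = 5, em_max_iter = 1)),
    "did not converge")
  expect_false(d$converged)
})

test_that("points outside the root region are rejected", {
  expect_error(
    em_estimate(cbind(c(0.5, 2), c(0.5, 0.5)), matrix(1, 2, 2),
                root = region(0, 1, 0, 1)),
    "outside the root")
})

test_that("density JSON serialisation round-trips the pieces", {
  set.seed(13)
  d <- em_estimate(cbind(runif(30), runif(30)), matrix(1, 30, 2),
                   root = region(0, 1, 0, 1),
                   config = opt_config(max_depth = 2))
  path <- tempfile(fileext = ".json")
  write_density_json(d, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$domain$hi1, 1)
  expect_equal(nrow(back$pieces), 16)
  expect_equal(sum(back$pieces$density * (back$pieces$hi1 - back$pieces$lo1) *
                     (back$pieces$hi2 - back$pieces$lo2)), 1,
               tolerance = 1e-9)
})
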