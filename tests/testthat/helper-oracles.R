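# Independent oracles used across the test files.  These deliberately
# avoid the package's recursion/memoisation machinery: the OPT oracle
# re-counts points region by region, the geometry oracle uses Monte Carlo.

# Brute-force OPT log marginal likelihood: direct expansion of the
# recursion with explicit point counting in every (sub)region.  Each axis
# may be bisected at most max_depth times; the split weight is 1/4 per
# axis while both remain available and 1/2 for the last one.
brute_log_phi <- function(pts, lo1, hi1, lo2, hi2, d1, d2, max_depth,
                          min_count = 1e-3) {
  inreg <- pts[, 1] >= lo1 & pts[, 1] < hi1 & pts[, 2] >= lo2 & pts[, 2] < hi2
  n <- sum(inreg)
  l0 <- -n * log((hi1 - lo1) * (hi2 - lo2))
  if ((d1 >= max_depth && d2 >= max_depth) || n <= min_count) return(l0)
  lw <- if (d1 < max_depth && d2 < max_depth) log(0.25) else log(0.5)
  m1 <- (lo1 + hi1) / 2
  m2 <- (lo2 + hi2) / 2
  cnt <- function(a, b, c, d)
    sum(pts[, 1] >= a & pts[, 1] < b & pts[, 2] >= c & pts[, 2] < d)
  s <- log(0.5) + l0
  if (d1 < max_depth) {
    s <- c(s, lw +
      beta_log_ratio(cnt(lo1, m1, lo2, hi2), cnt(m1, hi1, lo2, hi2)) +
      brute_log_phi(pts, lo1, m1, lo2, hi2, d1 + 1, d2, max_depth,
                    min_count) +
      brute_log_phi(pts, m1, hi1, lo2, hi2, d1 + 1, d2, max_depth,
                    min_count))
  }
  if (d2 < max_depth) {
    s <- c(s, lw +
      beta_log_ratio(cnt(lo1, hi1, lo2, m2), cnt(lo1, hi1, m2, hi2)) +
      brute_log_phi(pts, lo1, hi1, lo2, m2, d1, d2 + 1, max_depth,
                    min_count) +
      brute_log_phi(pts, lo1, hi1, m2, hi2, d1, d2 + 1, max_depth,
                    min_count))
  }
  mx <- max(s)
  mx + log(sum(exp(s - mx)))
}

# Brute-force posterior-mean cell masses: direct recursion over regions
# (no memoisation, prefix sums or difference arrays).  Returns the
# 2^(max_depth - d1) x 2^(max_depth - d2) matrix of masses the subtree
# deposits on its finest cells, given inflow mass mu.
brute_mass <- function(pts, lo1, hi1, lo2, hi2, d1, d2, max_depth,
                       min_count = 1e-3, mu = 1) {
  nr <- 2^(max_depth - d1)
  nc <- 2^(max_depth - d2)
  inreg <- pts[, 1] >= lo1 & pts[, 1] < hi1 & pts[, 2] >= lo2 & pts[, 2] < hi2
  n <- sum(inreg)
  if ((d1 >= max_depth && d2 >= max_depth) || n <= min_count)
    return(matrix(mu / (nr * nc), nr, nc))
  lphi <- brute_log_phi(pts, lo1, hi1, lo2, hi2, d1, d2, max_depth,
                        min_count)
  l0 <- -n * log((hi1 - lo1) * (hi2 - lo2))
  lw <- if (d1 < max_depth && d2 < max_depth) log(0.25) else log(0.5)
  m1 <- (lo1 + hi1) / 2
  m2 <- (lo2 + hi2) / 2
  cnt <- function(a, b, c, d)
    sum(pts[, 1] >= a & pts[, 1] < b & pts[, 2] >= c & pts[, 2] < d)
  rho <- exp(log(0.5) + l0 - lphi)
  out <- matrix(mu * rho / (nr * nc), nr, nc)
  if (d1 < max_depth) {
    na <- cnt(lo1, m1, lo2, hi2)
    q1 <- exp(lw + beta_log_ratio(na, n - na) +
                brute_log_phi(pts, lo1, m1, lo2, hi2, d1 + 1, d2,
                              max_depth, min_count) +
                brute_log_phi(pts, m1, hi1, lo2, hi2, d1 + 1, d2,
                              max_depth, min_count) - lphi)
    fa <- (na + 0.5) / (n + 1)
    out <- out + rbind(
      brute_mass(pts, lo1, m1, lo2, hi2, d1 + 1, d2, max_depth, min_count,
                 mu * q1 * fa),
      brute_mass(pts, m1, hi1, lo2, hi2, d1 + 1, d2, max_depth, min_count,
                 mu * q1 * (1 - fa)))
  }
  if (d2 < max_depth) {
    nb <- cnt(lo1, hi1, lo2, m2)
    q2 <- exp(lw + beta_log_ratio(nb, n - nb) +
                brute_log_phi(pts, lo1, hi1, lo2, m2, d1, d2 + 1,
                              max_depth, min_count) +
                brute_log_phi(pts, lo1, hi1, m2, hi2, d1, d2 + 1,
                              max_depth, min_count) - lphi)
    fb <- (nb + 0.5) / (n + 1)
    out <- out + cbind(
      brute_mass(pts, lo1, hi1, lo2, m2, d1, d2 + 1, max_depth, min_count,
                 mu * q2 * fb),
      brute_mass(pts, lo1, hi1, m2, hi2, d1, d2 + 1, max_depth, min_count,
                 mu * q2 * (1 - fb)))
  }
  out
}

# Monte-Carlo estimate of the below-diagonal area fraction of a rectangle.
mc_lower_fraction <- function(lo1, hi1, lo2, hi2, n = 2e5) {
  t1 <- runif(n, lo1, hi1)
  t2 <- runif(n, lo2, hi2)
  mean(t1 < t2)
}

# Numerical Beta function via direct integration of the integrand.
numeric_beta <- function(a, b) {
  stats::integrate(function(t) t^(a - 1) * (1 - t)^(b - 1), 0, 1,
                   rel.tol = 1e-10)$value
}

# Hand-rolled density object on a regular grid (for geometry tests).
grid_density <- function(mass, lo = 0, hi = 1) {
  m <- nrow(mass)
  cell_area <- ((hi - lo) / m)^2
  structure(list(density = mass / sum(mass) / cell_area,
                 breaks1 = seq(lo, hi, length.out = m + 1),
                 breaks2 = seq(lo, hi, length.out = m + 1),
                 domain = region(lo, hi, lo, hi),
                 iterations = NA_integer_, converged = NA),
            class = "cepa_density")
}

# Small chain cohort with a strict event order, in long format.
chain_cohort <- function(n, labels = c("A", "B", "C"), censor = 0) {
  t1 <- pmin(ceiling(rexp(n, 1 / 4)), 40)
  tabs <- list(t1)
  for (k in seq_along(labels)[-1])
    tabs[[k]] <- pmin(tabs[[k - 1]] + pmax(1, ceiling(rexp(n, 1 / 3))), 50)
  rows <- lapply(seq_along(labels), function(k) {
    cens <- runif(n) < censor
    data.frame(subject_id = sprintf("S%04d", seq_len(n)), event = labels[k],
               time = ifelse(cens, 53, tabs[[k]]),
               status = as.integer(!cens))
  })
  do.call(rbind, rows)
}
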