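#' Rectangular region of the event-time plane
#'
#' Regions are half-open rectangles `[lo1, hi1) x [lo2, hi2)`: a point on
#' the upper boundary of a cell belongs to the next cell up.  The root
#' region of an OPT fit must contain every observation.
#'
#' @param lo1,hi1 Bounds on the first (x) axis, `lo1 < hi1`.
#' @param lo2,hi2 Bounds on the second (y) axis, `lo2 < hi2`.
#' @return An object of class `cepa_region`.
#' @examples
#' region(0, 1, 0, 1)
#' @export
region <- function(lo1, hi1, lo2, hi2) {
  stopifnot(is.numeric(lo1), is.numeric(hi1), is.numeric(lo2), is.numeric(hi2),
            is.finite(c(lo1, hi1, lo2, hi2)))
  if (lo1 >= hi1 || lo2 >= hi2)
    stop("region must satisfy lo < hi on both axes")
  structure(list(lo1 = lo1, hi1 = hi1, lo2 = lo2, hi2 = hi2),
            class = "cepa_region")
}

#' @export
print.cepa_region <- function(x, ...) {
  cat(sprintf("<region [%g, %g) x [%g, %g)>\n", x$lo1, x$hi1, x$lo2, x$hi2))
  invisible(x)
}

#' Area of a region
#' @param r A [region()].
#' @return Numeric area.
#' @export
region_area <- function(r) {
  (r$hi1 - r$lo1) * (r$hi2 - r$lo2)
}

#' Log of the adjusted Beta-function ratio
#'
#' Computes `log[B(n1 + 1/2, n2 + 1/2) / B(1/2, 1/2)]`, the weight the OPT
#' recursion gives to a binary split with child counts `n1` and `n2`.
#' Counts may be fractional: censored observations contribute fractional
#' expected mass to child regions.  Evaluated via `lgamma` so that large
#' counts do not underflow.
#'
#' @param n1,n2 Nonnegative (possibly fractional) counts.  Vectorised.
#' @return `log B(n1+0.5, n2+0.5) - log B(0.5, 0.5)`.
#' @examples
#' beta_log_ratio(0, 0)  # 0
#' exp(beta_log_ratio(1, 1))  # 1/8
#' @export
beta_log_ratio <- function(n1, n2) {
  if (any(n1 < 0) || any(n2 < 0))
    stop("counts must be nonnegative")
  lgamma(n1 + 0.5) + lgamma(n2 + 0.5) - lgamma(n1 + n2 + 1) - log(pi)
}

#' Log-likelihood of n uniform points on a region
#'
#' The "stop" component of the OPT mixture: the likelihood of `n` samples
#' distributed uniformly over the region, `area(A)^(-n)`, in log form.
#'
#' @param r A [region()].
#' @param n Nonnegative (possibly fractional) sample count.
#' @return `-n * log(area(r))`.
#' @export
log_phi0 <- function(r, n) {
  stopifnot(inherits(r, "cepa_region"), n >= 0)
  -n * log(region_area(r))
}

#' OPT fitting configuration
#'
#' @param max_depth Maximum number of midpoint bisections per axis, i.e.
#'   the finest partition has `2^max_depth` cells along each axis.  While
#'   both axes can still be split the recursion weighs each axis's split
#'   term by 1/4; once an axis is exhausted the remaining axis's term
#'   carries weight 1/2.  The default 6 resolves the 1-53 week grid
#'   (`2^6 = 64` cells) and suits cohort- and benchmark-sized samples;
#'   raise it for larger, finer-grained data.
#' @param min_count Stop splitting a region once its (expected) sample
#'   count falls to this value or below.
#' @param em_tol EM convergence tolerance: total variation distance
#'   (total mass movement) between successive density estimates.
#' @param em_max_iter Maximum number of EM iterations.
#' @return An object of class `cepa_config`.
#' @export
opt_config <- function(max_depth = 6, min_count = 1e-3, em_tol = 1e-6,
                       em_max_iter = 100) {
  stopifnot(max_depth >= 1, max_depth <= 10, min_count >= 0, em_tol > 0,
            em_max_iter >= 1)
  structure(list(max_depth = as.integer(max_depth), min_count = min_count,
                 em_tol = em_tol, em_max_iter = as.integer(em_max_iter)),
            class = "cepa_config")
}

# default square root region covering all (finite) observations:
# [0, 1.001 * max) so the largest observation stays strictly inside
default_root <- function(x) {
  hi <- 1.001 * max(x)
  if (hi <= 0) hi <- 1
  region(0, hi, 0, hi)
}

# bin fully observed points onto the 2^max_depth grid of a root region
bin_points <- function(x, root, max_depth) {
  m <- 2L^max_depth
  w1 <- (root$hi1 - root$lo1) / m
  w2 <- (root$hi2 - root$lo2) / m
  i <- pmin(floor((x[, 1] - root$lo1) / w1), m - 1)
  j <- pmin(floor((x[, 2] - root$lo2) / w2), m - 1)
  if (any(x[, 1] < root$lo1 | x[, 1] >= root$hi1 |
          x[, 2] < root$lo2 | x[, 2] >= root$hi2))
    stop("points outside the root region")
  counts <- matrix(0, m, m)
  for (s in seq_len(nrow(x)))
    counts[i[s] + 1, j[s] + 1] <- counts[i[s] + 1, j[s] + 1] + 1
  counts
}

#' Build the OPT recursion tree
#'
#' Evaluates the OPT marginal likelihood recursion over the dyadic
#' partition of `root`: each region is either left undivided (likelihood
#' `Phi0`, weight 1/2) or bisected at the midpoint of one of the two axes
#' (weight 1/4 each while both axes can still be split, 1/2 for the last
#' available axis), with each split weighted by the Beta-ratio of its
#' child counts.  Regions reachable by different split orders coincide, so
#' the set of evaluated nodes forms a DAG and is returned as a table.
#'
#' @param x Either a two-column matrix of fully observed points, or an
#'   `m x m` matrix of per-cell (expected) counts with `m = 2^max_depth`
#'   passed via `counts = TRUE`.
#' @param root Root [region()]; defaults to `[0, 1.001 max)` squared for
#'   point input.
#' @param config An [opt_config()].
#' @param counts Set `TRUE` when `x` is already a count grid.
#' @return An object of class `cepa_opt_tree`: a data frame with one row
#'   per evaluated node (depths, indices, bounds, count `n`, `log_phi`,
#'   `log_phi0`, `terminal`), with the count grid, root and config attached
#'   as attributes.  The root node's `log_phi` is the OPT log marginal
#'   likelihood of the data.
#' @export
build_opt <- function(x, root = NULL, config = opt_config(), counts = FALSE) {
  stopifnot(inherits(config, "cepa_config"))
  if (counts) {
    grid <- as.matrix(x)
    if (is.null(root)) stop("root region required for count-grid input")
  } else {
    x <- as.matrix(x)
    if (ncol(x) != 2) stop("point input must have two columns")
    if (is.null(root)) root <- default_root(x)
    grid <- bin_points(x, root, config$max_depth)
  }
  m <- 2L^config$max_depth
  if (!all(dim(grid) == c(m, m)))
    stop(sprintf("count grid must be %d x %d for max_depth %d", m, m,
                 config$max_depth))
  tab <- cpp_opt_tree(grid, root$lo1, root$hi1, root$lo2, root$hi2,
                      config$max_depth, config$min_count)
  out <- as.data.frame(tab)
  out$terminal <- as.logical(out$terminal)
  structure(out, counts = grid, root = root, config = config,
            class = c("cepa_opt_tree", "data.frame"))
}

#' OPT log marginal likelihood at the root
#' @param tree A [build_opt()] result.
#' @return The root node's `log_phi`.
#' @export
opt_log_phi <- function(tree) {
  stopifnot(inherits(tree, "cepa_opt_tree"))
  tree$log_phi[tree$d1 == 0 & tree$d2 == 0]
}

new_cepa_density <- function(dens, root, config, counts = NULL,
                             iterations = NA_integer_, converged = NA) {
  m <- nrow(dens)
  breaks1 <- seq(root$lo1, root$hi1, length.out = m + 1)
  breaks2 <- seq(root$lo2, root$hi2, length.out = m + 1)
  structure(list(density = dens, breaks1 = breaks1, breaks2 = breaks2,
                 domain = root, config = config, counts = counts,
                 iterations = iterations, converged = converged),
            class = "cepa_density")
}

#' Piecewise-constant joint density from an OPT tree
#'
#' Turns the fitted recursion into a posterior-mean density: at each node
#' the stopping probability `rho(A) = Phi0(A) / (2 Phi(A))` assigns its
#' share of mass uniformly over the node, the remainder is divided between
#' the two axes in proportion to their terms in the OPT mixture, and
#' between the two children of a split by the posterior-mean fraction
#' `(N(child) + 1/2) / (N(A) + 1)`.  The result integrates to one over the
#' root region.
#'
#' @param tree A [build_opt()] result.
#' @return An object of class `cepa_density`: a piecewise-constant density
#'   on the dyadic grid, with `$density` (matrix of density values, rows =
#'   x-axis cells), `$breaks1`, `$breaks2`, and `$domain`.
#' @export
density_from_tree <- function(tree) {
  stopifnot(inherits(tree, "cepa_opt_tree"))
  root <- attr(tree, "root")
  config <- attr(tree, "config")
  grid <- attr(tree, "counts")
  dens <- cpp_opt_density(grid, root$lo1, root$hi1, root$lo2, root$hi2,
                          config$max_depth, config$min_count)
  new_cepa_density(dens, root, config, counts = grid, iterations = 1L,
                   converged = TRUE)
}

#' @export
print.cepa_density <- function(x, ...) {
  m <- nrow(x$density)
  cat(sprintf("<cepa_density: %d x %d grid on [%g, %g) x [%g, %g)>\n",
              m, m, x$domain$lo1, x$domain$hi1, x$domain$lo2, x$domain$hi2))
  cat(sprintf("  integral = %.8f", density_integral(x)))
  if (!is.na(x$iterations))
    cat(sprintf("; EM iterations = %d, converged = %s", x$iterations,
                x$converged))
  cat("\n")
  invisible(x)
}

#' Integral of a piecewise density over its domain
#' @param density A `cepa_density`.
#' @return Numeric; 1 up to numerical error for any fitted density.
#' @export
density_integral <- function(density) {
  cell_area <- diff(density$breaks1)[1] * diff(density$breaks2)[1]
  sum(density$density) * cell_area
}

#' @export
as.data.frame.cepa_density <- function(x, ...) {
  m <- nrow(x$density)
  data.frame(
    lo1 = rep(x$breaks1[-(m + 1)], times = m),
    hi1 = rep(x$breaks1[-1], times = m),
    lo2 = rep(x$breaks2[-(m + 1)], each = m),
    hi2 = rep(x$breaks2[-1], each = m),
    density = as.vector(x$density)
  )
}

# integral of the density over an arbitrary rectangle (partial cells
# handled by overlap fractions)
density_rect_mass <- function(density, lo1, hi1, lo2, hi2) {
  ov1 <- interval_overlap(density$breaks1, lo1, hi1)
  ov2 <- interval_overlap(density$breaks2, lo2, hi2)
  as.numeric(ov1 %*% density$density %*% ov2)
}

# per-cell overlap lengths of [a, b) with the cells defined by breaks
interval_overlap <- function(breaks, a, b) {
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  pmax(0, pmin(hi, b) - pmax(lo, a))
}

#' Expected count of one censored sample in a region
#'
#' The E-step kernel of the censored OPT fit: the probability, under the
#' current density estimate, that a sample's latent event times fall in
#' `r`, given what was observed.  A fully observed sample contributes its
#' indicator.  A sample censored in coordinate `j` at `x_j` is conditioned
#' on the tail `{t_j > x_j}`; an observed coordinate is conditioned on its
#' containing grid cell (the density is constant within a cell, so this
#' equals conditioning on the exact value).  If the conditioning set has
#' zero probability the allocation falls back to uniform over the set.
#'
#' @param r A [region()].
#' @param x Length-2 numeric vector of observed times.
#' @param delta Length-2 vector of event indicators (1 observed,
#'   0 censored).
#' @param density A `cepa_density` whose domain contains `x`.
#' @return A probability in `[0, 1]`.
#' @export
expected_count <- function(r, x, delta, density) {
  stopifnot(inherits(r, "cepa_region"), length(x) == 2, length(delta) == 2,
            all(delta %in% c(0, 1)))
  dom <- density$domain
  # conditioning set per axis as an interval
  cond_axis <- function(xv, dl, breaks, dlo, dhi) {
    if (dl == 1) {
      k <- findInterval(xv, breaks, rightmost.closed = FALSE)
      k <- min(max(k, 1L), length(breaks) - 1L)
      c(breaks[k], breaks[k + 1])
    } else {
      c(xv, dhi)
    }
  }
  s1 <- cond_axis(x[1], delta[1], density$breaks1, dom$lo1, dom$hi1)
  s2 <- cond_axis(x[2], delta[2], density$breaks2, dom$lo2, dom$hi2)
  if (all(delta == 1)) {
    return(as.numeric(x[1] >= r$lo1 && x[1] < r$hi1 &&
                      x[2] >= r$lo2 && x[2] < r$hi2))
  }
  denom <- density_rect_mass(density, s1[1], s1[2], s2[1], s2[2])
  rlo1 <- max(r$lo1, s1[1]); rhi1 <- min(r$hi1, s1[2])
  rlo2 <- max(r$lo2, s2[1]); rhi2 <- min(r$hi2, s2[2])
  if (rlo1 >= rhi1 || rlo2 >= rhi2) return(0)
  if (denom > 0) {
    num <- density_rect_mass(density, rlo1, rhi1, rlo2, rhi2)
    num / denom
  } else {
    # uniform fallback over the conditioning set
    ((rhi1 - rlo1) * (rhi2 - rlo2)) /
      ((s1[2] - s1[1]) * (s2[2] - s2[1]))
  }
}

#' Censored bivariate density estimation (OPT + EM)
#'
#' Estimates the joint density of two right-censored event times.  The
#' density is initialised uniform on the root region; each iteration
#' allocates every censored observation across the grid according to the
#' current density conditioned on its censoring pattern (E-step), then
#' refits the OPT posterior-mean density to the expected counts (M-step).
#' Iteration stops when the total variation distance between successive
#' densities falls below `config$em_tol` or after `config$em_max_iter`
#' iterations.  With no censored observations the fit reduces exactly to a
#' single OPT pass on the observed counts.
#'
#' @param times Two-column matrix of observed times `X = min(T, C)`.
#' @param status Two-column matrix of event indicators
#'   `Delta = I(T <= C)`.
#' @param root Root [region()]; default `[0, 1.001 max(times))` squared.
#' @param config An [opt_config()].
#' @return A `cepa_density` with `$iterations` and `$converged`; the final
#'   expected-count grid is kept in `$counts`.
#' @examples
#' x <- cbind(runif(50), runif(50) + 1)
#' d <- em_estimate(x, matrix(1, 50, 2), config = opt_config(max_depth = 4))
#' density_integral(d)
#' @export
em_estimate <- function(times, status, root = NULL, config = opt_config()) {
  times <- as.matrix(times)
  status <- as.matrix(status)
  stopifnot(ncol(times) == 2, all(dim(times) == dim(status)),
            nrow(times) >= 1, all(status %in% c(0, 1)),
            all(is.finite(times)), all(times >= 0),
            inherits(config, "cepa_config"))
  if (is.null(root)) root <- default_root(times)
  fit <- cpp_cepa_fit(times[, 1], times[, 2], as.integer(status[, 1]),
                      as.integer(status[, 2]), root$lo1, root$hi1, root$lo2,
                      root$hi2, config$max_depth, config$min_count,
                      config$em_tol, config$em_max_iter)
  if (!fit$converged)
    warning(sprintf("EM did not converge in %d iterations", fit$iterations))
  new_cepa_density(fit$density, root, config, counts = fit$counts,
                   iterations = fit$iterations, converged = fit$converged)
}

#' Serialize a joint density to JSON
#'
#' Writes `{domain, pieces: [{lo1, hi1, lo2, hi2, density}]}`.
#'
#' @param density A `cepa_density`.
#' @param path Output file path.
#' @export
write_density_json <- function(density, path) {
  dom <- density$domain
  obj <- list(domain = list(lo1 = dom$lo1, hi1 = dom$hi1, lo2 = dom$lo2,
                            hi2 = dom$hi2),
              pieces = as.data.frame(density))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
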