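#' Fraction of a rectangle below the diagonal
#'
#' Exact area fraction of `{(t1, t2) in r : t1 < t2}`, the geometric kernel
#' used to integrate a piecewise-constant density over the half-plane
#' where the first event precedes the second.
#'
#' @param r A [region()], or vectors of bounds via `lo1, hi1, lo2, hi2`.
#' @return Fraction in `[0, 1]`.
#' @examples
#' rectangle_lower_fraction(region(0, 1, 0, 1))  # 0.5
#' rectangle_lower_fraction(region(0, 2, 0, 1))  # 0.25
#' @export
rectangle_lower_fraction <- function(r) {
  lower_fraction_vec(r$lo1, r$hi1, r$lo2, r$hi2)
}

# vectorised over rectangle bounds; integrates length of {t2 > t1} along t1:
# the integrand clamp(hi2 - t1, 0, hi2 - lo2) is constant below lo2,
# triangular between lo2 and hi2, zero above
lower_fraction_vec <- function(lo1, hi1, lo2, hi2) {
  res <- numeric(length(lo1))
  for (k in seq_along(res)) {
    t0 <- lo1[k]; t1 <- hi1[k]; b0 <- lo2[k]; b1 <- hi2[k]
    h <- b1 - b0
    # segment 1: t < b0 -> height h
    s1 <- max(0, min(t1, b0) - t0)
    # segment 2: b0 <= t < b1 -> height b1 - t
    lo <- max(t0, b0); hi <- min(t1, b1)
    s2 <- if (hi > lo) (b1 - lo)^2 / 2 - (b1 - hi)^2 / 2 else 0
    res[k] <- (s1 * h + s2) / ((t1 - t0) * h)
  }
  res
}

#' Probability that the first event precedes the second
#'
#' Integrates a fitted joint density over `{t1 < t2}`.  Because the
#' density is continuous (piecewise constant over cells of positive area),
#' the tie set `{t1 = t2}` has measure zero, so this equals the
#' conditional precedence probability given that the two times differ.
#'
#' @param density A `cepa_density`.
#' @return `Pr(T1 < T2)` in `[0, 1]`.
#' @export
precedence_probability <- function(density) {
  m1 <- length(density$breaks1) - 1
  m2 <- length(density$breaks2) - 1
  lo1 <- rep(density$breaks1[-(m1 + 1)], times = m2)
  hi1 <- rep(density$breaks1[-1], times = m2)
  lo2 <- rep(density$breaks2[-(m2 + 1)], each = m1)
  hi2 <- rep(density$breaks2[-1], each = m1)
  frac <- lower_fraction_grid(density$breaks1, density$breaks2)
  cell_area <- diff(density$breaks1)[1] * diff(density$breaks2)[1]
  sum(density$density * frac) * cell_area
}

# m1 x m2 matrix of lower fractions for a grid (fast path: most cells are
# entirely above or below the diagonal)
lower_fraction_grid <- function(breaks1, breaks2) {
  m1 <- length(breaks1) - 1
  m2 <- length(breaks2) - 1
  lo1 <- breaks1[-(m1 + 1)]; hi1 <- breaks1[-1]
  lo2 <- breaks2[-(m2 + 1)]; hi2 <- breaks2[-1]
  out <- matrix(0, m1, m2)
  for (j in seq_len(m2)) {
    below <- hi1 <= lo2[j]          # entirely t1 < t2
    above <- lo1 >= hi2[j]          # entirely t1 >= t2
    out[below, j] <- 1
    mid <- which(!below & !above)
    if (length(mid))
      out[mid, j] <- lower_fraction_vec(lo1[mid], hi1[mid],
                                        rep(lo2[j], length(mid)),
                                        rep(hi2[j], length(mid)))
  }
  out
}

#' All-pairs precedence matrix
#'
#' Fits a censored bivariate density for each of the `k(k-1)/2` unordered
#' event pairs and records `p[i, j] = Pr(event i before event j)`; the
#' complementary entry is `1 - p[i, j]`.  Exactly `choose(k, 2)` density
#' estimations are performed.
#'
#' @param times `n x k` matrix of observed times, one column per event;
#'   column names are the event labels.
#' @param status `n x k` matrix of event indicators (1 observed,
#'   0 censored).
#' @param root Shared root [region()] for every pair; default per pair
#'   `[0, 1.001 max)` squared over that pair's times.
#' @param config An [opt_config()].
#' @return A `cepa_precedence` object: the `k x k` probability matrix with
#'   `NA` on the diagonal and event labels as dimnames.
#' @export
pairwise_matrix <- function(times, status, root = NULL,
                            config = opt_config()) {
  times <- as.matrix(times)
  status <- as.matrix(status)
  k <- ncol(times)
  if (k < 2) stop("at least two events are required")
  stopifnot(all(dim(times) == dim(status)))
  labels <- colnames(times)
  if (is.null(labels)) labels <- paste0("E", seq_len(k))
  p <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      r <- if (is.null(root)) default_root(times[, c(i, j)]) else root
      d <- em_estimate(times[, c(i, j)], status[, c(i, j)], root = r,
                       config = config)
      p[i, j] <- precedence_probability(d)
      p[j, i] <- 1 - p[i, j]
    }
  }
  as_precedence(p)
}

#' Construct a precedence matrix from given probabilities
#'
#' @param p Square numeric matrix with dimnames; off-diagonal entries must
#'   satisfy `p[i, j] + p[j, i] = 1` (checked to 1e-9).
#' @return A `cepa_precedence` object.
#' @export
as_precedence <- function(p) {
  p <- as.matrix(p)
  stopifnot(nrow(p) == ncol(p))
  if (is.null(rownames(p))) {
    dimnames(p) <- list(paste0("E", seq_len(nrow(p))),
                        paste0("E", seq_len(nrow(p))))
  }
  off <- upper.tri(p)
  if (any(abs(p[off] + t(p)[off] - 1) > 1e-9, na.rm = TRUE))
    stop("p[i, j] + p[j, i] must equal 1 off the diagonal")
  diag(p) <- NA_real_
  structure(p, class = c("cepa_precedence", "matrix"))
}

#' @export
print.cepa_precedence <- function(x, digits = 3, ...) {
  cat(sprintf("<precedence matrix, %d events> p[i, j] = Pr(i before j)\n",
              nrow(x)))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Write a precedence matrix to CSV (labels as header row/column)
#' @param pm A `cepa_precedence`.
#' @param path Output file.
#' @export
write_precedence_csv <- function(pm, path) {
  write.csv(as.data.frame(unclass(pm)), path, row.names = TRUE)
  invisible(path)
}

#' Read a precedence matrix written by [write_precedence_csv()]
#' @param path CSV file.
#' @return A `cepa_precedence`.
#' @export
read_precedence_csv <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  as_precedence(as.matrix(df))
}
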