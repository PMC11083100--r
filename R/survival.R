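#' Kaplan-Meier survival curve
#'
#' Standard product-limit estimator (right-censored observations leave the
#' risk set without contributing an event), computed with
#' [survival::survfit()].
#'
#' @param times Nonnegative observation times `X = min(T, C)`.
#' @param status Event indicators (1 observed, 0 censored).
#' @return A `cepa_survival` data frame: `time`, `surv` (right-continuous
#'   `Pr(T > t)`), and `surv_left` (`Pr(T >= t)`, the left limit used by
#'   [median_overall()]).
#' @examples
#' km_curve(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 1))
#' @export
km_curve <- function(times, status) {
  stopifnot(length(times) == length(status), length(times) >= 1,
            all(status %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, status) ~ 1)
  out <- data.frame(time = fit$time, surv = fit$surv,
                    surv_left = c(1, fit$surv[-length(fit$surv)]))
  structure(out, class = c("cepa_survival", "data.frame"),
            estimator = "km")
}

#' Univariate OPT survival curve
#'
#' One-dimensional specialisation of the censored OPT/EM machinery: a
#' region is either left undivided (weight 1/2) or bisected at its
#' midpoint (weight 1/2, scaled by the Beta-ratio of the child counts).
#' Censored observations are allocated over their tail `{t > x}` under the
#' current density and refit iteratively, exactly as in [em_estimate()].
#' The survival curve is `1 - CDF` of the estimated piecewise-constant
#' density, evaluated at the partition breaks (piecewise linear in
#' between, so the curve is continuous and `surv_left = surv`).
#'
#' @param times,status As in [km_curve()].
#' @param root_interval Length-2 interval containing all times; default
#'   `c(0, 1.001 * max(times))`.
#' @param config An [opt_config()].
#' @return A `cepa_survival` data frame with the fitted density attached
#'   as attributes `breaks` and `mass`.
#' @export
opt_univariate <- function(times, status, root_interval = NULL,
                           config = opt_config()) {
  stopifnot(length(times) == length(status), length(times) >= 1,
            all(status %in% c(0, 1)), all(times >= 0), all(is.finite(times)))
  if (is.null(root_interval)) {
    hi <- 1.001 * max(times)
    if (hi <= 0) hi <- 1
    root_interval <- c(0, hi)
  }
  lo <- root_interval[1]; hi <- root_interval[2]
  if (any(times < lo | times >= hi))
    stop("all times must lie in [root_interval[1], root_interval[2])")
  m <- 2L^config$max_depth
  w <- (hi - lo) / m
  cell <- pmin(floor((times - lo) / w), m - 1) + 1
  obs <- status == 1
  M0 <- tabulate(cell[obs], nbins = m)

  mass <- rep(1 / m, m)  # uniform initialisation (cell masses)
  iter <- 0L
  converged <- FALSE
  if (!any(!obs)) {
    mass <- opt_mass_1d(M0, lo, hi, config)
    iter <- 1L
    converged <- TRUE
  } else {
    cens_cell <- cell[!obs]
    cens_frac <- ((lo + cens_cell * w) - times[!obs]) / w  # share above x
    repeat {
      iter <- iter + 1L
      M <- M0
      for (s in seq_along(cens_cell)) {
        c0 <- cens_cell[s]
        wgt <- c(rep(0, c0 - 1), cens_frac[s], rep(1, m - c0))
        z <- wgt * mass
        Z <- sum(z)
        M <- M + if (Z > 0) z / Z else wgt / sum(wgt)
      }
      new_mass <- opt_mass_1d(M, lo, hi, config)
      delta <- 0.5 * sum(abs(new_mass - mass))
      mass <- new_mass
      if (delta < config$em_tol) { converged <- TRUE; break }
      if (iter >= config$em_max_iter) break
    }
    if (!converged)
      warning(sprintf("EM did not converge in %d iterations", iter))
  }
  breaks <- seq(lo, hi, length.out = m + 1)
  surv <- 1 - cumsum(mass)
  out <- data.frame(time = breaks, surv = c(1, surv),
                    surv_left = c(1, surv))
  structure(out, class = c("cepa_survival", "data.frame"),
            estimator = "opt", breaks = breaks, mass = mass,
            iterations = iter, converged = converged)
}

# 1-D OPT posterior-mean cell masses from a count vector (memoised over
# dyadic intervals; same cascade as the bivariate engine, single axis)
opt_mass_1d <- function(counts, lo, hi, config) {
  D <- config$max_depth
  m <- 2L^D
  Pfx <- c(0, cumsum(counts))
  len <- hi - lo
  memo <- new.env(parent = emptyenv())
  nct <- function(d, i) {
    s <- 2L^(D - d)
    Pfx[(i + 1) * s + 1] - Pfx[i * s + 1]
  }
  lphi <- function(d, i) {
    key <- paste0(d, ".", i)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    n <- nct(d, i)
    l0 <- -n * log(len / 2^d)
    val <- if (d >= D || n <= config$min_count) l0 else {
      n1 <- nct(d + 1, 2 * i); n2 <- nct(d + 1, 2 * i + 1)
      split_term <- log(0.5) + beta_log_ratio(n1, n2) +
        lphi(d + 1, 2 * i) + lphi(d + 1, 2 * i + 1)
      stop_term <- log(0.5) + l0
      mx <- max(stop_term, split_term)
      mx + log(exp(stop_term - mx) + exp(split_term - mx))
    }
    memo[[key]] <- val
    val
  }
  mass <- numeric(m)
  cascade <- function(d, i, mu) {
    n <- nct(d, i)
    s <- 2L^(D - d)
    cells <- (i * s + 1):((i + 1) * s)
    if (d >= D || n <= config$min_count) {
      mass[cells] <<- mass[cells] + mu / s
      return(invisible())
    }
    lp <- lphi(d, i)
    rho <- exp(log(0.5) - n * log(len / 2^d) - lp)
    rho <- min(max(rho, 0), 1)
    mass[cells] <<- mass[cells] + mu * rho / s
    n1 <- nct(d + 1, 2 * i)
    f1 <- (n1 + 0.5) / (n + 1)
    cascade(d + 1, 2 * i, mu * (1 - rho) * f1)
    cascade(d + 1, 2 * i + 1, mu * (1 - rho) * (1 - f1))
  }
  cascade(0, 0, 1)
  mass
}

#' Overall median event time from a survival curve
#'
#' The latest time on the curve's grid at which `Pr(T >= t) >= 0.5`,
#' censored subjects included through the survival estimate itself.  When
#' the survival probability never falls to 0.5 (heavy censoring) the grid
#' maximum is returned with attribute `reached = FALSE`.
#'
#' @param curve A `cepa_survival` from [km_curve()] or [opt_univariate()].
#' @return Median time, with attribute `reached`.
#' @export
median_overall <- function(curve) {
  stopifnot(inherits(curve, "cepa_survival"), nrow(curve) >= 1)
  ok <- curve$surv_left >= 0.5
  if (all(ok) && min(curve$surv) >= 0.5) {
    out <- max(curve$time)
    attr(out, "reached") <- FALSE
    return(out)
  }
  out <- max(curve$time[ok])
  attr(out, "reached") <- TRUE
  out
}

#' Observed median event time
#'
#' Median of the event-time distribution conditioned on the event being
#' observed within the maximum observation time: computed on the observed
#' events only (no reweighting for censoring), as the latest observed time
#' `t` with `Pr(T >= t | T <= t_max) >= 0.5`.
#'
#' @param times,status As in [km_curve()].
#' @param t_max Maximum observation time; must be at least every observed
#'   event time (censored records may carry a sentinel beyond it).
#' @return Median of the observed events.
#' @export
median_observed <- function(times, status, t_max = max(times)) {
  stopifnot(length(times) == length(status), all(status %in% c(0, 1)))
  if (any(times[status == 1] > t_max))
    stop("t_max must be >= all observed event times")
  obs <- times[status == 1 & times <= t_max]
  if (length(obs) == 0) stop("no observed events")
  cand <- sort(unique(obs))
  tailp <- vapply(cand, function(t) mean(obs >= t), numeric(1))
  max(cand[tailp >= 0.5])
}

#' Per-event summary table
#'
#' For each event in a long-format table: the censoring rate and the
#' overall (Kaplan-Meier based) and observed median onset times.
#'
#' @param table Long-format event table: data frame with columns
#'   `subject_id`, `event`, `time`, `status`.
#' @param t_max Maximum observation time (default: max time in the table).
#' @return A data frame with columns `event`, `censoring_rate`,
#'   `median_overall`, `median_observed`.  Events never observed get `NA`
#'   medians.
#' @export
summarize_events <- function(table, t_max = max(table$time)) {
  check_event_table(table)
  out <- lapply(split(table, table$event), function(d) {
    cr <- mean(d$status == 0)
    if (all(d$status == 0)) {
      data.frame(event = d$event[1], censoring_rate = cr,
                 median_overall = NA_real_, median_observed = NA_real_)
    } else {
      mo <- median_overall(km_curve(d$time, d$status))
      data.frame(event = d$event[1], censoring_rate = cr,
                 median_overall = as.numeric(mo),
                 median_observed = median_observed(d$time, d$status, t_max))
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Median diagnosis gap after an anchor event
#'
#' Bins subjects by the anchor event's onset time and reports, per bin,
#' the median gap `other - anchor` among subjects with both events
#' observed and the other event at or after the anchor (the network
#' direction).  A flat gap profile across anchor bins indicates that the
#' other event follows the anchor at a characteristic delay regardless of
#' when the anchor occurred.
#'
#' @param table Long-format event table (see [summarize_events()]).
#' @param anchor_label,other_label Event labels present in the table.
#' @param bin_width Width of the anchor-time bins (default 1, i.e. weekly
#'   bins on a week grid).
#' @return Data frame: `bin_lo`, `bin_hi`, `n`, `median_gap` (`NA` for
#'   empty bins).
#' @export
diagnosis_gap <- function(table, anchor_label, other_label, bin_width = 1) {
  check_event_table(table)
  stopifnot(anchor_label %in% table$event, other_label %in% table$event,
            bin_width > 0)
  a <- table[table$event == anchor_label & table$status == 1, ]
  b <- table[table$event == other_label & table$status == 1, ]
  merged <- merge(a[, c("subject_id", "time")], b[, c("subject_id", "time")],
                  by = "subject_id", suffixes = c("_anchor", "_other"))
  merged <- merged[merged$time_other >= merged$time_anchor, , drop = FALSE]
  lo <- floor(min(a$time) / bin_width) * bin_width
  hi <- ceiling((max(a$time) + 1e-9) / bin_width) * bin_width
  edges <- seq(lo, hi, by = bin_width)
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1])
  out$n <- 0L
  out$median_gap <- NA_real_
  if (nrow(merged)) {
    bin <- findInterval(merged$time_anchor, edges, rightmost.closed = FALSE)
    gap <- merged$time_other - merged$time_anchor
    for (k in seq_len(nrow(out))) {
      g <- gap[bin == k]
      out$n[k] <- length(g)
      if (length(g)) out$median_gap[k] <- median(g)
    }
  }
  out
}

check_event_table <- function(table) {
  need <- c("subject_id", "event", "time", "status")
  if (!all(need %in% names(table)))
    stop("event table must have columns ", paste(need, collapse = ", "))
  if (nrow(table) == 0) stop("event table is empty")
  if (!all(table$status %in% c(0, 1)))
    stop("status must be 0 (censored) or 1 (observed)")
  invisible(table)
}
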