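#' Construct a growth curve
#'
#' @param time sampling times in minutes, strictly increasing.
#' @param value OD600 or cell-volume values, strictly positive.
#' @param kind \code{"od"} or \code{"volume"}.
#' @param events optional data frame \code{(time, label)} annotating e.g. a
#'   media shift.
#' @return data frame of class \code{"growth_curve"}.
#' @export
growth_curve <- function(time, value, kind = c("od", "volume"),
                         events = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(time) == length(value), length(time) >= 2)
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  if (any(value <= 0)) stop("values must be positive")
  structure(data.frame(time = time, value = value),
            kind = kind, events = events,
            class = c("growth_curve", "data.frame"))
}

#' @export
plot.growth_curve <- function(x, log = "y", type = "b",
                              xlab = "Time (min)",
                              ylab = if (attr(x, "kind") == "od") "OD600"
                                     else "Cell volume", ...) {
  graphics::plot(x$time, x$value, log = log, type = type,
                 xlab = xlab, ylab = ylab, ...)
  ev <- attr(x, "events")
  if (!is.null(ev)) graphics::abline(v = ev$time, lty = 3)
  invisible(x)
}

# log2-slope of value vs time (min), converted to generations per hour
.log2_rate <- function(time, value) {
  unname(stats::coef(stats::lm(log2(value) ~ time))[2L]) * 60
}

#' Sliding-window growth-rate series
#'
#' In each centred window of \code{window_min} minutes the rate is the
#' OLS slope of log2(value) against time, times 60 (generations per hour).
#'
#' @param curve a \code{\link{growth_curve}}.
#' @param window_min window width in minutes (must contain >= 3 points).
#' @return data frame with columns \code{time} and \code{rate} (gen/hr) for
#'   every sample whose window holds at least 3 points.
#' @export
rate_series <- function(curve, window_min = 60) {
  t <- curve$time; v <- curve$value
  rows <- lapply(seq_along(t), function(i) {
    in_w <- abs(t - t[i]) <= window_min / 2
    if (sum(in_w) < 3L) return(NULL)
    data.frame(time = t[i], rate = .log2_rate(t[in_w], v[in_w]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no window contains >= 3 points")
  out
}

#' Lag time and post-lag growth rate by a two-segment piecewise fit
#'
#' Fits log2(value) with a continuous hinge model — constant up to a
#' breakpoint, then linear — by least squares, searching the breakpoint over
#' the observed sample times (no sub-sample optimisation; adequate at the
#' 15–20 min sampling of plate-reader curves).  The breakpoint is the lag;
#' the post-break slope times 60 is the growth rate in gen/hr.
#'
#' @param curve a \code{\link{growth_curve}} starting in a non-growing phase.
#' @param min_rate detection threshold (gen/hr): if the best fit's rate is
#'   below it, no growth is declared and the lag is NA (flagged).
#' @return list with \code{lag} (min), \code{rate} (gen/hr), \code{rss} and
#'   logical \code{growth_detected}.
#' @export
lag_and_rate <- function(curve, min_rate = 0.05) {
  t <- curve$time
  lv <- log2(curve$value)
  n <- length(t)
  if (n < 4L) stop("need at least 4 samples")
  cands <- t[seq_len(n - 3L)]   # keep >= 3 points after the break
  fits <- lapply(cands, function(b) {
    h <- pmax(t - b, 0)
    f <- stats::lm(lv ~ h)
    list(b = b, rate = unname(stats::coef(f)[2L]) * 60,
         rss = sum(stats::residuals(f)^2))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
  detected <- is.finite(best$rate) && best$rate >= min_rate
  if (!detected)
    warning("no growth detected (max rate below threshold); lag undefined")
  list(lag = if (detected) best$b else NA_real_,
       rate = best$rate, rss = best$rss, growth_detected = detected)
}

#' Recovery time: first 50 percent increase in density
#'
#' The time at which the culture's value first reaches \code{factor} times
#' its initial value, linearly interpolated between samples.  Scale
#' invariant by construction.
#'
#' @param curve a \code{\link{growth_curve}}.
#' @param factor threshold relative to the first sample (default 1.5).
#' @return time in minutes; if the curve never reaches the threshold,
#'   \code{NA} with attribute \code{censored = TRUE} (and a warning).
#' @export
recovery_time <- function(curve, factor = 1.5) {
  v0 <- curve$value[1L]
  thr <- factor * v0
  above <- curve$value >= thr
  if (!any(above)) {
    warning("curve never reaches ", factor, "x its initial value (censored)")
    return(structure(NA_real_, censored = TRUE))
  }
  i <- which(above)[1L]
  if (i == 1L) return(curve$time[1L])
  t0 <- curve$time[i - 1L]; t1 <- curve$time[i]
  v0i <- curve$value[i - 1L]; v1 <- curve$value[i]
  t0 + (thr - v0i) / (v1 - v0i) * (t1 - t0)
}

#' Growth rates flanking a nutrient upshift
#'
#' Log-linear rates in the windows \code{[t_shift - w, t_shift)} and
#' \code{(t_shift, t_shift + w]} around a media change; the experimental
#' convention is a 25-min window on each side.
#'
#' @param curve a \code{\link{growth_curve}} (single-cell volume curves
#'   should be averaged across cells first).
#' @param t_shift shift time in minutes.
#' @param window_min window width in minutes.
#' @return list with \code{rate_before} and \code{rate_after} (gen/hr).
#' @export
shift_response <- function(curve, t_shift, window_min = 25) {
  t <- curve$time; v <- curve$value
  before <- t >= t_shift - window_min & t < t_shift
  after <- t > t_shift & t <= t_shift + window_min
  if (sum(before) < 3L)
    stop("fewer than 3 points in the pre-shift window")
  if (sum(after) < 3L)
    stop("fewer than 3 points in the post-shift window")
  list(rate_before = .log2_rate(t[before], v[before]),
       rate_after  = .log2_rate(t[after], v[after]))
}

# first time a series drops below (1 - delta) x its initial plateau for
# k consecutive samples; plateau = mean of the first n_plateau samples
.change_point <- function(time, value, delta, k, n_plateau) {
  if (length(time) < 4L) stop("series needs >= 4 points")
  plateau <- mean(value[seq_len(min(n_plateau, length(value)))])
  below <- value < (1 - delta) * plateau
  run <- 0L
  for (i in seq_along(below)) {
    run <- if (below[i]) run + 1L else 0L
    if (run >= k) return(time[i - k + 1L])
  }
  NA_real_
}

#' Lead time between two declining time series
#'
#' How much earlier series A (e.g. the ribosomal proteome fraction) starts
#' its sustained decline than series B (e.g. the growth rate).  Each
#' series' change-point is the first time its value drops below
#' \code{(1 - delta)} times its initial plateau for \code{k} consecutive
#' samples; the lead is change-point(B) minus change-point(A), positive when
#' A leads.  Times keep the unit of the input series (hours for the
#' stationary-entry proteome course).
#'
#' @param series_a,series_b data frames with columns \code{time} and
#'   \code{value} (>= 4 points each).
#' @param delta relative drop defining the change-point (default 10 percent).
#' @param k consecutive samples required below the threshold.
#' @param n_plateau samples averaged into the initial plateau.
#' @return list with \code{lead}, \code{change_a}, \code{change_b}; if
#'   either series never declines, its change-point and the lead are NA
#'   (with a warning).
#' @export
lead_time <- function(series_a, series_b, delta = 0.1, k = 2, n_plateau = 3) {
  ca <- .change_point(series_a$time, series_a$value, delta, k, n_plateau)
  cb <- .change_point(series_b$time, series_b$value, delta, k, n_plateau)
  if (is.na(ca) || is.na(cb))
    warning("no sustained decline detected in ",
            paste(c("series_a", "series_b")[c(is.na(ca), is.na(cb))],
                  collapse = " and "))
  list(lead = cb - ca, change_a = ca, change_b = cb)
}

#' Average several growth curves point-wise
#'
#' Single-cell volume traces are averaged across cells before rate
#' estimation (the experimental convention averages 50 cells); curves must
#' share their sampling times.
#'
#' @param curves list of \code{\link{growth_curve}}s on a common time grid.
#' @return \code{\link{growth_curve}} of the point-wise mean values.
#' @export
average_growth_curves <- function(curves) {
  stopifnot(length(curves) >= 1)
  t0 <- curves[[1L]]$time
  ok <- vapply(curves, function(g)
    length(g$time) == length(t0) && all(g$time == t0), logical(1))
  if (!all(ok)) stop("curves must share a common time grid")
  growth_curve(t0, rowMeans(sapply(curves, function(g) g$value)),
               kind = attr(curves[[1L]], "kind"),
               events = attr(curves[[1L]], "events"))
}
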