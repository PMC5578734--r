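#' Fit the ribosome-content growth law
#'
#' Fits the linear scaling between the ribosomal proteome fraction \eqn{r}
#' and the cell growth rate \eqn{x} (generations per hour),
#' \deqn{r = s\,x + r_0,}
#' by ordinary least squares.  Under balanced growth the specific growth
#' rate is \eqn{\mu = x \ln 2} and the law reads \eqn{r = \gamma^{-1}\mu + r_0},
#' where \eqn{\gamma} is the rate at which an active ribosome synthesises its
#' own mass equivalent and \eqn{r_0} is the residual fraction of ribosomal
#' proteins that are not actively translating.  The fitted slope is reported
#' in both unit readings: \code{slope_minutes} \eqn{= 60 s} (the
#' linear-growth reading, in minutes) and \code{slope_per_mu}
#' \eqn{= 60 s/\ln 2} (minutes per unit specific growth rate).
#'
#' @param x growth rates in generations per hour, or a formula such as
#'   \code{r ~ x} evaluated in \code{data}.
#' @param r ribosomal proteome fractions (ignored when \code{x} is a formula).
#' @param data optional data frame in which a formula is evaluated.
#'
#' @return An object of class \code{"scaling_fit"}: a list with components
#'   \code{coefficients} (named \code{intercept}, \code{slope}), \code{se},
#'   \code{r.squared}, \code{n}, \code{slope_minutes}, \code{slope_per_mu},
#'   \code{model} (the underlying \code{\link[stats]{lm}} fit) and
#'   \code{data}.  Negative fitted intercepts are reported as-is (clamping
#'   would hide a model violation) with a warning.
#'
#' @examples
#' fit <- scaling_fit(c(0, 1), c(0.08, 0.43))   # exact two-point line
#' coef(fit)                                    # intercept 0.08, slope 0.35
#' predict(fit, x = 0.67, type = "inactive")    # ~0.25 inactive at fast growth
#' @seealso [predict.scaling_fit()], [gamma_inverse()], [slope_vs_gamma()],
#'   [residual_scenarios()], [ribosomal_scaling()]
#' @export
scaling_fit <- function(x, r = NULL, data = NULL) {
  if (inherits(x, "formula")) {
    mf <- stats::model.frame(x, data = data)
    r <- mf[[1L]]
    x <- mf[[2L]]
  }
  stopifnot(is.numeric(x), is.numeric(r), length(x) == length(r))
  keep <- stats::complete.cases(x, r)
  x <- x[keep]; r <- r[keep]
  if (length(x) < 2L)
    stop("scaling_fit() needs at least 2 points")
  if (diff(range(x)) <= 0)
    stop("growth rates span a zero range; slope is unidentifiable")
  fit <- stats::lm(r ~ x)
  cf <- stats::coef(fit)
  # exact lines (two-point fits, unit conversions) are legitimate inputs
  sm <- suppressWarnings(summary(fit))
  se <- sm$coefficients[, "Std. Error"]
  coefficients <- c(intercept = unname(cf[1L]), slope = unname(cf[2L]))
  if (coefficients[["intercept"]] < 0)
    warning("fitted intercept r0 is negative (reported unclamped)")
  structure(list(
    coefficients  = coefficients,
    se            = c(intercept = unname(se[1L]), slope = unname(se[2L])),
    r.squared     = sm$r.squared,
    n             = length(x),
    slope_minutes = unname(cf[2L]) * 60,
    slope_per_mu  = unname(cf[2L]) * 60 / log(2),
    model         = fit,
    data          = data.frame(x = x, r = r)
  ), class = "scaling_fit")
}

#' @export
coef.scaling_fit <- function(object, ...) object$coefficients

#' @export
residuals.scaling_fit <- function(object, ...) stats::residuals(object$model)

#' @export
fitted.scaling_fit <- function(object, ...) stats::fitted(object$model)

#' @export
print.scaling_fit <- function(x, digits = 4, ...) {
  cf <- x$coefficients
  cat("Ribosome-content growth law (OLS)\n")
  cat(sprintf("  r = %s * x + %s   (x in gen/hr, n = %d, R^2 = %s)\n",
              format(cf[["slope"]], digits = digits),
              format(cf[["intercept"]], digits = digits),
              x$n, format(x$r.squared, digits = digits)))
  cat(sprintf("  slope = %s min (linear reading);  dr/dmu = %s min\n",
              format(x$slope_minutes, digits = digits),
              format(x$slope_per_mu, digits = digits)))
  invisible(x)
}

#' @export
summary.scaling_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.scaling_fit")
}

#' @export
print.summary.scaling_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat(sprintf("  intercept r0 = %s +/- %s\n",
              format(f$coefficients[["intercept"]], digits = digits),
              format(f$se[["intercept"]], digits = digits)))
  cat(sprintf("  slope     s  = %s +/- %s per (gen/hr)\n",
              format(f$coefficients[["slope"]], digits = digits),
              format(f$se[["slope"]], digits = digits)))
  if (f$coefficients[["intercept"]] > 0) {
    rho <- predict(f, x = max(f$data$x), type = "inactive")
    cat(sprintf("  inactive ribosome share at x = %s gen/hr: %s\n",
                format(max(f$data$x), digits = digits),
                format(rho, digits = digits)))
  }
  invisible(x)
}

#' Predict from a fitted growth law
#'
#' @param object a \code{\link{scaling_fit}}.
#' @param x growth rates (gen/hr) at which to predict; defaults to the
#'   fitted points.
#' @param type \code{"fraction"} for the ribosomal proteome fraction
#'   \eqn{s x + r_0}; \code{"inactive"} for the inactive ribosome share
#'   \eqn{\rho = r_0/(s x + r_0)}; \code{"active_ratio"} for the
#'   active:inactive ratio \eqn{r_a/r_0 = s x / r_0}.
#' @param ... unused.
#' @return numeric vector, one value per element of \code{x}.
#' @export
predict.scaling_fit <- function(object, x = object$data$x,
                                type = c("fraction", "inactive", "active_ratio"),
                                ...) {
  type <- match.arg(type)
  cf <- object$coefficients
  s <- cf[["slope"]]; r0 <- cf[["intercept"]]
  if (type == "fraction") return(s * x + r0)
  if (r0 <= 0)
    stop("inactive-fraction predictions require a positive intercept r0")
  if (any(x < 0)) stop("growth rates must be >= 0")
  switch(type,
         inactive     = r0 / (s * x + r0),
         active_ratio = s * x / r0)
}

#' @export
plot.scaling_fit <- function(x, xlab = "Growth rate (gen/hr)",
                             ylab = "Ribosomal proteome fraction", ...) {
  graphics::plot(x$data$x, x$data$r, xlab = xlab, ylab = ylab, ...)
  graphics::abline(x$coefficients[["intercept"]], x$coefficients[["slope"]],
                   lty = 2)
  invisible(x)
}

#' Simulate proteome datasets on a fitted growth law
#'
#' Draws synthetic proteome datasets whose true ribosomal fraction lies on
#' the fitted line, via \code{\link{simulate_proteome}}; useful for
#' parametric-bootstrap checks of the fit.
#'
#' @param object a \code{\link{scaling_fit}} with a positive intercept.
#' @param nsim number of datasets.
#' @param seed integer seed; dataset \code{i} uses \code{seed + i - 1}.
#' @param ... further arguments passed to \code{\link{simulate_proteome}}.
#' @return list of \code{nsim} proteome simulations.
#' @export
simulate.scaling_fit <- function(object, nsim = 1, seed = 1, ...) {
  cf <- object$coefficients
  lapply(seq_len(nsim), function(i)
    simulate_proteome(slope = cf[["slope"]], intercept = cf[["intercept"]],
                      seed = seed + i - 1L, ...))
}

#' Translation time of a full ribosome
#'
#' First-principles estimate of \eqn{\gamma^{-1}}, the time an active
#' ribosome needs to synthesise its own mass equivalent: the amino-acid
#' count of the ribosome divided by the elongation rate.  With the
#' literature values for budding yeast (12,485 aa, 10.5 aa/s) this gives
#' 19.8, i.e. about 20 minutes.
#'
#' @param elongation_rate translation elongation rate, amino acids per second.
#' @param ribosome_aa amino acids composing one ribosome.
#' @return \eqn{\gamma^{-1}} in minutes.
#' @examples
#' gamma_inverse()            # 19.82 min
#' gamma_inverse(1, 60)       # 1 min
#' @export
gamma_inverse <- function(elongation_rate = 10.5, ribosome_aa = 12485) {
  stopifnot(elongation_rate > 0, ribosome_aa > 0)
  ribosome_aa / (elongation_rate * 60)
}

#' Inactive ribosome share predicted by the growth law
#'
#' \eqn{\rho(x) = r_0 / (s x + r_0)}: the share of ribosomal proteins not
#' engaged in translation, assuming the residual fraction \eqn{r_0} is
#' growth-rate independent.  At zero growth \eqn{\rho = 1}; with the
#' wild-type fit (s = 0.35, r0 = 0.08) fast growth at 0.67 gen/hr gives
#' \eqn{\rho \approx 0.25}.
#'
#' @param fit a \code{\link{scaling_fit}}.
#' @param x growth rates, gen/hr (>= 0).
#' @return \eqn{\rho} values in (0, 1].
#' @export
predict_inactive_fraction <- function(fit, x) {
  predict(fit, x = x, type = "inactive")
}

#' Active-to-inactive ribosome ratio
#'
#' \eqn{r_a/r_0 = s x / r_0}, algebraically equal to \eqn{(1-\rho)/\rho}.
#' The growth law predicts this ratio depends only on the growth condition,
#' not on gratuitous protein burden.
#'
#' @inheritParams predict_inactive_fraction
#' @return ratio values (0 at zero growth).
#' @export
active_inactive_ratio <- function(fit, x) {
  predict(fit, x = x, type = "active_ratio")
}

#' Compare the measured slope with the first-principles translation time
#'
#' Balanced-growth theory predicts the slope of \eqn{r} against the specific
#' growth rate \eqn{\mu} to equal \eqn{\gamma^{-1}}.  Whether theory and
#' measurement agree depends on the growth reading: against \eqn{\mu}
#' (exponential single-cell growth, \eqn{\mu = \ln 2/T_d}) the measured
#' slope is \code{slope_per_mu}; against generations per hour (linear
#' growth, \eqn{\mu = 1/T_d}) it is \code{slope_minutes}.  The two ratios
#' differ by exactly \eqn{\ln 2}.
#'
#' @param fit a \code{\link{scaling_fit}}.
#' @param gamma_inv_min \eqn{\gamma^{-1}} in minutes, e.g. from
#'   \code{\link{gamma_inverse}}.
#' @return list with \code{ratio_exponential} (\eqn{\gamma^{-1}} /
#'   \code{slope_per_mu}), \code{ratio_linear} (\eqn{\gamma^{-1}} /
#'   \code{slope_minutes}) and \code{percent_difference}
#'   (\eqn{(1 - \mathrm{ratio\_exponential}) \times 100}).
#' @examples
#' f <- scaling_fit(c(0, 1), c(0.08, 0.43))
#' slope_vs_gamma(f, gamma_inverse())  # exponential reading ~34% short
#' @export
slope_vs_gamma <- function(fit, gamma_inv_min = gamma_inverse()) {
  stopifnot(gamma_inv_min > 0, fit$slope_minutes > 0)
  ratio_exp <- gamma_inv_min / fit$slope_per_mu
  list(ratio_exponential  = ratio_exp,
       ratio_linear       = gamma_inv_min / fit$slope_minutes,
       percent_difference = (1 - ratio_exp) * 100)
}

#' Residual-fraction scenarios under different elongation-rate assumptions
#'
#' If the elongation rate \eqn{\gamma} is growth-rate independent, the
#' residual fraction stays constant, \eqn{r_0(x) = } intercept, and the
#' inactive share \eqn{\rho(x)} increases as growth slows.  If instead
#' \eqn{\gamma = a^{-1}\mu} scales with growth rate, the residual is
#' \eqn{r_0(x) = (s x + r_0) - a} and increases with growth rate.
#'
#' @param fit a \code{\link{scaling_fit}}.
#' @param scenario \code{"constant_gamma"} or \code{"gamma_proportional_to_mu"}.
#' @param a for the proportional scenario: the fixed fraction
#'   \eqn{a = \mu/\gamma}; values exceeding the intercept give a negative
#'   residual at zero growth and are flagged with a warning.
#' @return A function of \code{x} (gen/hr) returning a data frame with
#'   columns \code{x}, \code{r0} (residual fraction under the scenario) and
#'   \code{rho} (inactive share \code{r0 / (s x + intercept)}).
#' @export
residual_scenarios <- function(fit,
                               scenario = c("constant_gamma",
                                            "gamma_proportional_to_mu"),
                               a = NULL) {
  scenario <- match.arg(scenario)
  cf <- fit$coefficients
  s <- cf[["slope"]]; r0 <- cf[["intercept"]]
  if (scenario == "gamma_proportional_to_mu") {
    if (is.null(a)) stop("the proportional scenario needs the constant 'a'")
    if (a > r0 + 1e-12)
      warning("a exceeds the intercept: residual fraction is negative at x = 0")
  }
  function(x) {
    stopifnot(all(x >= 0))
    r <- s * x + r0
    res <- switch(scenario,
                  constant_gamma           = rep(r0, length(x)),
                  gamma_proportional_to_mu = r - a)
    data.frame(x = x, r0 = res, rho = res / r)
  }
}

#' Fit the growth law from proteome profiles
#'
#' Pipeline convenience: computes the proteome fraction of a gene group
#' (default the ribosomal proteins) in every profile, aggregates replicates
#' per condition, and fits \code{\link{scaling_fit}} on (growth rate,
#' fraction) points.
#'
#' @param profiles list of fractional \code{\link{proteome_profile}} objects
#'   carrying growth-rate metadata.
#' @param group_map gene-group map (data frame \code{protein_id}, \code{group}).
#' @param group group label whose fraction is fitted.
#' @param aggregate \code{"median"} (default; one point per condition) or
#'   \code{"none"} (all replicates enter the fit).
#' @return a \code{\link{scaling_fit}}; the aggregated points are in
#'   \code{$data}.
#' @export
ribosomal_scaling <- function(profiles, group_map, group = "ribosome",
                              aggregate = c("median", "none")) {
  aggregate <- match.arg(aggregate)
  pts <- data.frame(
    condition = vapply(profiles, function(p) p$condition, character(1)),
    x = vapply(profiles, function(p) p$growth_rate, numeric(1)),
    r = vapply(profiles, group_fraction, numeric(1),
               map = group_map, group = group)
  )
  if (aggregate == "median") {
    pts <- do.call(rbind, lapply(split(pts, pts$condition), function(d)
      data.frame(condition = d$condition[1L], x = d$x[1L],
                 r = stats::median(d$r))))
  }
  scaling_fit(pts$x, pts$r)
}
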