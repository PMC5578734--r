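#' Construct a competition-assay series
#'
#' Frequencies of the wild type in a head-to-head log-phase competition,
#' indexed by elapsed generations (computed from the dilution factors).
#'
#' @param generations dimensionless generation counts (>= 3 timepoints).
#' @param wt_frequency wild-type frequency per timepoint, strictly in (0, 1).
#' @return data frame of class \code{"competition_series"}.
#' @export
competition_series <- function(generations, wt_frequency) {
  stopifnot(length(generations) == length(wt_frequency),
            length(generations) >= 3)
  if (any(wt_frequency <= 0 | wt_frequency >= 1))
    stop("frequencies must lie strictly in (0, 1): log2 slope undefined at fixation")
  structure(data.frame(generations = generations,
                       wt_frequency = wt_frequency),
            class = c("competition_series", "data.frame"))
}

#' Relative fitness from a competition assay
#'
#' OLS slope of log2(wild-type frequency) against generations: positive
#' values mean a wild-type advantage.  The natural-log reading
#' (\code{fitness_ln} = slope times ln 2) is reported alongside, never
#' silently applied.
#'
#' @param series a \code{\link{competition_series}}.
#' @return list with \code{fitness} (log2 units per generation),
#'   \code{fitness_ln}, \code{se}, \code{intercept} and \code{r.squared}.
#' @export
fitness_from_competition <- function(series) {
  f <- stats::lm(log2(wt_frequency) ~ generations, data = series)
  sm <- suppressWarnings(summary(f))
  slope <- unname(stats::coef(f)[2L])
  list(fitness = slope,
       fitness_ln = slope * log(2),
       se = sm$coefficients[2L, "Std. Error"],
       intercept = unname(stats::coef(f)[1L]),
       r.squared = sm$r.squared)
}

#' Fitness cost per burden copy
#'
#' OLS slope of per-strain fitness (advantage of the unburdened competitor)
#' against burden copy number.
#'
#' @param copy_number integer copy numbers (>= 2 distinct values).
#' @param fitness per-generation relative fitness per strain.
#' @return list with \code{cost_per_copy}, \code{intercept} and \code{se}
#'   (NA for a two-point fit).
#' @export
per_copy_cost <- function(copy_number, fitness) {
  stopifnot(length(copy_number) == length(fitness))
  if (length(unique(copy_number)) < 2L)
    stop("need at least 2 distinct copy numbers")
  f <- stats::lm(fitness ~ copy_number)
  se <- tryCatch(suppressWarnings(summary(f)$coefficients[2L, "Std. Error"]),
                 error = function(e) NA_real_)
  list(cost_per_copy = unname(stats::coef(f)[2L]),
       intercept = unname(stats::coef(f)[1L]),
       se = se)
}

#' Absolute mCherry proteome fraction from the TDH3-fusion calibration
#'
#' The calibration strain expresses mCherry at the level of the TDH3
#' protein (a reference proteome fraction, about 2.2 percent by iBAQ); the
#' one-copy burden strain sits a measured relative deficit below it, giving
#' one-copy fraction = reference x (1 - deficit), about 1.9 percent.
#' Multi-copy strains scale linearly per copy unless measured relative
#' levels are supplied.
#'
#' @param reference_fraction proteome fraction of the calibration protein.
#' @param relative_deficit relative shortfall of the one-copy strain vs the
#'   calibration strain (0.145 = 14.5 percent lower).
#' @param copies burden copy number (0 gives 0).
#' @param relative_levels optional measured per-strain level relative to the
#'   one-copy strain, overriding the linear-in-copies default.
#' @return mCherry proteome fraction.
#' @examples
#' mcherry_calibration(0.022, 0.145, 1)  # ~0.019
#' @export
mcherry_calibration <- function(reference_fraction = 0.022,
                                relative_deficit = 0.145,
                                copies = 1, relative_levels = NULL) {
  stopifnot(reference_fraction >= 0, reference_fraction < 1,
            relative_deficit >= 0, relative_deficit < 1,
            copies >= 0)
  one_copy <- reference_fraction * (1 - relative_deficit)
  out <- if (is.null(relative_levels)) one_copy * copies
         else one_copy * relative_levels
  if (any(out >= 1)) stop("calibrated fraction reaches 1; inputs implausible")
  out
}

#' Growth-law fits across a burden strain series
#'
#' Fits the scaling law per strain and summarises how the burden moves its
#' parameters: the slope is expected to be burden-invariant while the
#' zero-growth intercept r0 decreases with copy number.
#'
#' @param strains data frame with columns \code{strain}, \code{copy_number},
#'   \code{growth_rate} (gen/hr) and \code{ribosomal_fraction}; every strain
#'   needs >= 2 conditions (exactly 2 gives an exact line without SEs).
#' @return object of class \code{"burden_scaling"}: list with \code{fits}
#'   (per-strain \code{\link{scaling_fit}}s), \code{table} (strain,
#'   copy_number, slope, intercept, se's), \code{slope_spread} (max pairwise
#'   slope difference), \code{pooled_slope_se} (the pooled standard error of
#'   a pairwise slope difference, \code{sqrt(2 * mean(se^2))}),
#'   \code{slope_homogeneity} (spread / pooled SE, a z-like statistic for
#'   the largest slope contrast; NA when no SEs exist) and
#'   \code{intercept_copy_cor}.
#' @export
burden_scaling <- function(strains) {
  need <- c("strain", "copy_number", "growth_rate", "ribosomal_fraction")
  stopifnot(all(need %in% names(strains)))
  by_strain <- split(strains, strains$strain)
  if (any(vapply(by_strain, nrow, integer(1)) < 2L))
    stop("every strain needs >= 2 conditions")
  fits <- lapply(by_strain, function(d)
    scaling_fit(d$growth_rate, d$ribosomal_fraction))
  tab <- data.frame(
    strain = names(fits),
    copy_number = vapply(by_strain, function(d) d$copy_number[1L], numeric(1)),
    slope = vapply(fits, function(f) f$coefficients[["slope"]], numeric(1)),
    intercept = vapply(fits, function(f) f$coefficients[["intercept"]],
                       numeric(1)),
    slope_se = vapply(fits, function(f) f$se[["slope"]], numeric(1)),
    intercept_se = vapply(fits, function(f) f$se[["intercept"]], numeric(1)),
    row.names = NULL
  )
  spread <- diff(range(tab$slope))
  pooled <- sqrt(2 * mean(tab$slope_se^2, na.rm = TRUE))
  structure(list(
    fits = fits, table = tab,
    slope_spread = spread,
    pooled_slope_se = pooled,
    slope_homogeneity = if (is.finite(pooled) && pooled > 0) spread / pooled
                        else NA_real_,
    intercept_copy_cor = if (length(unique(tab$copy_number)) > 1L)
      stats::cor(tab$copy_number, tab$intercept) else NA_real_
  ), class = "burden_scaling")
}

#' @export
print.burden_scaling <- function(x, digits = 4, ...) {
  cat("Growth-law fits across burden strains\n")
  print(x$table, digits = digits)
  cat(sprintf("  slope spread %s (pooled SE %s, homogeneity %s)\n",
              format(x$slope_spread, digits = digits),
              format(x$pooled_slope_se, digits = digits),
              format(x$slope_homogeneity, digits = digits)))
  cat(sprintf("  intercept vs copy number: r = %s\n",
              format(x$intercept_copy_cor, digits = digits)))
  invisible(x)
}

#' Predicted starvation-recovery delay from the residual ribosome pool
#'
#' Cells exit starvation on their residual (non-translating) ribosomes, so
#' the default model takes recovery time inversely proportional to
#' \eqn{r_0}: fold delay = r0_reference / r0_burden.  A log-pool alternative
#' (delay proportional to -log r0) is available behind \code{model}.
#'
#' @param r0_reference,r0_burden residual fractions of the reference and
#'   burdened strains (both > 0; \eqn{r_0 < 1}).
#' @param model \code{"inverse"} (default) or \code{"log"}.
#' @return list with \code{fold} (>= 1 when the burden shrinks the pool)
#'   and \code{percent_prolongation}.
#' @export
predict_recovery_delay <- function(r0_reference, r0_burden,
                                   model = c("inverse", "log")) {
  model <- match.arg(model)
  if (r0_reference <= 0 || r0_burden <= 0)
    stop("residual fractions must be positive")
  fold <- switch(model,
                 inverse = r0_reference / r0_burden,
                 log     = log(r0_burden) / log(r0_reference))
  list(fold = fold, percent_prolongation = (fold - 1) * 100)
}
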