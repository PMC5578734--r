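#' Ground truth attached to simulated datasets
#'
#' Every generator attaches a \code{synthetic_truth} record — the complete
#' set of generating parameters plus the seed — so parameter-recovery tests
#' can compare estimates against it.  Regeneration with the same parameters
#' and seed is bit-identical.
#'
#' @param kind one of \code{"proteome"}, \code{"trace"}, \code{"growth"},
#'   \code{"competition"}.
#' @param parameters named list of every generating quantity.
#' @param seed integer seed used.
#' @return object of class \code{"synthetic_truth"}.
#' @export
synthetic_truth <- function(kind = c("proteome", "trace", "growth",
                                     "competition"),
                            parameters, seed) {
  kind <- match.arg(kind)
  structure(list(kind = kind, parameters = parameters,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth (%s, seed %d):\n", x$kind, x$seed))
  utils::str(x$parameters, give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' Extract the ground truth of a simulated object
#'
#' @param x any generator output.
#' @return the attached \code{\link{synthetic_truth}} (or NULL).
#' @export
truth <- function(x) {
  if (!is.null(attr(x, "truth"))) attr(x, "truth") else x$truth
}

.lognorm_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Default proteome sector tilt rules
#'
#' Linear dependence of each sector's (pre-normalisation) proteome fraction
#' on growth rate x, emulating the observed condition trends: the
#' translation/ribosome sector rises with growth rate on the scaling line,
#' mitochondrial and stress sectors rise at slow growth, glycolysis stays
#' flat.  Twelve groups including the residual \code{"other"}.
#'
#' @param slope,intercept parameters of the ribosomal sector's line.
#' @return data frame with columns \code{group}, \code{intercept},
#'   \code{slope}.
#' @export
default_tilt_rules <- function(slope = 0.35, intercept = 0.08) {
  data.frame(
    group = c("ribosome", "translation_factors", "glycolysis",
              "mitochondria", "stress", "aa_synthesis", "chaperones",
              "nucleotide", "lipid", "cell_wall", "transport", "other"),
    intercept = c(intercept, 0.04, 0.12, 0.20, 0.10, 0.05, 0.05,
                  0.03, 0.03, 0.04, 0.06, 0.15),
    slope = c(slope, 0.05, 0.00, -0.15, -0.06, 0.03, 0.00,
              0.00, 0.00, 0.00, 0.00, 0.00)
  )
}

#' Simulate a condition-series proteome dataset
#'
#' Generates fractional proteome profiles over a series of growth
#' conditions in which the true ribosomal sector fraction follows the
#' scaling line \eqn{s x + r_0}; the other sectors follow their tilt rules
#' and are then renormalised so all sector fractions sum to one.  Within
#' each sector, per-protein weights are lognormal (drawn once per dataset);
#' replicates add independent multiplicative lognormal noise of the stated
#' coefficient of variation, after which each profile is renormalised to
#' sum to one.
#'
#' @param growth_rates condition growth rates, gen/hr (default: 15
#'   conditions spanning 0.15–0.67, the measured condition range).
#' @param slope,intercept ribosomal-sector line (fraction per gen/hr;
#'   fraction).  Configurations with \eqn{s x + r_0 > 1} anywhere are
#'   rejected.
#' @param n_replicates replicates per condition.
#' @param noise_cv per-protein multiplicative noise CV (0 = noiseless).
#' @param tilt_rules sector tilt table, see \code{\link{default_tilt_rules}};
#'   the \code{"ribosome"} row is overridden by \code{slope}/\code{intercept}.
#' @param n_proteins_per_group proteins simulated per sector.
#' @param seed integer seed.
#' @return list of class \code{"proteome_simulation"} with \code{profiles}
#'   (fractional \code{\link{proteome_profile}}s, one per condition x
#'   replicate), \code{group_map} (data frame \code{protein_id},
#'   \code{group}) and \code{truth}.
#' @export
simulate_proteome <- function(growth_rates = seq(0.15, 0.67, length.out = 15),
                              slope = 0.35, intercept = 0.08,
                              n_replicates = 3, noise_cv = 0.05,
                              tilt_rules = default_tilt_rules(slope, intercept),
                              n_proteins_per_group = 20, seed = 1) {
  stopifnot(all(growth_rates >= 0), intercept >= 0, intercept < 1,
            n_replicates >= 1, noise_cv >= 0, n_proteins_per_group >= 1)
  if (any(slope * growth_rates + intercept > 1))
    stop("s*x + r0 exceeds 1 for some growth rate; configuration rejected")
  if (!"ribosome" %in% tilt_rules$group)
    stop("tilt_rules must contain a 'ribosome' group")
  tilt_rules$intercept[tilt_rules$group == "ribosome"] <- intercept
  tilt_rules$slope[tilt_rules$group == "ribosome"] <- slope
  groups <- tilt_rules$group
  ids <- unlist(lapply(groups, function(g)
    sprintf("%s_%03d", g, seq_len(n_proteins_per_group))))
  group_map <- data.frame(
    protein_id = ids,
    group = rep(groups, each = n_proteins_per_group)
  )
  sdlog <- .lognorm_sdlog(noise_cv)
  out <- withr::with_seed(seed, {
    # within-sector protein weights: drawn once, shared by all conditions
    w <- lapply(groups, function(g) {
      v <- stats::rlnorm(n_proteins_per_group, 0, 1)
      v / sum(v)
    })
    names(w) <- groups
    profiles <- list()
    for (ci in seq_along(growth_rates)) {
      x <- growth_rates[ci]
      fr <- pmax(tilt_rules$intercept + tilt_rules$slope * x, 1e-3)
      names(fr) <- groups
      rib <- slope * x + intercept
      fr["ribosome"] <- rib
      othr <- setdiff(groups, "ribosome")
      fr[othr] <- fr[othr] * (1 - rib) / sum(fr[othr])
      true_ab <- unlist(lapply(groups, function(g) fr[[g]] * w[[g]]))
      names(true_ab) <- ids
      for (rep_i in seq_len(n_replicates)) {
        ab <- if (noise_cv > 0)
          true_ab * stats::rlnorm(length(true_ab), -sdlog^2 / 2, sdlog)
        else true_ab
        ab <- ab / sum(ab)
        profiles[[length(profiles) + 1L]] <- proteome_profile(
          ab, condition = sprintf("C%02d", ci),
          replicate = as.character(rep_i), growth_rate = x,
          fractional = TRUE)
      }
    }
    profiles
  })
  structure(list(
    profiles = out,
    group_map = group_map,
    truth = synthetic_truth("proteome", list(
      growth_rates = growth_rates, slope = slope, intercept = intercept,
      n_replicates = n_replicates, noise_cv = noise_cv,
      n_proteins_per_group = n_proteins_per_group,
      tilt_rules = tilt_rules), seed)
  ), class = "proteome_simulation")
}

#' Simulate a sucrose-gradient polysome trace
#'
#' Builds a trace of Gaussian peaks (40S, 60S, monosome, polysomes
#' n = 2..\code{n_polysome_max}) on a flat baseline.  Peak areas are set by
#' inverting the rRNA correction (\code{\link{rrna_fraction}}) so that the
#' true ribosome-equivalent inactive fraction equals \code{rho}: the
#' inactive equivalents (split between 40S, 60S and monosome) total
#' \code{rho}, the active polysome equivalents (geometric weights over n)
#' total \code{1 - rho}, and each raw area is its equivalent divided by
#' \eqn{f_n} (free subunits divide by 1).  Additive Gaussian noise is then
#' applied and the trace floored at zero.
#'
#' @param rho true inactive ribosome fraction in [0, 1] (1 = no polysomes).
#' @param polysome_weights relative weights of polysome peaks n = 2..N
#'   (default geometric decay 0.7; must be non-negative).
#' @param subunit_split how the inactive equivalents divide between 40S,
#'   60S and the monosome (normalised internally).
#' @param n_polysome_max highest polysome peak.
#' @param total_equivalents total ribosome-equivalent signal (sets the y
#'   scale).
#' @param peak_sd Gaussian peak width (gradient units).
#' @param baseline flat baseline absorbance.
#' @param noise_sd additive noise SD in OD units; NULL = 1 percent of the
#'   tallest peak.
#' @param dx sampling step along the gradient.
#' @param seed integer seed.
#' @return \code{\link{polysome_trace}} with a \code{truth} attribute
#'   holding rho, the per-peak areas/equivalents and all settings.
#' @export
simulate_polysome_trace <- function(rho = 0.18,
                                    polysome_weights =
                                      0.7^(0:(n_polysome_max - 2)),
                                    subunit_split =
                                      c(`40S` = 0.2, `60S` = 0.3, mono = 0.5),
                                    n_polysome_max = 8,
                                    total_equivalents = 1,
                                    peak_sd = 0.06, baseline = 0.02,
                                    noise_sd = NULL, dx = 0.005, seed = 1) {
  stopifnot(rho >= 0, rho <= 1, total_equivalents > 0, peak_sd > 0,
            baseline >= 0, length(polysome_weights) == n_polysome_max - 1)
  if (any(polysome_weights < 0)) stop("polysome weights must be non-negative")
  if (rho < 1 && sum(polysome_weights) <= 0)
    stop("need at least one polysome peak when rho < 1")
  pos_peaks <- canonical_peak_positions(n_polysome_max)
  split3 <- subunit_split / sum(subunit_split)
  eq <- c(rho * total_equivalents * split3,
          (1 - rho) * total_equivalents *
            polysome_weights / max(sum(polysome_weights), .Machine$double.eps))
  names(eq) <- names(pos_peaks)
  f <- c(1, 1, rrna_fraction(1), rrna_fraction(2:n_polysome_max))
  areas <- eq / f
  heights <- areas / (peak_sd * sqrt(2 * pi))
  if (is.null(noise_sd)) noise_sd <- 0.01 * max(heights)
  grid <- seq(0.5, max(pos_peaks) + 0.6, by = dx)
  signal <- baseline + Reduce(`+`, lapply(seq_along(areas), function(i)
    areas[i] * stats::dnorm(grid, pos_peaks[i], peak_sd)))
  od <- withr::with_seed(seed,
    pmax(signal + stats::rnorm(length(grid), 0, noise_sd), 0))
  tr <- polysome_trace(grid, od, label = sprintf("sim rho=%.2f", rho))
  attr(tr, "truth") <- synthetic_truth("trace", list(
    rho = rho, areas = areas, equivalents = eq,
    polysome_weights = polysome_weights, subunit_split = split3,
    n_polysome_max = n_polysome_max, total_equivalents = total_equivalents,
    peak_sd = peak_sd, baseline = baseline, noise_sd = noise_sd, dx = dx),
    seed)
  tr
}

#' Simulate a blank gradient trace
#'
#' A flat baseline plus noise over the same position grid as a simulated
#' trace; subtracting it in \code{\link{preprocess_trace}} removes the
#' baseline the way a blank sucrose gradient does experimentally.
#'
#' @param trace a simulated \code{\link{polysome_trace}} (supplies the grid
#'   and, via its truth, the baseline level).
#' @param noise_sd noise SD (default: the trace's own noise level).
#' @param seed integer seed.
#' @return \code{\link{polysome_trace}}.
#' @export
simulate_blank_trace <- function(trace, noise_sd = NULL, seed = 1) {
  tru <- truth(trace)
  baseline <- if (!is.null(tru)) tru$parameters$baseline else 0
  if (is.null(noise_sd))
    noise_sd <- if (!is.null(tru)) tru$parameters$noise_sd else 0
  od <- withr::with_seed(seed,
    pmax(baseline + stats::rnorm(nrow(trace), 0, noise_sd), 0))
  polysome_trace(trace$position, od, label = "blank")
}

#' Simulate a growth curve
#'
#' OD (or volume) stays at \code{od0} through a lag phase, then grows
#' exponentially at \code{rate} gen/hr, optionally switching to
#' \code{rate_after} at \code{t_shift} (a nutrient upshift) and flattening
#' logistically towards \code{saturation}.  Noise is multiplicative
#' Gaussian with the stated CV.
#'
#' @param od0 initial value.
#' @param lag lag duration, minutes.
#' @param rate exponential rate, gen/hr (>= 0).
#' @param t_shift,rate_after optional upshift time (min) and post-shift rate.
#' @param saturation carrying-capacity value (Inf = no saturation).
#' @param noise_cv multiplicative noise CV.
#' @param sampling sampling interval, minutes.
#' @param t_max duration, minutes.
#' @param kind \code{"od"} or \code{"volume"}.
#' @param seed integer seed.
#' @return \code{\link{growth_curve}} with a \code{truth} attribute.
#' @export
simulate_growth_curve <- function(od0 = 0.1, lag = 0, rate = 0.55,
                                  t_shift = NULL, rate_after = NULL,
                                  saturation = Inf, noise_cv = 0.02,
                                  sampling = 15, t_max = 300,
                                  kind = "od", seed = 1) {
  stopifnot(od0 > 0, lag >= 0, rate >= 0, sampling > 0, t_max > sampling)
  if (!is.null(t_shift)) stopifnot(!is.null(rate_after), rate_after >= 0)
  t <- seq(0, t_max, by = sampling)
  grow_min <- pmax(t - lag, 0)                     # minutes of growth
  log2u <- log2(od0) + (rate / 60) * grow_min
  if (!is.null(t_shift)) {
    extra <- pmax(t - pmax(t_shift, lag), 0)
    log2u <- log2u + ((rate_after - rate) / 60) * extra
  }
  u <- 2^log2u
  v <- if (is.finite(saturation)) saturation * u / (saturation + u - od0)
       else u
  value <- withr::with_seed(seed,
    pmax(v * (1 + stats::rnorm(length(t), 0, noise_cv)), .Machine$double.eps))
  ev <- if (!is.null(t_shift)) data.frame(time = t_shift, label = "shift")
        else NULL
  gc <- growth_curve(t, value, kind = kind, events = ev)
  attr(gc, "truth") <- synthetic_truth("growth", list(
    od0 = od0, lag = lag, rate = rate, t_shift = t_shift,
    rate_after = rate_after, saturation = saturation, noise_cv = noise_cv,
    sampling = sampling, t_max = t_max), seed)
  gc
}

#' Simulate a competition-assay frequency series
#'
#' log2 of the wild-type frequency drifts linearly with generations at
#' \code{fitness} (per generation), plus Gaussian noise on the log2 scale;
#' frequencies are clipped to the open interval (0, 1).
#'
#' @param fitness per-generation log2 drift (positive = WT advantage).
#' @param n_generations length of the competition, generations.
#' @param initial_wt_freq starting wild-type frequency in (0, 1); the assay
#'   protocol starts near 50 percent.
#' @param noise_sd noise SD on log2 frequency.
#' @param by spacing of timepoints in generations.
#' @param seed integer seed.
#' @return \code{\link{competition_series}} with a \code{truth} attribute.
#' @export
simulate_competition <- function(fitness = 0.02, n_generations = 20,
                                 initial_wt_freq = 0.5, noise_sd = 0,
                                 by = 2, seed = 1) {
  stopifnot(initial_wt_freq > 0, initial_wt_freq < 1, n_generations > 0)
  g <- seq(0, n_generations, by = by)
  log2f <- log2(initial_wt_freq) + fitness * g
  if (noise_sd > 0)
    log2f <- withr::with_seed(seed,
      log2f + stats::rnorm(length(g), 0, noise_sd))
  f <- pmin(pmax(2^log2f, 1e-9), 1 - 1e-9)
  cs <- competition_series(g, f)
  attr(cs, "truth") <- synthetic_truth("competition", list(
    fitness = fitness, n_generations = n_generations,
    initial_wt_freq = initial_wt_freq, noise_sd = noise_sd, by = by), seed)
  cs
}
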