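#' Read a long-format protein abundance table
#'
#' Expects a TSV with columns \code{protein_id}, \code{condition},
#' \code{replicate}, \code{abundance}; growth rates are joined from an
#' optional condition-metadata TSV (\code{condition},
#' \code{growth_rate_gen_per_hr}).
#'
#' @param path abundance TSV path.
#' @param meta_path optional condition-metadata TSV path.
#' @param fractional whether abundances are already proteome fractions.
#' @return list of \code{\link{proteome_profile}}s.
#' @export
read_proteome_table <- function(path, meta_path = NULL, fractional = FALSE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "condition", "replicate", "abundance")
  stopifnot(all(need %in% names(tab)))
  meta <- if (!is.null(meta_path))
    utils::read.delim(meta_path, stringsAsFactors = FALSE) else NULL
  key <- interaction(tab$condition, tab$replicate, drop = TRUE)
  lapply(split(tab, key), function(d) {
    x <- NA_real_
    if (!is.null(meta)) {
      hit <- match(d$condition[1L], meta$condition)
      if (!is.na(hit)) x <- meta$growth_rate_gen_per_hr[hit]
    }
    proteome_profile(stats::setNames(d$abundance, d$protein_id),
                     condition = d$condition[1L], replicate = d$replicate[1L],
                     growth_rate = x, fractional = fractional)
  })
}

#' Write proteome profiles as a long-format TSV
#'
#' @param profiles list of \code{\link{proteome_profile}}s.
#' @param path output TSV path.
#' @export
write_proteome_table <- function(profiles, path) {
  tab <- do.call(rbind, lapply(profiles, function(p)
    data.frame(protein_id = names(p$abundances), condition = p$condition,
               replicate = p$replicate, abundance = unname(p$abundances))))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-group map TSV (\code{protein_id}, \code{group})
#'
#' @param path TSV path.
#' @return data frame usable as the \code{map} argument of
#'   \code{\link{group_fraction}}.
#' @export
read_group_map <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "group") %in% names(m)))
  m
}

#' Read a gradient trace CSV (\code{position,od254})
#'
#' @param path CSV path.
#' @param label trace label.
#' @return \code{\link{polysome_trace}}.
#' @export
read_trace_csv <- function(path, label = basename(path)) {
  d <- utils::read.csv(path)
  stopifnot(all(c("position", "od254") %in% names(d)))
  polysome_trace(d$position, d$od254, label = label)
}

#' Write a gradient trace CSV
#'
#' @param trace a \code{\link{polysome_trace}}.
#' @param path output CSV path.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[, c("position", "od254")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a growth-curve CSV (\code{time_min,value})
#'
#' @param path CSV path.
#' @param kind \code{"od"} or \code{"volume"}.
#' @param events_path optional events CSV (\code{time,label}).
#' @return \code{\link{growth_curve}}.
#' @export
read_growth_csv <- function(path, kind = "od", events_path = NULL) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_min", "value") %in% names(d)))
  ev <- if (!is.null(events_path)) utils::read.csv(events_path) else NULL
  growth_curve(d$time_min, d$value, kind = kind, events = ev)
}

#' Write a growth-curve CSV
#'
#' @param curve a \code{\link{growth_curve}}.
#' @param path output CSV path.
#' @export
write_growth_csv <- function(curve, path) {
  utils::write.csv(data.frame(time_min = curve$time, value = curve$value),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a competition CSV (\code{generation,wt_frequency})
#'
#' @param path CSV path.
#' @return \code{\link{competition_series}}.
#' @export
read_competition_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("generation", "wt_frequency") %in% names(d)))
  competition_series(d$generation, d$wt_frequency)
}

#' Write a scaling-fit report as JSON
#'
#' Slope, intercept, standard errors, R-squared and both unit conversions.
#'
#' @param fit a \code{\link{scaling_fit}}.
#' @param path output JSON path.
#' @export
write_fit_report <- function(fit, path) {
  jsonlite::write_json(list(
    slope = fit$coefficients[["slope"]],
    intercept = fit$coefficients[["intercept"]],
    slope_se = fit$se[["slope"]],
    intercept_se = fit$se[["intercept"]],
    r_squared = fit$r.squared,
    n_points = fit$n,
    slope_minutes = fit$slope_minutes,
    slope_per_mu = fit$slope_per_mu
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a synthetic-truth sidecar as JSON
#'
#' @param truth a \code{\link{synthetic_truth}} (or generator output, from
#'   which the truth is extracted).
#' @param path output JSON path.
#' @export
write_truth_json <- function(truth, path) {
  if (!inherits(truth, "synthetic_truth")) truth <- truth(truth)
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
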