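#' Construct a proteome profile
#'
#' A profile holds the per-protein abundances measured in one condition and
#' replicate, together with the condition's growth rate (generations per
#' hour).  Abundances are either in arbitrary intensity units or, after
#' \code{\link{to_fractions}}, fractions of the total proteome.
#'
#' @param abundances named non-negative numeric vector (names are protein ids).
#' @param condition condition label.
#' @param replicate replicate label.
#' @param growth_rate growth rate in gen/hr (NA when unknown).
#' @param fractional logical; if TRUE the abundances must sum to 1 (1e-9).
#' @return object of class \code{"proteome_profile"}.
#' @export
proteome_profile <- function(abundances, condition = "cond", replicate = "1",
                             growth_rate = NA_real_, fractional = FALSE) {
  stopifnot(is.numeric(abundances), !is.null(names(abundances)))
  if (any(abundances < 0)) stop("abundances must be non-negative")
  if (!is.na(growth_rate) && growth_rate < 0)
    stop("growth_rate must be >= 0 or NA")
  if (fractional && abs(sum(abundances) - 1) > 1e-9)
    stop("fractional profile does not sum to 1")
  structure(list(abundances = abundances,
                 condition = as.character(condition),
                 replicate = as.character(replicate),
                 growth_rate = growth_rate,
                 fractional = fractional),
            class = "proteome_profile")
}

#' @export
print.proteome_profile <- function(x, ...) {
  cat(sprintf("proteome_profile: %d proteins, condition %s (rep %s), x = %s gen/hr%s\n",
              length(x$abundances), x$condition, x$replicate,
              format(x$growth_rate, digits = 3),
              if (x$fractional) ", fractional" else ""))
  invisible(x)
}

#' Top-3 label-free protein quantification
#'
#' Per protein, abundance is the sum of the three most intense unique
#' peptides; proteins with fewer than three unique peptides use all of them
#' (dropping them would bias against low-abundance proteins), and proteins
#' with no unique peptide are dropped and reported in the \code{"dropped"}
#' attribute.
#'
#' @param peptides data frame with columns \code{protein_id},
#'   \code{peptide_id}, \code{intensity} (>= 0) and logical \code{is_unique}.
#' @inheritParams proteome_profile
#' @return non-fractional \code{\link{proteome_profile}}; attribute
#'   \code{"dropped"} names the proteins without unique peptides and
#'   attribute \code{"n_below3"} counts proteins quantified from fewer than
#'   three peptides.
#' @export
quantify_top3 <- function(peptides, condition = "cond", replicate = "1",
                          growth_rate = NA_real_) {
  stopifnot(nrow(peptides) > 0,
            all(c("protein_id", "intensity", "is_unique") %in% names(peptides)))
  if (any(peptides$intensity < 0)) stop("peptide intensities must be >= 0")
  all_prot <- unique(peptides$protein_id)
  uniq <- peptides[peptides$is_unique, , drop = FALSE]
  ab <- vapply(split(uniq$intensity, uniq$protein_id), function(v)
    sum(sort(v, decreasing = TRUE)[seq_len(min(3L, length(v)))]), numeric(1))
  n_below3 <- sum(vapply(split(uniq$intensity, uniq$protein_id),
                         length, integer(1)) < 3L)
  dropped <- setdiff(all_prot, names(ab))
  if (length(dropped))
    message(length(dropped), " protein(s) without unique peptides dropped")
  out <- proteome_profile(ab, condition, replicate, growth_rate)
  attr(out, "dropped") <- dropped
  attr(out, "n_below3") <- n_below3
  out
}

#' Normalise a profile to proteome fractions
#'
#' Divides every abundance by the grand total (total-ion-current style
#' normalisation), so the profile sums to one and becomes scale invariant.
#'
#' @param profile a \code{\link{proteome_profile}}.
#' @return fractional \code{\link{proteome_profile}}.
#' @export
to_fractions <- function(profile) {
  tot <- sum(profile$abundances)
  if (tot <= 0) stop("cannot normalise an all-zero profile")
  proteome_profile(profile$abundances / tot, profile$condition,
                   profile$replicate, profile$growth_rate, fractional = TRUE)
}

#' Calibrate a profile to an external absolute reference
#'
#' Rescales the whole profile by a single factor — the median over shared
#' proteins of reference/profile — so absolute levels match an external
#' reference dataset while within-profile ratios are preserved.
#'
#' @param profile a \code{\link{proteome_profile}}.
#' @param reference named numeric vector of reference abundances.
#' @param min_shared minimum number of shared proteins required.
#' @return rescaled profile; attributes \code{"factor"} and \code{"n_shared"}.
#' @export
calibrate_to_reference <- function(profile, reference, min_shared = 50) {
  shared <- intersect(names(profile$abundances)[profile$abundances > 0],
                      names(reference))
  if (length(shared) < min_shared)
    stop(sprintf("only %d shared proteins (need >= %d) for calibration",
                 length(shared), min_shared))
  fac <- stats::median(reference[shared] / profile$abundances[shared])
  out <- proteome_profile(profile$abundances * fac, profile$condition,
                          profile$replicate, profile$growth_rate)
  attr(out, "factor") <- fac
  attr(out, "n_shared") <- length(shared)
  out
}

#' Proteome fraction of a gene group
#'
#' Sums the fractional abundances of the proteins assigned to a group
#' (sector).  Works identically on transcript-count tables cast as
#' fractional profiles.
#'
#' @param profile fractional \code{\link{proteome_profile}}.
#' @param map gene-group map: data frame with columns \code{protein_id} and
#'   \code{group}; a protein may appear under several groups (small overlaps
#'   are allowed and each group is summed independently).
#' @param group group label.
#' @return the group's proteome fraction.
#' @export
group_fraction <- function(profile, map, group) {
  if (!profile$fractional) stop("profile must be fractional (see to_fractions)")
  if (!group %in% map$group)
    stop(sprintf("unknown group label '%s'", group))
  ids <- unique(map$protein_id[map$group == group])
  sum(profile$abundances[intersect(names(profile$abundances), ids)])
}

#' Fractions of all gene groups, with a residual remainder
#'
#' @inheritParams group_fraction
#' @param residual label under which the unassigned remainder
#'   (1 minus the summed named-group mass, floored at 0) is reported; NULL
#'   to omit.
#' @return named numeric vector of group fractions.
#' @export
group_fractions <- function(profile, map, residual = "other") {
  groups <- setdiff(unique(map$group), residual)
  fr <- vapply(groups, group_fraction, numeric(1), profile = profile, map = map)
  if (!is.null(residual))
    fr <- c(fr, stats::setNames(max(0, 1 - sum(fr)), residual))
  fr
}

#' Pairwise Pearson correlation between proteome compositions
#'
#' For every pair of profiles the correlation is computed over the
#' intersection of proteins detected (abundance > 0) in both.  MS-derived
#' fractions span several decades, so the default correlates
#' \code{log10(fraction)} after flooring at a detection limit; raw-scale
#' correlation is available since either convention is defensible.
#'
#' @param profiles list of fractional \code{\link{proteome_profile}}s (>= 2).
#' @param scale \code{"log10"} (default) or \code{"raw"}.
#' @param floor detection floor applied before the log transform.
#' @return symmetric correlation matrix with unit diagonal, labelled
#'   \code{condition.replicate}; a pair sharing fewer than 2 proteins gets NA
#'   (with a warning).
#' @export
proteome_correlation <- function(profiles, scale = c("log10", "raw"),
                                 floor = 1e-7) {
  scale <- match.arg(scale)
  stopifnot(length(profiles) >= 2)
  labs <- vapply(profiles, function(p)
    paste(p$condition, p$replicate, sep = "."), character(1))
  labs <- make.unique(labs)
  n <- length(profiles)
  m <- diag(1, n)
  dimnames(m) <- list(labs, labs)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    ai <- profiles[[i]]$abundances
    aj <- profiles[[j]]$abundances
    shared <- intersect(names(ai)[ai > 0], names(aj)[aj > 0])
    if (length(shared) < 2L) {
      warning(sprintf("pair (%s, %s): < 2 shared proteins", labs[i], labs[j]))
      m[i, j] <- m[j, i] <- NA_real_
      next
    }
    vi <- ai[shared]; vj <- aj[shared]
    if (scale == "log10") {
      vi <- log10(pmax(vi, floor)); vj <- log10(pmax(vj, floor))
    }
    m[i, j] <- m[j, i] <- stats::cor(vi, vj)
  }
  m
}

#' Protein-by-condition log2 matrix normalised to each protein's mean
#'
#' Each entry is \code{log2(abundance / mean abundance of that protein
#' across conditions)}, the representation used for expression heatmaps.
#' Proteins must be detected in at least \code{min_detected} of the
#' conditions; remaining zeros are imputed at half the per-condition
#' detection floor (the smallest positive abundance in that column).
#'
#' @param profiles list of \code{\link{proteome_profile}}s (one per
#'   condition, or condition-replicate).
#' @param min_detected minimum fraction of conditions in which a protein
#'   must be detected to be retained.
#' @return numeric matrix, proteins in rows, profiles in columns; each row
#'   satisfies \code{mean(2^row) == 1}.
#' @export
log2_mean_normalized <- function(profiles, min_detected = 0.5) {
  ids <- sort(unique(unlist(lapply(profiles, function(p) names(p$abundances)))))
  labs <- make.unique(vapply(profiles, function(p)
    paste(p$condition, p$replicate, sep = "."), character(1)))
  m <- sapply(profiles, function(p) {
    v <- stats::setNames(numeric(length(ids)), ids)
    v[names(p$abundances)] <- p$abundances
    v
  })
  colnames(m) <- labs
  keep <- rowMeans(m > 0) >= min_detected
  if (!any(keep)) stop("no protein detected in enough conditions")
  m <- m[keep, , drop = FALSE]
  for (j in seq_len(ncol(m))) {
    pos <- m[, j] > 0
    if (any(!pos)) m[!pos, j] <- min(m[pos, j]) / 2
  }
  log2(m / rowMeans(m))
}
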