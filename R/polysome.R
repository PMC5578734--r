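#' Canonical peak positions of a sucrose-gradient profile
#'
#' Positions are in arbitrary gradient units; they carry no information
#' after x-alignment, so fixed canonical values are used: 40S at 1.0, 60S
#' at 1.4, the monosome at 1.9, and polysome peak n at 1.9 + 0.5 (n - 1).
#'
#' @param n_max highest resolved polysome peak.
#' @return named numeric vector of positions.
#' @export
canonical_peak_positions <- function(n_max = 8) {
  stopifnot(n_max >= 2)
  n <- 2:n_max
  c(`40S` = 1.0, `60S` = 1.4, mono = 1.9,
    stats::setNames(1.9 + 0.5 * (n - 1), paste0("poly", n)))
}

#' Construct a sucrose-gradient absorbance trace
#'
#' @param position strictly increasing gradient coordinate (arbitrary units).
#' @param od254 absorbance values at 254 nm (same length, >= 50 samples).
#' @param label condition/strain label.
#' @return data frame of class \code{"polysome_trace"} with columns
#'   \code{position} and \code{od254}.
#' @export
polysome_trace <- function(position, od254, label = "trace") {
  stopifnot(length(position) == length(od254), length(position) >= 50)
  if (any(diff(position) <= 0)) stop("positions must be strictly increasing")
  structure(data.frame(position = position, od254 = od254),
            label = label, class = c("polysome_trace", "data.frame"))
}

#' @export
plot.polysome_trace <- function(x, xlab = "Gradient position",
                                ylab = expression(OD[254]), type = "l", ...) {
  graphics::plot(x$position, x$od254, type = type,
                 xlab = xlab, ylab = ylab, main = attr(x, "label"), ...)
  invisible(x)
}

# moving-average smoother used only for peak/boundary detection
.smooth_trace <- function(y, window = 5L) {
  s <- as.numeric(stats::filter(y, rep(1 / window, window), sides = 2))
  s[is.na(s)] <- y[is.na(s)]
  s
}

#' Preprocess a gradient trace
#'
#' Subtracts a blank gradient (interpolated to the trace's positions),
#' optionally registers the trace to a reference in x (shifting so the
#' monosome peaks coincide) and in y (scaling so total areas match), and
#' floors negative values at zero, reporting the floored mass.
#'
#' @param trace,blank,reference \code{\link{polysome_trace}} objects; blank
#'   and reference are optional.
#' @param mono_window position window within which the monosome peak (the
#'   registration anchor) is searched.
#' @param scale_to_reference if TRUE, y-scale so the total area equals the
#'   reference's.
#' @return preprocessed \code{\link{polysome_trace}}; attributes
#'   \code{"x_shift"}, \code{"y_scale"} and \code{"floored_mass"}.
#' @export
preprocess_trace <- function(trace, blank = NULL, reference = NULL,
                             mono_window = c(1.5, 2.2),
                             scale_to_reference = FALSE) {
  y <- trace$od254
  pos <- trace$position
  if (!is.null(blank)) {
    if (max(blank$position) < min(pos) || min(blank$position) > max(pos))
      stop("blank does not overlap the trace's position range")
    b <- stats::approx(blank$position, blank$od254, xout = pos, rule = 2)$y
    y <- y - b
  }
  x_shift <- 0
  y_scale <- 1
  if (!is.null(reference)) {
    anchor <- function(tr) {
      sm <- .smooth_trace(tr$od254)
      in_win <- tr$position >= mono_window[1] & tr$position <= mono_window[2]
      if (!any(in_win) || max(sm[in_win]) <= 0)
        stop("no detectable monosome peak for x-registration")
      tr$position[in_win][which.max(sm[in_win])]
    }
    x_shift <- anchor(reference) - anchor(polysome_trace(pos, pmax(y, 0)))
    pos <- pos + x_shift
    if (scale_to_reference) {
      tot <- pracma::trapz(pos, pmax(y, 0))
      tot_ref <- pracma::trapz(reference$position, pmax(reference$od254, 0))
      if (tot <= 0) stop("trace has zero total area; cannot y-scale")
      y_scale <- tot_ref / tot
      y <- y * y_scale
    }
  }
  neg <- y < 0
  floored <- -pracma::trapz(pos, ifelse(neg, y, 0))
  y[neg] <- 0
  out <- polysome_trace(pos, y, label = attr(trace, "label"))
  attr(out, "x_shift") <- x_shift
  attr(out, "y_scale") <- y_scale
  attr(out, "floored_mass") <- floored
  out
}

#' Default peak windows for gradient quantification
#'
#' Windows around the canonical peak positions, edges at midpoints between
#' adjacent peaks.  The region beyond the last resolved polysome peak is a
#' \code{"tail"} window whose signal is corrected as polysomes with
#' \code{n_max + 1} ribosomes (the rRNA fraction is within 2 percent of 1
#' there, bounding the assignment error).
#'
#' @param n_max highest resolved polysome peak.
#' @return data frame with columns \code{label}, \code{lo}, \code{hi} and
#'   \code{n_ribo} (0 = free subunit, 1 = monosome, n >= 2 = polysome).
#' @export
default_peak_windows <- function(n_max = 8) {
  p <- canonical_peak_positions(n_max)
  mid <- (p[-1] + p[-length(p)]) / 2
  data.frame(
    label  = c(names(p), "tail"),
    lo     = c(p[1] - 0.25, mid, p[length(p)] + 0.25),
    hi     = c(mid, p[length(p)] + 0.25, Inf),
    n_ribo = c(0L, 0L, 1L, 2:n_max, n_max + 1L),
    row.names = NULL
  )
}

#' rRNA share of the absorbance signal of an n-ribosome particle
#'
#' A mono/polysome's 254 nm absorbance reflects both its rRNA and the mRNA
#' it rides on.  With L_rRNA = 5500 nt of rRNA per ribosome and an average
#' mRNA of L_mRNA = 1250 nt, the rRNA fraction of an n-ribosome particle is
#' \deqn{f_n = n L_{rRNA} / (n L_{rRNA} + L_{mRNA}),}
#' about 82 percent for monosomes and 96 percent for 5-ribosome polysomes.
#' Multiplying raw peak areas by \eqn{f_n} converts them to
#' ribosome-equivalents.
#'
#' @param n ribosomes per mRNA (integer >= 1).
#' @param L_rRNA total rRNA length per ribosome, nucleotides.
#' @param L_mRNA average mRNA length, nucleotides.
#' @return rRNA fraction(s) in (0, 1), strictly increasing in \code{n}.
#' @examples
#' rrna_fraction(1)  # 0.8148
#' rrna_fraction(5)  # 0.9565
#' @export
rrna_fraction <- function(n, L_rRNA = 5500, L_mRNA = 1250) {
  if (any(n < 1) || any(n != round(n))) stop("n must be integer >= 1")
  n * L_rRNA / (n * L_rRNA + L_mRNA)
}

#' Integrate gradient peaks into areas and ribosome-equivalents
#'
#' Segments the trace at the local minima of a lightly smoothed copy
#' between adjacent expected peaks (falling back to window edges when no
#' interior minimum exists), integrates each segment of the raw trace by
#' the trapezoidal rule, and applies the rRNA correction: free subunits
#' (40S/60S) are pure rRNA (factor 1), the monosome is weighted by
#' \eqn{f_1}, polysome peak n by \eqn{f_n}.
#'
#' @param trace preprocessed \code{\link{polysome_trace}}.
#' @param windows peak-window table as from \code{\link{default_peak_windows}}.
#' @param smooth_window moving-average width (samples) used only for
#'   boundary detection.
#' @return object of class \code{"peak_quantification"}: list with
#'   \code{areas}, \code{equivalents} (both named by peak label),
#'   \code{n_ribo}, \code{boundaries} and \code{constants}.
#' @export
integrate_peaks <- function(trace, windows = default_peak_windows(),
                            smooth_window = 5L) {
  stopifnot(nrow(windows) >= 2, all(diff(windows$lo) > 0))
  pos <- trace$position
  y <- trace$od254
  sm <- .smooth_trace(y, smooth_window)
  k <- nrow(windows)
  # peak apex per window (on the smoothed trace)
  apex <- vapply(seq_len(k), function(i) {
    in_w <- pos >= windows$lo[i] & pos <= min(windows$hi[i], max(pos))
    if (!any(in_w)) return(NA_real_)
    pos[in_w][which.max(sm[in_w])]
  }, numeric(1))
  # boundary between window i and i+1: minimum of smoothed trace between apexes
  bounds <- numeric(k + 1L)
  bounds[1L] <- max(windows$lo[1L], min(pos))
  bounds[k + 1L] <- min(windows$hi[k], max(pos))
  for (i in seq_len(k - 1L)) {
    a <- if (is.na(apex[i])) windows$hi[i] else apex[i]
    b <- if (is.na(apex[i + 1L])) windows$lo[i + 1L] else apex[i + 1L]
    between <- pos > a & pos < b
    bounds[i + 1L] <- if (any(between)) pos[between][which.min(sm[between])]
                      else windows$hi[i]
  }
  # snap boundaries to grid indices so adjacent segments share their edge
  # sample exactly (keeps integration additive under window splitting)
  idx <- cummax(vapply(bounds, function(b)
    which.min(abs(pos - b)), integer(1)))
  bounds <- pos[idx]
  areas <- vapply(seq_len(k), function(i) {
    seg <- idx[i]:idx[i + 1L]
    if (length(seg) < 2L) return(0)
    pracma::trapz(pos[seg], y[seg])
  }, numeric(1))
  names(areas) <- windows$label
  f <- ifelse(windows$n_ribo == 0L, 1, rrna_fraction(pmax(windows$n_ribo, 1L)))
  equivalents <- areas * f
  missing <- windows$label[is.na(apex)]
  if (length(missing))
    warning("no apex detected for: ", paste(missing, collapse = ", "))
  structure(list(areas = areas, equivalents = equivalents,
                 n_ribo = stats::setNames(windows$n_ribo, windows$label),
                 boundaries = bounds,
                 constants = list(L_rRNA = 5500, L_mRNA = 1250)),
            class = "peak_quantification")
}

#' @export
print.peak_quantification <- function(x, digits = 4, ...) {
  cat("Gradient peak quantification\n")
  print(round(rbind(area = x$areas, ribosome_equiv = x$equivalents), digits))
  cat(sprintf("  inactive fraction rho = %s (raw %s);  P:M = %s\n",
              format(inactive_fraction(x), digits = digits),
              format(inactive_fraction(x, corrected = FALSE), digits = digits),
              format(polysome_monosome_ratio(x), digits = digits)))
  invisible(x)
}

.inactive_labels <- function(pq) names(pq$n_ribo)[pq$n_ribo <= 1L]

#' Inactive ribosome fraction from a quantified gradient
#'
#' \eqn{\rho} = (40S + 60S + monosome) signal over total ribosome signal,
#' by default on rRNA-corrected ribosome-equivalents (the uncorrected
#' raw-area variant is available since the published convention leaves the
#' arithmetic implicit).
#'
#' @param pq a \code{\link{integrate_peaks}} result.
#' @param corrected use ribosome-equivalents (TRUE) or raw areas.
#' @return \eqn{\rho} in [0, 1].
#' @export
inactive_fraction <- function(pq, corrected = TRUE) {
  v <- if (corrected) pq$equivalents else pq$areas
  tot <- sum(v)
  if (tot <= 0) stop("zero total signal; rho undefined")
  sum(v[.inactive_labels(pq)]) / tot
}

#' Polysome-to-monosome ratio
#'
#' Defined as the summed raw polysome areas divided by the raw
#' (40S + 60S + monosome) area — uncorrected by construction, matching the
#' experimental definition.
#'
#' @inheritParams inactive_fraction
#' @return the ratio.
#' @export
polysome_monosome_ratio <- function(pq) {
  inact <- sum(pq$areas[.inactive_labels(pq)])
  if (inact <= 0) stop("zero (40S + 60S + monosome) signal; ratio undefined")
  sum(pq$areas[pq$n_ribo >= 2L]) / inact
}

#' Quantify a raw gradient trace end to end
#'
#' Convenience wrapper: \code{\link{preprocess_trace}} then
#' \code{\link{integrate_peaks}}.
#'
#' @inheritParams preprocess_trace
#' @inheritParams integrate_peaks
#' @return a \code{"peak_quantification"}.
#' @export
quantify_trace <- function(trace, blank = NULL, reference = NULL,
                           windows = default_peak_windows(), ...) {
  integrate_peaks(preprocess_trace(trace, blank, reference, ...), windows)
}
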