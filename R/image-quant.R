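#' Manders overlap coefficient M1
#'
#' Fraction of above-threshold channel-A intensity residing in pixels
#' where channel B is also above its threshold:
#' `M1 = sum(A[A > tA & B > tB]) / sum(A[A > tA])`. Ranges from 0
#' (non-overlapping images) to 1 (complete co-localization).
#'
#' @param a,b intensity matrices of equal shape (e.g. a cytoskeletal
#'   marker and a nascent-translation channel).
#' @param threshold_a,threshold_b nonnegative intensity thresholds.
#' @return M1 in `[0, 1]`.
#' @export
manders_m1 <- function(a, b, threshold_a = 0, threshold_b = 0) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)),
            threshold_a >= 0, threshold_b >= 0,
            all(is.finite(a)), all(is.finite(b)), all(a >= 0), all(b >= 0))
  sel_a <- a > threshold_a
  denom <- sum(a[sel_a])
  if (denom == 0) stop("no channel-A intensity above threshold; M1 undefined")
  sum(a[sel_a & (b > threshold_b)]) / denom
}

#' Otsu automatic threshold
#'
#' Maximises between-class variance over a 256-bin intensity histogram;
#' intended as an explicit, logged alternative to GUI auto-thresholds.
#'
#' @param img intensity matrix.
#' @param n_bins histogram resolution.
#' @return threshold on the intensity scale of `img`.
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  v <- as.numeric(img)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (utils::head(br, -1) + utils::tail(br, -1)) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Corrected total cell fluorescence
#'
#' `CTCF = integrated ROI density - area(ROI) * mean background
#' fluorescence`, with the background level taken as the mean over the
#' per-ROI mean intensities of the supplied background regions.
#'
#' @param img intensity matrix.
#' @param roi logical mask of the measured region (nonempty, same shape).
#' @param background_rois list of one or more logical background masks.
#' @return CTCF value (may be negative for regions dimmer than
#'   background).
#' @export
ctcf <- function(img, roi, background_rois) {
  stopifnot(is.matrix(img), is.logical(roi), all(dim(roi) == dim(img)))
  if (!is.list(background_rois)) background_rois <- list(background_rois)
  if (length(background_rois) < 1L) stop("need at least one background ROI")
  if (sum(roi) == 0L) stop("empty ROI")
  bg_means <- vapply(background_rois, function(m) {
    stopifnot(is.logical(m), all(dim(m) == dim(img)))
    if (sum(m) == 0L) stop("empty background ROI")
    mean(img[m])
  }, numeric(1))
  sum(img[roi]) - sum(roi) * mean(bg_means)
}

#' Intensity correlation analysis score
#'
#' Sum over the ROI of the product of mean-centered intensities,
#' `sum((A - mean(A)) * (B - mean(B)))`, with the channel means taken over
#' the same ROI. Positive scores indicate correlated (co-varying)
#' staining.
#'
#' @param a,b intensity matrices of equal shape.
#' @param roi optional logical mask; default is the whole image.
#' @return ICA score (0 with a warning when a channel is constant).
#' @export
ica_score <- function(a, b, roi = NULL) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)))
  if (is.null(roi)) roi <- matrix(TRUE, nrow(a), ncol(a))
  stopifnot(is.logical(roi), all(dim(roi) == dim(a)))
  if (sum(roi) == 0L) stop("empty ROI")
  va <- a[roi]; vb <- b[roi]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("constant channel within ROI; ICA score is 0")
    return(0)
  }
  sum((va - mean(va)) * (vb - mean(vb)))
}

#' Share of ROIs with positive intensity correlation
#'
#' Summarises a set of per-ROI [ica_score()] values as the percentage
#' with positive covariance-style score (one reading of "percentage of A
#' channel over B channel intensity correlation"; see the vignette for
#' the ambiguity).
#'
#' @param scores numeric vector of per-ROI ICA scores.
#' @return percentage in `[0, 100]`.
#' @export
ica_percentage <- function(scores) {
  stopifnot(length(scores) > 0)
  100 * mean(scores > 0)
}

#' Normalise measurements to a control group
#'
#' Expresses values as a percentage of the control-group mean (e.g.
#' fluorescence quantifications normalised to a vehicle group).
#'
#' @param values numeric vector of measurements.
#' @param control numeric vector of control-group measurements with
#'   positive mean.
#' @return `100 * values / mean(control)`.
#' @export
normalize_to_control <- function(values, control) {
  m <- mean(control)
  if (!is.finite(m) || m <= 0) stop("control mean must be positive")
  100 * values / m
}
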