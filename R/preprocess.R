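#' Peak-picking parameters
#'
#' Thresholds mirror an mMass-style picker: a local maximum is accepted when
#' its signal-to-noise ratio, absolute intensity and intensity relative to the
#' base peak all clear their thresholds. Defaults are the study settings
#' (S/N 10.0, absolute 0.14, relative 0).
#'
#' @param snr_min minimum signal-to-noise ratio
#' @param abs_int_min minimum absolute (TIC-normalized) intensity
#' @param rel_int_min minimum intensity as a fraction of the base peak
#' @param picking_height centroiding height as percent of the apex; 100 means
#'   the centroid is computed over the apex's FWHM support
#' @param baseline_on apply rolling-minimum baseline correction first
#' @param smoothing_on apply Savitzky-Golay-like smoothing first
#' @param remove_shoulders drop local maxima inside the FWHM support of a
#'   larger accepted peak
#' @return list of class `picking_params`
#' @export
picking_params <- function(snr_min = 10.0, abs_int_min = 0.14,
                           rel_int_min = 0.0, picking_height = 100,
                           baseline_on = TRUE, smoothing_on = TRUE,
                           remove_shoulders = TRUE) {
  stopifnot(snr_min >= 0, abs_int_min >= 0, rel_int_min >= 0)
  structure(list(snr_min = snr_min, abs_int_min = abs_int_min,
                 rel_int_min = rel_int_min, picking_height = picking_height,
                 baseline_on = baseline_on, smoothing_on = smoothing_on,
                 remove_shoulders = remove_shoulders),
            class = "picking_params")
}

#' TIC-normalize a dataset
#'
#' Scales each pixel spectrum by (dataset-mean TIC / pixel TIC), so every
#' non-empty pixel ends up with the same total ion count while intensities
#' stay on a count-like scale (the dataset total is conserved). Pixels with
#' zero TIC are left as zeros and counted in the `n_zero_tic` attribute.
#'
#' @param dataset continuous-mode [msi_dataset()] with at least one non-zero
#'   pixel
#' @return normalized [msi_dataset()] with attribute `n_zero_tic`
#' @export
tic_normalize <- function(dataset) {
  stopifnot(dataset$mode == "continuous")
  tic <- rowSums(dataset$intensity)
  if (all(tic == 0)) stop("all-zero dataset: cannot TIC-normalize")
  target <- mean(tic)
  scale <- ifelse(tic > 0, target / tic, 0)
  dataset$intensity <- dataset$intensity * scale
  attr(dataset, "n_zero_tic") <- sum(tic == 0)
  attr(dataset, "tic_normalized") <- TRUE
  dataset
}

#' Mean spectrum of an ROI
#'
#' Arithmetic mean per m/z bin over the pixels carrying `region`'s label.
#'
#' @param dataset continuous-mode, TIC-normalized [msi_dataset()]
#' @param region one of `"tumor"`, `"necrosis"`, `"off_tissue"`,
#'   `"on_tissue"` (tumor + necrosis combined) or `"excluded"`
#' @return list with `mz`, `intensity`, `n_pixels`, `region`
#' @export
roi_mean_spectrum <- function(dataset, region) {
  stopifnot(dataset$mode == "continuous")
  sel <- if (region == "on_tissue") {
    dataset$roi %in% c("tumor", "necrosis")
  } else {
    dataset$roi == region
  }
  if (!any(sel)) {
    stop("no pixels labeled '", region, "' in section ",
         dataset$meta$section_id %||% "<unnamed>")
  }
  list(mz = dataset$mz,
       intensity = colMeans(dataset$intensity[sel, , drop = FALSE]),
       n_pixels = sum(sel), region = region)
}

.rolling_min <- function(x, k) {
  # centered rolling minimum, window of k points (k odd)
  n <- length(x)
  h <- (k - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    min(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

.rolling_mean <- function(x, k) {
  n <- length(x)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Baseline-correct a profile spectrum
#'
#' Subtracts a rolling-minimum baseline (default window 5 Da) smoothed by a
#' rolling mean of the same width, clipping the result at zero. If the window
#' exceeds the axis span the global minimum is subtracted instead.
#'
#' @param spectrum list with `mz` (uniform axis) and `intensity`
#' @param window_da baseline window width in Da
#' @return spectrum list with corrected `intensity`
#' @export
baseline_correct <- function(spectrum, window_da = 5) {
  mz <- spectrum$mz
  y <- spectrum$intensity
  span <- diff(range(mz))
  if (span <= window_da || length(mz) < 3L) {
    spectrum$intensity <- pmax(y - min(y), 0)
    return(spectrum)
  }
  step <- stats::median(diff(mz))
  k <- max(3L, 2L * floor(window_da / step / 2L) + 1L)
  base <- .rolling_mean(.rolling_min(y, k), k)
  spectrum$intensity <- pmax(y - base, 0)
  spectrum$baseline <- base
  spectrum
}

.sg_smooth <- function(y, k) {
  # moving quadratic fit (Savitzky-Golay) with symmetric window of k points
  if (k < 5L) return(y)
  half <- (k - 1L) %/% 2L
  x <- -half:half
  X <- cbind(1, x, x^2)
  w <- (solve(crossprod(X)) %*% t(X))[1, ]  # center-point filter weights
  n <- length(y)
  out <- stats::filter(y, rev(w), sides = 2)
  out <- as.numeric(out)
  out[is.na(out)] <- y[is.na(out)]  # leave edges unsmoothed
  out
}

#' Pick peaks from a profile spectrum
#'
#' Accepts local maxima clearing the S/N, absolute and relative intensity
#' thresholds. Noise is the median absolute deviation of the intensity in a
#' sliding 10-Da window, scaled by 1.4826; the centroid m/z is the
#' intensity-weighted mean over the apex's FWHM support; shoulder peaks (local
#' maxima inside the FWHM support of a larger accepted peak) are removed when
#' `remove_shoulders` is set.
#'
#' @param spectrum list with `mz` (uniform axis) and `intensity`
#'   (baseline-corrected unless `params$baseline_on`)
#' @param params a [picking_params()] object
#' @return data.frame with columns `mz`, `intensity` (apex height), `snr`,
#'   sorted by m/z
#' @export
pick_peaks <- function(spectrum, params = picking_params()) {
  empty <- data.frame(mz = numeric(0), intensity = numeric(0),
                      snr = numeric(0))
  if (length(spectrum$mz) == 0) return(empty)
  if (isTRUE(params$baseline_on)) spectrum <- baseline_correct(spectrum)
  mz <- spectrum$mz
  y <- spectrum$intensity
  n <- length(y)
  if (n < 3L) return(empty)
  step <- stats::median(diff(mz))
  if (isTRUE(params$smoothing_on)) {
    k_sg <- max(5L, 2L * floor(0.5 / step / 2L) + 1L)
    if (k_sg < n) y <- pmax(.sg_smooth(y, k_sg), 0)
  }

  # noise floor: MAD * 1.4826 in a sliding 10-Da window
  k_noise <- max(5L, 2L * floor(10 / step / 2L) + 1L)
  half <- (k_noise - 1L) %/% 2L
  noise_at <- function(i) {
    win <- y[max(1L, i - half):min(n, i + half)]
    1.4826 * stats::median(abs(win - stats::median(win)))
  }

  apex <- which(y[-c(1, n)] > y[-c(n - 1, n)] + 0 &
                y[-c(1, n)] >= y[-(1:2)]) + 1L
  apex <- apex[y[apex] > 0]
  if (!length(apex)) return(empty)

  base_peak <- max(y)
  peaks <- lapply(apex, function(i) {
    h <- y[i]
    nz <- noise_at(i)
    snr <- if (nz > 0) h / nz else Inf
    if (snr < params$snr_min) return(NULL)
    if (h < params$abs_int_min) return(NULL)
    if (h < params$rel_int_min * base_peak) return(NULL)
    # FWHM support around the apex
    lo <- i
    while (lo > 1L && y[lo - 1L] >= h / 2 && y[lo - 1L] <= y[lo]) lo <- lo - 1L
    hi <- i
    while (hi < n && y[hi + 1L] >= h / 2 && y[hi + 1L] <= y[hi]) hi <- hi + 1L
    sup <- lo:hi
    data.frame(mz = sum(mz[sup] * y[sup]) / sum(y[sup]), intensity = h,
               snr = snr, lo = mz[lo], hi = mz[hi])
  })
  peaks <- do.call(rbind, peaks)
  if (is.null(peaks) || !nrow(peaks)) return(empty)
  peaks <- peaks[order(peaks$mz), , drop = FALSE]

  if (isTRUE(params$remove_shoulders) && nrow(peaks) > 1) {
    keep <- rep(TRUE, nrow(peaks))
    ord <- order(-peaks$intensity)
    for (i in ord) {
      if (!keep[i]) next
      inside <- which(keep & peaks$mz >= peaks$lo[i] & peaks$mz <= peaks$hi[i] &
                      peaks$intensity < peaks$intensity[i])
      keep[inside] <- FALSE
    }
    peaks <- peaks[keep, , drop = FALSE]
  }
  rownames(peaks) <- NULL
  peaks[, c("mz", "intensity", "snr")]
}
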