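#' MSI dataset container
#'
#' Holds one tissue section's pixel spectra plus section metadata and an ROI
#' label per pixel. Two storage modes mirror imzML: `"continuous"` (one shared
#' m/z axis, intensities as a pixels x bins matrix) and `"processed"`
#' (per-pixel m/z and intensity vectors of individual lengths).
#'
#' @param mz continuous mode: numeric strictly increasing axis; processed
#'   mode: list of such vectors, one per pixel
#' @param intensity continuous mode: numeric matrix (pixels x bins) of
#'   non-negative intensities; processed mode: list of vectors matching `mz`
#' @param coords data.frame with integer columns `x`, `y` (0-based grid
#'   indices, x = column, y = row), one row per pixel
#' @param meta list with `section_id`, `bio_sample`, `tech_rep` (1..3, equals
#'   measurement day unless `day` given), `arm` ("treated"/"control"),
#'   optionally `day`
#' @param roi character/factor of per-pixel labels from
#'   `c("tumor","necrosis","off_tissue","excluded")`; defaults to all
#'   `"excluded"`
#' @return object of class `msi_dataset`
#' @export
msi_dataset <- function(mz, intensity, coords, meta = list(), roi = NULL) {
  mode <- if (is.list(mz)) "processed" else "continuous"
  coords <- as.data.frame(coords)
  stopifnot(all(c("x", "y") %in% names(coords)))
  n_pix <- nrow(coords)
  if (mode == "continuous") {
    intensity <- as.matrix(intensity)
    stopifnot(nrow(intensity) == n_pix, ncol(intensity) == length(mz))
    if (length(mz) > 1 && any(diff(mz) <= 0)) {
      stop("m/z axis must be strictly increasing")
    }
    if (any(intensity < 0)) stop("intensities must be non-negative")
  } else {
    stopifnot(length(mz) == n_pix, length(intensity) == n_pix)
    for (i in seq_len(n_pix)) {
      if (length(mz[[i]]) != length(intensity[[i]])) {
        stop("pixel ", i, ": mz and intensity lengths differ")
      }
      if (length(mz[[i]]) > 1 && any(diff(mz[[i]]) <= 0)) {
        stop("pixel ", i, ": m/z values must be strictly increasing")
      }
      if (any(intensity[[i]] < 0)) stop("pixel ", i, ": negative intensity")
    }
  }
  if (is.null(roi)) roi <- rep("excluded", n_pix)
  roi <- validate_roi_labels(roi, n_pix)
  meta <- validate_section_meta(meta)
  structure(list(mode = mode, mz = mz, intensity = intensity,
                 coords = coords, meta = meta, roi = roi),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  rng <- mz_range(x)
  cat(sprintf("<msi_dataset> %s mode, %d pixels, m/z %.3f-%.3f\n",
              x$mode, n_pixels(x), rng[1], rng[2]))
  cat("  section:", x$meta$section_id %||% "<unset>",
      " bio:", x$meta$bio_sample %||% "?",
      " rep:", x$meta$tech_rep %||% NA,
      " arm:", x$meta$arm %||% "?", "\n")
  print(table(x$roi))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of pixels in a dataset
#' @param dataset an [msi_dataset()]
#' @return integer pixel count
#' @export
n_pixels <- function(dataset) nrow(dataset$coords)

#' m/z range of a dataset
#' @param dataset an [msi_dataset()]
#' @return numeric length-2 `c(min, max)`
#' @export
mz_range <- function(dataset) {
  if (dataset$mode == "continuous") range(dataset$mz)
  else range(unlist(lapply(dataset$mz, range)))
}

.ROI_LEVELS <- c("tumor", "necrosis", "off_tissue", "excluded")

validate_roi_labels <- function(roi, n_pix) {
  roi <- as.character(roi)
  stopifnot(length(roi) == n_pix)
  bad <- setdiff(unique(roi), .ROI_LEVELS)
  if (length(bad)) stop("unknown ROI label(s): ", paste(bad, collapse = ", "))
  factor(roi, levels = .ROI_LEVELS)
}

validate_section_meta <- function(meta) {
  if (!is.null(meta$tech_rep)) {
    stopifnot(meta$tech_rep %in% 1:3)
    if (is.null(meta$day)) meta$day <- meta$tech_rep
  }
  if (!is.null(meta$arm)) stopifnot(meta$arm %in% c("treated", "control"))
  meta
}

#' Bin a processed-mode dataset onto a uniform m/z axis
#'
#' Each pixel's centroid/profile points are accumulated (summed) into fixed
#' bins so that cross-pixel statistics are well defined. Continuous-mode
#' input is returned unchanged.
#'
#' @param dataset an [msi_dataset()]
#' @param mz_min,mz_max axis limits in Da
#' @param step bin width in Da
#' @return continuous-mode [msi_dataset()]
#' @export
bin_to_axis <- function(dataset, mz_min = 500, mz_max = 1300, step = 0.1) {
  if (dataset$mode == "continuous") return(dataset)
  axis <- seq(mz_min, mz_max, by = step)
  n_pix <- n_pixels(dataset)
  mat <- matrix(0, n_pix, length(axis))
  for (i in seq_len(n_pix)) {
    idx <- round((dataset$mz[[i]] - mz_min) / step) + 1L
    ok <- idx >= 1L & idx <= length(axis)
    if (any(ok)) {
      acc <- tapply(dataset$intensity[[i]][ok], idx[ok], sum)
      mat[i, as.integer(names(acc))] <- acc
    }
  }
  msi_dataset(axis, mat, dataset$coords, dataset$meta,
              as.character(dataset$roi))
}

.sideband_idx <- function(mz, m, window_da) {
  # local-baseline sidebands flanking the integration window, placed inside
  # +/-0.75 Da so the +1 isotope (at +1.003 Da) stays clear of them
  lo <- window_da + 0.05
  hi <- window_da + 0.35
  which((mz >= m - hi & mz <= m - lo) | (mz >= m + lo & mz <= m + hi))
}

#' Per-pixel intensity of selected masses
#'
#' Integrates (sums) the TIC-normalized profile intensity inside a fixed-width
#' window around each query mass and subtracts a local baseline (the median of
#' flanking sideband bins scaled to the window width), yielding the
#' pixels x masses table that the matrix-peak filter, the iterative
#' mixed-model testing and the pixel ROC analysis operate on. Baseline
#' subtraction keeps additive background (chemical noise, detector floor) from
#' compressing fold changes.
#'
#' @param dataset continuous-mode [msi_dataset()]
#' @param masses numeric vector of m/z values
#' @param window_da half-width of the integration window in Da; the default
#'   0.4 covers the rendered peak width plus the maximum per-section
#'   calibration shift
#' @param baseline_sub subtract the sideband local baseline (default `TRUE`)
#' @return numeric matrix, `n_pixels x length(masses)`; column names are the
#'   formatted masses
#' @export
pixel_intensity_table <- function(dataset, masses, window_da = 0.4,
                                  baseline_sub = TRUE) {
  stopifnot(dataset$mode == "continuous")
  out <- matrix(0, n_pixels(dataset), length(masses))
  for (j in seq_along(masses)) {
    sel <- which(dataset$mz >= masses[j] - window_da &
                 dataset$mz <= masses[j] + window_da)
    if (!length(sel)) next
    sig <- rowSums(dataset$intensity[, sel, drop = FALSE])
    if (baseline_sub) {
      side <- .sideband_idx(dataset$mz, masses[j], window_da)
      if (length(side)) {
        base <- apply(dataset$intensity[, side, drop = FALSE], 1,
                      stats::median) * length(sel)
        sig <- pmax(sig - base, 0)
      }
    }
    out[, j] <- sig
  }
  colnames(out) <- sprintf("%.4f", masses)
  out
}

#' Intensity of selected masses in a mean spectrum
#'
#' Same windowed integration (with sideband local-baseline subtraction) as
#' [pixel_intensity_table()] but for a single (mean) spectrum.
#'
#' @param spectrum list with `mz` and `intensity` vectors
#' @param masses numeric vector of m/z values
#' @param window_da half-width of the window in Da
#' @param baseline_sub subtract the sideband local baseline (default `TRUE`)
#' @return numeric vector, one value per mass
#' @export
spectrum_mass_intensity <- function(spectrum, masses, window_da = 0.4,
                                    baseline_sub = TRUE) {
  vapply(masses, function(m) {
    sel <- which(spectrum$mz >= m - window_da & spectrum$mz <= m + window_da)
    if (!length(sel)) return(0)
    sig <- sum(spectrum$intensity[sel])
    if (baseline_sub) {
      side <- .sideband_idx(spectrum$mz, m, window_da)
      if (length(side)) {
        sig <- max(sig - stats::median(spectrum$intensity[side]) *
                     length(sel), 0)
      }
    }
    sig
  }, numeric(1))
}
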