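# Shared fixture builders. Everything is generated in code; no binary files.

# profile spectrum with Gaussian peaks on a uniform axis
gaussian_spectrum <- function(centers, heights, mz_min = 600, mz_max = 700,
                              step = 0.1, fwhm = 0.3, offset = 0,
                              noise = NULL) {
  mz <- seq(mz_min, mz_max, by = step)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  y <- rep(offset, length(mz))
  for (k in seq_along(centers)) {
    y <- y + heights[k] * exp(-(mz - centers[k])^2 / (2 * sigma^2))
  }
  if (!is.null(noise)) y <- y + noise
  list(mz = mz, intensity = y)
}

# tiny continuous-mode dataset built by hand
tiny_dataset <- function(intensity, mz = NULL, roi = NULL, meta = list()) {
  intensity <- as.matrix(intensity)
  if (is.null(mz)) mz <- seq(500, by = 0.1, length.out = ncol(intensity))
  n <- nrow(intensity)
  coords <- data.frame(x = (seq_len(n) - 1L) %% 4L,
                       y = (seq_len(n) - 1L) %/% 4L)
  msi_dataset(mz, intensity, coords, meta = meta, roi = roi)
}

# small but complete study configuration used across pipeline tests;
# any generator_config() argument can be overridden through ...
tiny_study_config <- function(seed = 7, ...) {
  args <- list(grid = c(16, 16), n_true_lipids = 8, n_matrix_peaks = 2,
               n_tumor_up = 2, n_necrosis_up = 1, n_treated_up = 1,
               n_control_up = 1, seed = seed)
  do.call(generator_config, utils::modifyList(args, list(...)))
}

# per-replicate intensity data.frame in the shape common_across_tech_reps
# returns (columns I_1, I_2, I_3)
rep_intensity_df <- function(mz, ...) {
  ints <- list(...)
  df <- data.frame(mz = mz, span_ppm = 0)
  for (k in seq_along(ints)) df[[paste0("I_", k)]] <- ints[[k]]
  df
}
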