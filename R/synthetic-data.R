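#' Synthetic MSI study configuration
#'
#' Emulates the study design: 8 biological xenograft samples (4 treated with a
#' glutaminase inhibitor, 4 control) x 3 technical replicate sections, each
#' measured on a different day; positive-mode lipid peaks on an m/z 500-1300
#' axis; tumor, necrosis and off-tissue regions; matrix peaks elevated
#' off-tissue; +1 isotopes; per-section calibration shift; shared day-level
#' intensity effects; spatially autocorrelated lognormal pixel noise.
#'
#' Default noise scales are chosen to land in the reproducibility regime the
#' workflow is built for: a day-effect CV of 0.25 and intraday CV of 0.15
#' put the whole-dataset and interday CVs in the 20-35% range and intraday
#' around 15%.
#'
#' @param n_bio biological samples (first `n_treated` are treated)
#' @param n_treated treated samples
#' @param n_tech technical replicates per sample (section `k` measured on
#'   day `k`)
#' @param grid `c(width, height)` in pixels
#' @param mz_min,mz_max,mz_step uniform m/z axis (Da)
#' @param n_true_lipids planted reproducible lipids
#' @param n_matrix_peaks planted matrix-derived peaks
#' @param n_tumor_up,tn_up_log2fc lipids elevated in tumor and their log2FC
#' @param n_necrosis_up,tn_down_log2fc lipids elevated in necrosis (log2FC
#'   applies tumor-vs-necrosis, so it is negative)
#' @param n_treated_up,arm_up_log2fc lipids elevated in the treated arm
#' @param n_control_up,arm_down_log2fc lipids elevated in the control arm
#' @param tissue_radius_frac tissue ellipse radius as fraction of the half
#'   grid (controls the off-tissue fraction)
#' @param necrosis_frac_of_tissue necrosis blob area as fraction of tissue
#' @param pixel_noise_cv lognormal pixel noise CV
#' @param day_effect_cv lognormal day-level effect CV (shared by all sections
#'   measured the same day)
#' @param intraday_cv lognormal per-section jitter CV
#' @param section_mass_shift_ppm max absolute per-section calibration shift
#'   (drawn uniformly in +/- this value; must stay below half the merge
#'   window)
#' @param isotope_ratio +1 isotope to monoisotopic intensity ratio
#' @param matrix_off_factor off-tissue amplification of matrix peaks
#' @param spatial_corr_length Gaussian correlation length of the pixel noise
#'   field, in pixels
#' @param noise_sd additive (half-normal) background noise per bin; the
#'   default makes total background dominate total lipid signal, as
#'   matrix-derived chemical noise does in positive-mode MALDI-TOF TIC
#' @param base_meanlog,base_sdlog lognormal parameters of lipid base
#'   intensities
#' @param seed master seed; all randomness derives from it
#' @return list of class `generator_config`
#' @export
generator_config <- function(n_bio = 8, n_treated = 4, n_tech = 3,
                             grid = c(40, 40),
                             mz_min = 500, mz_max = 1300, mz_step = 0.1,
                             n_true_lipids = 26, n_matrix_peaks = 5,
                             n_tumor_up = 6, tn_up_log2fc = 1.0,
                             n_necrosis_up = 2, tn_down_log2fc = -0.6,
                             n_treated_up = 3, arm_up_log2fc = 0.5,
                             n_control_up = 1, arm_down_log2fc = 0.8,
                             tissue_radius_frac = 0.84,
                             necrosis_frac_of_tissue = 0.35,
                             pixel_noise_cv = 0.4, day_effect_cv = 0.25,
                             intraday_cv = 0.15,
                             section_mass_shift_ppm = 75,
                             isotope_ratio = 0.35, matrix_off_factor = 10,
                             spatial_corr_length = 2, noise_sd = 1.5,
                             base_meanlog = log(30), base_sdlog = 0.8,
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_treated <= n_bio, n_tech >= 1,
            n_tumor_up + n_necrosis_up <= n_true_lipids,
            n_treated_up + n_control_up <= n_true_lipids,
            tissue_radius_frac > 0, tissue_radius_frac <= 1,
            necrosis_frac_of_tissue > 0, necrosis_frac_of_tissue < 1,
            section_mass_shift_ppm >= 0)
  structure(cfg, class = "generator_config")
}

#' Ground truth of a synthetic study
#'
#' Draws everything shared across sections: peak identities and m/z values,
#' base intensities, region/arm effect assignments, matrix-peak set, isotope
#' parents, and the per-(peak, day) shared day effects. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [generator_config()]
#' @return list of class `study_truth` with `peaks` (data.frame: name, mz,
#'   base, tn_log2fc, arm_log2fc, is_matrix, is_isotope_of), `day_effect`
#'   (peaks x days matrix), `bio_samples`, `arms`
#' @export
study_truth <- function(cfg) {
  set.seed(derive_seed(cfg$seed, 4L))
  n_peaks0 <- cfg$n_true_lipids + cfg$n_matrix_peaks
  # well-separated centers so clusters and isotopes never collide
  lo <- cfg$mz_min + 20
  hi <- cfg$mz_max - 20
  candidates <- seq(lo, hi, by = 5)
  stopifnot(length(candidates) >= n_peaks0)
  centers <- sort(sample(candidates, n_peaks0)) +
    stats::runif(n_peaks0, -1, 1)

  lipid_idx <- seq_len(cfg$n_true_lipids)
  matrix_idx <- cfg$n_true_lipids + seq_len(cfg$n_matrix_peaks)
  tn <- rep(0, n_peaks0)
  up <- sample(lipid_idx, cfg$n_tumor_up)
  tn[up] <- cfg$tn_up_log2fc
  down <- sample(setdiff(lipid_idx, up), cfg$n_necrosis_up)
  tn[down] <- cfg$tn_down_log2fc
  arm <- rep(0, n_peaks0)
  arm_up <- sample(lipid_idx, cfg$n_treated_up)
  arm[arm_up] <- cfg$arm_up_log2fc
  arm_dn <- sample(setdiff(lipid_idx, arm_up), cfg$n_control_up)
  arm[arm_dn] <- -cfg$arm_down_log2fc

  base <- stats::rlnorm(n_peaks0, cfg$base_meanlog, cfg$base_sdlog)
  peaks <- data.frame(
    name = c(sprintf("L%02d", lipid_idx), sprintf("M%02d",
                                                  seq_len(cfg$n_matrix_peaks))),
    mz = centers, base = base, tn_log2fc = tn, arm_log2fc = arm,
    is_matrix = c(rep(FALSE, cfg$n_true_lipids),
                  rep(TRUE, cfg$n_matrix_peaks)),
    is_isotope_of = NA_character_, stringsAsFactors = FALSE)
  # +1 isotopes of the true lipids
  if (cfg$isotope_ratio > 0) {
    iso <- peaks[lipid_idx, ]
    iso$name <- paste0(iso$name, "_iso")
    iso$mz <- iso$mz + 1.00335
    iso$base <- iso$base * cfg$isotope_ratio
    iso$is_isotope_of <- peaks$name[lipid_idx]
    peaks <- rbind(peaks, iso)
  }
  n_peaks <- nrow(peaks)
  sdl_day <- sqrt(log(1 + cfg$day_effect_cv^2))
  day_effect <- matrix(
    stats::rlnorm(n_peaks * cfg$n_tech, -sdl_day^2 / 2, sdl_day),
    n_peaks, cfg$n_tech)
  # isotopes co-vary perfectly with their parent peak
  iso_rows <- which(!is.na(peaks$is_isotope_of))
  if (length(iso_rows)) {
    parent_rows <- match(peaks$is_isotope_of[iso_rows], peaks$name)
    day_effect[iso_rows, ] <- day_effect[parent_rows, , drop = FALSE]
  }

  arms <- c(rep("treated", cfg$n_treated),
            rep("control", cfg$n_bio - cfg$n_treated))
  bio <- c(sprintf("T%d", seq_len(cfg$n_treated)),
           sprintf("C%d", seq_len(cfg$n_bio - cfg$n_treated)))
  structure(list(peaks = peaks, day_effect = day_effect, bio_samples = bio,
                 arms = stats::setNames(arms, bio)),
            class = "study_truth")
}

# spatially correlated standard-normal field on a W x H grid
.gauss_field <- function(W, H, corr_length) {
  z <- matrix(stats::rnorm(W * H), H, W)
  if (corr_length <= 0) return(z)
  half <- max(1L, ceiling(3 * corr_length))
  k <- stats::dnorm(-half:half, sd = corr_length)
  k <- k / sum(k)
  sm_rows <- apply(z, 2, function(col) {
    as.numeric(stats::filter(c(rev(col[seq_len(half)]), col,
                               rev(col[H - seq_len(half) + 1L])),
                             k, sides = 2))[half + seq_len(H)]
  })
  sm <- t(apply(sm_rows, 1, function(row) {
    as.numeric(stats::filter(c(rev(row[seq_len(half)]), row,
                               rev(row[W - seq_len(half) + 1L])),
                             k, sides = 2))[half + seq_len(W)]
  }))
  sm / sqrt(sum(k^2))  # restore unit variance (up to edge effects)
}

# contiguous region mask: off-tissue frame, tumor, necrosis blob,
# excluded boundary pixels between tumor and necrosis
.draw_roi <- function(W, H, tissue_radius_frac, necrosis_frac) {
  xs <- matrix(rep(0:(W - 1L), each = H), H, W)
  ys <- matrix(rep(0:(H - 1L), W), H, W)
  cx <- (W - 1) / 2
  cy <- (H - 1) / 2
  rx <- tissue_radius_frac * W / 2
  ry <- tissue_radius_frac * H / 2
  tissue <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
  # necrosis blob: disc centered at a random interior point, radius set to
  # the target fraction of the tissue area
  ncx <- cx + stats::runif(1, -0.3, 0.3) * rx
  ncy <- cy + stats::runif(1, -0.3, 0.3) * ry
  nr <- sqrt(necrosis_frac * sum(tissue) / pi)
  necro <- tissue & ((xs - ncx)^2 + (ys - ncy)^2 <= nr^2)
  roi <- matrix("off_tissue", H, W)
  roi[tissue] <- "tumor"
  roi[necro] <- "necrosis"
  # mixed boundary pixels are excluded, mirroring pathologist practice
  is_boundary <- necro &
    (rbind(necro[-1, ], FALSE) != necro |
     rbind(FALSE, necro[-H, ]) != necro |
     cbind(necro[, -1], FALSE) != necro |
     cbind(FALSE, necro[, -W]) != necro)
  roi[is_boundary & tissue] <- "excluded"
  list(roi = roi, xs = xs, ys = ys)
}

#' Simulate one tissue section
#'
#' Renders every planted peak as a Gaussian (FWHM 0.3 Da) on the uniform axis.
#' Per pixel p and peak l, the apex amplitude is
#' `base_l * 2^(tn_l * 1[tumor]) * 2^(arm_l * 1[treated]) * day_(l,day) *
#' jitter_(l,section) * eps_(l,p)`, where `log(eps)` is a spatially correlated
#' Gaussian field; lipids are absent off-tissue while matrix peaks are
#' amplified there; all centers are shifted by the section's calibration
#' offset; half-normal detector noise is added to every bin. Deterministic
#' given the config seed and section indices.
#'
#' @param cfg a [generator_config()]
#' @param truth matching [study_truth()]
#' @param bio_idx biological sample index (1-based)
#' @param tech technical replicate index (1..n_tech)
#' @param day measurement day (defaults to `tech`; set differently to emulate
#'   same-day replicate sections)
#' @return continuous-mode [msi_dataset()] with ROI labels and metadata;
#'   attribute `mass_shift_ppm` records the drawn calibration shift
#' @export
simulate_section <- function(cfg, truth, bio_idx, tech, day = tech) {
  set.seed(derive_seed(cfg$seed, 5L, bio_idx, tech, day))
  W <- cfg$grid[1]
  H <- cfg$grid[2]
  n_pix <- W * H
  axis <- seq(cfg$mz_min, cfg$mz_max, by = cfg$mz_step)
  peaks <- truth$peaks
  n_peaks <- nrow(peaks)
  arm <- truth$arms[[bio_idx]]
  treated <- arm == "treated"

  m <- .draw_roi(W, H, cfg$tissue_radius_frac, cfg$necrosis_frac_of_tissue)
  roi <- as.vector(m$roi)
  coords <- data.frame(x = as.vector(m$xs), y = as.vector(m$ys))

  shift_ppm <- stats::runif(1, -cfg$section_mass_shift_ppm,
                            cfg$section_mass_shift_ppm)
  centers <- peaks$mz * (1 + shift_ppm * 1e-6)

  sdl_intra <- sqrt(log(1 + cfg$intraday_cv^2))
  jitter <- stats::rlnorm(n_peaks, -sdl_intra^2 / 2, sdl_intra)
  sdl_pix <- sqrt(log(1 + cfg$pixel_noise_cv^2))

  is_tumor <- roi == "tumor"
  is_necro <- roi == "necrosis"
  is_off <- roi == "off_tissue"
  on_tissue <- !is_off

  A <- matrix(0, n_pix, n_peaks)
  for (l in seq_len(n_peaks)) {
    if (!is.na(peaks$is_isotope_of[l])) next  # filled from the parent below
    eps <- exp(as.vector(.gauss_field(W, H, cfg$spatial_corr_length)) *
                 sdl_pix - sdl_pix^2 / 2)
    amp <- peaks$base[l] * truth$day_effect[l, day] * jitter[l] * eps
    if (peaks$is_matrix[l]) {
      amp[is_off] <- amp[is_off] * cfg$matrix_off_factor
    } else {
      amp <- amp * 2^(peaks$tn_log2fc[l] * is_tumor) *
        2^(peaks$arm_log2fc[l] * treated)
      amp[is_off] <- 0
    }
    A[, l] <- amp
  }
  # isotope amplitudes track their parent pixel for pixel
  iso_rows <- which(!is.na(peaks$is_isotope_of))
  if (length(iso_rows)) {
    parent_rows <- match(peaks$is_isotope_of[iso_rows], peaks$name)
    A[, iso_rows] <- A[, parent_rows, drop = FALSE] * cfg$isotope_ratio
  }

  # Gaussian profiles, apex height 1, FWHM 0.3 Da
  sigma <- 0.3 / (2 * sqrt(2 * log(2)))
  G <- matrix(0, n_peaks, length(axis))
  for (l in seq_len(n_peaks)) {
    sel <- which(abs(axis - centers[l]) <= 4 * sigma)
    G[l, sel] <- exp(-(axis[sel] - centers[l])^2 / (2 * sigma^2))
  }
  intensity <- A %*% G
  if (cfg$noise_sd > 0) {
    intensity <- intensity +
      abs(matrix(stats::rnorm(n_pix * length(axis), 0, cfg$noise_sd),
                 n_pix, length(axis)))
  }

  bio <- truth$bio_samples[bio_idx]
  ds <- msi_dataset(axis, intensity, coords,
                    meta = list(section_id = sprintf("%s_R%d", bio, tech),
                                bio_sample = bio, tech_rep = tech, arm = arm,
                                day = day),
                    roi = roi)
  attr(ds, "mass_shift_ppm") <- shift_ppm
  ds
}

#' Generate the full synthetic study
#'
#' All `n_bio x n_tech` sections plus the ground truth. Memory heavy at the
#' default size (each section is a dense pixels x bins matrix); the pipeline
#' helpers in [summarize_sections()] stream sections instead.
#'
#' @param cfg a [generator_config()]
#' @return list with `sections` (list of [msi_dataset()]) and `truth`
#' @export
generate_study <- function(cfg) {
  truth <- study_truth(cfg)
  sections <- list()
  for (b in seq_len(cfg$n_bio)) {
    for (r in seq_len(cfg$n_tech)) {
      ds <- simulate_section(cfg, truth, b, r)
      sections[[ds$meta$section_id]] <- ds
    }
  }
  list(sections = sections, truth = truth)
}

#' Confusion counts of a master list against the ground truth
#'
#' Master masses are matched to planted non-matrix, non-isotope lipid m/z
#' values within `ppm_window`. Recall is over the planted lipids; precision is
#' the fraction of master entries that match a planted lipid.
#'
#' @param master_mz numeric vector of master-list m/z values (or a data.frame
#'   with an `mz` column)
#' @param truth a [study_truth()]
#' @param ppm_window match window in ppm
#' @return list with `tp`, `fp`, `fn`, `recall`, `precision`,
#'   `matched_names`
#' @export
truth_confusion <- function(master_mz, truth, ppm_window = 220) {
  if (is.data.frame(master_mz)) master_mz <- master_mz$mz
  target <- truth$peaks[!truth$peaks$is_matrix &
                        is.na(truth$peaks$is_isotope_of), ]
  hit_true <- vapply(target$mz, function(m) {
    any(abs(master_mz - m) / m * 1e6 <= ppm_window)
  }, logical(1))
  entry_ok <- vapply(master_mz, function(m) {
    any(abs(target$mz - m) / target$mz * 1e6 <= ppm_window)
  }, logical(1))
  tp <- sum(hit_true)
  list(tp = tp, fp = sum(!entry_ok), fn = sum(!hit_true),
       recall = tp / nrow(target),
       precision = if (length(master_mz)) mean(entry_ok) else NA_real_,
       matched_names = target$name[hit_true])
}
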