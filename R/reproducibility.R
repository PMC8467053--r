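#' Whole-dataset CV of master-list masses
#'
#' Per mass, intensities of all sections measured on the same day are averaged
#' (one day-level dataset mean per technical-replicate day), and the CV is
#' taken across the day-level means; the report aggregates the per-mass CVs as
#' mean +/- SD. Masses missing in a section are imputed as 0 and counted.
#'
#' @param section_intensities numeric matrix, masses x sections, of
#'   per-section tissue mean-spectrum intensities at the master masses (NA =
#'   missing)
#' @param days integer/character vector assigning each section (column) to its
#'   measurement day
#' @param mz optional m/z values naming the rows
#' @return list of class `cv_report`: `per_mz_cv`, `cv_avg`, `cv_sd`, `mode`,
#'   `n_imputed`
#' @export
whole_dataset_cv <- function(section_intensities, days, mz = NULL) {
  stopifnot(ncol(section_intensities) == length(days))
  n_imputed <- sum(is.na(section_intensities))
  section_intensities[is.na(section_intensities)] <- 0
  day_levels <- sort(unique(days))
  day_means <- vapply(day_levels, function(d) {
    rowMeans(section_intensities[, days == d, drop = FALSE])
  }, numeric(nrow(section_intensities)))
  day_means <- matrix(day_means, nrow = nrow(section_intensities))
  per_mz <- apply(day_means, 1, cv)
  if (!is.null(mz)) names(per_mz) <- sprintf("%.4f", mz)
  structure(list(per_mz_cv = per_mz, cv_avg = mean(per_mz, na.rm = TRUE),
                 cv_sd = stats::sd(per_mz, na.rm = TRUE),
                 mode = "whole_dataset", n_imputed = n_imputed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s: CV_avg = %.1f +/- %.1f%% over %d masses\n",
              x$mode, x$cv_avg, x$cv_sd, length(x$per_mz_cv)))
  invisible(x)
}

.replicate_cv <- function(section_intensities, mode, mz = NULL) {
  stopifnot(ncol(section_intensities) == 3)
  per_mz <- apply(section_intensities, 1, cv)
  if (!is.null(mz)) names(per_mz) <- sprintf("%.4f", mz)
  structure(list(per_mz_cv = per_mz, cv_avg = mean(per_mz, na.rm = TRUE),
                 cv_sd = stats::sd(per_mz, na.rm = TRUE), mode = mode,
                 n_imputed = 0L),
            class = "cv_report")
}

#' Intraday CV of master-list masses
#'
#' Per-mass CV across three technical-replicate sections of one biological
#' sample measured on the same day, aggregated as mean +/- SD across masses.
#'
#' @param section_intensities masses x 3 matrix of section mean intensities
#' @param mz optional m/z values naming the rows
#' @return `cv_report` (see [whole_dataset_cv()])
#' @export
intraday_cv <- function(section_intensities, mz = NULL) {
  .replicate_cv(section_intensities, "intraday", mz)
}

#' Interday CV of master-list masses
#'
#' As [intraday_cv()] but for three technical replicates measured on
#' different days.
#'
#' @param section_intensities masses x 3 matrix of section mean intensities
#' @param mz optional m/z values naming the rows
#' @return `cv_report`
#' @export
interday_cv <- function(section_intensities, mz = NULL) {
  .replicate_cv(section_intensities, "interday", mz)
}

#' Convert a CV report to a data.frame
#' @param x a `cv_report`
#' @param ... unused
#' @return data.frame with `mz` (when available) and `cv_percent`
#' @export
as.data.frame.cv_report <- function(x, ...) {
  data.frame(mz = names(x$per_mz_cv) %||% seq_along(x$per_mz_cv),
             cv_percent = unname(x$per_mz_cv))
}
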