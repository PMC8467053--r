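#' Master-peak-list filter configuration
#'
#' Defaults are the study settings: 220 ppm mass merging, CV < 45% within
#' regions, CV < 60% on per-replicate log2 fold changes, matrix peaks removed
#' above 0.9 AUC (off- vs on-tissue), master-list membership requiring at
#' least two biological replicates and mean TIC-normalized intensity > 1.
#'
#' @param ppm_window merge window in ppm
#' @param cv_region_max CV gate for region peak intensities, percent (strict)
#' @param cv_log2fc_max CV gate for per-replicate log2FC, percent (strict)
#' @param matrix_auc_min AUC above which a peak is called matrix-derived
#'   (strict, off-tissue as positive class)
#' @param min_bio_reps minimum biological replicates ("at least two",
#'   inclusive)
#' @param min_mean_intensity minimum mean TIC-normalized intensity (strict)
#' @param isotope_delta +1 isotope spacing in Da
#' @param isotope_tol_ppm tolerance for isotope spacing matches, ppm
#' @param min_detect_freq automated stand-in for the study's visual
#'   low-quality-signal screen: minimum fraction of tissue pixels in which a
#'   mass is detectable
#' @param detect_floor pixel intensity above which a mass counts as detected
#'   for `min_detect_freq`
#' @return list of class `filter_config`
#' @export
filter_config <- function(ppm_window = 220, cv_region_max = 45,
                          cv_log2fc_max = 60, matrix_auc_min = 0.9,
                          min_bio_reps = 2, min_mean_intensity = 1.0,
                          isotope_delta = 1.00335, isotope_tol_ppm = 220,
                          min_detect_freq = 0.01, detect_floor = 1.0) {
  cfg <- as.list(environment())
  stopifnot(all(unlist(cfg[c("ppm_window", "cv_region_max", "cv_log2fc_max",
                             "matrix_auc_min", "min_bio_reps",
                             "min_mean_intensity", "isotope_delta",
                             "isotope_tol_ppm")]) > 0))
  structure(cfg, class = "filter_config")
}

#' Coefficient of variation, percent
#'
#' `100 * sample SD (n-1 denominator) / mean`. Needs at least two values and a
#' non-zero mean; a zero mean yields `NA` with a warning.
#'
#' @param values numeric vector, length >= 2
#' @return CV in percent, or `NA_real_` when the mean is zero
#' @export
cv <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  if (m == 0) {
    warning("CV undefined for zero mean")
    return(NA_real_)
  }
  100 * stats::sd(values) / m
}

#' Merge peak lists into ppm mass clusters
#'
#' Pools all peaks, sorts by m/z, and breaks between consecutive values whose
#' gap exceeds `ppm_window` relative to the smaller value (single-linkage gap
#' clustering; deterministic and order-free). Equals the transitive closure of
#' all pairwise within-window relations. A cluster may chain beyond the window
#' end to end; `span_ppm` records the realized span.
#'
#' @param peaklists list of data.frames with columns `mz`, `intensity` (other
#'   columns are carried through as member annotations); list names become the
#'   `replicate_id` member column when absent
#' @param ppm_window merge window in ppm
#' @return list of clusters, each a list with `rep_mz` (intensity-weighted
#'   mean), `members` (data.frame) and `span_ppm`
#' @export
merge_by_ppm <- function(peaklists, ppm_window = 220) {
  if (!length(peaklists)) return(list())
  if (is.data.frame(peaklists)) peaklists <- list(peaklists)
  nm <- names(peaklists)
  pooled <- do.call(rbind, lapply(seq_along(peaklists), function(i) {
    df <- peaklists[[i]]
    if (!nrow(df)) return(NULL)
    stopifnot(all(c("mz", "intensity") %in% names(df)))
    if (!"replicate_id" %in% names(df)) {
      df$replicate_id <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else
        as.character(i)
    }
    df
  }))
  if (is.null(pooled) || !nrow(pooled)) return(list())
  pooled <- pooled[order(pooled$mz), , drop = FALSE]
  gaps <- diff(pooled$mz) / pooled$mz[-nrow(pooled)] * 1e6
  grp <- cumsum(c(1, as.integer(gaps > ppm_window)))
  lapply(split(pooled, grp), function(members) {
    rownames(members) <- NULL
    w <- members$intensity
    rep_mz <- if (sum(w) > 0) sum(members$mz * w) / sum(w) else
      mean(members$mz)
    span <- (max(members$mz) - min(members$mz)) / min(members$mz) * 1e6
    list(rep_mz = rep_mz, members = members, span_ppm = span)
  })
}

#' Keep masses common to all technical replicates
#'
#' Clusters built from one biological sample's per-replicate region peak lists
#' are kept when every expected replicate contributed at least one member.
#' Per-replicate intensity is the maximum over that replicate's members.
#'
#' @param clusters output of [merge_by_ppm()]
#' @param rep_ids expected replicate identifiers (default `c("1","2","3")`)
#' @return data.frame with `mz` (cluster representative), `span_ppm`, and one
#'   `I_<rep>` intensity column per replicate
#' @export
common_across_tech_reps <- function(clusters, rep_ids = as.character(1:3)) {
  rep_ids <- as.character(rep_ids)
  rows <- lapply(clusters, function(cl) {
    have <- unique(as.character(cl$members$replicate_id))
    if (!all(rep_ids %in% have)) return(NULL)
    ints <- vapply(rep_ids, function(r) {
      max(cl$members$intensity[cl$members$replicate_id == r])
    }, numeric(1))
    out <- data.frame(mz = cl$rep_mz, span_ppm = cl$span_ppm)
    out[paste0("I_", rep_ids)] <- as.list(ints)
    out
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    rows <- data.frame(mz = numeric(0), span_ppm = numeric(0))
    rows[paste0("I_", rep_ids)] <- list(numeric(0))
  }
  rownames(rows) <- NULL
  rows[order(rows$mz), , drop = FALSE]
}

.intensity_cols <- function(df) grep("^I_", names(df), value = TRUE)

#' CV gate on per-replicate intensities
#'
#' Keeps masses whose per-replicate intensity CV is strictly below `max_cv`.
#'
#' @param peaks data.frame from [common_across_tech_reps()]
#' @param max_cv CV threshold in percent (strict `<`)
#' @return filtered data.frame with a `cv` column appended
#' @export
cv_gate <- function(peaks, max_cv = 45) {
  cols <- .intensity_cols(peaks)
  stopifnot(length(cols) >= 2)
  peaks$cv <- apply(peaks[cols], 1, cv)
  peaks[!is.na(peaks$cv) & peaks$cv < max_cv, , drop = FALSE]
}

#' log2 fold-change consistency gate
#'
#' For masses detected in both tumor and necrosis in all technical replicates,
#' computes per-replicate `log2(I_tumor / I_necrosis)` and keeps the mass when
#' the CV of those fold changes is strictly below `max_cv`. Masses with a zero
#' (or missing) necrosis intensity in any replicate are excluded and counted.
#'
#' @param tumor,necrosis data.frames from [common_across_tech_reps()] with the
#'   same `I_<rep>` columns
#' @param max_cv CV threshold in percent (strict `<`)
#' @param ppm_window window for pairing tumor and necrosis masses
#' @return data.frame with `mz`, per-replicate `fc_<rep>` columns, `fc_cv` and
#'   mean intensities; attribute `n_excluded_zero` counts exclusions
#' @export
log2fc_consistency_gate <- function(tumor, necrosis, max_cv = 60,
                                    ppm_window = 220) {
  cols <- .intensity_cols(tumor)
  stopifnot(identical(cols, .intensity_cols(necrosis)))
  empty <- data.frame(mz = numeric(0))
  if (!nrow(tumor) || !nrow(necrosis)) {
    attr(empty, "n_excluded_zero") <- 0L
    return(empty)
  }
  t_df <- tumor; t_df$.region <- "tumor"; t_df$intensity <- rowMeans(t_df[cols])
  n_df <- necrosis; n_df$.region <- "necrosis"
  n_df$intensity <- rowMeans(n_df[cols])
  clusters <- merge_by_ppm(list(t_df, n_df), ppm_window)
  n_zero <- 0L
  rows <- lapply(clusters, function(cl) {
    m <- cl$members
    if (!all(c("tumor", "necrosis") %in% m$.region)) return(NULL)
    it <- as.numeric(m[m$.region == "tumor", cols][1, ])
    in_ <- as.numeric(m[m$.region == "necrosis", cols][1, ])
    if (any(in_ <= 0) || any(it <= 0)) {
      n_zero <<- n_zero + 1L
      return(NULL)
    }
    fc <- log2(it / in_)
    out <- data.frame(mz = cl$rep_mz)
    out[sub("^I_", "fc_", cols)] <- as.list(fc)
    out$fc_cv <- cv(fc)
    out$mean_tumor <- mean(it)
    out$mean_necrosis <- mean(in_)
    out
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) rows <- empty
  else {
    rows <- rows[!is.na(rows$fc_cv) & rows$fc_cv < max_cv, , drop = FALSE]
    rownames(rows) <- NULL
  }
  attr(rows, "n_excluded_zero") <- n_zero
  rows
}

#' Rank-statistic ROC AUC
#'
#' Mann-Whitney formulation with ties counted one half: the probability that a
#' random positive outranks a random negative.
#'
#' @param pos,neg numeric vectors of scores for the positive and negative
#'   class
#' @return AUC in `[0, 1]`
#' @export
rank_auc <- function(pos, neg) {
  stopifnot(length(pos) > 0, length(neg) > 0)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Remove matrix-derived peaks by on/off-tissue ROC
#'
#' For each candidate mass, computes the AUC of pixel intensities with
#' off-tissue as the positive class; the mass is removed when the AUC is
#' strictly above `auc_min` and the off-tissue mean exceeds the on-tissue
#' mean. Without off-tissue pixels the filter is skipped with a warning.
#'
#' @param pixel_table pixels x masses matrix, see [pixel_intensity_table()]
#' @param roi per-pixel labels aligned with the table's rows
#' @param auc_min AUC threshold (strict `>`)
#' @return list with `kept`, `removed` (column indices), and a data.frame
#'   `audit` (per mass: auc, mean_on, mean_off, removed)
#' @export
matrix_peak_filter <- function(pixel_table, roi, auc_min = 0.9) {
  roi <- as.character(roi)
  off <- roi == "off_tissue"
  on <- roi %in% c("tumor", "necrosis")
  n_mass <- ncol(pixel_table)
  if (!any(off)) {
    warning("no off-tissue pixels: matrix-peak filter skipped")
    audit <- data.frame(column = seq_len(n_mass), auc = NA_real_,
                        mean_on = NA_real_, mean_off = NA_real_,
                        removed = FALSE)
    return(list(kept = seq_len(n_mass), removed = integer(0), audit = audit))
  }
  stopifnot(any(on))
  auc <- vapply(seq_len(n_mass), function(j) {
    rank_auc(pixel_table[off, j], pixel_table[on, j])
  }, numeric(1))
  mean_off <- unname(colMeans(pixel_table[off, , drop = FALSE]))
  mean_on <- unname(colMeans(pixel_table[on, , drop = FALSE]))
  removed <- auc > auc_min & mean_off > mean_on
  list(kept = which(!removed), removed = which(removed),
       audit = data.frame(column = seq_len(n_mass), auc = auc,
                          mean_on = mean_on, mean_off = mean_off,
                          removed = removed))
}

#' Remove +1 isotope peaks
#'
#' Scanning in ascending m/z, a peak is flagged as an isotope and removed when
#' a retained peak sits one isotope spacing below it (within `tol_ppm`) with
#' strictly greater intensity, so monoisotopic peaks are always retained.
#'
#' @param peaks data.frame with `mz` and `intensity`, any other columns kept
#' @param delta isotope spacing in Da (default 1.00335)
#' @param tol_ppm spacing tolerance in ppm
#' @return filtered data.frame; attribute `removed` holds the dropped rows
#' @export
isotope_filter <- function(peaks, delta = 1.00335, tol_ppm = 220) {
  if (!nrow(peaks)) return(peaks)
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  keep <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    lower <- which(keep[seq_len(i - 1L)])
    if (!length(lower)) next
    gap <- peaks$mz[i] - peaks$mz[lower]
    hit <- abs(gap - delta) <= tol_ppm * 1e-6 * peaks$mz[i]
    if (any(hit & peaks$intensity[lower] > peaks$intensity[i])) {
      keep[i] <- FALSE
    }
  }
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- peaks[!keep, , drop = FALSE]
  out
}

#' Assemble the master peak list across biological samples
#'
#' Pools the per-biological-sample candidate lists (each already gated,
#' matrix- and isotope-filtered), clusters across samples by ppm, and keeps
#' masses present in at least `min_bio_reps` distinct samples with overall
#' mean intensity strictly above `min_mean_intensity`. A final isotope
#' re-check runs on the assembled list. Output is ordered by m/z and invariant
#' under permutation of the input samples.
#'
#' @param per_bio_lists named list (one element per biological sample) of
#'   data.frames with columns `mz`, `mean_intensity` and optionally `source`
#' @param cfg a [filter_config()]
#' @return data.frame with `mz`, `n_bio`, `bio_samples`, `mean_intensity`,
#'   `sources`
#' @export
build_master_list <- function(per_bio_lists, cfg = filter_config()) {
  stopifnot(length(names(per_bio_lists)) == length(per_bio_lists))
  pooled <- lapply(sort(names(per_bio_lists)), function(s) {
    df <- per_bio_lists[[s]]
    if (is.null(df) || !nrow(df)) return(NULL)
    stopifnot(all(c("mz", "mean_intensity") %in% names(df)))
    data.frame(mz = df$mz, intensity = df$mean_intensity,
               bio_sample = s,
               source = if ("source" %in% names(df)) df$source else "",
               stringsAsFactors = FALSE)
  })
  pooled <- do.call(rbind, pooled)
  if (is.null(pooled) || !nrow(pooled)) {
    return(data.frame(mz = numeric(0), n_bio = integer(0),
                      bio_samples = character(0), mean_intensity = numeric(0),
                      sources = character(0)))
  }
  clusters <- merge_by_ppm(list(pooled), cfg$ppm_window)
  rows <- lapply(clusters, function(cl) {
    m <- cl$members
    samples <- sort(unique(m$bio_sample))
    # within a sample, duplicates (e.g. tumor + log2fc lists) collapse to max
    per_sample <- vapply(samples, function(s) {
      max(m$intensity[m$bio_sample == s])
    }, numeric(1))
    data.frame(mz = cl$rep_mz, n_bio = length(samples),
               bio_samples = paste(samples, collapse = ","),
               mean_intensity = mean(per_sample),
               sources = paste(sort(unique(unlist(strsplit(
                 m$source[nzchar(m$source)], ",")))), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_bio >= cfg$min_bio_reps &
             out$mean_intensity > cfg$min_mean_intensity, , drop = FALSE]
  out$intensity <- out$mean_intensity
  out <- isotope_filter(out, cfg$isotope_delta, cfg$isotope_tol_ppm)
  out$intensity <- NULL
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}
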