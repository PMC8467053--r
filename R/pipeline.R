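# Stage orchestration: streams sections (regenerating them from the seed on
# demand rather than holding 24 dense pixel matrices in memory), builds the
# per-sample candidate lists, assembles the master peak list, and runs the
# reproducibility, region and treatment analyses.

#' Per-section mean-spectrum summaries
#'
#' Generates (or takes) each section, TIC-normalizes it, and keeps only what
#' the peak-list stages need: metadata, ROI pixel counts, and the tumor,
#' necrosis and whole-tissue mean spectra.
#'
#' @param cfg a [generator_config()]; ignored when `sections` is given
#' @param truth matching [study_truth()]; computed from `cfg` when missing
#' @param sections optional list of ready [msi_dataset()]s (already labeled);
#'   each is TIC-normalized here
#' @param exclude section ids to drop (mirrors the exclusion of contaminated
#'   sections)
#' @return list of per-section summaries (`meta`, `n_roi`, `tumor`,
#'   `necrosis`, `tissue` mean spectra); attribute `excluded` records drops
#' @export
summarize_sections <- function(cfg, truth = NULL, sections = NULL,
                               exclude = character(0)) {
  if (is.null(sections)) {
    if (is.null(truth)) truth <- study_truth(cfg)
    idx <- expand.grid(tech = seq_len(cfg$n_tech), bio = seq_len(cfg$n_bio))
    gen <- function(k) simulate_section(cfg, truth, idx$bio[k], idx$tech[k])
    n <- nrow(idx)
  } else {
    gen <- function(k) sections[[k]]
    n <- length(sections)
  }
  out <- list()
  for (k in seq_len(n)) {
    ds <- tic_normalize(gen(k))
    id <- ds$meta$section_id
    if (id %in% exclude) next
    out[[id]] <- list(
      meta = ds$meta,
      n_roi = table(ds$roi),
      tumor = roi_mean_spectrum(ds, "tumor"),
      necrosis = roi_mean_spectrum(ds, "necrosis"),
      tissue = roi_mean_spectrum(ds, "on_tissue"))
  }
  attr(out, "excluded") <- exclude
  out
}

#' Per-biological-sample candidate peak lists
#'
#' For each biological sample: picks peaks from the tumor and necrosis mean
#' spectra of its technical replicates, merges within the ppm window, keeps
#' masses common to all replicates, applies the region CV gate and the log2FC
#' consistency gate, and unions the three lists with ppm dedup.
#'
#' @param summaries output of [summarize_sections()]
#' @param fcfg a [filter_config()]
#' @param params a [picking_params()]
#' @return named list (per biological sample) of data.frames `mz`,
#'   `mean_intensity`, `source` (comma-joined flags from
#'   tumor/necrosis/log2fc)
#' @export
per_sample_candidates <- function(summaries, fcfg = filter_config(),
                                  params = picking_params()) {
  bio <- unique(vapply(summaries, function(s) s$meta$bio_sample, character(1)))
  out <- list()
  for (b in bio) {
    secs <- Filter(function(s) s$meta$bio_sample == b, summaries)
    reps <- as.character(vapply(secs, function(s) s$meta$tech_rep, numeric(1)))
    region_common <- list()
    for (region in c("tumor", "necrosis")) {
      lists <- lapply(secs, function(s) pick_peaks(s[[region]], params))
      names(lists) <- reps
      clusters <- merge_by_ppm(lists, fcfg$ppm_window)
      common <- common_across_tech_reps(clusters, rep_ids = reps)
      region_common[[region]] <- common
    }
    gated <- lapply(region_common, cv_gate, max_cv = fcfg$cv_region_max)
    fc <- log2fc_consistency_gate(region_common$tumor,
                                  region_common$necrosis,
                                  max_cv = fcfg$cv_log2fc_max,
                                  ppm_window = fcfg$ppm_window)
    pieces <- list()
    for (region in c("tumor", "necrosis")) {
      g <- gated[[region]]
      if (nrow(g)) {
        pieces[[region]] <- data.frame(
          mz = g$mz, intensity = rowMeans(g[.intensity_cols(g)]),
          source = region)
      }
    }
    if (nrow(fc)) {
      pieces$log2fc <- data.frame(
        mz = fc$mz, intensity = (fc$mean_tumor + fc$mean_necrosis) / 2,
        source = "log2fc")
    }
    if (!length(pieces)) {
      out[[b]] <- data.frame(mz = numeric(0), mean_intensity = numeric(0),
                             source = character(0))
      next
    }
    clusters <- merge_by_ppm(pieces, fcfg$ppm_window)
    out[[b]] <- do.call(rbind, lapply(clusters, function(cl) {
      data.frame(mz = cl$rep_mz,
                 mean_intensity = mean(cl$members$intensity),
                 source = paste(sort(unique(cl$members$source)),
                                collapse = ","))
    }))
    rownames(out[[b]]) <- NULL
  }
  out
}

#' Pixel-level intensities at selected masses for every section
#'
#' Streams (regenerates) each section, TIC-normalizes it, and extracts the
#' pixels x masses table plus per-pixel annotations.
#'
#' @param cfg a [generator_config()]; ignored when `sections` is given
#' @param truth matching [study_truth()]
#' @param masses m/z values to extract
#' @param sections optional list of ready [msi_dataset()]s
#' @param exclude section ids to drop
#' @param window_da integration window half-width, see
#'   [pixel_intensity_table()]
#' @return list with `intensity` (matrix), `roi`, `bio_sample`, `section_id`,
#'   `tech_rep`, `arm`, `day` (vectors aligned with rows), `masses`
#' @export
collect_pixel_data <- function(cfg, truth = NULL, masses, sections = NULL,
                               exclude = character(0), window_da = 0.4) {
  if (is.null(sections)) {
    if (is.null(truth)) truth <- study_truth(cfg)
    idx <- expand.grid(tech = seq_len(cfg$n_tech), bio = seq_len(cfg$n_bio))
    gen <- function(k) simulate_section(cfg, truth, idx$bio[k], idx$tech[k])
    n <- nrow(idx)
  } else {
    gen <- function(k) sections[[k]]
    n <- length(sections)
  }
  parts <- list()
  for (k in seq_len(n)) {
    ds <- tic_normalize(gen(k))
    id <- ds$meta$section_id
    if (id %in% exclude) next
    parts[[id]] <- list(
      tab = pixel_intensity_table(ds, masses, window_da),
      roi = as.character(ds$roi), meta = ds$meta)
  }
  list(
    intensity = do.call(rbind, lapply(parts, `[[`, "tab")),
    roi = unlist(lapply(parts, `[[`, "roi"), use.names = FALSE),
    bio_sample = unlist(lapply(parts, function(p)
      rep(p$meta$bio_sample, length(p$roi))), use.names = FALSE),
    section_id = unlist(lapply(parts, function(p)
      rep(p$meta$section_id, length(p$roi))), use.names = FALSE),
    tech_rep = unlist(lapply(parts, function(p)
      rep(p$meta$tech_rep, length(p$roi))), use.names = FALSE),
    arm = unlist(lapply(parts, function(p)
      rep(p$meta$arm, length(p$roi))), use.names = FALSE),
    day = unlist(lapply(parts, function(p)
      rep(p$meta$day, length(p$roi))), use.names = FALSE),
    masses = masses)
}

#' Matrix, isotope and detectability filters per biological sample
#'
#' Applies, per biological sample and against its own sections' pixels: the
#' off-tissue ROC matrix-peak filter, the +1 isotope filter, and the
#' detection-frequency screen standing in for visual quality inspection.
#'
#' @param per_sample output of [per_sample_candidates()]
#' @param pixel_data output of [collect_pixel_data()] at the pooled candidate
#'   masses
#' @param fcfg a [filter_config()]
#' @return list with `lists` (filtered per-sample data.frames) and `audit`
#'   (data.frame of removals with reasons)
#' @export
apply_sample_filters <- function(per_sample, pixel_data,
                                 fcfg = filter_config()) {
  audit <- list()
  masses <- pixel_data$masses
  match_col <- function(mz) {
    j <- which.min(abs(masses - mz))
    if (abs(masses[j] - mz) / mz * 1e6 <= fcfg$ppm_window) j else NA_integer_
  }
  lists <- lapply(names(per_sample), function(b) {
    df <- per_sample[[b]]
    if (!nrow(df)) return(df)
    rows <- pixel_data$bio_sample == b
    cols <- vapply(df$mz, match_col, integer(1))
    ok <- !is.na(cols)
    tab <- pixel_data$intensity[rows, cols[ok], drop = FALSE]
    roi <- pixel_data$roi[rows]

    mf <- matrix_peak_filter(tab, roi, fcfg$matrix_auc_min)
    if (length(mf$removed)) {
      audit[[length(audit) + 1]] <<- data.frame(
        bio_sample = b, mz = df$mz[ok][mf$removed], reason = "matrix_peak")
    }
    keep1 <- df[ok, , drop = FALSE][mf$kept, , drop = FALSE]
    tab <- tab[, mf$kept, drop = FALSE]

    tissue <- roi %in% c("tumor", "necrosis")
    freq <- colMeans(tab[tissue, , drop = FALSE] > fcfg$detect_floor)
    low <- freq < fcfg$min_detect_freq
    if (any(low)) {
      audit[[length(audit) + 1]] <<- data.frame(
        bio_sample = b, mz = keep1$mz[low], reason = "low_detect_freq")
    }
    keep2 <- keep1[!low, , drop = FALSE]

    keep2$intensity <- keep2$mean_intensity
    out <- isotope_filter(keep2, fcfg$isotope_delta, fcfg$isotope_tol_ppm)
    rem <- attr(out, "removed")
    if (!is.null(rem) && nrow(rem)) {
      audit[[length(audit) + 1]] <<- data.frame(
        bio_sample = b, mz = rem$mz, reason = "isotope")
    }
    out$intensity <- NULL
    out
  })
  names(lists) <- names(per_sample)
  audit <- if (length(audit)) do.call(rbind, audit) else
    data.frame(bio_sample = character(0), mz = numeric(0),
               reason = character(0))
  list(lists = lists, audit = audit)
}

#' Run the master-peak-list stage end to end
#'
#' Streams the synthetic study through mean-spectrum summarization, peak
#' picking, replicate merging, CV and log2FC gates, matrix/isotope/quality
#' filters and cross-sample assembly.
#'
#' @param cfg a [generator_config()]
#' @param fcfg a [filter_config()]
#' @param params a [picking_params()]
#' @param exclude section ids to drop
#' @return list with `master` (the master peak list), `per_sample`,
#'   `filtered`, `summaries`, `pixel_data` (at the pooled candidate masses),
#'   `truth`, `audit`
#' @export
run_masterlist <- function(cfg = generator_config(), fcfg = filter_config(),
                           params = picking_params(),
                           exclude = character(0)) {
  truth <- study_truth(cfg)
  summaries <- summarize_sections(cfg, truth, exclude = exclude)
  per_sample <- per_sample_candidates(summaries, fcfg, params)

  pooled <- do.call(rbind, lapply(per_sample, function(df) {
    if (!nrow(df)) return(NULL)
    data.frame(mz = df$mz, intensity = df$mean_intensity)
  }))
  cand_clusters <- merge_by_ppm(list(pooled), fcfg$ppm_window)
  cand_mz <- vapply(cand_clusters, `[[`, numeric(1), "rep_mz")

  pixel_data <- collect_pixel_data(cfg, truth, cand_mz, exclude = exclude)
  filtered <- apply_sample_filters(per_sample, pixel_data, fcfg)
  master <- build_master_list(filtered$lists, fcfg)
  list(master = master, per_sample = per_sample, filtered = filtered$lists,
       summaries = summaries, pixel_data = pixel_data, truth = truth,
       audit = filtered$audit)
}

#' Section-level intensities of master masses from mean spectra
#'
#' @param summaries output of [summarize_sections()]
#' @param master_mz master-list m/z values
#' @param spectrum which stored mean spectrum to use (`"tissue"`, `"tumor"`
#'   or `"necrosis"`)
#' @return masses x sections matrix with section ids as column names
#' @export
section_mass_matrix <- function(summaries, master_mz,
                                spectrum = c("tissue", "tumor", "necrosis")) {
  spectrum <- match.arg(spectrum)
  m <- vapply(summaries, function(s) {
    spectrum_mass_intensity(s[[spectrum]], master_mz)
  }, numeric(length(master_mz)))
  matrix(m, nrow = length(master_mz),
         dimnames = list(sprintf("%.4f", master_mz), names(summaries)))
}

#' Whole-dataset CV report for a pipeline run
#'
#' @param summaries output of [summarize_sections()]
#' @param master_mz master-list m/z values
#' @return a `cv_report`, see [whole_dataset_cv()]
#' @export
run_whole_dataset_cv <- function(summaries, master_mz) {
  mat <- section_mass_matrix(summaries, master_mz, "tissue")
  days <- vapply(summaries, function(s) s$meta$day, numeric(1))
  whole_dataset_cv(mat, days, mz = master_mz)
}

#' Intraday / interday CV from dedicated replicate sets
#'
#' Simulates three technical-replicate sections of one biological sample
#' measured either on the same day (`mode = "intraday"`) or on three
#' different days (`mode = "interday"`) and reports the per-mass CV of the
#' whole-tissue mean intensities.
#'
#' @param cfg a [generator_config()]
#' @param master_mz master-list m/z values
#' @param bio_idx biological sample index used for the replicate sections
#' @param mode `"intraday"` or `"interday"`
#' @return a `cv_report`
#' @export
run_replicate_cv <- function(cfg, master_mz, bio_idx = 1,
                             mode = c("interday", "intraday")) {
  mode <- match.arg(mode)
  truth <- study_truth(cfg)
  days <- if (mode == "intraday") c(1L, 1L, 1L) else 1:3
  mat <- vapply(1:3, function(r) {
    ds <- tic_normalize(simulate_section(cfg, truth, bio_idx, r,
                                         day = days[r]))
    spectrum_mass_intensity(roi_mean_spectrum(ds, "on_tissue"), master_mz)
  }, numeric(length(master_mz)))
  mat <- matrix(mat, nrow = length(master_mz))
  if (mode == "intraday") intraday_cv(mat, mz = master_mz) else
    interday_cv(mat, mz = master_mz)
}

.match_mass_columns <- function(masses, targets, ppm_window = 220) {
  vapply(targets, function(mz) {
    j <- which.min(abs(masses - mz))
    if (abs(masses[j] - mz) / mz * 1e6 <= ppm_window) j else NA_integer_
  }, integer(1))
}

#' Tumor-vs-necrosis iterative LMM stage
#'
#' Runs [iterative_lmm()] separately per technical replicate at the master
#' masses and combines the replicates with [call_significant()].
#'
#' @param pixel_data output of [collect_pixel_data()]
#' @param master_mz master-list m/z values
#' @param cfg an [lmm_config()]
#' @return list with `results_by_rep` and `calls`
#' @export
run_region_stats <- function(pixel_data, master_mz, cfg = lmm_config()) {
  cols <- .match_mass_columns(pixel_data$masses, master_mz)
  stopifnot(!anyNA(cols))
  reps <- sort(unique(pixel_data$tech_rep))
  results <- lapply(reps, function(r) {
    rows <- pixel_data$tech_rep == r
    rep_cfg <- cfg
    rep_cfg$seed <- derive_seed(cfg$seed, 10L, r)
    iterative_lmm(pixel_data$intensity[rows, cols, drop = FALSE],
                  pixel_data$roi[rows], pixel_data$bio_sample[rows],
                  pixel_data$section_id[rows], rep_cfg, masses = master_mz)
  })
  names(results) <- paste0("rep", reps)
  list(results_by_rep = results, calls = call_significant(results, cfg))
}

#' Treated-vs-control marker stage
#'
#' Wilcoxon rank-sum tests per technical replicate on section tumor
#' mean-spectrum intensities (treated vs control sections), pixel-level ROC
#' per (biological sample, technical replicate) against all opposite-arm
#' tumor pixels, PCA of the section tumor spectra, and the combined marker
#' call.
#'
#' @param summaries output of [summarize_sections()]
#' @param pixel_data output of [collect_pixel_data()]
#' @param master_mz master-list m/z values
#' @param cfg a [treatment_config()]
#' @return list with `markers` (per-mass calls), `wilcox_p`, `auc_table`,
#'   `pca`, `log2fc`
#' @export
run_treatment_stats <- function(summaries, pixel_data, master_mz,
                                cfg = treatment_config()) {
  tumor_mat <- section_mass_matrix(summaries, master_mz, "tumor")
  arms <- vapply(summaries, function(s) s$meta$arm, character(1))
  reps <- vapply(summaries, function(s) s$meta$tech_rep, numeric(1))
  bios <- vapply(summaries, function(s) s$meta$bio_sample, character(1))
  rep_levels <- sort(unique(reps))
  n_mass <- length(master_mz)

  wilcox_p <- matrix(NA_real_, n_mass, length(rep_levels),
                     dimnames = list(NULL, paste0("rep", rep_levels)))
  for (k in seq_along(rep_levels)) {
    sel <- reps == rep_levels[k]
    tr <- tumor_mat[, sel & arms == "treated", drop = FALSE]
    ct <- tumor_mat[, sel & arms == "control", drop = FALSE]
    if (ncol(tr) >= 3 && ncol(ct) >= 3) {
      wilcox_p[, k] <- vapply(seq_len(n_mass), function(i) {
        wilcoxon_rank_sum(tr[i, ], ct[i, ])
      }, numeric(1))
    }
  }

  log2fc <- vapply(seq_len(n_mass), function(i) {
    log2(mean(tumor_mat[i, arms == "control"]) /
           mean(tumor_mat[i, arms == "treated"]))
  }, numeric(1))

  cols <- .match_mass_columns(pixel_data$masses, master_mz)
  stopifnot(!anyNA(cols))
  tumor_rows <- pixel_data$roi == "tumor"
  auc_rows <- list()
  for (k in rep_levels) {
    in_rep <- tumor_rows & pixel_data$tech_rep == k
    for (b in unique(pixel_data$bio_sample)) {
      own <- in_rep & pixel_data$bio_sample == b
      if (!any(own)) next
      arm_b <- pixel_data$arm[own][1]
      opp <- in_rep & pixel_data$arm != arm_b
      if (!any(opp)) next
      for (i in seq_len(n_mass)) {
        auc <- pixel_roc_auc(pixel_data$intensity[own, cols[i]],
                             pixel_data$intensity[opp, cols[i]],
                             subset_n = cfg$roc_subset_n,
                             seed = derive_seed(cfg$seed, 20L, k, i))
        auc_rows[[length(auc_rows) + 1]] <- data.frame(
          mass_idx = i, bio_sample = b, arm = arm_b, tech_rep = k,
          auc = as.numeric(auc))
      }
    }
  }
  auc_table <- do.call(rbind, auc_rows)

  pca <- pca_scores(t(tumor_mat))
  markers <- call_treatment_markers(wilcox_p, auc_table, log2fc, cfg,
                                    mz = master_mz)
  list(markers = markers, wilcox_p = wilcox_p, auc_table = auc_table,
       pca = pca, log2fc = log2fc)
}

#' Run the complete analysis pipeline on a synthetic study
#'
#' Master list, whole-dataset/intraday/interday CV reports, tumor-vs-necrosis
#' iterative LMM calls, treatment markers and lipid annotation, end to end.
#'
#' @param cfg a [generator_config()]
#' @param fcfg a [filter_config()]
#' @param params a [picking_params()]
#' @param lmm_cfg an [lmm_config()]
#' @param treat_cfg a [treatment_config()]
#' @param exclude section ids to drop
#' @param annotate annotate the master list against the bundled lipid table
#' @return list with `master`, `cv` (list of three `cv_report`s), `region`,
#'   `treatment`, `truth`, `audit`, `summaries`, `pixel_data`
#' @export
run_pipeline <- function(cfg = generator_config(), fcfg = filter_config(),
                         params = picking_params(), lmm_cfg = lmm_config(),
                         treat_cfg = treatment_config(),
                         exclude = character(0), annotate = TRUE) {
  ml <- run_masterlist(cfg, fcfg, params, exclude = exclude)
  master <- ml$master
  if (annotate && nrow(master)) master <- annotate_master_list(master)
  cv_reports <- list(
    whole_dataset = run_whole_dataset_cv(ml$summaries, master$mz),
    interday = run_replicate_cv(cfg, master$mz, mode = "interday"),
    intraday = run_replicate_cv(cfg, master$mz, mode = "intraday"))
  region <- run_region_stats(ml$pixel_data, master$mz, lmm_cfg)
  treatment <- run_treatment_stats(ml$summaries, ml$pixel_data, master$mz,
                                   treat_cfg)
  list(master = master, cv = cv_reports, region = region,
       treatment = treatment, truth = ml$truth, audit = ml$audit,
       summaries = ml$summaries, pixel_data = ml$pixel_data)
}
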