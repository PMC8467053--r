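#' Iterative LMM configuration
#'
#' Study defaults: 1% of single spectra drawn per iteration, 100 iterations,
#' significance at `abs(log2FC) > 0.5` and `p < 0.05` in at least two
#' technical replicates.
#'
#' @param fraction fraction of pixels drawn per iteration, `0 < fraction <= 1`
#' @param iterations number of subsampling iterations
#' @param lfc_min absolute log2FC threshold (strict `>`)
#' @param p_max adjusted p-value threshold (strict `<`)
#' @param min_sig_tech_reps technical replicates that must qualify
#' @param seed master seed for reproducible subsampling
#' @return list of class `lmm_config`
#' @export
lmm_config <- function(fraction = 0.01, iterations = 100, lfc_min = 0.5,
                       p_max = 0.05, min_sig_tech_reps = 2, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1, iterations >= 1)
  structure(as.list(environment()), class = "lmm_config")
}

#' Treatment-marker configuration
#'
#' Study defaults: Wilcoxon p < 0.05 in at least two of three technical
#' replicates; ROC AUC >= 0.7 in at least two of three technical replicates of
#' a biological sample and in at least three of four biological samples of an
#' arm; ROC computed on equally sized subsets of up to 15,000 tumor spectra
#' per arm.
#'
#' @param wilcoxon_p_max Wilcoxon p threshold (strict `<`)
#' @param wilcoxon_min_tech_reps tech reps required below `wilcoxon_p_max`
#' @param auc_min AUC threshold (inclusive `>=`)
#' @param auc_min_tech_reps tech reps per biological sample required at
#'   `auc_min` (out of 3; scaled down proportionally when reps are missing)
#' @param auc_min_bio_reps biological samples per arm required (out of 4;
#'   scaled down proportionally when samples are missing)
#' @param roc_subset_n pixels per arm for the ROC subsets
#' @param seed seed for the ROC subsampling
#' @return list of class `treatment_config`
#' @export
treatment_config <- function(wilcoxon_p_max = 0.05, wilcoxon_min_tech_reps = 2,
                             auc_min = 0.7, auc_min_tech_reps = 2,
                             auc_min_bio_reps = 3, roc_subset_n = 15000,
                             seed = 1L) {
  structure(as.list(environment()), class = "treatment_config")
}

#' Counter-based derived seed
#'
#' Fans a master seed out to independent per-(stage, replicate, iteration)
#' seeds so results are reproducible and independent of execution order.
#' Stays below 2^31.
#'
#' @param seed master seed (integer)
#' @param ... integer counters (stage index, replicate, iteration, ...)
#' @return integer seed in `[1, 2^31 - 2]`
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  v <- as.numeric(seed) %% 2147483647
  for (k in seq_along(idx)) {
    v <- (v * 48271 + as.numeric(idx[k]) * 16807 + k) %% 2147483647
  }
  as.integer(v) + 1L
}

#' Stratified pixel subsample
#'
#' Draws `max(1, round(fraction * n))` pixels uniformly without replacement
#' from every stratum (section x region), using the current RNG state.
#'
#' @param strata factor/character stratum label per pixel
#' @param fraction sampling fraction
#' @return integer vector of selected pixel indices (ascending)
#' @export
subsample_pixels <- function(strata, fraction) {
  stopifnot(fraction > 0, fraction <= 1, length(strata) > 0)
  idx <- split(seq_along(strata), strata, drop = TRUE)
  sort(unlist(lapply(idx, function(i) {
    n <- max(1L, round(fraction * length(i)))
    if (n >= length(i)) i else sample(i, n)
  }), use.names = FALSE))
}

#' Fit the region linear mixed model
#'
#' Fits `intensity = b0 + b1 * 1[tumor] + b_sample + eps` with a random
#' intercept per biological sample by REML (via nlme, as in the original
#' analysis) and returns the Wald p-value for the region effect. Singular or
#' failed fits, and designs with a single biological sample, fall back to
#' ordinary least squares with a flag.
#'
#' @param intensity numeric response vector
#' @param region factor/character with levels `necrosis` (reference) and
#'   `tumor` (both present)
#' @param bio_sample grouping factor
#' @return list with `beta` (tumor effect), `p`, `fallback` (logical)
#' @export
fit_lmm <- function(intensity, region, bio_sample) {
  region <- factor(as.character(region), levels = c("necrosis", "tumor"))
  stopifnot(nlevels(droplevels(region)) == 2)
  bio_sample <- factor(bio_sample)
  df <- data.frame(y = intensity, region = region, bio = bio_sample)
  if (nlevels(droplevels(bio_sample)) < 2) {
    fit <- stats::lm(y ~ region, data = df)
    s <- summary(fit)$coefficients
    return(list(beta = s["regiontumor", "Estimate"],
                p = s["regiontumor", "Pr(>|t|)"], fallback = TRUE))
  }
  res <- tryCatch({
    fit <- nlme::lme(y ~ region, random = ~ 1 | bio, data = df,
                     method = "REML",
                     control = nlme::lmeControl(returnObject = TRUE))
    tt <- summary(fit)$tTable
    list(beta = tt["regiontumor", "Value"],
         p = tt["regiontumor", "p-value"], fallback = FALSE)
  }, error = function(e) NULL)
  if (is.null(res)) {
    fit <- stats::lm(y ~ region, data = df)
    s <- summary(fit)$coefficients
    res <- list(beta = s["regiontumor", "Estimate"],
                p = s["regiontumor", "Pr(>|t|)"], fallback = TRUE)
  }
  res
}

#' Iterative subsampled LMM testing of tumor vs necrosis
#'
#' Per iteration, a stratified 1% pixel subsample is drawn; per mass, the
#' log2 fold change is `log2(mean tumor / mean necrosis)` over the drawn
#' pixels and the p-value comes from [fit_lmm()]; p-values are
#' Benjamini-Hochberg adjusted across masses within the iteration. Reported
#' values are means (and ranges) across iterations. Iterations where a region
#' mean is zero for a mass skip that mass's log2FC (counted in `n_skipped`).
#'
#' @param intensities pixels x masses matrix (TIC-normalized, untransformed)
#' @param region per-pixel region label (`tumor` / `necrosis` rows only are
#'   used)
#' @param bio_sample per-pixel biological sample id
#' @param section_id per-pixel section id (stratification unit together with
#'   region)
#' @param cfg an [lmm_config()]
#' @param masses optional m/z values for the output (defaults to column
#'   names)
#' @return data.frame per mass: `mz`, `mean_log2fc`, `log2fc_min`,
#'   `log2fc_max`, `mean_adj_p`, `p_min`, `p_max`, `n_skipped`, `n_fallback`
#' @export
iterative_lmm <- function(intensities, region, bio_sample, section_id,
                          cfg = lmm_config(), masses = NULL) {
  sel <- region %in% c("tumor", "necrosis")
  intensities <- intensities[sel, , drop = FALSE]
  region <- as.character(region[sel])
  bio_sample <- as.character(bio_sample[sel])
  section_id <- as.character(section_id[sel])
  both <- intersect(unique(bio_sample[region == "tumor"]),
                    unique(bio_sample[region == "necrosis"]))
  stopifnot("need tumor and necrosis pixels in >= 2 biological samples" =
              length(both) >= 2)
  n_mass <- ncol(intensities)
  if (is.null(masses)) {
    masses <- if (!is.null(colnames(intensities))) {
      as.numeric(colnames(intensities))
    } else {
      seq_len(n_mass)
    }
  }
  strata <- paste(section_id, region)
  lfc <- p_adj <- matrix(NA_real_, cfg$iterations, n_mass)
  n_fallback <- 0L
  for (it in seq_len(cfg$iterations)) {
    set.seed(derive_seed(cfg$seed, 1L, it))
    idx <- subsample_pixels(strata, cfg$fraction)
    reg_i <- region[idx]
    bio_i <- bio_sample[idx]
    p_raw <- numeric(n_mass)
    for (j in seq_len(n_mass)) {
      y <- intensities[idx, j]
      mt <- mean(y[reg_i == "tumor"])
      mn <- mean(y[reg_i == "necrosis"])
      if (mt > 0 && mn > 0) lfc[it, j] <- log2(mt / mn)
      fit <- fit_lmm(y, reg_i, bio_i)
      p_raw[j] <- fit$p
      if (fit$fallback) n_fallback <- n_fallback + 1L
    }
    p_adj[it, ] <- stats::p.adjust(p_raw, method = "BH")
  }
  data.frame(
    mz = masses,
    mean_log2fc = colMeans(lfc, na.rm = TRUE),
    log2fc_min = suppressWarnings(apply(lfc, 2, min, na.rm = TRUE)),
    log2fc_max = suppressWarnings(apply(lfc, 2, max, na.rm = TRUE)),
    mean_adj_p = colMeans(p_adj),
    p_min = apply(p_adj, 2, min),
    p_max = apply(p_adj, 2, max),
    n_skipped = as.integer(colSums(is.na(lfc))),
    n_fallback = rep(n_fallback, n_mass))
}

#' Call region-significant masses across technical replicates
#'
#' A mass is significant when `abs(mean_log2fc) > lfc_min` and
#' `mean_adj_p < p_max` in at least `min_sig_tech_reps` technical replicates
#' with a consistent fold-change sign; qualifying replicates with conflicting
#' signs leave the mass uncalled and flagged.
#'
#' @param results_by_rep named list of [iterative_lmm()] outputs, one per
#'   technical replicate, sharing the same `mz` order
#' @param cfg an [lmm_config()]
#' @return data.frame per mass: `mz`, `n_sig_reps`, `significant`,
#'   `direction` (`tumor_up` / `necrosis_up` / `none`), `sign_conflict`,
#'   `mean_log2fc` (across replicates)
#' @export
call_significant <- function(results_by_rep, cfg = lmm_config()) {
  stopifnot(length(results_by_rep) >= 2)
  mz <- results_by_rep[[1]]$mz
  for (r in results_by_rep) stopifnot(identical(r$mz, mz))
  lfc <- vapply(results_by_rep, function(r) r$mean_log2fc, numeric(length(mz)))
  p <- vapply(results_by_rep, function(r) r$mean_adj_p, numeric(length(mz)))
  lfc <- matrix(lfc, nrow = length(mz))
  p <- matrix(p, nrow = length(mz))
  qual <- abs(lfc) > cfg$lfc_min & p < cfg$p_max & !is.na(lfc) & !is.na(p)
  out <- data.frame(mz = mz, n_sig_reps = rowSums(qual),
                    significant = FALSE, direction = "none",
                    sign_conflict = FALSE,
                    mean_log2fc = rowMeans(lfc, na.rm = TRUE))
  for (i in seq_along(mz)) {
    q <- which(qual[i, ])
    if (length(q) < cfg$min_sig_tech_reps) next
    signs <- sign(lfc[i, q])
    if (length(unique(signs)) > 1) {
      out$sign_conflict[i] <- TRUE
      next
    }
    out$significant[i] <- TRUE
    out$direction[i] <- if (signs[1] > 0) "tumor_up" else "necrosis_up"
  }
  out
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact for up to 10 observations per group without ties; otherwise the
#' normal approximation with tie correction. Completely tied data yield p = 1.
#'
#' @param group_a,group_b numeric vectors (each of length >= 3)
#' @return two-sided p-value
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 3, length(group_b) >= 3)
  if (stats::var(c(group_a, group_b)) == 0) return(1)
  exact <- length(group_a) <= 10 && length(group_b) <= 10 &&
    !any(duplicated(c(group_a, group_b)))
  suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = !exact,
                       alternative = "two.sided")$p.value)
}

#' Pixel-level ROC AUC between treatment arms
#'
#' Rank-statistic AUC (ties one half) with treated as the positive class, on
#' equally sized random subsets of up to `subset_n` pixels per arm. Groups
#' smaller than `subset_n` are used whole (flagged in the `subset_used`
#' attribute).
#'
#' @param treated,control numeric intensity vectors (non-empty)
#' @param subset_n subset size per arm
#' @param seed seed for the subsampling
#' @return AUC; attributes `subset_used` (actual subset size) and `truncated`
#' @export
pixel_roc_auc <- function(treated, control, subset_n = 15000, seed = 1L) {
  stopifnot(length(treated) > 0, length(control) > 0)
  n <- as.integer(min(subset_n, length(treated), length(control)))
  set.seed(derive_seed(seed, 2L, length(treated), length(control)))
  t_sub <- if (length(treated) > n) sample(treated, n) else treated
  c_sub <- if (length(control) > n) sample(control, n) else control
  auc <- rank_auc(t_sub, c_sub)
  attr(auc, "subset_used") <- n
  attr(auc, "truncated") <- n < subset_n
  auc
}

#' Call treatment markers from Wilcoxon and ROC results
#'
#' Wilcoxon criterion: p below `wilcoxon_p_max` in at least
#' `wilcoxon_min_tech_reps` of the available technical replicates. AUC
#' criterion: per biological sample (its tumor pixels scored against all
#' opposite-arm tumor pixels, with its own arm as positive class), AUC at or
#' above `auc_min` in at least 2 of 3 of its available technical replicates,
#' satisfied by at least 3 of 4 biological samples of one arm; denominators
#' scale down proportionally when sections are missing. A mass is a marker
#' when either criterion holds; direction comes from the sign of the
#' control-vs-treated log2FC.
#'
#' @param wilcox_p masses x tech-reps matrix of Wilcoxon p-values (NA =
#'   replicate unavailable)
#' @param auc_table data.frame with columns `mass_idx`, `bio_sample`, `arm`,
#'   `tech_rep`, `auc` (AUC computed with the sample's own arm as positive
#'   class)
#' @param log2fc_ctrl_vs_treated per-mass log2(mean control / mean treated)
#' @param cfg a [treatment_config()]
#' @param mz optional m/z values for the output
#' @return data.frame per mass: `mz`, `wilcoxon_pass`, `n_wilcoxon_reps`,
#'   `auc_pass`, `auc_arm`, `mean_auc`, `log2fc`, `marker`, `direction`
#' @export
call_treatment_markers <- function(wilcox_p, auc_table,
                                   log2fc_ctrl_vs_treated,
                                   cfg = treatment_config(), mz = NULL) {
  wilcox_p <- as.matrix(wilcox_p)
  n_mass <- nrow(wilcox_p)
  if (is.null(mz)) mz <- seq_len(n_mass)
  out <- data.frame(mz = mz, wilcoxon_pass = FALSE, n_wilcoxon_reps = 0L,
                    auc_pass = FALSE, auc_arm = "none",
                    mean_auc = NA_real_,
                    log2fc = log2fc_ctrl_vs_treated, marker = FALSE,
                    direction = "none", stringsAsFactors = FALSE)
  for (i in seq_len(n_mass)) {
    p <- wilcox_p[i, ]
    avail <- sum(!is.na(p))
    need <- ceiling(cfg$wilcoxon_min_tech_reps / 3 * avail)
    out$n_wilcoxon_reps[i] <- sum(p < cfg$wilcoxon_p_max, na.rm = TRUE)
    out$wilcoxon_pass[i] <- avail > 0 && out$n_wilcoxon_reps[i] >= need

    at <- auc_table[auc_table$mass_idx == i, , drop = FALSE]
    for (arm in c("treated", "control")) {
      aa <- at[at$arm == arm, , drop = FALSE]
      if (!nrow(aa)) next
      samples <- unique(aa$bio_sample)
      pass_s <- vapply(samples, function(s) {
        a <- aa$auc[aa$bio_sample == s]
        need_r <- ceiling(cfg$auc_min_tech_reps / 3 * length(a))
        sum(a >= cfg$auc_min) >= need_r
      }, logical(1))
      need_b <- ceiling(cfg$auc_min_bio_reps / 4 * length(samples))
      if (sum(pass_s) >= need_b) {
        out$auc_pass[i] <- TRUE
        out$auc_arm[i] <- arm
        qual <- aa$auc[aa$bio_sample %in% samples[pass_s] &
                       aa$auc >= cfg$auc_min]
        out$mean_auc[i] <- mean(qual)
        break
      }
    }
    out$marker[i] <- out$wilcoxon_pass[i] || out$auc_pass[i]
    if (out$marker[i] && !is.na(out$log2fc[i]) && out$log2fc[i] != 0) {
      out$direction[i] <- if (out$log2fc[i] < 0) "treated_up" else
        "control_up"
    }
  }
  out
}

#' Principal component analysis of section mean spectra
#'
#' Columns (masses) are mean-centered; principal axes come from the singular
#' value decomposition; each component's sign is fixed so its
#' largest-magnitude loading is positive. Constant columns are dropped with a
#' warning.
#'
#' @param X sections x masses matrix
#' @return list with `scores` (sections x PCs), `loadings` (masses x PCs),
#'   `explained_variance` (fractions), `dropped` (constant columns)
#' @export
pca_scores <- function(X) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 3)
  const <- apply(X, 2, function(v) stats::var(v) == 0)
  if (any(const)) {
    warning(sum(const), " constant column(s) dropped before PCA")
    X <- X[, !const, drop = FALSE]
  }
  fit <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  flip <- apply(fit$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(fit$x, 2, flip, `*`)
  loadings <- sweep(fit$rotation, 2, flip, `*`)
  list(scores = scores, loadings = loadings,
       explained_variance = fit$sdev^2 / sum(fit$sdev^2),
       dropped = which(const))
}
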