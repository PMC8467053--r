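test_that("stratified subsampling rounds per stratum and is reproducible", {
  strata <- rep(c("s1 tumor", "s1 necrosis"), c(400, 250))
  set.seed(derive_seed(5, 1L, 1L))
  idx <- subsample_pixels(strata, 0.01)
  expect_identical(sum(strata[idx] == "s1 tumor"), 4L)    # round(4.0)
  expect_identical(sum(strata[idx] == "s1 necrosis"), 2L) # round(2.5) -> 2
  set.seed(derive_seed(5, 1L, 1L))
  expect_identical(subsample_pixels(strata, 0.01), idx)
  # a stratum never loses its last pixel
  set.seed(1)
  expect_length(subsample_pixels(rep("a", 10), 0.01), 1L)
})

test_that("repeated draws hit every pixel at close to the nominal fraction", {
  n <- 500; fraction <- 0.1; draws <- 200
  counts <- integer(n)
  for (it in seq_len(draws)) {
    set.seed(derive_seed(2, 1L, it))
    idx <- subsample_pixels(rep("s", n), fraction)
    counts[idx] <- counts[idx] + 1L
  }
  freq <- counts / draws
  se <- sqrt(fraction * (1 - fraction) / draws)
  # individually ~99.7% of pixels sit within 3 SE; none stray past 4.5 SE
  expect_gt(mean(abs(freq - fraction) <= 3 * se), 0.98)
  expect_true(all(abs(freq - fraction) <= 4.5 * se))
  expect_equal(mean(freq), fraction)  # exact: 50 of 500 drawn each time
})

test_that("the LMM recovers the region effect and falls back gracefully", {
  set.seed(8)
  bio <- rep(paste0("b", 1:8), each = 20)
  region <- rep(rep(c("necrosis", "tumor"), each = 10), 8)
  b_i <- rep(rnorm(8, 0, 0.5), each = 20)
  y <- 10 + 2 * (region == "tumor") + b_i + rnorm(160)
  fit <- fit_lmm(y, region, bio)
  expect_false(fit$fallback)
  expect_lt(abs(fit$beta - 2), 0.5)
  expect_lt(fit$p, 1e-6)

  one <- fit_lmm(y[1:20], region[1:20], bio[1:20])
  expect_true(one$fallback)
})

test_that("the LMM has power > 0.9 for a 2-sigma shift at n = 50 per group", {
  reject <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    bio <- rep(paste0("b", 1:5), each = 20)
    region <- rep(rep(c("necrosis", "tumor"), each = 10), 5)
    y <- 2 * (region == "tumor") + rep(rnorm(5, 0, 0.3), each = 20) +
      rnorm(100)
    fit_lmm(y, region, bio)$p < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.9)
})

test_that("iterative LMM at fraction 1, single iteration equals one full fit", {
  # noiseless construction: tumor exactly 2x necrosis per pixel
  bio <- rep(paste0("b", 1:3), each = 8)
  region <- rep(rep(c("tumor", "necrosis"), each = 4), 3)
  section <- bio
  base <- rep(c(10, 12, 14), each = 8)
  intens <- cbind(m1 = base * ifelse(region == "tumor", 2, 1))
  cfg <- lmm_config(fraction = 1, iterations = 1, seed = 3)
  res <- iterative_lmm(intens, region, bio, section, cfg, masses = 700)
  expect_equal(res$mean_log2fc, 1)           # exactly log2(2)
  expect_equal(res$log2fc_min, res$log2fc_max)
  direct <- fit_lmm(intens[, 1], region, bio)
  expect_equal(res$mean_adj_p, direct$p)     # one mass: BH is identity
  expect_identical(res$n_skipped, 0L)
})

test_that("BH adjustment matches the closed-form step-up procedure", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    stepped <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(stepped)))
    pmin(adj, 1)[order(o)]
  }
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.5), "BH"),
               bh_oracle(c(0.01, 0.02, 0.03, 0.5)))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.5), "BH"),
               c(0.04, 0.04, 0.04, 0.5))
  for (seed in 1:5) {
    set.seed(seed)
    p <- runif(sample(3:30, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p))
  }
})

test_that("significance calls require effect, p, replication and sign agreement", {
  mk <- function(lfc, p) data.frame(mz = c(790.6, 639.5, 700.0, 710.0),
                                    mean_log2fc = lfc, mean_adj_p = p)
  # reported means: 790.6 (1.01, 0.011) up; 639.5 (-0.61, 0.018) down;
  # 700 fails the effect gate; 710 significant in one replicate only
  reps <- list(
    rep1 = mk(c(1.01, -0.61, 0.40, 0.90), c(0.011, 0.018, 0.001, 0.01)),
    rep2 = mk(c(1.01, -0.61, 0.40, 0.90), c(0.011, 0.018, 0.001, 0.50)),
    rep3 = mk(c(1.01, -0.61, 0.40, 0.10), c(0.011, 0.018, 0.001, 0.90)))
  calls <- call_significant(reps, lmm_config())
  expect_identical(calls$significant, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(calls$direction[1:2], c("tumor_up", "necrosis_up"))

  # conflicting signs across qualifying replicates block the call
  conflict <- list(
    rep1 = data.frame(mz = 1, mean_log2fc = 1.0, mean_adj_p = 0.01),
    rep2 = data.frame(mz = 1, mean_log2fc = -1.0, mean_adj_p = 0.01))
  cc <- call_significant(conflict, lmm_config())
  expect_false(cc$significant)
  expect_true(cc$sign_conflict)
})

test_that("Wilcoxon rank-sum p-values match exact enumeration", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)  # 2/C(6,3)
  expect_equal(wilcoxon_rank_sum(1:4, 5:8), 2 / 70)
  expect_equal(wilcoxon_rank_sum(c(2, 2, 2), c(2, 2, 2)), 1)

  # oracle: enumerate all assignments of ranks to group A
  wilcox_oracle <- function(a, b) {
    r <- rank(c(a, b))
    w_obs <- sum(r[seq_along(a)])
    all_w <- apply(combn(length(a) + length(b), length(a)), 2,
                   function(ix) sum(r[ix]))
    mean(abs(all_w - mean(all_w)) >= abs(w_obs - mean(all_w)) - 1e-9)
  }
  for (seed in 1:6) {
    set.seed(seed)
    a <- sample(1000, 4)
    b <- sample(setdiff(1:1000, a), 5)  # tie-free across groups
    expect_equal(wilcoxon_rank_sum(a, b), wilcox_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("rank AUC equals the brute-force pairwise mean", {
  auc_oracle <- function(pos, neg) {
    mean(outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n)))
  }
  expect_equal(rank_auc(c(5, 6, 7), c(1, 2, 3)), 1)
  expect_equal(rank_auc(c(1, 2), c(1, 2)), 0.5)
  for (seed in 1:6) {
    set.seed(seed)
    pos <- sample(20, 60, replace = TRUE)  # heavy ties
    neg <- sample(20, 40, replace = TRUE)
    expect_equal(rank_auc(pos, neg), auc_oracle(pos, neg))
  }
})

test_that("pixel ROC AUC is invariant under strictly monotone transforms", {
  set.seed(12)
  tr <- rlnorm(300, 1, 0.5)
  ct <- rlnorm(300, 0.5, 0.5)
  a1 <- pixel_roc_auc(tr, ct, subset_n = 300)
  a2 <- pixel_roc_auc(log(tr), log(ct), subset_n = 300)
  a3 <- pixel_roc_auc(tr^3, ct^3, subset_n = 300)
  expect_equal(as.numeric(a1), as.numeric(a2))
  expect_equal(as.numeric(a1), as.numeric(a3))
  expect_false(attr(a1, "truncated"))

  a4 <- pixel_roc_auc(tr, ct, subset_n = 100, seed = 4)
  expect_identical(attr(a4, "subset_used"), 100L)
})

test_that("treatment marker calls follow both criteria with strict boundaries", {
  # mass 1 mirrors a reported marker (p = 0.01 twice, AUC 0.71);
  # mass 2: p = 0.06 everywhere and strong AUC (borderline Wilcoxon case);
  # mass 3: AUC 0.69 everywhere fails the >= 0.7 rule and p never qualifies
  wilcox_p <- rbind(c(0.01, 0.01, 0.20),
                    c(0.06, 0.06, 0.06),
                    c(0.30, 0.40, 0.50))
  auc_of <- function(mass, a) {
    expand.grid(bio_sample = paste0("T", 1:4), tech_rep = 1:3,
                stringsAsFactors = FALSE) |>
      transform(mass_idx = mass, arm = "treated", auc = a)
  }
  auc_table <- rbind(auc_of(1, 0.71), auc_of(2, 0.87), auc_of(3, 0.69))
  calls <- call_treatment_markers(wilcox_p, auc_table,
                                  log2fc_ctrl_vs_treated = c(-0.34, 1.11,
                                                             -0.2),
                                  cfg = treatment_config(),
                                  mz = c(768.6, 604.7, 700.0))
  expect_identical(calls$marker, c(TRUE, TRUE, FALSE))
  expect_identical(calls$wilcoxon_pass, c(TRUE, FALSE, FALSE))
  expect_identical(calls$auc_pass, c(TRUE, TRUE, FALSE))
  expect_identical(calls$direction[1:2], c("treated_up", "control_up"))
  expect_equal(calls$mean_auc[1], 0.71)
})

test_that("marker denominators adjust when a technical replicate is missing", {
  wilcox_p <- matrix(c(0.01, 0.01, NA), 1)  # 2 of 2 available reps qualify
  auc_table <- data.frame(mass_idx = 1,
                          bio_sample = rep(paste0("T", 1:4), each = 2),
                          arm = "treated", tech_rep = rep(1:2, 4),
                          auc = 0.75)
  calls <- call_treatment_markers(wilcox_p, auc_table, -0.5)
  expect_true(calls$wilcoxon_pass)
  expect_true(calls$auc_pass)
})

test_that("PCA explained variance and scores match the eigendecomposition", {
  set.seed(13)
  # two perfectly correlated variables -> PC1 explains everything
  v <- rnorm(10)
  p1 <- pca_scores(cbind(v, 2 * v))
  expect_equal(p1$explained_variance[1], 1)

  # orthogonal equal-variance variables -> an even split
  n <- 4000
  x <- rnorm(n); y <- rnorm(n)
  p2 <- pca_scores(cbind(x, y))
  expect_lt(abs(p2$explained_variance[1] - 0.5), 0.05)

  # oracle: eigendecomposition of the covariance matrix
  X <- matrix(rnorm(15 * 6), 15, 6)
  p3 <- pca_scores(X)
  ev <- eigen(cov(X))
  expect_equal(p3$explained_variance, ev$values / sum(ev$values))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  expect_equal(unname(as.matrix(dist(p3$scores))),
               unname(as.matrix(dist(Xc))))  # scores preserve distances

  expect_warning(p4 <- pca_scores(cbind(X, const = 5)), "constant")
  expect_identical(ncol(p4$loadings), 6L)
})
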