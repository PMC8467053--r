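test_that("ppm merging splits exactly at the window", {
  pl <- function(mz) data.frame(mz = mz, intensity = 1)
  # 0.150/700 * 1e6 = 214.3 ppm < 220 -> one cluster
  expect_length(merge_by_ppm(list(pl(700.000), pl(700.150)), 220), 1L)
  # 0.160/700 * 1e6 = 228.6 ppm > 220 -> two clusters
  expect_length(merge_by_ppm(list(pl(700.000), pl(700.160)), 220), 2L)
})

test_that("identical lists merge into one cluster per mass with one member per list", {
  df <- data.frame(mz = c(600.1, 700.2, 800.3), intensity = c(1, 2, 3))
  cl <- merge_by_ppm(list(a = df, b = df, c = df), 220)
  expect_length(cl, 3L)
  for (c_ in cl) {
    expect_identical(sort(as.character(c_$members$replicate_id)),
                     c("a", "b", "c"))
  }
})

test_that("cluster representatives are intensity-weighted and bounded", {
  cl <- merge_by_ppm(list(data.frame(mz = c(700.00, 700.10),
                                     intensity = c(1, 3))), 220)[[1]]
  expect_equal(cl$rep_mz, (700.00 * 1 + 700.10 * 3) / 4)
  expect_gte(cl$rep_mz, 700.00)
  expect_lte(cl$rep_mz, 700.10)
  expect_equal(cl$span_ppm, 0.1 / 700 * 1e6)
})

test_that("gap clustering equals brute-force transitive closure", {
  closure_partition <- function(mz, ppm) {
    # oracle: union-find over all pairwise within-window relations
    parent <- seq_along(mz)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_along(mz)) for (j in seq_along(mz)) {
      if (abs(mz[i] - mz[j]) / min(mz[i], mz[j]) * 1e6 <= ppm) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <<- rj
      }
    }
    parent <- vapply(seq_along(mz), find, integer(1))
    split(mz, parent)
  }
  for (seed in 1:8) {
    set.seed(seed)
    mz <- sort(runif(sample(5:50, 1), 500, 1300))
    got <- merge_by_ppm(list(data.frame(mz = mz, intensity = 1)), 220)
    got_sets <- lapply(got, function(cl) sort(cl$members$mz))
    want <- closure_partition(mz, 220)
    want_sets <- unname(lapply(want, sort))
    expect_setequal(lapply(got_sets, paste, collapse = "|"),
                    lapply(want_sets, paste, collapse = "|"))
  }
})

test_that("coefficient of variation matches hand computations", {
  expect_equal(cv(c(2, 2, 2)), 0)
  expect_equal(cv(c(1, 2, 3)), 50)          # sd = 1, mean = 2
  expect_equal(cv(c(10, 30)), 70.71068, tolerance = 1e-6)
  expect_warning(res <- cv(c(-1, 1)), "zero mean")
  expect_true(is.na(res))
  expect_error(cv(5))
})

test_that("masses must appear in every technical replicate to be common", {
  lists <- list(
    "1" = data.frame(mz = c(700.00, 750.00, 800.00), intensity = c(5, 2, 9)),
    "2" = data.frame(mz = c(700.01, 800.01), intensity = c(6, 8)),
    "3" = data.frame(mz = c(700.02, 760.00, 800.02), intensity = c(7, 1, 10)))
  common <- common_across_tech_reps(merge_by_ppm(lists, 220))
  expect_identical(nrow(common), 2L)  # 750 in {1}, 760 in {3} dropped
  expect_equal(common$I_1, c(5, 9))
  expect_equal(common$I_3, c(7, 10))
})

test_that("planted common masses survive replicate intersection exactly", {
  set.seed(9)
  common_mz <- sort(runif(5, 600, 1200))
  lists <- lapply(1:3, function(r) {
    extra <- runif(1, 600, 1200)  # one replicate-specific mass each
    df <- data.frame(mz = sort(c(common_mz * (1 + rnorm(5, 0, 2e-5)), extra)),
                     intensity = runif(6, 1, 10))
    df
  })
  names(lists) <- 1:3
  common <- common_across_tech_reps(merge_by_ppm(lists, 220))
  expect_identical(nrow(common), 5L)
})

test_that("the CV gate is strict at its boundary", {
  peaks <- rep_intensity_df(c(700, 710, 720),
                            c(1, 1, 0.55), c(1, 2, 1.00), c(1, 3, 1.45))
  # rows: cv 0 (kept), cv 50 (dropped at threshold 45)
  kept <- cv_gate(peaks, 45)
  expect_false(710 %in% kept$mz)
  expect_true(700 %in% kept$mz)
  # strict <: a peak whose CV equals the threshold exactly is dropped
  boundary <- cv(c(0.55, 1, 1.45))
  expect_equal(boundary, 45)
  kept_at <- cv_gate(peaks, boundary)
  expect_identical(kept_at$mz, 700)
  expect_equal(kept_at$cv, 0)
})

test_that("log2FC consistency gate keeps consistent ratios and excludes zeros", {
  tumor <- rep_intensity_df(c(700, 710, 720),
                            c(2, 2, 2), c(4, 4, 2), c(2, 6, 2))
  necrosis <- rep_intensity_df(c(700.001, 710.001, 720.001),
                               c(1, 2, 1), c(2, 2, 0), c(1, 2, 1))
  # 700: fc = (1,1,1): cv 0 -> kept; 710: fc = (0,1,1.585): cv ~93 -> dropped
  # 720: zero necrosis in rep 2 -> excluded
  out <- log2fc_consistency_gate(tumor, necrosis, max_cv = 60)
  expect_identical(nrow(out), 1L)
  expect_equal(out$mz, 700, tolerance = 1e-5)
  expect_equal(unlist(out[paste0("fc_", 1:3)]), c(1, 1, 1),
               ignore_attr = TRUE)
  expect_identical(attr(out, "n_excluded_zero"), 1L)

  # fc per rep (0.5, 1.0, 1.5): cv 50 < 60 -> kept
  t2 <- rep_intensity_df(700, 2 ^ 0.5, 2, 2 ^ 1.5)
  n2 <- rep_intensity_df(700.001, 1, 1, 1)
  expect_identical(nrow(log2fc_consistency_gate(t2, n2, 60)), 1L)
  expect_identical(nrow(log2fc_consistency_gate(t2, n2, 45)), 0L)
})

test_that("matrix-peak filter removes off-tissue-elevated masses only", {
  set.seed(5)
  n_on <- 60; n_off <- 40
  roi <- c(rep("tumor", 30), rep("necrosis", 30), rep("off_tissue", 40))
  matrix_peak <- c(rlnorm(n_on, log(2), 0.3), rlnorm(n_off, log(20), 0.3))
  tissue_peak <- c(rlnorm(n_on, log(20), 0.3), rlnorm(n_off, log(2), 0.3))
  flat_peak <- rep(1, 100)
  tab <- cbind(matrix_peak, tissue_peak, flat_peak)
  res <- matrix_peak_filter(tab, roi, 0.9)
  expect_identical(res$removed, 1L)
  expect_setequal(res$kept, c(2L, 3L))
  expect_gt(res$audit$auc[1], 0.99)
  expect_lt(res$audit$auc[2], 0.01)
  expect_equal(res$audit$auc[3], 0.5)  # ties counted one half

  expect_warning(res2 <- matrix_peak_filter(tab, rep("tumor", 100), 0.9),
                 "skipped")
  expect_length(res2$removed, 0L)
})

test_that("isotope filter drops +1 satellites but keeps overlaps", {
  peaks <- data.frame(mz = c(740.52, 741.523), intensity = c(10, 4))
  out <- isotope_filter(peaks)
  expect_equal(out$mz, 740.52)
  expect_equal(attr(out, "removed")$mz, 741.523)

  overlap <- data.frame(mz = c(740.52, 741.523), intensity = c(4, 10))
  expect_identical(nrow(isotope_filter(overlap)), 2L)

  lone <- data.frame(mz = 812.54, intensity = 3)
  expect_identical(nrow(isotope_filter(lone)), 1L)

  # a removed isotope cannot shield a higher isotope: retained set semantics
  chain <- data.frame(mz = c(740.52, 741.523, 742.527),
                      intensity = c(10, 4, 5))
  out <- isotope_filter(chain)
  expect_equal(out$mz, c(740.52, 742.527))
})

test_that("gates are pure filters and idempotent", {
  peaks <- rep_intensity_df(c(700, 710, 720, 730),
                            c(1, 1, 5, 2), c(1, 2, 5, 2), c(1, 3, 9, 2))
  once <- cv_gate(peaks, 45)
  twice <- cv_gate(once, 45)
  expect_true(all(once$mz %in% peaks$mz))
  expect_identical(once$mz, twice$mz)

  iso_in <- data.frame(mz = c(700, 701.003, 705), intensity = c(9, 3, 1))
  once <- isotope_filter(iso_in)
  expect_identical(isotope_filter(once)$mz, once$mz)
})

test_that("master list needs two biological replicates and mean intensity > 1", {
  mk <- function(mz, int) data.frame(mz = mz, mean_intensity = int)
  lists <- list(
    A = mk(c(700, 710, 720), c(5, 5, 0.9)),
    B = mk(c(700.001, 720.001), c(7, 0.9)),
    C = mk(730, 5))
  master <- build_master_list(lists, filter_config())
  # 700 in A+B kept; 710 single-sample dropped; 720 mean 0.9 dropped;
  # 730 single-sample dropped
  expect_identical(nrow(master), 1L)
  expect_equal(master$mz, 700.0005, tolerance = 1e-6)
  expect_identical(master$n_bio, 2L)
  expect_identical(master$bio_samples, "A,B")
})

test_that("planted reproducible masses are recovered exactly from 8 samples", {
  set.seed(21)
  repro <- sort(runif(20, 600, 1200))
  singles <- sort(runif(10, 600, 1200))
  lists <- lapply(1:8, function(b) {
    mz <- repro * (1 + rnorm(20, 0, 2e-5))
    if (b <= 10) mz <- c(mz, singles[min(b, 10)])
    data.frame(mz = sort(mz), mean_intensity = runif(length(mz), 2, 9))
  })
  names(lists) <- paste0("S", 1:8)
  master <- build_master_list(lists, filter_config())
  expect_identical(nrow(master), 20L)
})

test_that("master list is invariant under permutation of input samples", {
  set.seed(22)
  mz <- sort(runif(6, 600, 1200))
  lists <- lapply(1:4, function(b) {
    data.frame(mz = mz * (1 + rnorm(6, 0, 1e-5)),
               mean_intensity = runif(6, 2, 9))
  })
  names(lists) <- c("S1", "S2", "S3", "S4")
  m1 <- build_master_list(lists, filter_config())
  m2 <- build_master_list(rev(lists), filter_config())
  expect_equal(m1, m2)
})
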