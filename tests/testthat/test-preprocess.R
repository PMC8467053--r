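test_that("TIC normalization equalizes totals and conserves overall signal", {
  ds <- tiny_dataset(rbind(c(4, 3, 2, 1, 0), c(10, 8, 6, 4, 2)))
  out <- tic_normalize(ds)
  expect_equal(rowSums(out$intensity), c(20, 20))  # mean TIC of 10 and 30
  expect_equal(sum(out$intensity), sum(ds$intensity))

  uniform <- tiny_dataset(rbind(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(tic_normalize(uniform)$intensity, uniform$intensity)
})

test_that("zero-TIC pixels stay zero and are flagged", {
  ds <- tiny_dataset(rbind(c(1, 2, 3), c(0, 0, 0), c(3, 2, 1)))
  out <- tic_normalize(ds)
  expect_equal(out$intensity[2, ], c(0, 0, 0))
  expect_identical(attr(out, "n_zero_tic"), 1L)
  expect_error(tic_normalize(tiny_dataset(matrix(0, 2, 3))), "all-zero")
})

test_that("ROI mean spectra are per-label arithmetic means", {
  roi <- c("tumor", "necrosis", "tumor", "necrosis")
  ds <- tiny_dataset(rbind(c(2, 2, 2), c(9, 9, 9), c(4, 4, 4), c(7, 7, 7)),
                     roi = roi, meta = list(section_id = "s1"))
  expect_equal(roi_mean_spectrum(ds, "tumor")$intensity, c(3, 3, 3))
  expect_equal(roi_mean_spectrum(ds, "necrosis")$intensity, c(8, 8, 8))
  expect_equal(roi_mean_spectrum(ds, "on_tissue")$intensity, c(5.5, 5.5, 5.5))

  one <- tiny_dataset(rbind(c(1, 5, 2), c(0, 0, 0)),
                      roi = c("tumor", "off_tissue"))
  expect_equal(roi_mean_spectrum(one, "tumor")$intensity, c(1, 5, 2))
  expect_error(roi_mean_spectrum(ds, "off_tissue"), "off_tissue")
})

test_that("tumor mean is independent of necrosis values (checkerboard)", {
  roi <- rep(c("tumor", "necrosis"), 8)
  set.seed(3)
  tum <- matrix(rep(runif(5, 1, 10), each = 8), 8, 5)
  a <- matrix(0, 16, 5); a[roi == "tumor", ] <- tum
  a[roi == "necrosis", ] <- 1
  b <- a; b[roi == "necrosis", ] <- 99
  dsa <- tiny_dataset(a, roi = roi)
  dsb <- tiny_dataset(b, roi = roi)
  expect_equal(roi_mean_spectrum(dsa, "tumor")$intensity,
               roi_mean_spectrum(dsb, "tumor")$intensity)
})

test_that("ROI mean spectrum is linear in the data", {
  set.seed(4)
  m <- matrix(abs(rnorm(4 * 6)), 4, 6)
  ds <- tiny_dataset(m, roi = rep("tumor", 4))
  ds3 <- tiny_dataset(3 * m, roi = rep("tumor", 4))
  expect_equal(roi_mean_spectrum(ds3, "tumor")$intensity,
               3 * roi_mean_spectrum(ds, "tumor")$intensity)
})

test_that("baseline correction removes flat offsets and keeps peak apexes", {
  flat <- list(mz = seq(500, 600, 0.1), intensity = rep(7, 1001))
  expect_equal(baseline_correct(flat)$intensity, rep(0, 1001))

  sp <- gaussian_spectrum(650, 100, mz_min = 600, mz_max = 700)
  corr <- baseline_correct(sp)
  expect_gt(max(corr$intensity), 99)  # apex preserved within 1%

  off <- gaussian_spectrum(650, 100, mz_min = 600, mz_max = 700, offset = 5)
  corr_off <- baseline_correct(off)
  expect_lt(abs(max(corr_off$intensity) - 100), 5)  # offset removed within 5%
  far <- abs(corr_off$mz - 650) > 10
  expect_lt(mean(corr_off$intensity[far]), 0.25)

  narrow <- list(mz = seq(500, 502, 0.1), intensity = rep(3, 21))
  expect_equal(baseline_correct(narrow)$intensity, rep(0, 21))
})

test_that("peak picking applies S/N and absolute intensity thresholds", {
  # Gaussian noise with unit SD puts the windowed MAD noise floor near 1
  set.seed(26)
  n_pts <- 1001
  sp <- gaussian_spectrum(650, 100, mz_min = 600, mz_max = 700,
                          noise = rnorm(n_pts))
  pk <- pick_peaks(sp, picking_params(smoothing_on = FALSE,
                                      baseline_on = FALSE))
  expect_identical(nrow(pk), 1L)
  expect_lt(abs(pk$mz - 650), 0.05)
  expect_gt(pk$snr, 50)
  expect_lt(pk$snr, 200)

  # apex below the 0.14 absolute threshold is rejected even at high S/N
  set.seed(27)
  weak <- gaussian_spectrum(650, 0.1, mz_min = 600, mz_max = 700,
                            noise = abs(rnorm(n_pts, 0, 0.002)))
  expect_identical(nrow(pick_peaks(weak, picking_params(
    smoothing_on = FALSE, baseline_on = FALSE))), 0L)
  # and passes once the threshold is below the apex
  expect_identical(nrow(pick_peaks(weak, picking_params(
    abs_int_min = 0.05, smoothing_on = FALSE, baseline_on = FALSE))), 1L)
})

test_that("resolved Gaussian pairs give two accurate centroids", {
  sp <- gaussian_spectrum(c(649.73, 655.08), c(80, 60), mz_min = 600,
                          mz_max = 700, step = 0.02,
                          noise = rep(c(0.01, -0.01), length.out = 5001)
                            + 0.01)
  pk <- pick_peaks(sp, picking_params(abs_int_min = 1, smoothing_on = FALSE,
                                      baseline_on = FALSE))
  expect_identical(nrow(pk), 2L)
  expect_lt(abs(pk$mz[1] - 649.73), 0.01)
  expect_lt(abs(pk$mz[2] - 655.08), 0.01)
})

test_that("peak count is monotone non-increasing in each threshold", {
  set.seed(11)
  centers <- sort(runif(12, 610, 690))
  heights <- runif(12, 0.2, 50)
  sp <- gaussian_spectrum(centers, heights, mz_min = 600, mz_max = 700,
                          noise = abs(rnorm(1001, 0, 0.05)))
  n_at <- function(snr, abs_min) {
    nrow(pick_peaks(sp, picking_params(snr_min = snr, abs_int_min = abs_min,
                                       smoothing_on = FALSE)))
  }
  for (thresholds in list(c(1, 5, 20, 100), c(0.01, 0.14, 1, 10))) {
    counts <- if (identical(thresholds[2], 5)) {
      vapply(thresholds, n_at, numeric(1), abs_min = 0.14)
    } else {
      vapply(thresholds, function(a) n_at(10, a), numeric(1))
    }
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("empty spectra yield empty peak lists", {
  expect_identical(nrow(pick_peaks(list(mz = numeric(0),
                                        intensity = numeric(0)))), 0L)
})
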