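test_that("continuous-mode imzML round-trips bit-identically", {
  set.seed(42)
  ds <- tiny_dataset(matrix(abs(rnorm(3 * 50)), 3, 50),
                     mz = seq(500, by = 0.5, length.out = 50))
  path <- file.path(withr::local_tempdir(), "cont.imzML")
  write_imzml(ds, path)
  back <- read_imzml(path)
  expect_identical(back$mode, "continuous")
  expect_identical(back$mz, ds$mz)
  expect_identical(back$intensity, unname(ds$intensity))
  expect_identical(back$coords, ds$coords)
})

test_that("processed-mode imzML preserves per-pixel axis lengths", {
  set.seed(1)
  lens <- c(10L, 12L, 7L)
  mzs <- lapply(lens, function(n) sort(runif(n, 500, 1300)))
  ints <- lapply(lens, function(n) abs(rnorm(n)))
  ds <- msi_dataset(mzs, ints, data.frame(x = 0:2, y = c(0L, 0L, 1L)))
  path <- file.path(withr::local_tempdir(), "proc.imzML")
  write_imzml(ds, path)
  back <- read_imzml(path)
  expect_identical(back$mode, "processed")
  expect_identical(vapply(back$mz, length, integer(1)), lens)
  expect_equal(back$mz, ds$mz)
  expect_equal(back$intensity, ds$intensity)
})

test_that("acquisition m/z range is preserved on read", {
  ds <- tiny_dataset(matrix(1, 2, 201), mz = seq(500, 1300, by = 4))
  path <- file.path(withr::local_tempdir(), "range.imzML")
  write_imzml(ds, path)
  back <- read_imzml(path)
  expect_gte(mz_range(back)[1], 500)
  expect_lte(mz_range(back)[2], 1300)
})

test_that("missing .ibd companion is an I/O error", {
  ds <- tiny_dataset(matrix(1, 2, 5))
  path <- file.path(withr::local_tempdir(), "orphan.imzML")
  write_imzml(ds, path)
  file.remove(sub("imzML$", "ibd", path))
  expect_error(read_imzml(path), "ibd")
})

test_that("ROI masks attach labels and default missing pixels to excluded", {
  ds <- tiny_dataset(matrix(1, 6, 5))
  dir <- withr::local_tempdir()

  all_tumor <- file.path(dir, "all_tumor.csv")
  write.csv(data.frame(x = ds$coords$x, y = ds$coords$y, label = "tumor"),
            all_tumor, row.names = FALSE)
  expect_true(all(read_roi_mask(all_tumor, ds) == "tumor"))

  one_necro <- file.path(dir, "one.csv")
  write.csv(data.frame(x = ds$coords$x[3], y = ds$coords$y[3],
                       label = "necrosis"), one_necro, row.names = FALSE)
  roi <- read_roi_mask(one_necro, ds)
  expect_identical(sum(roi == "necrosis"), 1L)
  expect_identical(sum(roi == "excluded"), 5L)
})

test_that("unknown ROI labels are rejected naming the offending row", {
  ds <- tiny_dataset(matrix(1, 4, 5))
  path <- file.path(withr::local_tempdir(), "bad.csv")
  write.csv(data.frame(x = c(0, 1), y = c(0, 0),
                       label = c("tumor", "stroma")), path, row.names = FALSE)
  expect_error(read_roi_mask(path, ds), "stroma")
  expect_error(read_roi_mask(path, ds), "row 2")
})

test_that("ROI masks never silently drop labeled pixels", {
  ds <- tiny_dataset(matrix(1, 8, 5))
  path <- file.path(withr::local_tempdir(), "roi.csv")
  labels <- c("tumor", "tumor", "necrosis", "off_tissue")
  write.csv(data.frame(x = ds$coords$x[1:4], y = ds$coords$y[1:4],
                       label = labels), path, row.names = FALSE)
  roi <- read_roi_mask(path, ds)
  expect_identical(sum(roi != "excluded"), length(labels))
  # a row addressing a pixel outside the grid is an error, not a drop
  write.csv(data.frame(x = 99, y = 99, label = "tumor"), path,
            row.names = FALSE)
  expect_error(read_roi_mask(path, ds), "absent")
})

test_that("section metadata round-trips through YAML", {
  meta <- list(section_id = "T1_R2", bio_sample = "T1", tech_rep = 2L,
               arm = "treated")
  path <- file.path(withr::local_tempdir(), "meta.yaml")
  write_section_meta(meta, path)
  back <- read_section_meta(path)
  expect_identical(back$bio_sample, "T1")
  expect_identical(back$tech_rep, 2L)
  expect_identical(back$day, 2L)  # defaults to the technical replicate
  expect_error(write_section_meta(list(tech_rep = 5), path))
})

test_that("master peak list TSV writes all rows and round-trips", {
  master <- reference_table("master_list")
  path <- file.path(withr::local_tempdir(), "master.tsv")
  write_peaklist_tsv(master, path)
  back <- read_peaklist_tsv(path)
  expect_identical(nrow(back), 26L)

  empty <- master[0, ]
  expect_warning(write_peaklist_tsv(empty, path), "empty")
  expect_identical(nrow(read_peaklist_tsv(path)), 0L)

  three <- data.frame(mz = c(609.123456, 740.654321, 812.5),
                      intensity = c(1.234567, 2.345678, 3))
  write_peaklist_tsv(three, path, provenance = list(seed = 1))
  back <- read_peaklist_tsv(path)
  expect_equal(back$mz, round(three$mz, 6))
  expect_equal(back$intensity, round(three$intensity, 6))
})

test_that("processed-mode binning accumulates onto the uniform axis", {
  ds <- msi_dataset(list(c(600.04, 600.91), c(700.5)),
                    list(c(2, 3), c(5)),
                    data.frame(x = 0:1, y = c(0L, 0L)))
  binned <- bin_to_axis(ds, 500, 1300, 0.1)
  expect_identical(binned$mode, "continuous")
  expect_equal(sum(binned$intensity[1, ]), 5)
  expect_equal(binned$intensity[1, which.min(abs(binned$mz - 600.0))], 2)
  expect_equal(binned$intensity[2, which.min(abs(binned$mz - 700.5))], 5)
})

test_that("dataset invariants are enforced", {
  expect_error(tiny_dataset(matrix(-1, 2, 3)), "non-negative")
  expect_error(msi_dataset(c(500, 499), matrix(1, 1, 2),
                           data.frame(x = 0, y = 0)), "increasing")
  expect_error(tiny_dataset(matrix(1, 2, 3), roi = rep("lesion", 2)),
               "unknown ROI")
})
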