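#!/usr/bin/env Rscript
# Stage 3: technical reproducibility of the master-list masses.
#
# Whole-dataset CV: per mass, the CV across the three day-level dataset mean
# intensities (all sections of one day averaged). Interday/intraday CV: per
# mass across three technical replicates of one biological sample measured on
# different days / the same day.

library(lipidmsi)

seed <- 1L
cfg <- generator_config(seed = seed)
ml <- readRDS("scratch/masterlist_run.rds")  # produced by 02_masterlist.R

wd <- run_whole_dataset_cv(ml$summaries, ml$master$mz)
inter <- run_replicate_cv(cfg, ml$master$mz, mode = "interday")
intra <- run_replicate_cv(cfg, ml$master$mz, mode = "intraday")

per_mass <- data.frame(
  mz = ml$master$mz,
  wd_cv = unname(wd$per_mz_cv),
  interday_cv = unname(inter$per_mz_cv),
  intraday_cv = unname(intra$per_mz_cv))
dir.create("results", showWarnings = FALSE)
write_results_tsv(per_mass, "results/cv_report.tsv",
                  provenance = list(
                    seed = seed,
                    wd_cv_avg = sprintf("%.1f +/- %.1f", wd$cv_avg, wd$cv_sd),
                    interday_cv_avg = sprintf("%.1f +/- %.1f", inter$cv_avg,
                                              inter$cv_sd),
                    intraday_cv_avg = sprintf("%.1f +/- %.1f", intra$cv_avg,
                                              intra$cv_sd)))

cat(sprintf("whole-dataset CV_avg: %.1f +/- %.1f %%\n", wd$cv_avg, wd$cv_sd))
cat(sprintf("interday CV_avg:      %.1f +/- %.1f %%\n", inter$cv_avg,
            inter$cv_sd))
cat(sprintf("intraday CV_avg:      %.1f +/- %.1f %%\n", intra$cv_avg,
            intra$cv_sd))
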