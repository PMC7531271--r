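#!/usr/bin/env Rscript
# Full-data reference statistics for the simulated datasets: per-population
# Ho/Hs/FIS with undefined-FIS ("NaN") accounting, overall FST (both
# multilocus conventions), and the marker-type contrast with the
# microsatellite dataset. Reads the archives of 01_simulate.R.

suppressPackageStartupMessages(library(popsampling))
data_dir <- "results/data"
out <- "results"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

rows <- list()
for (regime in c("high", "low")) {
  d <- load_genotypes(file.path(data_dir, paste0("snp_", regime, ".vcf")), "vcf")
  s <- basic_stats(d)
  write_stats_csv(s, file.path(out, paste0("perlocus_", regime, ".csv")))
  utils::write.csv(s$per_pop, file.path(out, paste0("perpop_", regime, ".csv")),
                   row.names = FALSE)
  rows[[regime]] <- data.frame(
    dataset = paste0("simulated_", regime), marker = "snp",
    mean_hs = s$mean_hs, mean_fis = s$mean_fis,
    fst_ratio = s$fst_ratio, fst_mean = s$fst_mean,
    mean_nan_fis = s$mean_nan_fis)
  message(sprintf("%s flow: Hs %.4f, FIS %.4f, FST %.4f (NaN/pop %.0f)",
                  regime, s$mean_hs, s$mean_fis, s$fst_ratio, s$mean_nan_fis))
}

micro <- load_genotypes(file.path(data_dir, "microsat_high.csv"), "csv_genotypes")
sm <- basic_stats(micro)
rows$micro <- data.frame(dataset = "simulated_high", marker = "microsat",
                         mean_hs = sm$mean_hs, mean_fis = sm$mean_fis,
                         fst_ratio = sm$fst_ratio, fst_mean = sm$fst_mean,
                         mean_nan_fis = sm$mean_nan_fis)
message(sprintf("microsatellites: Hs %.4f, FST %.4f (higher diversity, lower
  differentiation than SNPs, as expected for multi-allelic markers)",
  sm$mean_hs, sm$fst_ratio))

utils::write.csv(do.call(rbind, rows), file.path(out, "summary_table.csv"),
                 row.names = FALSE)
message("wrote results/summary_table.csv")
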