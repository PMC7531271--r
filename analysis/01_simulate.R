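#!/usr/bin/env Rscript
# Simulate the two hierarchical demographic models (high and low
# between-cluster gene flow) at the default study design and archive the
# datasets and landscape metadata used by the downstream analyses.
# Problem size is kept desk-scale: 3000 ascertained SNP loci per regime
# (per-locus draws are independent, so means are unbiased at any size).

suppressPackageStartupMessages(library(popsampling))
seed <- 20260924L
n_loci <- 3000L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (regime in c("high", "low")) {
  message("== regime: ", regime)
  model <- build_hierarchical_model(regime, seed = seed)
  ls <- generate_landscape(model, "island", seed = seed + 1L)
  dataset <- simulate_snp_genotypes(ls$model, n_loci, 15L, seed = seed + 2L)
  write_model(ls$model, file.path(out, paste0("model_", regime, ".yaml")))
  write_metadata(ls$metadata, file.path(out, paste0("metadata_", regime, ".csv")))
  write_vcf(dataset, file.path(out, paste0("snp_", regime, ".vcf")))
  message("  ", n_loci, " loci x ", length(dataset$pop), " individuals written")
}

# a microsatellite-style companion dataset (22 loci), as used for the
# marker-type comparison
model <- build_hierarchical_model("high", seed = seed)
micro <- simulate_microsat_genotypes(model, 22L, mutation_rate = 5e-4,
                                     n_diploids_per_pop = 15L, seed = seed + 3L)
write_genotypes_csv(micro, file.path(out, "microsat_high.csv"))
message("microsatellite dataset written (22 loci)")
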