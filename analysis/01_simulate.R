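#!/usr/bin/env Rscript
# Stage 1: generate the synthetic invasion (occurrence records) and the
# SNP cohort with full ground truth, and write them in the standard
# exchange formats so later stages (and external tools) can read them.

source("analysis/00_common.R")

occ <- make_invasion()
cat(sprintf("simulated %d occurrence records over %d-%d\n",
            nrow(occ), min(occ$year), max(occ$year)))
write.csv(occ[, c("id", "x", "y", "year", "verified")],
          file.path(DATA_DIR, "occurrences.csv"), row.names = FALSE)

sim <- make_genotypes()
cat(sprintf("simulated %d individuals x %d loci in %d localities; %d clutches\n",
            nrow(sim$G$calls), ncol(sim$G$calls),
            length(unique(sim$G$locality_of)), length(sim$pedigree)))
write_genotypes_vcf(sim$G, file.path(DATA_DIR, "genotypes.vcf"))
write_genotypes_csv(sim$G, file.path(DATA_DIR, "genotypes_012.csv"))
write.csv(LOCALITIES, file.path(DATA_DIR, "localities.csv"),
          row.names = FALSE)
write.csv(data.frame(id = names(sim$G$locality_of),
                     locality_id = sim$G$locality_of),
          file.path(DATA_DIR, "individual_localities.csv"),
          row.names = FALSE)
jsonlite::write_json(
  list(seed = SEED, barrier_x_m = 8000,
       sources = attr(occ, "truth")$sources,
       sigma_true_m = attr(occ, "truth")$sigma_true,
       fullsib_sets = sim$pedigree),
  file.path(DATA_DIR, "truth.json"), auto_unbox = TRUE, digits = NA)
cat("inputs written under", DATA_DIR, "\n")
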