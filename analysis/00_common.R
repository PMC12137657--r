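# Shared setup for the analysis drivers: a synthetic two-origin river
# invasion with a dispersal barrier, emulating the structure of the
# bullfrog system (staggered introductions, a canal-like barrier
# splitting the valley, clutch-structured sampling). Every driver
# sources this file so all stages see the same ground truth.

library(spreadgen)

SEED <- 20260928 %% 100000
DATA_DIR <- "results/data"
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)

# valley geometry: a 16-km west-flowing river axis; the barrier (a
# canal analogue) crosses it at x = 8 km
BARRIER <- rbind(c(8000, -30000), c(8000, 30000))
LOCALITIES <- data.frame(locality_id = 1:8,
                         x = seq(0, 16000, length.out = 8), y = 0)

make_invasion <- function() {
  truth <- invasion_truth(
    sources = data.frame(x = c(1000, 5000, 11000, 15000),
                         y = c(0, 0, 0, 0),
                         intro_year = c(1997, 2002, 2001, 2004)),
    sigma_true = 700, detection_prob = 0.5,
    barrier = BARRIER, ldd_rate = 0.03)
  simulate_invasion(truth, 1997:2009, seed = SEED, growth = 0.6,
                    max_points = 600)
}

make_genotypes <- function() {
  truth <- genotype_truth(
    origin_of_source = c(1, 1, 1, 1, 2, 2, 2, 2),
    fst_between_origins = 0.3, migration_rate = 0.08,
    barrier_migration_rate = 0.002, barrier_after = 4)
  simulate_genotypes(truth, n_loci = 400, n_gen = 12,
                     samples_per_deme = 12, seed = SEED + 1,
                     clutch_sizes = c(1, 1, 2, 3), missing_rate = 0.02)
}
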