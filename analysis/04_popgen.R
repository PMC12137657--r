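#!/usr/bin/env Rscript
# Stage 4: kinship filtering, per-locality diversity, differentiation,
# Bayesian admixture clustering with Evanno model choice, PCoA, AMOVA
# and the isolation-by-distance Mantel tests.

source("analysis/00_common.R")

lmap_df <- read.csv(file.path(DATA_DIR, "individual_localities.csv"))
lmap <- setNames(lmap_df$locality_id, lmap_df$id)
G <- read_genotypes(file.path(DATA_DIR, "genotypes.vcf"), lmap)
print(G)

## full-sib filtering before population-level statistics
K <- wang_relatedness(G)
filt <- filter_fullsibs(K, G$locality_of, threshold = 0.5, seed = SEED)
cat(sprintf("full-sib filter: %d qualifying pairs, %d individuals removed, %d retained\n",
            filt$n_pairs, length(filt$removed), length(filt$retained)))
Gf <- genotype_matrix(G$calls[filt$retained, , drop = FALSE],
                      G$locality_of[filt$retained])

div <- heterozygosity(Gf)
write.csv(div, "results/diversity.csv", row.names = FALSE)
cat(sprintf("Ho range %.3f-%.3f (mean %.3f); F_IS range %.3f-%.3f\n",
            min(div$Ho, na.rm = TRUE), max(div$Ho, na.rm = TRUE),
            mean(div$Ho, na.rm = TRUE), min(div$F_IS, na.rm = TRUE),
            max(div$F_IS, na.rm = TRUE)))

fst <- pairwise_fst(Gf)
write.csv(fst, "results/fst_matrix.csv")
cat(sprintf("pairwise F_ST range %.3f-%.3f (mean %.3f)\n",
            min(fst[upper.tri(fst)], na.rm = TRUE),
            max(fst[upper.tri(fst)], na.rm = TRUE),
            mean(fst[upper.tri(fst)], na.rm = TRUE)))

## hierarchical admixture clustering
tree <- hierarchical_clustering(Gf, q_threshold = 0.6, max_k = 4,
                                replicates = 3, n_burn = 100,
                                n_iter = 400, seed = SEED)
cat(sprintf("level-1 clusters: K = %s\n", tree$k))
print(tree$members)
for (nm in names(tree$children))
  cat(sprintf("  substructure in %s: K = %s\n", nm, tree$children[[nm]]$k))
jsonlite::write_json(
  list(k1 = tree$k, members = as.list(tree$members),
       q = as.data.frame(tree$q),
       children_k = lapply(tree$children, `[[`, "k")),
  "results/cluster_tree.json", auto_unbox = TRUE, digits = NA)

## ordination
pc <- pcoa_genotypes(Gf, k = 4)
write.csv(data.frame(id = rownames(pc$coords), pc$coords,
                     locality_id = Gf$locality_of),
          "results/pcoa_coords.csv", row.names = FALSE)
cat(sprintf("PCoA axis 1/2 explain %.1f%% / %.1f%% of variance\n",
            pc$pct_var[1], pc$pct_var[2]))

## AMOVA between the level-1 clusters
cluster_of <- tree$members
am <- amova(Gf, cluster_of, n_perm = 1000, seed = SEED)
cat(sprintf("AMOVA: Phi_ST = %.3f (p = %.4g)\n", am$phi_st, am$p_value))

## isolation by distance: chord distance vs Euclidean distance
lf <- locality_frequencies(Gf)
usable <- rownames(lf$freq)[vapply(rownames(lf$freq), function(l)
  sum(Gf$locality_of == l) >= 2, TRUE)]
gd <- chord_distance(lf$freq[usable, , drop = FALSE])
loc <- LOCALITIES[match(usable, as.character(LOCALITIES$locality_id)), ]
geo <- as.matrix(dist(loc[, c("x", "y")]))
dimnames(geo) <- dimnames(gd)
mt <- mantel_test(geo, gd, n_perm = 999, seed = SEED)
cat(sprintf("IBD (all localities): Mantel r = %.3f, p = %.3g\n",
            mt$r, mt$p))

jsonlite::write_json(
  list(amova = am[c("phi_st", "p_value", "n_perm")],
       mantel_all = mt,
       fst_mean = mean(fst[upper.tri(fst)], na.rm = TRUE),
       fullsib_pairs = filt$n_pairs,
       retained = length(filt$retained)),
  "results/popgen_tests.json", auto_unbox = TRUE, digits = NA)
cat("wrote diversity.csv, fst_matrix.csv, cluster_tree.json, pcoa_coords.csv, popgen_tests.json\n")
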