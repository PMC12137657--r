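#!/usr/bin/env Rscript
# Stage 6: landscape resistance from isolation-by-distance residuals at
# three spatial scales, and the kriged moving-window diversity surface
# correlated with the geoprofile hit scores.

source("analysis/00_common.R")

lmap_df <- read.csv(file.path(DATA_DIR, "individual_localities.csv"))
lmap <- setNames(lmap_df$locality_id, lmap_df$id)
G <- read_genotypes(file.path(DATA_DIR, "genotypes.vcf"), lmap)

ind_loc <- LOCALITIES[match(G$locality_of, LOCALITIES$locality_id), ]
coords <- data.frame(x = ind_loc$x, y = ind_loc$y)
gd <- prevosti_distance(G$calls / 2)

template <- raster_grid(-2000, -2000, 1000,
                        n_rows = 5, n_cols = 20)
for (dmax in c(2000, 5000, 10000)) {
  res <- tryCatch(fit_ibd_residuals(gd, coords, dmax),
                  error = function(e) NULL)
  if (is.null(res)) { cat("d_max", dmax, ": too few pairs\n"); next }
  rs <- map_resistance(res, template, n_resample = 1000, seed = SEED)
  write_raster(rs$mean, sprintf("results/resistance_%dkm.asc", dmax / 1000))
  write_raster(rs$class, sprintf("results/resistance_class_%dkm.asc",
                                 dmax / 1000))
  cls <- rs$class$values
  cat(sprintf("d_max %2d km: %d pairs, %d barrier and %d corridor cells\n",
              dmax / 1000, nrow(res), sum(cls == 1, na.rm = TRUE),
              sum(cls == -1, na.rm = TRUE)))
}

## moving-window rarefied Ho, kriged, against hit scores
hit <- tryCatch(read_raster("results/hit_scores.asc"),
                error = function(e) NULL)
if (!is.null(hit)) {
  ds <- windowed_heterozygosity(G, coords, hit, window = 10,
                                rarefaction_n = 5, seed = SEED)
  filled <- krige_surface(ds)
  write_raster(filled$grid, "results/ho_surface.asc")
  corr <- correlate_ho_hitscore(filled, hit, LOCALITIES)
  cat(sprintf("Ho vs hit score at %d localities: r = %.3f (t = %.2f, p = %.3g)\n",
              corr$n, corr$r, corr$t, corr$p))
  jsonlite::write_json(corr[c("r", "t", "p", "n")],
                       "results/ho_hitscore.json",
                       auto_unbox = TRUE, digits = NA)
} else {
  cat("run analysis/02_geoprofile.R first for the hit-score surface\n")
}
cat("wrote resistance and diversity surfaces under results/\n")
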