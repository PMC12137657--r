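#' Default pipeline configuration
#'
#' Returns the full parameter list for [run_all()] with the defaults
#' used throughout the package; override any element via `...`.
#' `seed` has no default and must be supplied explicitly: the pipeline
#' refuses wall-clock seeding.
#'
#' @param ... overrides.
#' @return named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    cutoff_year = 2009, dedup_radius = 200,
    sigma_mean_km = 5, sigma_var_km2 = 10, sigma_shape = 1.5,
    n_burn = 1000, n_sample = 10000, n_chains = 5, cell_m = 250,
    buffer_m = 1000,
    max_k = 6, replicates = 3, adm_burn = 60, adm_iter = 240,
    q_threshold = 0.6,
    fullsib_threshold = 0.5, edge_threshold = 0.35,
    d_max = c(2000, 5000, 10000), n_resample = 1000,
    window = 10, rarefaction_n = 5,
    n_perm_amova = 1000, n_perm_mantel = 999,
    seed = NULL)
  override <- list(...)
  cfg[names(override)] <- override
  cfg
}

#' Run the full invasion-reconstruction pipeline
#'
#' Executes occurrence thinning, geographic profiling, occupancy and
#' expansion speed, diversity and structure, connectivity, kinship,
#' resistance and diversity-surface stages in dependency order on
#' in-memory inputs, collecting everything into one report. A stage
#' failure is recorded in the manifest (with the failing stage named)
#' and later dependent stages are skipped.
#'
#' @param occurrences projected occurrence data frame.
#' @param G a [genotype_matrix()].
#' @param localities data frame `locality_id`, `x`, `y`.
#' @param config [pipeline_config()]; `config$seed` is mandatory.
#' @param divider optional polyline for the two-cluster occupancy split.
#' @param out_dir optional directory: surfaces, tables and a JSON
#'   manifest are written there.
#' @return list of stage results plus `manifest`.
#' @export
run_all <- function(occurrences, G, localities, config = pipeline_config(),
                    divider = NULL, out_dir = NULL) {
  if (is.null(config$seed)) stop("config$seed must be set explicitly")
  seed <- as.integer(config$seed)
  manifest <- list(seed = seed, parameters = config[order(names(config))],
                   stages = list())
  report <- list()
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      NULL
    })
    if (!is.null(res))
      manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  report$geoprofile <- run_stage("geoprofile", {
    thin <- thin_records(occurrences, config$cutoff_year,
                         config$dedup_radius)
    prior <- suppressWarnings(sigma_prior(config$sigma_mean_km,
                                          config$sigma_var_km2,
                                          config$sigma_shape))
    gp <- run_dpm(thin, prior, config$n_burn, config$n_sample,
                  config$n_chains, config$cell_m, seed = seed)
    list(thinned = thin, profile = gp)
  })

  report$occupancy <- run_stage("occupancy", {
    series <- expansion_speed(eoo_by_year(occurrences, config$buffer_m))
    out <- list(total = series)
    if (!is.null(divider)) {
      halves <- split_clusters(occurrences, divider)
      for (side in names(halves))
        if (nrow(halves[[side]]) > 1)
          out[[side]] <- expansion_speed(
            eoo_by_year(halves[[side]], config$buffer_m,
                        cluster_label = side))
    }
    out
  })

  report$kinship <- run_stage("kinship", {
    K <- wang_relatedness(G)
    filt <- filter_fullsibs(K, G$locality_of, config$fullsib_threshold,
                            seed = seed)
    edges <- kin_edges(K, G$locality_of, config$edge_threshold)
    list(relatedness = K, filter = filt, edges = edges)
  })

  Gf <- if (!is.null(report$kinship))
    genotype_matrix(G$calls[report$kinship$filter$retained, , drop = FALSE],
                    G$locality_of[report$kinship$filter$retained]) else G

  report$diversity <- run_stage("diversity", heterozygosity(Gf))
  report$fst <- run_stage("fst", pairwise_fst(Gf))
  report$pcoa <- run_stage("pcoa", pcoa_genotypes(Gf))

  report$clustering <- run_stage("clustering",
    hierarchical_clustering(Gf, config$q_threshold, config$max_k,
                            config$replicates, config$adm_burn,
                            config$adm_iter, seed = seed))

  cluster_of <- NULL
  if (!is.null(report$clustering) && !is.null(report$clustering$members))
    cluster_of <- report$clustering$members

  report$amova <- run_stage("amova", {
    if (is.null(cluster_of)) stop("no level-1 clusters available")
    amova(Gf, cluster_of, config$n_perm_amova, seed = seed)
  })

  report$ibd <- run_stage("ibd", {
    lf <- locality_frequencies(Gf)
    usable <- rownames(lf$freq)[rowSums(lf$n >= 1) > 0 &
      vapply(rownames(lf$freq),
             function(l) sum(Gf$locality_of == l) >= 2, TRUE)]
    loc <- localities[match(usable, as.character(localities$locality_id)), ]
    gd <- chord_distance(lf$freq[usable, , drop = FALSE])
    geo <- as.matrix(dist(loc[, c("x", "y")]))
    dimnames(geo) <- dimnames(gd)
    list(mantel = mantel_test(geo, gd, config$n_perm_mantel, seed = seed),
         chord = gd, geo = geo)
  })

  report$migration <- run_stage("migration", {
    M <- directional_migration(Gf)
    summ <- migration_summary(M)
    out <- list(matrix = M, summary = summ)
    if (!is.null(cluster_of)) {
      cl <- cluster_of[as.character(summ$locality_id)]
      ok <- !is.na(cl) & cl != "unassigned" & !is.na(summ$R_IE)
      if (length(unique(cl[ok])) == 2)
        out$cluster_test <- compare_clusters(summ$R_IE[ok], cl[ok])
    }
    if (!is.null(report$geoprofile) &&
        nrow(report$geoprofile$profile$source_estimates) > 0)
      out$source_distance <- ratio_vs_source_distance(
        summ, localities,
        as.data.frame(report$geoprofile$profile$source_estimates) |>
          setNames(c("x", "y")))
    out
  })

  report$resistance <- run_stage("resistance", {
    ind_loc <- localities[match(as.character(Gf$locality_of),
                                as.character(localities$locality_id)), ]
    coords <- data.frame(x = ind_loc$x, y = ind_loc$y)
    pf <- Gf$calls / 2            # within-individual allele frequency
    gd <- prevosti_distance(pf)
    template <- if (!is.null(report$geoprofile))
      report$geoprofile$profile$surface else {
        xr <- range(localities$x); yr <- range(localities$y)
        raster_grid(xr[1] - 2000, yr[1] - 2000, config$cell_m * 4,
                    ceiling((yr[2] - yr[1] + 4000) / (config$cell_m * 4)),
                    ceiling((xr[2] - xr[1] + 4000) / (config$cell_m * 4)))
      }
    lapply(setNames(config$d_max, paste0("d", config$d_max)), function(dm) {
      res <- fit_ibd_residuals(gd, coords, dm)
      map_resistance(res, template, config$n_resample, seed = seed)
    })
  })

  report$diversity_surface <- run_stage("diversity_surface", {
    if (is.null(report$geoprofile)) stop("needs the geoprofile surface")
    ind_loc <- localities[match(as.character(Gf$locality_of),
                                as.character(localities$locality_id)), ]
    ds <- windowed_heterozygosity(Gf, data.frame(x = ind_loc$x,
                                                 y = ind_loc$y),
                                  report$geoprofile$profile$surface,
                                  config$window, config$rarefaction_n,
                                  seed = seed)
    filled <- krige_surface(ds)
    corr <- correlate_ho_hitscore(filled,
                                  report$geoprofile$profile$hit_scores,
                                  localities)
    list(surface = filled, correlation = corr)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    if (!is.null(report$geoprofile)) {
      paths <- c(paths,
                 write_raster(report$geoprofile$profile$surface,
                              file.path(out_dir, "geoprofile_surface.asc")),
                 write_raster(report$geoprofile$profile$hit_scores,
                              file.path(out_dir, "hit_scores.asc")))
    }
    if (!is.null(report$diversity))
      write.csv(report$diversity,
                p <- file.path(out_dir, "diversity.csv"), row.names = FALSE)
    manifest$files <- as.list(tools::md5sum(paths))
    jsonlite::write_json(manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report$manifest <- manifest
  report
}
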