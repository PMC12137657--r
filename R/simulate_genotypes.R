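#' Ground truth for synthetic genotypes
#'
#' @param origin_of_source integer vector (1 or 2) giving the founder
#'   origin of each deme's source.
#' @param fst_between_origins target differentiation between the two
#'   founder allele-frequency pools (Balding-Nichols).
#' @param migration_rate per-generation symmetric neighbour exchange
#'   along the 1-D river axis.
#' @param barrier_migration_rate reduced rate across the barrier.
#' @param barrier_after index b: the barrier lies between demes b and
#'   b+1 (`NA` for no barrier).
#' @return list of class `genotype_truth`.
#' @export
genotype_truth <- function(origin_of_source, fst_between_origins = 0.3,
                           migration_rate = 0.05,
                           barrier_migration_rate = 0.005,
                           barrier_after = NA) {
  if (!all(origin_of_source %in% c(1, 2)))
    stop("origins must be 1 or 2")
  if (migration_rate < 0 || migration_rate > 0.5 ||
      barrier_migration_rate < 0 || barrier_migration_rate > 0.5)
    stop("migration rates must be in [0, 0.5]")
  if (fst_between_origins < 0 || fst_between_origins >= 1)
    stop("fst_between_origins must be in [0, 1)")
  structure(list(origin_of_source = origin_of_source,
                 fst_between_origins = fst_between_origins,
                 migration_rate = migration_rate,
                 barrier_migration_rate = barrier_migration_rate,
                 barrier_after = barrier_after),
            class = "genotype_truth")
}

#' Simulate SNP genotypes along a stepping-stone river system
#'
#' Two founder allele-frequency pools are built by drawing ancestral
#' frequencies from `Uniform(0.1, 0.9)` and perturbing each pool with
#' Balding-Nichols beta noise at the target F_ST. Each deme starts from
#' its origin's pool, then undergoes `n_gen` generations of
#' Wright-Fisher drift (deme size `N`) with symmetric nearest-neighbour
#' migration along the deme ordering, reduced to
#' `barrier_migration_rate` across the barrier. Sampling draws whole
#' clutches: each clutch shares two parents drawn from the deme's
#' frequencies, so clutch-mates are true full sibs (recorded in the
#' pedigree).
#'
#' @param truth a [genotype_truth()]; `origin_of_source` must have one
#'   entry per deme.
#' @param n_loci number of biallelic loci (>= 50).
#' @param n_gen generations of drift.
#' @param samples_per_deme individuals sampled per deme.
#' @param seed RNG seed.
#' @param N deme size (diploid individuals).
#' @param clutch_sizes sampler for clutch sizes: sizes are drawn from
#'   this vector with replacement until the deme quota is filled
#'   (truncating the last clutch); size-1 entries are unrelated singles.
#' @param deme_ids optional locality ids (default `1:n_demes`).
#' @param missing_rate fraction of calls independently set to missing.
#' @param founder_chain when `TRUE`, demes after the first are seeded by
#'   a serial bottleneck of `founder_size` diploid founders from their
#'   upstream neighbour (serial founder effect) instead of directly from
#'   their origin pool.
#' @param founder_size bottleneck size for `founder_chain`.
#' @return list with `G` (a [genotype_matrix()]), `pedigree` (list of
#'   character vectors of full-sib sets, clutches of size >= 2), and
#'   `founder_freqs` (2 x n_loci matrix).
#' @export
simulate_genotypes <- function(truth, n_loci = 500, n_gen = 20,
                               samples_per_deme = 10, seed = 1, N = 50,
                               clutch_sizes = c(1, 1, 2, 3),
                               deme_ids = NULL, missing_rate = 0,
                               founder_chain = FALSE, founder_size = 5) {
  if (n_loci < 50) stop("n_loci must be >= 50")
  n_demes <- length(truth$origin_of_source)
  if (samples_per_deme > 2 * N)
    stop("samples_per_deme exceeds 2N")
  if (is.null(deme_ids)) deme_ids <- seq_len(n_demes)
  set.seed(as.integer(seed))

  # founder pools via Balding-Nichols
  p_anc <- runif(n_loci, 0.1, 0.9)
  Fst <- truth$fst_between_origins
  founder <- matrix(0, 2, n_loci)
  if (Fst == 0) {
    founder[1, ] <- p_anc; founder[2, ] <- p_anc
  } else {
    theta <- (1 - Fst) / Fst
    for (o in 1:2)
      founder[o, ] <- rbeta(n_loci, p_anc * theta, (1 - p_anc) * theta)
  }

  # deme frequencies: matrix demes x loci
  p <- founder[truth$origin_of_source, , drop = FALSE]
  if (founder_chain && n_demes > 1) {
    # serial founder effect: each deme is seeded by a small bottleneck
    # from its upstream neighbour, progressively eroding diversity
    for (d in 2:n_demes)
      p[d, ] <- rbinom(n_loci, 2 * founder_size, p[d - 1, ]) /
        (2 * founder_size)
  }

  m <- truth$migration_rate
  mb <- truth$barrier_migration_rate
  bar <- truth$barrier_after
  for (g in seq_len(n_gen)) {
    if (n_demes > 1) {
      # migration rate for the link between deme i and i+1
      link_m <- rep(m, n_demes - 1)
      if (!is.na(bar) && bar >= 1 && bar < n_demes) link_m[bar] <- mb
      p_new <- p
      for (d in seq_len(n_demes)) {
        inflow_w <- 0; inflow <- 0
        if (d > 1) { inflow <- inflow + link_m[d - 1] * p[d - 1, ]; inflow_w <- inflow_w + link_m[d - 1] }
        if (d < n_demes) { inflow <- inflow + link_m[d] * p[d + 1, ]; inflow_w <- inflow_w + link_m[d] }
        p_new[d, ] <- (1 - inflow_w) * p[d, ] + inflow
      }
      p <- p_new
    }
    # Wright-Fisher binomial drift
    for (d in seq_len(n_demes))
      p[d, ] <- rbinom(n_loci, 2 * N, p[d, ]) / (2 * N)
  }

  # sampling with clutch structure
  calls <- NULL; ids <- character(0); loc <- c()
  pedigree <- list()
  draw_geno <- function(freq) rbinom(n_loci, 2, freq)  # HW individual
  for (d in seq_len(n_demes)) {
    quota <- samples_per_deme
    k <- 0
    while (quota > 0) {
      size <- min(clutch_sizes[sample.int(length(clutch_sizes), 1)], quota)
      k <- k + 1
      members <- character(0)
      if (size == 1) {
        g <- draw_geno(p[d, ])
        id <- sprintf("d%02d_s%02d", deme_ids[d], length(ids) + 1)
        calls <- rbind(calls, g); ids <- c(ids, id)
        loc <- c(loc, deme_ids[d])
      } else {
        mother <- rbind(rbinom(n_loci, 1, p[d, ]), rbinom(n_loci, 1, p[d, ]))
        father <- rbind(rbinom(n_loci, 1, p[d, ]), rbinom(n_loci, 1, p[d, ]))
        for (cix in seq_len(size)) {
          mg <- mother[cbind(sample.int(2, n_loci, replace = TRUE), seq_len(n_loci))]
          fg <- father[cbind(sample.int(2, n_loci, replace = TRUE), seq_len(n_loci))]
          g <- mg + fg
          id <- sprintf("d%02d_s%02d", deme_ids[d], length(ids) + 1)
          calls <- rbind(calls, g); ids <- c(ids, id)
          loc <- c(loc, deme_ids[d])
          members <- c(members, id)
        }
        if (length(members) >= 2)
          pedigree[[length(pedigree) + 1]] <- members
      }
      quota <- quota - size
    }
  }
  rownames(calls) <- ids
  colnames(calls) <- paste0("L", seq_len(n_loci))
  if (missing_rate > 0)
    calls[runif(length(calls)) < missing_rate] <- NA
  locality_of <- setNames(loc, ids)
  G <- genotype_matrix(calls, locality_of)
  list(G = G, pedigree = pedigree, founder_freqs = founder,
       deme_freqs = p, truth = truth)
}

#' Full-sib pairs implied by a pedigree
#'
#' @param pedigree list of full-sib sets (character vectors).
#' @return two-column character matrix of pairs.
#' @export
pedigree_pairs <- function(pedigree) {
  out <- matrix(character(0), ncol = 2)
  for (fam in pedigree)
    if (length(fam) >= 2)
      out <- rbind(out, t(combn(fam, 2)))
  colnames(out) <- c("id1", "id2")
  out
}
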