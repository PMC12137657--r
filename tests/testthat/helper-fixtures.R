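# Shared fixtures built in code.

# Tiny genotype matrix with known tallies (2 localities x 5 individuals).
toy_genotypes <- function() {
  calls <- rbind(
    i1 = c(0L, 1L, 2L, 1L),
    i2 = c(1L, 1L, 2L, 0L),
    i3 = c(0L, 0L, 2L, NA),
    i4 = c(2L, 1L, 2L, 1L),
    i5 = c(1L, 2L, 2L, 2L))
  colnames(calls) <- paste0("L", 1:4)
  genotype_matrix(calls, setNames(c(1, 1, 1, 2, 2), rownames(calls)))
}

# i.i.d. records from a mixture of bivariate-normal sources (the
# geoprofiler's own generative model) for calibration experiments.
mixture_records <- function(centres, n_per, sigma_m) {
  centres <- as.matrix(centres)
  xy <- do.call(rbind, lapply(seq_len(nrow(centres)), function(k)
    cbind(rnorm(n_per, centres[k, 1], sigma_m),
          rnorm(n_per, centres[k, 2], sigma_m))))
  data.frame(id = sprintf("r%04d", seq_len(nrow(xy))),
             x = xy[, 1], y = xy[, 2], year = 2000L, verified = TRUE)
}

# One-year invasion pulse: sources piled at the origin with a large
# per-point colonisation rate, so every non-source record's position IS
# a single dispersal displacement.
displacement_sample <- function(n_draws, sigma_m, seed, ldd_rate = 0) {
  growth <- ceiling(n_draws / 10)
  tr <- invasion_truth(data.frame(x = rep(0, 10), y = rep(0, 10),
                                  intro_year = 2000),
                       sigma_true = sigma_m, detection_prob = 1,
                       ldd_rate = ldd_rate)
  rec <- simulate_invasion(tr, 2000, seed = seed, growth = growth,
                           max_points = 10 * (growth + 10))
  rec[rec$x != 0 | rec$y != 0, ]
}

# Pedigree helper: HW parents from known frequencies, Mendelian kids.
make_pedigree_pairs <- function(p, n_pairs, relation = c("fullsib",
                                                         "unrelated",
                                                         "parent-offspring")) {
  relation <- match.arg(relation)
  L <- length(p)
  draw_gamete <- function(geno) ifelse(geno == 1, rbinom(L, 1, 0.5),
                                       geno / 2)
  out <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    mum <- rbinom(L, 2, p); dad <- rbinom(L, 2, p)
    if (relation == "fullsib") {
      a <- draw_gamete(mum) + draw_gamete(dad)
      b <- draw_gamete(mum) + draw_gamete(dad)
    } else if (relation == "parent-offspring") {
      a <- mum
      b <- draw_gamete(mum) + draw_gamete(dad)
    } else {
      a <- rbinom(L, 2, p)
      b <- rbinom(L, 2, p)
    }
    out[[k]] <- rbind(a, b)
  }
  calls <- do.call(rbind, out)
  rownames(calls) <- paste0("i", seq_len(nrow(calls)))
  genotype_matrix(calls, setNames(rep(1, nrow(calls)), rownames(calls)))
}

# Monte-Carlo union-of-discs area (rejection sampling oracle), km^2.
mc_union_area <- function(centres, r, n = 2e5) {
  centres <- as.matrix(centres)
  xmin <- min(centres[, 1]) - r; xmax <- max(centres[, 1]) + r
  ymin <- min(centres[, 2]) - r; ymax <- max(centres[, 2]) + r
  px <- runif(n, xmin, xmax); py <- runif(n, ymin, ymax)
  inside <- rep(FALSE, n)
  for (i in seq_len(nrow(centres)))
    inside <- inside | ((px - centres[i, 1])^2 + (py - centres[i, 2])^2 <= r^2)
  mean(inside) * (xmax - xmin) * (ymax - ymin) / 1e6
}
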