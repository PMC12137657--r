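#' Per-locality diversity statistics
#'
#' Per locus within a locality: Ho is the heterozygote fraction among
#' non-missing calls and He the unbiased expected heterozygosity
#' `2p(1-p) * 2n/(2n-1)`. Locality values are means over loci with data;
#' F_IS = 1 - sum(Ho)/sum(He) over polymorphic loci (a ratio of
#' multilocus sums; monomorphic loci are uninformative about inbreeding
#' and drop out). Localities with fewer than 2 genotyped individuals
#' carry `NA` statistics.
#'
#' @param G a [genotype_matrix()].
#' @return data frame with columns `locality_id`, `n`, `Ho`, `He`,
#'   `F_IS`.
#' @export
heterozygosity <- function(G) {
  locs <- sort(unique(G$locality_of))
  out <- lapply(locs, function(loc) {
    calls <- G$calls[G$locality_of == loc, , drop = FALSE]
    n_ind <- nrow(calls)
    if (n_ind < 2)
      return(data.frame(locality_id = loc, n = n_ind, Ho = NA_real_,
                        He = NA_real_, F_IS = NA_real_))
    n_l <- colSums(!is.na(calls))
    usable <- n_l >= 2
    ho <- colMeans(calls == 1, na.rm = TRUE)
    p <- colMeans(calls, na.rm = TRUE) / 2
    he <- 2 * p * (1 - p) * (2 * n_l) / (2 * n_l - 1)
    ho <- ho[usable]; he <- he[usable]
    poly <- he > 0
    fis <- if (any(poly)) 1 - sum(ho[poly]) / sum(he[poly]) else NA_real_
    data.frame(locality_id = loc, n = n_ind, Ho = mean(ho), He = mean(he),
               F_IS = fis)
  })
  do.call(rbind, out)
}

#' Per-locality alternate-allele frequencies
#'
#' @param G a [genotype_matrix()].
#' @return list with `freq` (localities x loci), `n` (non-missing
#'   individuals per locality x locus) and `het` (observed heterozygote
#'   fraction), each with locality rownames.
#' @export
locality_frequencies <- function(G) {
  locs <- sort(unique(G$locality_of))
  freq <- het <- nn <- matrix(NA_real_, length(locs), ncol(G$calls),
                              dimnames = list(locs, colnames(G$calls)))
  for (i in seq_along(locs)) {
    calls <- G$calls[G$locality_of == locs[i], , drop = FALSE]
    nn[i, ] <- colSums(!is.na(calls))
    freq[i, ] <- colMeans(calls, na.rm = TRUE) / 2
    het[i, ] <- colMeans(calls == 1, na.rm = TRUE)
  }
  list(freq = freq, n = nn, het = het)
}

# Weir & Cockerham (1984) variance components for one biallelic locus
# across r populations. Returns c(a, b, c) or NULL when undefined.
.wc84_components <- function(n, p, h) {
  ok <- n >= 1
  n <- n[ok]; p <- p[ok]; h <- h[ok]
  r <- length(n)
  if (r < 2 || sum(n) == 0) return(NULL)
  nbar <- mean(n)
  if (nbar <= 1) return(NULL)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  if (nc <= 0) return(NULL)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

#' Pairwise Weir-Cockerham F_ST between localities
#'
#' Multilocus ratio-of-sums estimator (sum of `a` components over sum of
#' `a + b + c`); negative estimates are reported as computed. Pairs with
#' no shared polymorphic locus get `NA`.
#'
#' @param G a [genotype_matrix()].
#' @return symmetric matrix with locality dimnames.
#' @export
pairwise_fst <- function(G) {
  lf <- locality_frequencies(G)
  locs <- rownames(lf$freq)
  K <- length(locs)
  if (K < 2) stop("need at least 2 localities")
  out <- matrix(0, K, K, dimnames = list(locs, locs))
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    num <- den <- 0
    for (l in seq_len(ncol(lf$freq))) {
      n <- c(lf$n[i, l], lf$n[j, l])
      p <- c(lf$freq[i, l], lf$freq[j, l])
      h <- c(lf$het[i, l], lf$het[j, l])
      if (any(n < 1) || any(is.na(p))) next
      if (max(p) == 0 || min(p) == 1) next      # monomorphic in the pair
      comp <- .wc84_components(n, p, h)
      if (is.null(comp)) next
      num <- num + comp["a"]
      den <- den + sum(comp)
    }
    out[i, j] <- out[j, i] <- if (den > 0) num / den else NA_real_
  }
  out
}

#' Chord genetic distance between groups
#'
#' Cavalli-Sforza & Edwards chord distance on biallelic frequencies:
#' `D_c = (2 / (pi * L)) * sum_l sqrt(2 * (1 - sum_a sqrt(p1a * p2a)))`.
#' Loci missing in either group are dropped pairwise (L adjusted).
#'
#' @param freq groups x loci matrix of alternate-allele frequencies.
#' @return symmetric distance matrix.
#' @export
chord_distance <- function(freq) {
  K <- nrow(freq)
  out <- matrix(0, K, K, dimnames = list(rownames(freq), rownames(freq)))
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    ok <- !is.na(freq[i, ]) & !is.na(freq[j, ])
    L <- sum(ok)
    if (L == 0) { out[i, j] <- out[j, i] <- NA_real_; next }
    p1 <- freq[i, ok]; p2 <- freq[j, ok]
    s <- sqrt(p1 * p2) + sqrt((1 - p1) * (1 - p2))
    d <- 2 / (pi * L) * sum(sqrt(2 * pmax(0, 1 - s)))
    out[i, j] <- out[j, i] <- d
  }
  out
}

#' Prevosti genetic distance
#'
#' `(1 / (2L)) * sum_l sum_a |p1a - p2a|`; for biallelic loci this is
#' `(1/L) * sum_l |p1 - p2|`. Works on group frequencies or on
#' individual genotypes expressed as within-individual frequencies
#' (0, 0.5, 1), the form used for the IBD residual analysis.
#'
#' @param freq rows x loci matrix of alternate-allele frequencies (`NA`
#'   dropped pairwise).
#' @return symmetric distance matrix.
#' @export
prevosti_distance <- function(freq) {
  K <- nrow(freq)
  out <- matrix(0, K, K, dimnames = list(rownames(freq), rownames(freq)))
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    ok <- !is.na(freq[i, ]) & !is.na(freq[j, ])
    L <- sum(ok)
    if (L == 0) { out[i, j] <- out[j, i] <- NA_real_; next }
    # biallelic: |p1-p2| + |(1-p1)-(1-p2)| = 2|p1-p2|, over 2L
    out[i, j] <- out[j, i] <- sum(abs(freq[i, ok] - freq[j, ok])) / L
  }
  out
}

#' Two-level AMOVA on squared genotype distances
#'
#' Partitions squared Euclidean distances between 0/1/2 genotype rows
#' (mean-imputed per locus) into among- and within-cluster components;
#' `Phi_ST` is the among-cluster fraction. Significance by permuting
#' individuals across clusters.
#'
#' @param G a [genotype_matrix()].
#' @param cluster_of named vector locality id -> cluster label.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return list with `phi_st`, `sigma2_among`, `sigma2_within`,
#'   `p_value`, `n_perm`.
#' @export
amova <- function(G, cluster_of, n_perm = 1000, seed = 1) {
  cl <- cluster_of[as.character(G$locality_of)]
  if (any(is.na(cl))) stop("locality missing from cluster map")
  if (length(unique(cl)) < 2) stop("need at least 2 clusters")
  if (any(table(cl) < 2)) stop("cluster with a single individual")
  M <- .impute_mean(G$calls)
  d2 <- as.matrix(dist(M))^2
  phi_obs <- .amova_phi(d2, cl)
  set.seed(as.integer(seed))
  n_ge <- 0
  for (b in seq_len(n_perm)) {
    phi_b <- .amova_phi(d2, sample(cl))
    if (!is.na(phi_b$phi) && phi_b$phi >= phi_obs$phi) n_ge <- n_ge + 1
  }
  list(phi_st = phi_obs$phi, sigma2_among = phi_obs$s2a,
       sigma2_within = phi_obs$s2w,
       p_value = (1 + n_ge) / (n_perm + 1), n_perm = n_perm)
}

.amova_phi <- function(d2, cl) {
  N <- nrow(d2)
  groups <- split(seq_len(N), cl)
  g <- length(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- sum(vapply(groups, function(ix) {
    if (length(ix) < 2) return(0)
    sum(d2[ix, ix][upper.tri(d2[ix, ix])]) / length(ix)
  }, numeric(1)))
  ss_among <- ss_total - ss_within
  df_a <- g - 1
  df_w <- N - g
  ms_a <- ss_among / df_a
  ms_w <- ss_within / df_w
  n0 <- (N - sum(vapply(groups, length, 1)^2) / N) / df_a
  s2w <- ms_w
  s2a <- (ms_a - ms_w) / n0
  list(phi = s2a / (s2a + s2w), s2a = s2a, s2w = s2w)
}

.impute_mean <- function(calls) {
  M <- calls
  mode(M) <- "double"
  mu <- colMeans(M, na.rm = TRUE)
  keep <- !is.nan(mu)
  M <- M[, keep, drop = FALSE]
  mu <- mu[keep]
  idx <- which(is.na(M), arr.ind = TRUE)
  if (nrow(idx)) M[idx] <- mu[idx[, 2]]
  M
}

#' Principal coordinate analysis of genotypes
#'
#' Missing calls are imputed with the locus mean allele value, then
#' classical PCoA (double-centred Euclidean distances) is applied.
#'
#' @param G a [genotype_matrix()].
#' @param k number of axes returned (default all positive-eigenvalue
#'   axes).
#' @return list with `coords` (individuals x axes), `eig`
#'   (eigenvalues), `pct_var` (percent variance per positive axis).
#' @export
pcoa_genotypes <- function(G, k = NULL) {
  M <- .impute_mean(G$calls)
  if (nrow(M) < 3) stop("need at least 3 individuals")
  d <- dist(M)
  n <- nrow(M)
  res <- cmdscale(d, k = n - 1, eig = TRUE)
  eig <- res$eig
  pos <- eig > 1e-8
  if (is.null(k)) k <- sum(pos)
  k <- min(k, ncol(res$points))
  coords <- res$points[, seq_len(k), drop = FALSE]
  rownames(coords) <- rownames(M)
  list(coords = coords, eig = eig,
       pct_var = 100 * eig[pos] / sum(eig[pos]))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the upper-triangle entries; the null
#' distribution permutes rows and columns of `D2` simultaneously.
#' One-sided p for positive association with the add-one convention.
#'
#' @param D1,D2 symmetric matrices with identical dimnames order.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return list with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(D1, D2, n_perm = 999, seed = 1) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  if (!all(dim(D1) == dim(D2))) stop("dimension mismatch")
  if (!is.null(dimnames(D1)) && !is.null(dimnames(D2)) &&
      !identical(rownames(D1), rownames(D2)))
    stop("label order mismatch")
  ut <- upper.tri(D1)
  v1 <- D1[ut]
  if (sd(v1) == 0 || sd(D2[ut]) == 0) stop("constant distance matrix")
  r_obs <- cor(v1, D2[ut])
  set.seed(as.integer(seed))
  n <- nrow(D1)
  n_ge <- 0
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    r_b <- cor(v1, D2[perm, perm][ut])
    if (r_b >= r_obs) n_ge <- n_ge + 1
  }
  list(r = r_obs, p = (1 + n_ge) / (n_perm + 1), n_perm = n_perm)
}
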