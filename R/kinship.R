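#' Pairwise relatedness (Wang moment estimator)
#'
#' Moment estimator built on the genotype similarity categories of a
#' pair at each locus (identical genotypes; homozygote-heterozygote
#' sharing an allele; no shared allele) whose expectations are linear in
#' the pair's one- and two-pair IBD coefficients (phi, delta). The
#' population allele-moment terms a2, a3, a4 are estimated from the full
#' sample with factorial-moment (small-sample) bias corrections, loci
#' are weighted by the inverse of `u = 2*a2 - a3` (down-weighting
#' near-fixed, uninformative loci), the category equations are solved
#' per pair, and relatedness is `phi/2 + delta`. Loci with a missing
#' call in either individual are skipped pairwise.
#'
#' @param G a [genotype_matrix()].
#' @param min_loci pairs sharing fewer informative loci are flagged
#'   unreliable.
#' @param freq optional vector of known population alternate-allele
#'   frequencies per locus; when supplied the allele-moment terms use
#'   them directly (no small-sample correction needed). When absent,
#'   frequencies come from the full sample with factorial-moment bias
#'   corrections; note that sample-referenced estimates centre the mean
#'   pairwise relatedness within the sample near `-1/(n-1)` rather than
#'   0.
#' @return list with `r` (symmetric relatedness matrix), `phi`, `delta`,
#'   `n_loci` (informative loci per pair) and `unreliable` (logical
#'   matrix).
#' @export
wang_relatedness <- function(G, min_loci = 20, freq = NULL) {
  calls <- G$calls
  n <- nrow(calls); L <- ncol(calls)
  if (n < 2) stop("need at least 2 individuals")

  # allele-moment terms per locus
  a2 <- a3 <- a4 <- rep(NA_real_, L)
  if (!is.null(freq)) {
    if (length(freq) != L) stop("freq must have one entry per locus")
    usable <- !is.na(freq) & freq > 0 & freq < 1
    pm <- cbind(freq, 1 - freq)
    a2 <- rowSums(pm^2)
    a3 <- rowSums(pm^3)
    a4 <- rowSums(pm^4)
  } else {
    # sample counts with factorial-moment (small-sample) corrections
    cnt1 <- colSums(calls, na.rm = TRUE)          # alt allele count
    S <- 2 * colSums(!is.na(calls))               # genes sampled
    usable <- S >= 4 & cnt1 > 0 & cnt1 < S        # polymorphic, enough genes
    for (l in which(usable)) {
      m <- c(cnt1[l], S[l] - cnt1[l])             # counts of the 2 alleles
      s <- S[l]
      a2[l] <- sum(m * (m - 1)) / (s * (s - 1))
      a3[l] <- sum(m * (m - 1) * (m - 2)) / (s * (s - 1) * (s - 2))
      a4[l] <- sum(m * (m - 1) * (m - 2) * (m - 3)) /
        (s * (s - 1) * (s - 2) * (s - 3))
    }
  }
  b <- 2 * a2^2 - a4
  cc <- a2 - 2 * a2^2 + a4
  d <- 4 * (a3 - a4)
  e <- 2 * (a2 - 3 * a3 + 2 * a4)
  u <- 2 * a2 - a3
  w <- ifelse(usable & u > 0, 1 / u, 0)

  r_mat <- phi_mat <- del_mat <- matrix(NA_real_, n, n,
                                        dimnames = list(rownames(calls),
                                                        rownames(calls)))
  nl_mat <- matrix(0L, n, n, dimnames = dimnames(r_mat))
  for (i in seq_len(n - 1)) {
    gi <- calls[i, ]
    for (j in (i + 1):n) {
      gj <- calls[j, ]
      ok <- !is.na(gi) & !is.na(gj) & usable & w > 0
      nl <- sum(ok)
      nl_mat[i, j] <- nl_mat[j, i] <- nl
      if (nl == 0) next
      g1 <- gi[ok]; g2 <- gj[ok]
      # similarity categories (biallelic): cat1 identical genotypes;
      # cat2 hom + het sharing an allele; cat4 opposite homozygotes
      cat1 <- g1 == g2
      cat2 <- (g1 == 1) != (g2 == 1)               # exactly one heterozygote
      wk <- w[ok]
      W <- sum(wk)
      P1 <- sum(wk * cat1) / W
      P2 <- sum(wk * cat2) / W
      bw <- sum(wk * b[ok]) / W
      cw <- sum(wk * cc[ok]) / W
      dw <- sum(wk * d[ok]) / W
      ew <- sum(wk * e[ok]) / W
      # solve  cw*phi + (1-bw)*delta = P1 - bw
      #        ew*phi -      dw*delta = P2 - dw
      det <- -(cw * dw + ew * (1 - bw))
      if (abs(det) < 1e-14) next
      phi <- (-(P1 - bw) * dw - (1 - bw) * (P2 - dw)) / det
      del <- (ew * (P1 - bw) - cw * (P2 - dw)) / -det
      r_mat[i, j] <- r_mat[j, i] <- phi / 2 + del
      phi_mat[i, j] <- phi_mat[j, i] <- phi
      del_mat[i, j] <- del_mat[j, i] <- del
    }
  }
  list(r = r_mat, phi = phi_mat, delta = del_mat, n_loci = nl_mat,
       unreliable = nl_mat < min_loci)
}

#' Remove one member of each putative full-sib pair
#'
#' Among same-locality pairs with relatedness at or above `threshold`,
#' one random member per qualifying pair is removed iteratively until no
#' qualifying pair remains. Deterministic under `seed`; the removal
#' order is logged.
#'
#' @param K output of [wang_relatedness()] (or any symmetric relatedness
#'   matrix in `K$r`).
#' @param locality_of named vector individual -> locality.
#' @param threshold full-sib calling threshold.
#' @param seed RNG seed.
#' @return list with `retained` ids, `removed` ids (in removal order)
#'   and `n_pairs` (qualifying pairs found initially).
#' @export
filter_fullsibs <- function(K, locality_of, threshold = 0.5, seed = 1) {
  r <- if (is.list(K)) K$r else K
  ids <- rownames(r)
  loc <- locality_of[ids]
  same_loc <- outer(loc, loc, "==")
  qual <- !is.na(r) & r >= threshold & same_loc
  diag(qual) <- FALSE
  n_pairs0 <- sum(qual[upper.tri(qual)])
  set.seed(as.integer(seed))
  active <- rep(TRUE, length(ids))
  removed <- character(0)
  repeat {
    q <- qual & outer(active, active, "&")
    pr <- which(q & upper.tri(q), arr.ind = TRUE)
    if (nrow(pr) == 0) break
    pick <- pr[sample.int(nrow(pr), 1), ]
    victim <- pick[[sample.int(2, 1)]]
    active[victim] <- FALSE
    removed <- c(removed, ids[victim])
  }
  list(retained = ids[active], removed = removed, n_pairs = n_pairs0)
}

#' Cross-locality kin edges
#'
#' Pairs of individuals from different localities with relatedness at or
#' above `threshold`; such pairs are candidate recent dispersal events.
#'
#' @param K output of [wang_relatedness()].
#' @param locality_of named vector individual -> locality.
#' @param threshold edge threshold.
#' @return data frame `id1`, `id2`, `loc1`, `loc2`, `r`.
#' @export
kin_edges <- function(K, locality_of, threshold = 0.35) {
  r <- K$r
  ids <- rownames(r)
  loc <- locality_of[ids]
  sel <- which(!is.na(r) & r >= threshold & upper.tri(r) &
                 outer(loc, loc, "!="), arr.ind = TRUE)
  data.frame(id1 = ids[sel[, 1]], id2 = ids[sel[, 2]],
             loc1 = loc[sel[, 1]], loc2 = loc[sel[, 2]],
             r = r[sel], stringsAsFactors = FALSE)
}
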