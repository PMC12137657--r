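#' Bayesian admixture clustering (Gibbs sampler)
#'
#' Admixture model with uncorrelated allele frequencies: cluster
#' frequencies carry Beta(1, 1) priors, each allele copy a latent
#' cluster label, and individual admixture a symmetric Dirichlet(alpha)
#' prior with alpha = 1. Returns the posterior-mean admixture matrix and
#' the mean observed-data log-likelihood over retained iterations.
#'
#' @param G a [genotype_matrix()].
#' @param K number of clusters (>= 1, <= individuals).
#' @param n_burn,n_iter burn-in and retained iterations.
#' @param seed RNG seed.
#' @param alpha Dirichlet concentration of admixture proportions.
#' @return object of class `qmatrix`: list with `q` (individuals x K,
#'   rows sum to 1), `mean_lnl`, `K`.
#' @export
admixture_mcmc <- function(G, K, n_burn = 100, n_iter = 400, seed = 1,
                           alpha = 1) {
  n <- nrow(G$calls)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K exceeds the number of individuals")
  calls <- G$calls
  calls[is.na(calls)] <- -1L
  if (K == 1) {
    # no latent structure: q is trivially 1; lnl from observed frequencies
    p <- colMeans(G$calls, na.rm = TRUE) / 2
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    lnl <- 0
    for (l in seq_len(ncol(calls))) {
      g <- G$calls[, l]
      g <- g[!is.na(g)]
      lnl <- lnl + sum(ifelse(g == 1, log(2) + log(p[l]) + log(1 - p[l]),
                              ifelse(g == 2, 2 * log(p[l]),
                                     2 * log(1 - p[l]))))
    }
    q <- matrix(1, n, 1, dimnames = list(rownames(G$calls), NULL))
    return(structure(list(q = q, mean_lnl = lnl, K = 1L),
                     class = "qmatrix"))
  }
  set.seed(as.integer(seed))
  res <- .admixture_chain_cpp(calls, K, n_burn, n_iter, alpha)
  q <- res$q
  rownames(q) <- rownames(G$calls)
  structure(list(q = q, mean_lnl = res$mean_lnl, K = as.integer(K)),
            class = "qmatrix")
}

#' @export
print.qmatrix <- function(x, ...) {
  cat("qmatrix: K =", x$K, "; mean ln L =", format(x$mean_lnl), "\n")
  invisible(x)
}

# Align columns of q2 to q1 by the cluster permutation maximising the
# summed column correlation (exhaustive for K <= 8).
.align_q <- function(q1, q2) {
  K <- ncol(q1)
  if (K == 1) return(q2)
  if (K > 8) stop("exhaustive alignment supported for K <= 8")
  perms <- .permutations(K)
  best <- NULL; best_score <- -Inf
  for (i in seq_len(nrow(perms))) {
    pm <- perms[i, ]
    score <- sum(vapply(seq_len(K), function(k) {
      s1 <- sd(q1[, k]); s2 <- sd(q2[, pm[k]])
      if (s1 == 0 || s2 == 0) return(1 - mean(abs(q1[, k] - q2[, pm[k]])))
      cor(q1[, k], q2[, pm[k]])
    }, numeric(1)))
    if (score > best_score) { best_score <- score; best <- pm }
  }
  q2[, best, drop = FALSE]
}

.permutations <- function(K) {
  if (K == 1) return(matrix(1, 1, 1))
  sub <- .permutations(K - 1)
  out <- NULL
  for (pos in seq_len(K)) {
    left <- if (pos > 1) sub[, 1:(pos - 1), drop = FALSE] else NULL
    right <- if (pos <= K - 1) sub[, pos:(K - 1), drop = FALSE] else NULL
    out <- rbind(out, cbind(left, K, right))
  }
  unname(out)
}

#' Consolidate replicate admixture runs at one K
#'
#' Runs are label-aligned to the first run (clusters are exchangeable
#' across runs) and averaged element-wise; rows are renormalised.
#'
#' @param runs list of `qmatrix` objects at the same K.
#' @return consolidated `qmatrix` (mean_lnl = mean over runs).
#' @export
consolidate_runs <- function(runs) {
  if (length(runs) == 1) return(runs[[1]])
  K <- runs[[1]]$K
  n <- nrow(runs[[1]]$q)
  for (r in runs)
    if (r$K != K || nrow(r$q) != n) stop("inconsistent run dimensions")
  acc <- runs[[1]]$q
  for (r in runs[-1]) acc <- acc + .align_q(runs[[1]]$q, r$q)
  q <- acc / length(runs)
  q <- q / rowSums(q)
  structure(list(q = q, mean_lnl = mean(vapply(runs, `[[`, 0, "mean_lnl")),
                 K = K), class = "qmatrix")
}

#' Evanno delta-K model choice
#'
#' From replicate mean log-likelihoods per K: `L'(K) = L(K) - L(K-1)`,
#' `|L''(K)| = |L'(K+1) - L'(K)|`, `deltaK = |L''(K)| / SD(L(K))`. The
#' best K is the interior argmax of deltaK; if no interior K has a
#' defined positive curvature the result is "indeterminate" (`NA`).
#'
#' @param lnl_by_k named list: K value (as character of integer) ->
#'   numeric vector of replicate mean log-likelihoods.
#' @return list with `table` (data frame K, mean_lnl, sd_lnl, lprime,
#'   lsecond, delta_k) and `best_k` (integer or NA).
#' @export
evanno_delta_k <- function(lnl_by_k) {
  Ks <- sort(as.integer(names(lnl_by_k)))
  if (length(Ks) < 3) stop("need at least 3 consecutive K values")
  if (any(diff(Ks) != 1)) stop("K values must be consecutive")
  mean_l <- vapply(as.character(Ks), function(k) mean(lnl_by_k[[k]]), 0)
  sd_l <- vapply(as.character(Ks), function(k) sd(lnl_by_k[[k]]), 0)
  nK <- length(Ks)
  lprime <- c(NA, diff(mean_l))
  lsecond <- rep(NA_real_, nK)
  for (i in 2:(nK - 1)) lsecond[i] <- abs(lprime[i + 1] - lprime[i])
  delta <- rep(NA_real_, nK)
  for (i in 2:(nK - 1)) {
    if (is.na(sd_l[i]) || sd_l[i] == 0) {
      warning("zero SD at K = ", Ks[i], "; deltaK undefined there")
      next
    }
    delta[i] <- lsecond[i] / sd_l[i]
  }
  tab <- data.frame(K = Ks, mean_lnl = mean_l, sd_lnl = sd_l,
                    lprime = lprime, lsecond = lsecond, delta_k = delta)
  rownames(tab) <- NULL
  interior <- which(!is.na(delta) & delta > 1e-8)
  best_k <- if (length(interior) == 0) NA_integer_ else
    Ks[interior[which.max(delta[interior])]]
  list(table = tab, best_k = best_k)
}

#' Hierarchical admixture clustering with locality assignment
#'
#' Level 1: run replicate admixture chains over `K = 1..max_k`, choose K
#' by the Evanno method, consolidate runs and assign each locality to
#' the cluster where its individuals' mean q is >= `q_threshold` (else
#' unassigned). Each cluster with >= 2 localities is then re-analysed
#' for substructure; recursion stops when the best K is 1 or
#' indeterminate.
#'
#' @param G a [genotype_matrix()].
#' @param q_threshold locality assignment threshold on mean q.
#' @param max_k largest K examined.
#' @param replicates admixture runs per K.
#' @param n_burn,n_iter MCMC sizes per run.
#' @param seed RNG seed.
#' @param max_depth recursion cap.
#' @return nested list: each node has `k` (chosen K, NA if
#'   indeterminate), `q` (consolidated locality-level means), `members`
#'   (locality -> cluster label or "unassigned") and `children`.
#' @export
hierarchical_clustering <- function(G, q_threshold = 0.6, max_k = 6,
                                    replicates = 3, n_burn = 60,
                                    n_iter = 240, seed = 1,
                                    max_depth = 2) {
  .cluster_node(G, q_threshold, max_k, replicates, n_burn, n_iter,
                seed, depth = 1, max_depth = max_depth)
}

.cluster_node <- function(G, q_threshold, max_k, replicates, n_burn,
                          n_iter, seed, depth, max_depth) {
  n <- nrow(G$calls)
  kmax <- min(max_k, n - 1)
  lnl_by_k <- list()
  cons <- list()
  for (K in seq_len(kmax)) {
    runs <- lapply(seq_len(replicates), function(r)
      admixture_mcmc(G, K, n_burn, n_iter, seed = seed + 1000 * K + r))
    lnl_by_k[[as.character(K)]] <- vapply(runs, `[[`, 0, "mean_lnl")
    cons[[as.character(K)]] <- consolidate_runs(runs)
  }
  best_k <- if (kmax >= 3) evanno_delta_k(lnl_by_k)$best_k else NA_integer_
  # deltaK cannot assess K = 1; require a material likelihood gain over
  # the unstructured model (1% of |ln L|) before accepting any K > 1
  if (!is.na(best_k) && best_k > 1) {
    l1 <- mean(lnl_by_k[["1"]])
    lb <- mean(lnl_by_k[[as.character(best_k)]])
    if (lb - l1 < 0.01 * abs(l1)) best_k <- 1L
  }
  node <- list(k = best_k, q = NULL, members = NULL, children = list())
  if (is.na(best_k) || best_k == 1) return(node)
  qm <- cons[[as.character(best_k)]]
  # locality-level mean q and threshold assignment
  loc <- G$locality_of
  locs <- sort(unique(loc))
  qloc <- t(vapply(locs, function(lc)
    colMeans(qm$q[loc == lc, , drop = FALSE]), numeric(best_k)))
  rownames(qloc) <- locs
  assign <- apply(qloc, 1, function(v)
    if (max(v) >= q_threshold) which.max(v) else NA_integer_)
  members <- ifelse(is.na(assign), "unassigned",
                    paste0("cluster", assign))
  names(members) <- locs
  node$q <- qloc
  node$members <- members
  if (depth < max_depth) {
    for (k in seq_len(best_k)) {
      sub_locs <- locs[!is.na(assign) & assign == k]
      if (length(sub_locs) < 2) next
      keep <- loc %in% sub_locs
      if (sum(keep) < 4) next
      subG <- genotype_matrix(G$calls[keep, , drop = FALSE],
                              G$locality_of[keep])
      node$children[[paste0("cluster", k)]] <-
        .cluster_node(subG, q_threshold, max_k, replicates, n_burn,
                      n_iter, seed + 17 * k, depth + 1, max_depth)
    }
  }
  node
}
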