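# Differentiation of a deme against a hypothetical pool, multilocus:
# Nei's G_ST and Jost's D from mean within/total heterozygosities.
# Returns c(gst, d) or NA when every shared locus is monomorphic.
.pool_differentiation <- function(px, ppool, eps = 1e-12) {
  ok <- !is.na(px) & !is.na(ppool)
  if (!any(ok)) return(c(NA, NA))
  px <- px[ok]; ppool <- ppool[ok]
  hx <- 2 * px * (1 - px)
  hp <- 2 * ppool * (1 - ppool)
  pb <- (px + ppool) / 2
  ht <- mean(2 * pb * (1 - pb))
  hs <- mean((hx + hp) / 2)
  if (ht <= eps) return(c(NA, NA))
  gst <- max((ht - hs) / ht, eps)
  d <- max(2 * (ht - hs) / (1 - hs), eps)   # n/(n-1) with n = 2 demes
  c(gst, d)
}

# Composite Nm combining the G_ST- and D-based migration transforms
# (geometric mean of the two Wright-style conversions).
.nm_alcala <- function(gst, d) {
  nm_g <- (1 / gst - 1) / 4
  nm_d <- (1 / d - 1) / 4
  sqrt(pmax(nm_g, 0) * pmax(nm_d, 0))
}

#' Directional relative migration rates between localities
#'
#' For every ordered locality pair (a, b) a hypothetical pool with
#' allele frequencies averaged from a and b is formed; the
#' differentiation of each member from the pool is converted to an Nm
#' value via a composite of G_ST and Jost's D, and the directional rate
#' a -> b is the Nm derived from b's differentiation from the pool (a
#' deme receiving many migrants resembles the pool). All rates are
#' divided by the global maximum, so the largest rate is 1.
#'
#' @param G a [genotype_matrix()].
#' @param min_n minimum genotyped individuals per locality.
#' @return list with `m` (directed rate matrix, rows = from, cols = to,
#'   `NA` diagonal), `raw` (unnormalised Nm), `statistic`.
#' @export
directional_migration <- function(G, min_n = 2) {
  lf <- locality_frequencies(G)
  keep <- rowSums(lf$n >= 1) > 0 &
    vapply(rownames(lf$freq),
           function(l) sum(G$locality_of == l) >= min_n, TRUE)
  freq <- lf$freq[keep, , drop = FALSE]
  locs <- rownames(freq)
  K <- length(locs)
  if (K < 2) stop("need at least 2 localities with enough individuals")
  raw <- matrix(NA_real_, K, K, dimnames = list(locs, locs))
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    pool <- (freq[i, ] + freq[j, ]) / 2
    di <- .pool_differentiation(freq[i, ], pool)
    dj <- .pool_differentiation(freq[j, ], pool)
    if (any(is.na(c(di, dj)))) next                 # monomorphic pair
    # the rate INTO a deme reflects that deme's closeness to the pool
    raw[i, j] <- .nm_alcala(dj[1], dj[2])   # i -> j from j vs pool
    raw[j, i] <- .nm_alcala(di[1], di[2])   # j -> i from i vs pool
  }
  mx <- max(raw, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) stop("no defined migration rates")
  list(m = raw / mx, raw = raw, statistic = "Nm_Alcala")
}

#' Per-locality immigration/emigration summary
#'
#' `I(a)` is the mean rate into a (column mean), `E(a)` the mean rate
#' out of a (row mean), and `R_I/E = I/E` (`NA` when E = 0).
#'
#' @param M output of [directional_migration()] (or a directed rate
#'   matrix).
#' @return data frame `locality_id`, `I`, `E`, `R_IE`.
#' @export
migration_summary <- function(M) {
  m <- if (is.list(M)) M$m else M
  I <- colMeans(m, na.rm = TRUE)
  E <- rowMeans(m, na.rm = TRUE)
  R <- ifelse(E > 0, I / E, NA_real_)
  data.frame(locality_id = rownames(m), I = I, E = E, R_IE = R,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare a statistic between two clusters (Mann-Whitney U)
#'
#' Exact test for combined n <= 20 without ties; tie-corrected normal
#' approximation otherwise. Two-sided.
#'
#' @param values numeric vector (e.g. per-locality R_I/E).
#' @param cluster factor/vector with exactly two levels, aligned with
#'   `values`.
#' @return list with `W` (U statistic of the first group), `p`,
#'   `method`.
#' @export
compare_clusters <- function(values, cluster) {
  cluster <- as.factor(cluster)
  if (nlevels(cluster) != 2) stop("need exactly two clusters")
  g1 <- values[cluster == levels(cluster)[1]]
  g2 <- values[cluster == levels(cluster)[2]]
  if (length(g1) < 2 || length(g2) < 2) stop("each group needs n >= 2")
  exact <- (length(g1) + length(g2)) <= 20 &&
    !any(duplicated(c(g1, g2)))
  ht <- suppressWarnings(wilcox.test(g1, g2, exact = exact,
                                     correct = !exact))
  list(W = unname(ht$statistic), p = ht$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Immigration/emigration ratio versus distance to the nearest source
#'
#' Ordinary least squares of R_I/E on the Euclidean distance to the
#' nearest inferred source, with Cook's distances so influential
#' localities are identifiable.
#'
#' @param summary output of [migration_summary()].
#' @param localities data frame `locality_id`, `x`, `y`.
#' @param sources matrix/data frame of source coordinates (`x`, `y`).
#' @param drop optional locality ids excluded before fitting.
#' @return list with `slope`, `t`, `p`, `cooks` (named per locality),
#'   `fit` (the `lm` object), `distances`.
#' @export
ratio_vs_source_distance <- function(summary, localities, sources,
                                     drop = NULL) {
  df <- merge(summary, localities[, c("locality_id", "x", "y")],
              by = "locality_id")
  if (!is.null(drop)) df <- df[!(df$locality_id %in% drop), , drop = FALSE]
  df <- df[!is.na(df$R_IE), , drop = FALSE]
  if (nrow(df) < 3) stop("need at least 3 localities after drops")
  src <- as.matrix(as.data.frame(sources)[, c("x", "y")])
  dist_src <- vapply(seq_len(nrow(df)), function(i)
    min(sqrt((src[, 1] - df$x[i])^2 + (src[, 2] - df$y[i])^2)),
    numeric(1))
  if (sd(dist_src) == 0) stop("all distances equal; slope undefined")
  fit <- lm(df$R_IE ~ dist_src)
  sm <- summary(fit)$coefficients
  list(slope = sm[2, 1], t = sm[2, 3], p = sm[2, 4],
       cooks = setNames(cooks.distance(fit), df$locality_id),
       fit = fit,
       distances = setNames(dist_src, df$locality_id))
}
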