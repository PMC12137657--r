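#' Thin occurrence records for geographic profiling
#'
#' Records after `cutoff_year` are removed (post-ban observations are
#' assumed to reflect natural dispersal, and the profiler ignores
#' chronology anyway); the remainder are clustered by single linkage at
#' `dedup_radius` and only the earliest record per cluster is kept (year
#' ties broken by smallest id).
#'
#' @param records occurrence data frame (`id`, `x`, `y`, `year`).
#' @param cutoff_year last year retained.
#' @param dedup_radius single-linkage merge radius in metres.
#' @return thinned records data frame.
#' @export
thin_records <- function(records, cutoff_year = 2009, dedup_radius = 200) {
  if (dedup_radius <= 0) stop("dedup_radius must be positive")
  rec <- records[records$year <= cutoff_year, , drop = FALSE]
  if (nrow(rec) == 0) return(rec)
  if (nrow(rec) == 1) { rownames(rec) <- NULL; return(rec) }
  d <- dist(rec[, c("x", "y")])
  cl <- cutree(hclust(d, method = "single"), h = dedup_radius)
  keep <- vapply(split(seq_len(nrow(rec)), cl), function(ix) {
    sub <- rec[ix, , drop = FALSE]
    ix[order(sub$year, sub$id)][1]
  }, integer(1))
  out <- rec[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct the dispersal-scale prior
#'
#' An inverse-gamma prior on sigma^2 with the given shape; the scale is
#' chosen so the implied distribution of sigma has the requested mean.
#' The (mean, variance, shape) triple is over-determined, so the
#' achieved variance of sigma is reported and a warning is raised when
#' it differs from the request by more than 1%.
#'
#' @param mean_km prior mean of sigma, km.
#' @param variance_km2 requested prior variance of sigma, km^2.
#' @param shape inverse-gamma shape (> 1 so the variance is finite).
#' @return list of class `sigma_prior` with inverse-gamma parameters
#'   `a0`, `b0` (on sigma^2, km^2), the achieved variance, and
#'   `density(s)` over sigma in km.
#' @export
sigma_prior <- function(mean_km = 5, variance_km2 = 10, shape = 1.5) {
  if (mean_km <= 0 || variance_km2 <= 0 || shape <= 0)
    stop("mean, variance and shape must be positive")
  if (shape <= 1)
    stop("shape must exceed 1 for sigma to have finite mean and variance")
  a0 <- shape
  # E[sigma] = sqrt(b0) * gamma(a0 - 1/2) / gamma(a0)
  b0 <- (mean_km * exp(lgamma(a0) - lgamma(a0 - 0.5)))^2
  achieved_var <- b0 / (a0 - 1) - mean_km^2
  if (abs(achieved_var - variance_km2) / variance_km2 > 0.01)
    warning(sprintf(paste0("prior (mean, variance, shape) over-determined; ",
                           "honouring mean and shape gives variance %.3f ",
                           "km^2 (requested %.3f)"),
                    achieved_var, variance_km2))
  dens <- function(s)
    ifelse(s > 0,
           2 * exp(a0 * log(b0) - lgamma(a0) - (2 * a0 + 1) * log(s) - b0 / s^2),
           0)
  structure(list(mean_km = mean_km, variance_km2 = variance_km2,
                 shape = shape, a0 = a0, b0 = b0,
                 achieved_variance_km2 = achieved_var, density = dens),
            class = "sigma_prior")
}

#' Run the Dirichlet-process-mixture geographic profiler
#'
#' Records are modelled as draws from a mixture of bivariate normal
#' sources with shared scale sigma; the number of sources follows a
#' Chinese restaurant process with concentration `alpha`. The source
#' centre prior is uniform on the record bounding box expanded by a
#' `guard_km` band. Multiple chains are run from one seeded RNG stream.
#'
#' @param records thinned occurrence data frame (`x`, `y` in metres),
#'   at least 3 rows.
#' @param prior a [sigma_prior()].
#' @param n_burn,n_sample burn-in and retained iterations per chain.
#' @param n_chains number of MCMC chains.
#' @param cell_m surface cell size in metres.
#' @param seed RNG seed.
#' @param alpha CRP concentration.
#' @param guard_km guard band around the record bounding box, km.
#' @param m_aux auxiliary components per reallocation sweep.
#' @return object of class `geoprofile_result`: `sigma_samples` (km,
#'   samples x chains), `k_posterior`, `surface` and `hit_scores`
#'   ([raster_grid()]s), `gelman_rubin`, `source_estimates`, `k_mode`,
#'   `sigma_mean_km`, `sigma_ci_km`.
#' @export
run_dpm <- function(records, prior = sigma_prior(), n_burn = 1000,
                    n_sample = 10000, n_chains = 5, cell_m = 250,
                    seed = 1, alpha = 1, guard_km = 10, m_aux = 3) {
  if (nrow(records) < 3) stop("need at least 3 records")
  if (n_burn < 1 || n_sample < 1) stop("n_burn and n_sample must be >= 1")
  guard <- guard_km * 1000
  xr <- range(records$x); yr <- range(records$y)
  frame <- c(xr[1] - guard, xr[2] + guard, yr[1] - guard, yr[2] + guard)
  n_cols <- max(1L, ceiling((frame[2] - frame[1]) / cell_m))
  n_rows <- max(1L, ceiling((frame[4] - frame[3]) / cell_m))
  X <- as.matrix(records[, c("x", "y")])
  b0_m2 <- prior$b0 * 1e6
  set.seed(as.integer(seed))
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    chains[[ch]] <- .dpm_chain_cpp(X, frame, alpha, prior$a0, b0_m2,
                                   n_burn, n_sample, m_aux,
                                   frame[1], frame[3], cell_m,
                                   n_rows, n_cols,
                                   sigma2_init = (prior$mean_km * 1000)^2)
    if (any(!is.finite(chains[[ch]]$sigma)))
      stop("non-finite sigma sample; check record coordinates")
  }
  sigma_km <- vapply(chains, function(c) c$sigma / 1000,
                     numeric(n_sample))
  sigma_km <- matrix(sigma_km, ncol = n_chains)
  k_all <- unlist(lapply(chains, `[[`, "k"))
  k_tab <- table(k_all) / length(k_all)
  k_posterior <- setNames(as.numeric(k_tab), names(k_tab))
  surf_vals <- Reduce(`+`, lapply(chains, `[[`, "surface")) / n_chains
  surface <- raster_grid(frame[1], frame[3], cell_m, n_rows, n_cols,
                         surf_vals)
  hs <- hit_scores(surface)
  gr <- if (n_chains >= 2) gelman_rubin(sigma_km) else NA_real_
  k_mode <- as.integer(names(k_posterior)[which.max(k_posterior)])

  # source estimates: k-means on sampled centres from samples at the
  # modal component count, weighted by centre occupancy
  cent <- do.call(rbind, lapply(seq_along(chains), function(ch) {
    cc <- chains[[ch]]$centres
    kk <- chains[[ch]]$k
    cc[kk[cc$sample + 1] == k_mode, c("x", "y"), drop = FALSE]
  }))
  source_estimates <- if (nrow(cent) >= k_mode && k_mode >= 1) {
    if (k_mode == 1) {
      matrix(colMeans(cent), ncol = 2, dimnames = list(NULL, c("x", "y")))
    } else {
      km <- suppressWarnings(kmeans(cent, centers = k_mode, nstart = 5,
                                    iter.max = 50))
      unname(km$centers)
    }
  } else matrix(numeric(0), ncol = 2)

  structure(list(sigma_samples = sigma_km, k_posterior = k_posterior,
                 surface = surface, hit_scores = hs, gelman_rubin = gr,
                 source_estimates = source_estimates, k_mode = k_mode,
                 sigma_mean_km = mean(sigma_km),
                 sigma_ci_km = unname(quantile(sigma_km, c(0.025, 0.975))),
                 frame = frame, alpha = alpha),
            class = "geoprofile_result")
}

#' @export
print.geoprofile_result <- function(x, ...) {
  cat("geoprofile: modal source count", x$k_mode,
      sprintf("; sigma %.2f km [%.2f, %.2f]; R-hat %.4f\n",
              x$sigma_mean_km, x$sigma_ci_km[1], x$sigma_ci_km[2],
              x$gelman_rubin))
  invisible(x)
}

#' Hit-score surface from a posterior source-density surface
#'
#' The hit score of a cell is the proportion of the study area with
#' strictly higher posterior density, plus half the tied cells: the
#' fraction of the area to search before reaching that cell. Values lie
#' in (0, 1]; low scores mark likely source locations.
#'
#' @param surface a [raster_grid()] of posterior density.
#' @return [raster_grid()] of hit scores.
#' @export
hit_scores <- function(surface) {
  v <- surface$values
  ok <- !is.na(v)
  if (!any(ok)) stop("all-nodata surface")
  n <- sum(ok)
  vv <- v[ok]
  # rank-based: (# greater + 0.5 * # tied) / n
  r <- rank(-vv, ties.method = "average")   # 1 = highest
  hs <- (r - 0.5) / n
  out <- v
  out[ok] <- hs
  raster_grid(surface$x_origin, surface$y_origin, surface$cell_size,
              surface$n_rows, surface$n_cols, out, surface$nodata)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' `R_hat = sqrt(((n-1)/n * W + B/n) / W)` with `B` the between-chain
#' and `W` the mean within-chain variance.
#'
#' @param chains matrix (samples x chains) or list of equal-length
#'   numeric vectors.
#' @return the potential scale reduction factor.
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  m <- ncol(chains); n <- nrow(chains)
  if (m < 2) stop("need at least 2 chains")
  if (n < 10) stop("need at least 10 samples per chain")
  W <- mean(apply(chains, 2, var))
  if (W == 0) stop("zero within-chain variance")
  B <- n * var(colMeans(chains))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Extract the raster value at point locations
#'
#' @param grid a [raster_grid()].
#' @param xy two-column matrix of point coordinates (metres).
#' @return numeric vector (NA outside the grid or at nodata cells).
#' @export
raster_value_at <- function(grid, xy) {
  xy <- as.matrix(xy)
  col <- floor((xy[, 1] - grid$x_origin) / grid$cell_size) + 1
  row_b <- floor((xy[, 2] - grid$y_origin) / grid$cell_size) + 1
  row <- grid$n_rows - row_b + 1
  ok <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  out <- rep(NA_real_, nrow(xy))
  out[ok] <- grid$values[cbind(row[ok], col[ok])]
  out
}
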