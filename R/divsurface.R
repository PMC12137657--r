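#' Moving-window rarefied observed heterozygosity surface
#'
#' For each cell, all individuals within the surrounding `window` x
#' `window` cell block are pooled; when at least `rarefaction_n` are
#' available, the cell's Ho is the mean over `n_draws` seeded draws of
#' `rarefaction_n` individuals of their mean per-individual
#' heterozygosity (fraction of heterozygous calls among non-missing).
#' Rarefaction makes cells with different sampling intensity
#' comparable. Cells with too few individuals are nodata.
#'
#' @param G a [genotype_matrix()].
#' @param coords matrix/data frame of individual coordinates (`x`,
#'   `y`), rows aligned with `rownames(G$calls)`.
#' @param grid a [raster_grid()] template.
#' @param window window side, in cells.
#' @param rarefaction_n individuals per draw (>= 2).
#' @param n_draws rarefaction draws per cell.
#' @param seed RNG seed.
#' @return list of class `diversity_surface`: `grid` ([raster_grid()]
#'   of rarefied Ho), `window`, `rarefaction_n`, `n_ind` (individuals
#'   per window).
#' @export
windowed_heterozygosity <- function(G, coords, grid, window = 10,
                                    rarefaction_n = 5, n_draws = 100,
                                    seed = 1) {
  if (rarefaction_n < 2) stop("rarefaction_n must be >= 2")
  coords <- as.matrix(coords[, c("x", "y")])
  ind_het <- rowMeans(G$calls == 1, na.rm = TRUE)
  cs <- grid$cell_size
  col <- floor((coords[, 1] - grid$x_origin) / cs) + 1
  row_b <- floor((coords[, 2] - grid$y_origin) / cs) + 1
  half_lo <- floor((window - 1) / 2)
  half_hi <- window - 1 - half_lo
  vals <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  n_ind <- matrix(0L, grid$n_rows, grid$n_cols)
  set.seed(as.integer(seed))
  for (rb in seq_len(grid$n_rows)) {      # rb: row from bottom
    for (cl in seq_len(grid$n_cols)) {
      inside <- col >= cl - half_lo & col <= cl + half_hi &
        row_b >= rb - half_lo & row_b <= rb + half_hi
      m <- sum(inside)
      r_top <- grid$n_rows - rb + 1
      n_ind[r_top, cl] <- m
      if (m < rarefaction_n) next
      hets <- ind_het[inside]
      if (m == rarefaction_n) {
        vals[r_top, cl] <- mean(hets)
      } else {
        draws <- vapply(seq_len(n_draws), function(b)
          mean(hets[sample.int(m, rarefaction_n)]), numeric(1))
        vals[r_top, cl] <- mean(draws)
      }
    }
  }
  structure(list(grid = raster_grid(grid$x_origin, grid$y_origin, cs,
                                    grid$n_rows, grid$n_cols, vals),
                 window = window, rarefaction_n = rarefaction_n,
                 n_ind = n_ind),
            class = "diversity_surface")
}

# Fit an exponential semivariogram gamma(h) = sill * (1 - exp(-h/range))
# to empirical binned semivariances; returns c(sill, range).
.fit_exp_variogram <- function(coords, values, n_bins = 12) {
  d <- as.matrix(dist(coords))
  ut <- upper.tri(d)
  h <- d[ut]
  sv <- 0.5 * (outer(values, values, "-")^2)[ut]
  if (length(h) < 5 || max(h) == 0) return(NULL)
  breaks <- seq(0, max(h), length.out = n_bins + 1)
  bin <- cut(h, breaks, include.lowest = TRUE)
  hb <- tapply(h, bin, mean)
  gb <- tapply(sv, bin, mean)
  ok <- !is.na(hb) & !is.na(gb)
  if (sum(ok) < 3) return(NULL)
  hb <- hb[ok]; gb <- gb[ok]
  obj <- function(par) {
    sill <- exp(par[1]); rng <- exp(par[2])
    sum((gb - sill * (1 - exp(-hb / rng)))^2)
  }
  init <- c(log(max(gb, 1e-12)), log(max(hb) / 3))
  fit <- try(optim(init, obj), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  c(sill = exp(fit$par[1]), range = exp(fit$par[2]))
}

#' Fill a partial diversity surface by ordinary kriging
#'
#' Ordinary kriging with an exponential variogram fitted to the defined
#' cells (zero nugget: defined cells are reproduced exactly). If the
#' variogram fit fails the fill falls back to inverse-distance
#' weighting, flagged in the result.
#'
#' @param partial a `diversity_surface` (or [raster_grid()]) with
#'   defined and nodata cells.
#' @param max_neighbours kriging neighbourhood size cap.
#' @return `diversity_surface` with `grid` filled everywhere,
#'   `method` ("kriging" or "idw") and the variogram parameters.
#' @export
krige_surface <- function(partial, max_neighbours = 50) {
  grid <- if (inherits(partial, "diversity_surface")) partial$grid else partial
  v <- grid$values
  def <- which(!is.na(v), arr.ind = TRUE)
  if (nrow(def) < 5) stop("need at least 5 defined cells")
  centres <- raster_cell_centres(grid)
  px <- centres$x[def[, 2]]
  py <- centres$y[def[, 1]]
  pv <- v[def]
  vg <- if (var(pv) > 0) .fit_exp_variogram(cbind(px, py), pv) else NULL
  out <- v
  miss <- which(is.na(v), arr.ind = TRUE)
  method <- if (is.null(vg)) "idw" else "kriging"
  if (method == "kriging") {
    gamma_f <- function(h) vg["sill"] * (1 - exp(-h / vg["range"]))
    for (m in seq_len(nrow(miss))) {
      cx <- centres$x[miss[m, 2]]; cy <- centres$y[miss[m, 1]]
      d0 <- sqrt((px - cx)^2 + (py - cy)^2)
      use <- order(d0)[seq_len(min(max_neighbours, length(d0)))]
      k <- length(use)
      D <- as.matrix(dist(cbind(px[use], py[use])))
      A <- rbind(cbind(gamma_f(D), 1), c(rep(1, k), 0))
      bvec <- c(gamma_f(d0[use]), 1)
      w <- try(solve(A, bvec), silent = TRUE)
      if (inherits(w, "try-error")) {
        wt <- 1 / pmax(d0[use], 1e-6)^2
        out[miss[m, 1], miss[m, 2]] <- sum(wt * pv[use]) / sum(wt)
      } else {
        out[miss[m, 1], miss[m, 2]] <- sum(w[seq_len(k)] * pv[use])
      }
    }
  } else {
    for (m in seq_len(nrow(miss))) {
      cx <- centres$x[miss[m, 2]]; cy <- centres$y[miss[m, 1]]
      d0 <- pmax(sqrt((px - cx)^2 + (py - cy)^2), 1e-6)
      wt <- 1 / d0^2
      out[miss[m, 1], miss[m, 2]] <- sum(wt * pv) / sum(wt)
    }
  }
  res <- list(grid = raster_grid(grid$x_origin, grid$y_origin,
                                 grid$cell_size, grid$n_rows, grid$n_cols,
                                 out),
              method = method, variogram = vg)
  if (inherits(partial, "diversity_surface")) {
    res$window <- partial$window
    res$rarefaction_n <- partial$rarefaction_n
  }
  class(res) <- "diversity_surface"
  res
}

#' Correlate diversity with geoprofile hit scores at localities
#'
#' Extracts the interpolated Ho surface and the hit-score surface at
#' each locality's cell and reports the Pearson correlation with
#' `t = r * sqrt((n-2)/(1-r^2))` and its two-sided p. A significantly
#' negative correlation (low diversity far from sources) is the
#' serial-founder-effect signature; its absence is evidence for
#' long-distance dispersal or multiple introductions.
#'
#' @param surface `diversity_surface` (kriged).
#' @param hit a [raster_grid()] of hit scores on the SAME grid.
#' @param localities data frame `locality_id`, `x`, `y`.
#' @return list with `r`, `t`, `p`, `n`, `values` (per-locality pairs).
#' @export
correlate_ho_hitscore <- function(surface, hit, localities) {
  grid <- surface$grid
  if (grid$n_rows != hit$n_rows || grid$n_cols != hit$n_cols ||
      grid$cell_size != hit$cell_size ||
      grid$x_origin != hit$x_origin || grid$y_origin != hit$y_origin)
    stop("diversity and hit-score rasters are on different grids")
  xy <- as.matrix(localities[, c("x", "y")])
  ho <- raster_value_at(grid, xy)
  hs <- raster_value_at(hit, xy)
  ok <- !is.na(ho) & !is.na(hs)
  if (sum(ok) < 3) stop("need at least 3 localities on both surfaces")
  r <- cor(ho[ok], hs[ok])
  n <- sum(ok)
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(t), df = n - 2)
  list(r = r, t = t, p = p, n = n,
       values = data.frame(locality_id = localities$locality_id[ok],
                           Ho = ho[ok], hit_score = hs[ok]))
}
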