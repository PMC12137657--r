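#' Isolation-by-distance residuals between individual pairs
#'
#' Fits the distance-decay model `genetic = a + b * log(1 + geographic)`
#' by least squares over pairs closer than `d_max`, and returns each
#' pair's residual rescaled to \[-1, 1\] by the maximum absolute
#' residual. Positive residuals mark pairs more differentiated than
#' their distance predicts (candidate barriers between them), negative
#' residuals mark corridors.
#'
#' @param gen_d symmetric matrix of individual-pair genetic distances
#'   (e.g. [prevosti_distance()] on within-individual frequencies).
#' @param coords data frame/matrix of individual coordinates (`x`, `y`),
#'   rows aligned with `gen_d` labels.
#' @param d_max pair-inclusion cutoff, metres.
#' @return data frame of class `ibd_residuals`: `i`, `j`, `x1`, `y1`,
#'   `x2`, `y2`, `geo_d`, `gen_d`, `residual` (scaled); attributes
#'   `coef` (a, b) and `scale` (max |raw residual|).
#' @export
fit_ibd_residuals <- function(gen_d, coords, d_max) {
  gen_d <- as.matrix(gen_d)
  coords <- as.matrix(coords[, c("x", "y")])
  n <- nrow(gen_d)
  if (nrow(coords) != n) stop("coords/gen_d size mismatch")
  ut <- which(upper.tri(gen_d), arr.ind = TRUE)
  geo <- sqrt((coords[ut[, 1], 1] - coords[ut[, 2], 1])^2 +
                (coords[ut[, 1], 2] - coords[ut[, 2], 2])^2)
  gd <- gen_d[upper.tri(gen_d)]
  keep <- geo <= d_max & !is.na(gd)
  if (sum(keep) < 10) stop("fewer than 10 pairs within d_max")
  geo <- geo[keep]; gd <- gd[keep]; ut <- ut[keep, , drop = FALSE]
  if (sd(geo) == 0) stop("degenerate geometry: all pairs equidistant")
  X <- log1p(geo)
  fit <- lm(gd ~ X)
  res <- unname(residuals(fit))
  scale <- max(abs(res))
  if (scale < 1e-12) scale <- 1        # degenerate: perfect fit
  out <- data.frame(i = ut[, 1], j = ut[, 2],
                    x1 = coords[ut[, 1], 1], y1 = coords[ut[, 1], 2],
                    x2 = coords[ut[, 2], 1], y2 = coords[ut[, 2], 2],
                    geo_d = geo, gen_d = gd, residual = res / scale)
  attr(out, "coef") <- coef(fit)
  attr(out, "scale") <- scale
  class(out) <- c("ibd_residuals", "data.frame")
  out
}

#' Map landscape resistance from IBD residuals
#'
#' Each cell's resistance is the mean scaled residual of all pair
#' segments crossing it. Per cell, a null distribution is built by
#' drawing the same number of residuals from the full pool without
#' replacement `n_resample` times; the cell is classed `barrier` when
#' its observed mean exceeds the upper `1 - alpha/2` null quantile,
#' `corridor` below the `alpha/2` quantile, else `not-significant`.
#' Cells crossed by no segment are nodata.
#'
#' @param residuals output of [fit_ibd_residuals()].
#' @param grid a [raster_grid()] template (values ignored).
#' @param n_resample null draws per cell.
#' @param alpha two-sided significance level.
#' @param seed RNG seed.
#' @return list of class `resistance_surface`: `mean` ([raster_grid()]
#'   of mean residuals), `class` ([raster_grid()] with -1 corridor, 0
#'   not-significant, +1 barrier, NA where no segment crosses),
#'   `n_pairs` (segments per cell), `d_max` attributes carried through.
#' @export
map_resistance <- function(residuals, grid, n_resample = 1000,
                           alpha = 0.05, seed = 1) {
  n_cells <- grid$n_rows * grid$n_cols
  sums <- matrix(0, grid$n_rows, grid$n_cols)
  cnts <- matrix(0L, grid$n_rows, grid$n_cols)
  cell_members <- vector("list", n_cells)
  for (p in seq_len(nrow(residuals))) {
    cells <- segment_cells(residuals$x1[p], residuals$y1[p],
                           residuals$x2[p], residuals$y2[p], grid)
    if (nrow(cells) == 0) next
    for (q in seq_len(nrow(cells))) {
      r <- cells[q, 1]; c <- cells[q, 2]
      sums[r, c] <- sums[r, c] + residuals$residual[p]
      cnts[r, c] <- cnts[r, c] + 1L
      k <- (c - 1L) * grid$n_rows + r
      cell_members[[k]] <- c(cell_members[[k]], p)
    }
  }
  mean_v <- ifelse(cnts > 0, sums / cnts, NA_real_)
  pool <- residuals$residual
  cls <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  set.seed(as.integer(seed))
  for (r in seq_len(grid$n_rows)) for (c in seq_len(grid$n_cols)) {
    k <- cnts[r, c]
    if (k == 0) next
    if (k >= length(pool)) { cls[r, c] <- 0; next }
    null_means <- vapply(seq_len(n_resample), function(b)
      mean(pool[sample.int(length(pool), k)]), numeric(1))
    lo <- quantile(null_means, alpha / 2, names = FALSE)
    hi <- quantile(null_means, 1 - alpha / 2, names = FALSE)
    cls[r, c] <- if (mean_v[r, c] > hi) 1 else if (mean_v[r, c] < lo) -1 else 0
  }
  structure(list(
    mean = raster_grid(grid$x_origin, grid$y_origin, grid$cell_size,
                       grid$n_rows, grid$n_cols, mean_v),
    class = raster_grid(grid$x_origin, grid$y_origin, grid$cell_size,
                        grid$n_rows, grid$n_cols, cls),
    n_pairs = cnts, n_resample = n_resample, alpha = alpha),
    class = "resistance_surface")
}

#' Cells crossed by a segment
#'
#' Exact traversal: the segment parameter is split at every crossing of
#' a vertical or horizontal grid line and the midpoint of each piece is
#' mapped to its cell.
#'
#' @param x1,y1,x2,y2 segment endpoints, metres.
#' @param grid a [raster_grid()].
#' @return integer matrix with columns `row`, `col` (row 1 = top row).
#' @export
segment_cells <- function(x1, y1, x2, y2, grid) {
  cs <- grid$cell_size
  ts <- c(0, 1)
  lines_between <- function(lo, hi, origin) {
    from <- ceiling((lo - origin) / cs)
    to <- floor((hi - origin) / cs)
    if (from > to) numeric(0) else origin + (from:to) * cs
  }
  if (x2 != x1) {
    xs <- lines_between(min(x1, x2), max(x1, x2), grid$x_origin)
    ts <- c(ts, (xs - x1) / (x2 - x1))
  }
  if (y2 != y1) {
    ys <- lines_between(min(y1, y2), max(y1, y2), grid$y_origin)
    ts <- c(ts, (ys - y1) / (y2 - y1))
  }
  ts <- sort(unique(pmin(pmax(ts, 0), 1)))
  if (length(ts) < 2) ts <- c(0, 1)
  tm <- (ts[-1] + ts[-length(ts)]) / 2
  px <- x1 + tm * (x2 - x1)
  py <- y1 + tm * (y2 - y1)
  col <- floor((px - grid$x_origin) / cs) + 1
  row_b <- floor((py - grid$y_origin) / cs) + 1
  row <- grid$n_rows - row_b + 1
  ok <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  unique(cbind(row = row[ok], col = col[ok]))
}
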