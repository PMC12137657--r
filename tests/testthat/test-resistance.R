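test_that("IBD residuals follow the fitted log-distance curve", {
  set.seed(33)
  n <- 12
  coords <- data.frame(x = runif(n, 0, 5000), y = runif(n, 0, 5000))
  geo <- as.matrix(dist(coords))
  # genetic distances generated exactly on the curve -> residuals 0
  gd_exact <- 0.05 + 0.02 * log1p(geo)
  diag(gd_exact) <- 0
  res <- fit_ibd_residuals(gd_exact, coords, d_max = 1e6)
  expect_lt(max(abs(res$residual)), 1e-9)

  # coefficients match closed-form normal equations on log1p(distance)
  gd_noisy <- gd_exact + as.matrix(dist(matrix(rnorm(n), n, 1))) * 0.001
  diag(gd_noisy) <- 0
  res2 <- fit_ibd_residuals(gd_noisy, coords, d_max = 1e6)
  ut <- upper.tri(geo)
  X <- cbind(1, log1p(geo[ut]))
  beta <- solve(t(X) %*% X, t(X) %*% gd_noisy[ut])
  expect_equal(unname(attr(res2, "coef")), as.vector(beta),
               tolerance = 1e-9)
  # residuals scaled to [-1, 1] with the extremes attained
  expect_equal(max(abs(res2$residual)), 1)

  expect_error(fit_ibd_residuals(matrix(0, 3, 3),
                                 data.frame(x = rep(1, 3), y = rep(1, 3)),
                                 1e6),
               "pairs")
})

test_that("segment-cell traversal matches a supersampling oracle", {
  grid <- raster_grid(0, 0, 100, 3, 3)
  # diagonal across the 3x3 grid
  cells <- segment_cells(10, 10, 290, 290, grid)
  over <- t(vapply(seq(0, 1, length.out = 5000), function(t) {
    px <- 10 + t * 280; py <- 10 + t * 280
    c(3 - (floor(py / 100) + 1) + 1, floor(px / 100) + 1)
  }, numeric(2)))
  over <- unique(over)
  expect_setequal(paste(cells[, 1], cells[, 2]),
                  paste(over[, 1], over[, 2]))

  # horizontal segment stays in one raster row
  ch <- segment_cells(10, 150, 290, 150, grid)
  expect_true(all(ch[, "row"] == 2))
  expect_setequal(ch[, "col"], 1:3)

  # random segments against the oracle
  set.seed(44)
  for (k in 1:10) {
    p <- runif(4, -50, 350)
    cells_k <- segment_cells(p[1], p[2], p[3], p[4], grid)
    ts <- seq(0, 1, length.out = 20000)
    px <- p[1] + ts * (p[3] - p[1]); py <- p[2] + ts * (p[4] - p[2])
    col <- floor(px / 100) + 1; row <- 3 - floor(py / 100)
    ok <- col >= 1 & col <= 3 & row >= 1 & row <= 3
    oracle <- unique(cbind(row[ok], col[ok]))
    expect_setequal(paste(cells_k[, 1], cells_k[, 2]),
                    paste(oracle[, 1], oracle[, 2]))
  }
})

test_that("resistance classification responds to residual structure", {
  grid <- raster_grid(0, 0, 100, 4, 4)
  # all-zero residuals: defined cells all not-significant
  res0 <- data.frame(i = 1, j = 2, x1 = c(10, 210), y1 = c(10, 210),
                     x2 = c(390, 350), y2 = c(390, 250),
                     geo_d = 1, gen_d = 0, residual = 0)
  rs0 <- map_resistance(res0, grid, n_resample = 50, seed = 1)
  vals <- rs0$class$values
  expect_true(all(vals[!is.na(vals)] == 0))
  expect_true(any(is.na(rs0$mean$values)))       # uncrossed cells nodata

  # one strongly positive residual crossing a remote cell alone
  set.seed(2)
  n <- 40
  res1 <- data.frame(i = seq_len(n), j = seq_len(n) + n,
                     x1 = runif(n, 0, 180), y1 = runif(n, 210, 390),
                     x2 = runif(n, 0, 180), y2 = runif(n, 210, 390),
                     geo_d = 1, gen_d = 0,
                     residual = rnorm(n, 0, 0.05))
  hot <- data.frame(i = 99, j = 100, x1 = 310, y1 = 50, x2 = 390, y2 = 90,
                    geo_d = 1, gen_d = 0, residual = 1)
  rs1 <- map_resistance(rbind(res1, hot), grid, n_resample = 400,
                        alpha = 0.05, seed = 3)
  hot_cells <- segment_cells(310, 50, 390, 90, grid)
  expect_true(all(rs1$class$values[hot_cells] == 1))
})

test_that("windowed heterozygosity rarefies and respects its contracts", {
  # window holding exactly rarefaction_n individuals = their direct Ho
  calls <- rbind(a = c(1L, 1L, 0L, 2L), b = c(1L, 0L, 0L, 2L),
                 c = c(1L, 1L, 1L, 1L))
  G <- genotype_matrix(calls, setNames(rep(1, 3), rownames(calls)))
  coords <- data.frame(x = c(50, 60, 70), y = c(50, 60, 70))
  grid <- raster_grid(0, 0, 100, 3, 3)
  ds <- windowed_heterozygosity(G, coords, grid, window = 3,
                                rarefaction_n = 3, seed = 1)
  direct <- mean(rowMeans(calls == 1))
  centre <- ds$grid$values[2, 2]
  expect_equal(centre, direct, tolerance = 1e-12)

  # fully heterozygous individuals give Ho = 1 wherever defined
  calls2 <- matrix(1L, 4, 5, dimnames = list(letters[1:4], NULL))
  G2 <- genotype_matrix(calls2, setNames(rep(1, 4), rownames(calls2)))
  ds2 <- windowed_heterozygosity(G2, data.frame(x = runif(4, 0, 300),
                                                y = runif(4, 0, 300)),
                                 grid, window = 3, rarefaction_n = 2,
                                 seed = 1)
  v <- ds2$grid$values
  expect_true(all(v[!is.na(v)] == 1))
  expect_error(windowed_heterozygosity(G2, coords[1:4, ], grid,
                                       rarefaction_n = 1), ">= 2")

  # rarefied mean tracks the exhaustive average of subset Ho values
  set.seed(3)
  calls3 <- matrix(sample(0:2, 6 * 30, replace = TRUE), 6, 30,
                   dimnames = list(paste0("i", 1:6), NULL))
  G3 <- genotype_matrix(calls3, setNames(rep(1, 6), rownames(calls3)))
  ds3 <- windowed_heterozygosity(G3, data.frame(x = rep(150, 6),
                                                y = rep(150, 6)),
                                 grid, window = 3, rarefaction_n = 3,
                                 n_draws = 400, seed = 5)
  het <- rowMeans(calls3 == 1)
  combos <- combn(6, 3)
  exhaustive <- mean(apply(combos, 2, function(ix) mean(het[ix])))
  expect_equal(ds3$grid$values[2, 2], exhaustive, tolerance = 0.02)
})

test_that("kriging honours defined cells and recovers smooth fields", {
  grid <- raster_grid(0, 0, 100, 6, 6)
  v <- matrix(NA_real_, 6, 6)
  v[cbind(c(1, 2, 4, 5, 6, 3), c(2, 5, 1, 4, 6, 3))] <- 0.3
  part <- raster_grid(0, 0, 100, 6, 6, v)
  filled <- krige_surface(part)
  expect_true(all(!is.na(filled$grid$values)))
  expect_true(all(abs(filled$grid$values - 0.3) < 1e-6))

  # linear trend: interpolation within 5% of the plane
  cen <- raster_cell_centres(grid)
  plane <- outer(cen$y, cen$x, function(y, x) 0.1 + 0.0004 * x + 0.0002 * y)
  v2 <- plane
  set.seed(9)
  interior <- as.vector(outer(2:5, 2:5, function(r, c) (c - 1) * 6 + r))
  holes <- sample(interior, 8)
  v2[holes] <- NA
  filled2 <- krige_surface(raster_grid(0, 0, 100, 6, 6, v2))
  expect_equal(filled2$grid$values[holes], plane[holes], tolerance = 0.05)
  # defined cells are reproduced exactly
  expect_identical(filled2$grid$values[-holes], plane[-holes])
  expect_error(krige_surface(raster_grid(0, 0, 1, 2, 2,
                                         matrix(c(1, NA, NA, NA), 2))),
               "5 defined")
})

test_that("diversity-hit-score correlation matches its closed form", {
  grid <- raster_grid(0, 0, 100, 5, 5)
  hit <- raster_grid(0, 0, 100, 5, 5, matrix(seq(0.02, 1, length.out = 25),
                                             5, 5))
  ho_vals <- 0.1 + 0.2 * hit$values
  ds <- structure(list(grid = raster_grid(0, 0, 100, 5, 5, ho_vals)),
                  class = "diversity_surface")
  locs <- data.frame(locality_id = 1:5,
                     x = c(50, 150, 250, 350, 450),
                     y = c(50, 150, 250, 350, 450))
  res <- correlate_ho_hitscore(ds, hit, locs)
  expect_equal(res$r, 1, tolerance = 1e-9)

  # n = 5 hand case for the t statistic
  set.seed(10)
  noisy <- raster_grid(0, 0, 100, 5, 5,
                       ho_vals + matrix(rnorm(25, 0, 0.05), 5, 5))
  ds2 <- structure(list(grid = noisy), class = "diversity_surface")
  res2 <- correlate_ho_hitscore(ds2, hit, locs)
  ho <- raster_value_at(noisy, as.matrix(locs[, c("x", "y")]))
  hs <- raster_value_at(hit, as.matrix(locs[, c("x", "y")]))
  r_hand <- cor(ho, hs)
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(res2$r, r_hand)
  expect_equal(res2$t, t_hand)
  expect_equal(res2$p, 2 * pt(-abs(t_hand), 3))

  other <- raster_grid(0, 0, 200, 5, 5, ho_vals)
  ds3 <- structure(list(grid = other), class = "diversity_surface")
  expect_error(correlate_ho_hitscore(ds3, hit, locs), "different grids")
})
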