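test_that("projection matches closed-form offsets and round-trips", {
  ref <- c(5, 51)
  expect_equal(unname(project_coordinates(rbind(ref), ref)), cbind(0, 0))
  # 1 degree north: R * pi/180
  p <- project_coordinates(rbind(c(5, 52)), ref)
  expect_equal(as.numeric(p[1, "y"]), 6371000 * pi / 180, tolerance = 1e-9)
  expect_equal(as.numeric(p[1, "x"]), 0)
  # 0.01 degree of longitude at 51 N
  p2 <- project_coordinates(rbind(c(5.01, 51)), ref)
  expect_equal(as.numeric(p2[1, "x"]), 6371000 * cos(51 * pi / 180) * 0.01 * pi / 180,
               tolerance = 1e-9)
  # round trip within 100 km of the reference
  set.seed(1)
  lonlat <- cbind(5 + runif(100, -1.4, 1.4), 51 + runif(100, -0.9, 0.9))
  back <- unproject_coordinates(project_coordinates(lonlat, ref), ref)
  expect_lt(max(abs(back - lonlat)), 1e-6)
  expect_error(project_coordinates(rbind(c(0, 91)), ref), "latitude")
})

test_that("occurrence reader filters, validates and reports", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,longitude,latitude,year,verified",
               "a,5.0,51.0,2001,TRUE",
               "b,5.1,51.1,2005,FALSE",
               "c,5.2,51.0,2003,TRUE"), f)
  occ <- suppressMessages(read_occurrences(f))
  expect_equal(nrow(occ), 2)
  expect_equal(occ$year, c(2001L, 2003L))
  expect_equal(attr(occ, "n_dropped"), 1)

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,longitude,latitude,year", f2)
  expect_error(read_occurrences(f2), "verified")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,longitude,latitude,year,verified"), f3)
  expect_equal(nrow(suppressMessages(read_occurrences(f3))), 0)

  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,longitude,latitude,year,verified",
               "a,5.0,51.0,not-a-year,TRUE",
               "b,5.0,51.0,2004,TRUE"), f4)
  occ4 <- suppressMessages(read_occurrences(f4))
  expect_equal(occ4$id, "b")
})

test_that("VCF and 012 CSV representations give identical genotypes", {
  G <- toy_genotypes()
  vcf <- withr::local_tempfile(fileext = ".vcf")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_genotypes_vcf(G, vcf)
  write_genotypes_csv(G, csv)
  lmap <- G$locality_of
  G_vcf <- read_genotypes(vcf, lmap)
  G_csv <- read_genotypes(csv, lmap)
  expect_identical(G_vcf$calls, G_csv$calls)
  expect_identical(G_vcf$calls, G$calls)
  # ./. handled as missing
  expect_true(is.na(G_vcf$calls["i3", "L4"]))
})

test_that("multi-allelic VCF sites are skipped with a warning", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "s1", "s2", sep = "\t"),
               paste("1", "1", "snp1", "A", "T", ".", "PASS", ".", "GT",
                     "0/0", "0/1", sep = "\t"),
               paste("1", "2", "bad", "A", "T,G", ".", "PASS", ".", "GT",
                     "0/1", "1/2", sep = "\t")), vcf)
  expect_warning(G <- read_genotypes(vcf, setNames(c(1, 1), c("s1", "s2"))),
                 "non-biallelic")
  expect_equal(ncol(G$calls), 1)
  expect_equal(unname(G$calls[, "snp1"]), c(0L, 1L))
})

test_that("genotype matrix rejects unmapped individuals and bad shapes", {
  calls <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("L1", "L2")))
  expect_error(genotype_matrix(calls, c(a = 1)), "absent")
  expect_error(genotype_matrix(calls[1, , drop = FALSE], c(a = 1)),
               "at least 2")
})

test_that("ESRI ASCII raster write/read is an exact involution", {
  set.seed(42)
  v <- matrix(rnorm(100), 10, 10)
  v[3, 7] <- NA
  g <- raster_grid(1000, -500, 250, 10, 10, v)
  f <- withr::local_tempfile(fileext = ".asc")
  write_raster(g, f)
  g2 <- read_raster(f)
  expect_identical(g2$values, g$values)
  expect_equal(g2$x_origin, g$x_origin)
  expect_equal(g2$cell_size, g$cell_size)
  # 1x1 grid: six header lines then the value
  g1 <- raster_grid(0, 0, 1, 1, 1, matrix(7, 1, 1))
  f1 <- withr::local_tempfile(fileext = ".asc")
  write_raster(g1, f1)
  lines <- readLines(f1)
  expect_length(lines, 7)
  expect_equal(as.numeric(lines[7]), 7)
  # malformed header rejected
  f2 <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 1", "nrows 1", "cellsize 1", "xllcorner 0",
               "yllcorner 0", "NODATA_value -9999", "7"), f2)
  expect_error(read_raster(f2), "malformed")
})

test_that("river distances follow the network and snap without penalty", {
  # straight segment: along-network = Euclidean
  net <- list(rbind(c(0, 0), c(1000, 0)))
  loc <- data.frame(locality_id = 1:2, x = c(100, 900), y = c(0, 0))
  d <- river_distance(loc, net)
  expect_equal(d[1, 2], 800, tolerance = 1e-9)

  # Y-shaped network: distance = sum of branch distances to the junction
  net_y <- list(rbind(c(0, 0), c(1000, 0)),
                rbind(c(1000, 0), c(1000, 800)),
                rbind(c(1000, 0), c(2000, 0)))
  loc_y <- data.frame(locality_id = 1:2, x = c(200, 1000), y = c(0, 500))
  dy <- river_distance(loc_y, net_y)
  expect_equal(dy[1, 2], 800 + 500, tolerance = 1e-9)

  # snapping offset is not added to the path length
  loc_off <- data.frame(locality_id = 1:2, x = c(100, 900), y = c(50, 0))
  d_off <- river_distance(loc_off, net)
  expect_equal(d_off[1, 2], 800, tolerance = 1e-9)

  # river distance >= Euclidean between snapped points (random nets)
  set.seed(7)
  for (rep in 1:5) {
    pts <- matrix(runif(8, 0, 1000), 4, 2)
    net_r <- list(pts[1:2, ], pts[2:3, ], pts[3:4, ])
    locs <- data.frame(locality_id = 1:3,
                       x = runif(3, 0, 1000), y = runif(3, 0, 1000))
    dr <- river_distance(locs, net_r)
    snapped <- attr(dr, "snapped")
    euclid <- as.matrix(dist(snapped))
    expect_true(all(dr - euclid >= -1e-6))
  }

  # disconnected components are reported
  net_d <- list(rbind(c(0, 0), c(100, 0)), rbind(c(5000, 0), c(5100, 0)))
  loc_d <- data.frame(locality_id = 1:2, x = c(50, 5050), y = c(0, 0))
  expect_error(river_distance(loc_d, net_d), "disconnected")
})

test_that("GeoJSON polylines are parsed", {
  f <- withr::local_tempfile(fileext = ".geojson")
  writeLines('{"type":"FeatureCollection","features":[
    {"type":"Feature","geometry":{"type":"LineString",
      "coordinates":[[4.9,51.0],[5.0,51.05],[5.1,51.1]]}}]}', f)
  pls <- read_river_geojson(f)
  expect_length(pls, 1)
  expect_equal(dim(pls[[1]]), c(3, 2))
  expect_equal(pls[[1]][2, ], c(5.0, 51.05))
})
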