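# Exact area of a union of equal-radius discs via Green's theorem over
# the exposed boundary arcs. For each disc, the angular intervals of its
# boundary lying strictly inside another disc are removed; each exposed
# arc contributes 0.5 * integral(x dy - y dx). Holes enclosed by rings
# of discs are handled automatically (their bounding arcs integrate with
# opposite sign). Discs whose boundary is fully covered contribute
# nothing.
.disc_union_area <- function(centres, r) {
  centres <- as.matrix(centres)
  n <- nrow(centres)
  if (n == 0) return(0)
  # drop exact duplicates (coincident discs)
  centres <- unique(round(centres, 9))
  n <- nrow(centres)
  area <- 0
  for (i in seq_len(n)) {
    ci <- centres[i, ]
    ints <- matrix(numeric(0), ncol = 2)     # covered angular intervals
    contained <- FALSE
    for (j in seq_len(n)) {
      if (j == i) next
      cj <- centres[j, ]
      d <- sqrt(sum((cj - ci)^2))
      if (d >= 2 * r) next
      if (d == 0) next                        # duplicate already removed
      # boundary of i inside disc j: angular half-width around direction
      # to j with cos(half) = d / (2r)
      half <- acos(min(1, max(-1, d / (2 * r))))
      mid <- atan2(cj[2] - ci[2], cj[1] - ci[1])
      lo <- mid - half; hi <- mid + half
      # normalise to [0, 2pi), split wrapped intervals
      lo <- lo %% (2 * pi); hi <- hi %% (2 * pi)
      if (lo <= hi) ints <- rbind(ints, c(lo, hi)) else
        ints <- rbind(ints, c(lo, 2 * pi), c(0, hi))
    }
    # merge covered intervals, find exposed complement
    if (nrow(ints) > 0) {
      ints <- ints[order(ints[, 1]), , drop = FALSE]
      merged <- matrix(numeric(0), ncol = 2)
      cur <- ints[1, ]
      for (k in seq_len(nrow(ints))[-1]) {
        if (ints[k, 1] <= cur[2] + 1e-12) cur[2] <- max(cur[2], ints[k, 2])
        else { merged <- rbind(merged, cur); cur <- ints[k, ] }
      }
      merged <- rbind(merged, cur)
      if (nrow(merged) == 1 && merged[1, 1] <= 1e-12 &&
          merged[1, 2] >= 2 * pi - 1e-12) contained <- TRUE
      # exposed arcs = complement in [0, 2pi)
      exposed <- matrix(numeric(0), ncol = 2)
      if (!contained) {
        prev_end <- 0
        for (k in seq_len(nrow(merged))) {
          if (merged[k, 1] > prev_end)
            exposed <- rbind(exposed, c(prev_end, merged[k, 1]))
          prev_end <- max(prev_end, merged[k, 2])
        }
        if (prev_end < 2 * pi)
          exposed <- rbind(exposed, c(prev_end, 2 * pi))
      }
    } else {
      exposed <- matrix(c(0, 2 * pi), ncol = 2)
    }
    if (contained || nrow(exposed) == 0) next
    # Green contribution of arc [t1, t2] on circle (ci, r):
    # 0.5 * int (r^2 + ci_x r cos t + ci_y r sin t) dt
    for (k in seq_len(nrow(exposed))) {
      t1 <- exposed[k, 1]; t2 <- exposed[k, 2]
      area <- area + 0.5 * (r^2 * (t2 - t1) +
                              ci[1] * r * (sin(t2) - sin(t1)) +
                              ci[2] * r * (cos(t1) - cos(t2)))
    }
  }
  area
}

#' Cumulative extent of occupancy by year
#'
#' For each year, all records observed up to and including that year
#' (colonised ponds are assumed to stay occupied) are buffered by
#' `buffer_m`; overlapping buffers are merged and the union area
#' reported in km^2. The union area is exact (circular-arc geometry).
#'
#' @param records occurrence data frame (`x`, `y`, `year`).
#' @param buffer_m buffer radius, metres.
#' @param cluster_label optional tag carried into the output.
#' @return data frame of class `eoo_series` with columns `year`,
#'   `eoo_km2` and (if given) `cluster`.
#' @export
eoo_by_year <- function(records, buffer_m = 1000, cluster_label = NULL) {
  if (nrow(records) < 1) stop("need at least one record")
  years <- sort(unique(records$year))
  eoo <- vapply(years, function(y) {
    pts <- records[records$year <= y, c("x", "y"), drop = FALSE]
    .disc_union_area(pts, buffer_m) / 1e6
  }, numeric(1))
  out <- data.frame(year = years, eoo_km2 = eoo)
  if (!is.null(cluster_label)) out$cluster <- cluster_label
  class(out) <- c("eoo_series", "data.frame")
  out
}

#' Yearly range-expansion speed from an EOO series
#'
#' The reported speed formula `E = sqrt(C / pi)` maps an area to an
#' equivalent-circle radius; whether `C` is the cumulative extent or its
#' yearly increase is ambiguous, so both readings are computed. The
#' default `radius-difference` mode takes `E_y = r_y - r_{y-1}` with
#' `r_y = sqrt(C_y / pi)` (the advance of an equivalent circular front,
#' metres/year); `increment-radius` takes `E_y = sqrt((C_y - C_{y-1}) /
#' pi)`.
#'
#' @param series output of [eoo_by_year()] (>= 2 years).
#' @param mode default speed definition flagged in the output.
#' @return the series with columns `speed_radius_diff_m`,
#'   `speed_increment_m` and `speed_m_per_yr` (the chosen mode, per
#'   year, interpolated across gap years by dividing by the year gap).
#' @export
expansion_speed <- function(series,
                            mode = c("radius-difference", "increment-radius")) {
  mode <- match.arg(mode)
  if (nrow(series) < 2) stop("need at least 2 years")
  if (any(diff(series$eoo_km2) < -1e-9))
    stop("EOO must be non-decreasing (cumulative union)")
  r_m <- sqrt(series$eoo_km2 * 1e6 / pi)
  dy <- diff(series$year)
  dC <- pmax(0, diff(series$eoo_km2 * 1e6))
  speed_rd <- c(NA, diff(r_m) / dy)
  speed_ir <- c(NA, sqrt(dC / pi) / dy)
  series$speed_radius_diff_m <- speed_rd
  series$speed_increment_m <- speed_ir
  series$speed_m_per_yr <- if (mode == "radius-difference") speed_rd else speed_ir
  attr(series, "speed_mode") <- mode
  series
}

#' Split records into two subsets by a divider polyline
#'
#' Records are assigned to the side of the divider given by the sign of
#' the cross product with the nearest divider segment. Records exactly
#' on the divider take the side of their nearest off-divider neighbour
#' (logged via message).
#'
#' @param records occurrence data frame.
#' @param divider polyline matrix (x, y).
#' @return list with elements `left` and `right` (record subsets).
#' @export
split_clusters <- function(records, divider) {
  divider <- as.matrix(divider)
  side_of <- function(p) {
    best_d <- Inf; best_s <- 0
    for (i in seq_len(nrow(divider) - 1)) {
      a <- divider[i, ]; b <- divider[i + 1, ]
      pr <- .project_on_segment(p, a, b)
      if (pr$dist < best_d) {
        best_d <- pr$dist
        cross <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
        best_s <- sign(cross)
      }
    }
    best_s
  }
  s <- vapply(seq_len(nrow(records)),
              function(i) side_of(c(records$x[i], records$y[i])), numeric(1))
  if (any(s == 0)) {
    message(sum(s == 0), " record(s) exactly on the divider; assigned to ",
            "the side of their nearest neighbour")
    off <- which(s != 0)
    for (i in which(s == 0)) {
      d2 <- (records$x[off] - records$x[i])^2 + (records$y[off] - records$y[i])^2
      s[i] <- s[off[which.min(d2)]]
    }
  }
  list(left = records[s > 0, , drop = FALSE],
       right = records[s < 0, , drop = FALSE])
}
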