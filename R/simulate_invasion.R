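# Segment intersection test used for barrier rejection and cluster splits.
# Proper crossing or touching counts as an intersection.
.segments_intersect <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  o1 <- orient(p1, p2, q1); o2 <- orient(p1, p2, q2)
  o3 <- orient(q1, q2, p1); o4 <- orient(q1, q2, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  on_seg <- function(a, b, c)
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  (o1 == 0 && on_seg(p1, p2, q1)) || (o2 == 0 && on_seg(p1, p2, q2)) ||
    (o3 == 0 && on_seg(q1, q2, p1)) || (o4 == 0 && on_seg(q1, q2, p2))
}

# Does the segment a-b cross any edge of the polyline (matrix of vertices)?
.crosses_polyline <- function(a, b, polyline) {
  if (is.null(polyline)) return(FALSE)
  pl <- as.matrix(polyline)
  for (i in seq_len(nrow(pl) - 1))
    if (.segments_intersect(a, b, pl[i, ], pl[i + 1, ])) return(TRUE)
  FALSE
}

#' Ground truth for a synthetic invasion
#'
#' @param sources matrix/data frame with columns `x`, `y`, `intro_year`
#'   (1 to 10 sources).
#' @param sigma_true dispersal kernel scale: the per-year displacement is
#'   bivariate normal with standard deviation `sigma_true` metres per
#'   axis.
#' @param detection_prob per-occupied-point per-year detection
#'   probability.
#' @param barrier optional polyline (matrix of x,y) dispersal cannot
#'   cross.
#' @param ldd_rate probability a displacement is drawn from the
#'   long-distance tail (the same kernel scaled by 5).
#' @return list of class `invasion_truth`.
#' @export
invasion_truth <- function(sources, sigma_true, detection_prob = 0.3,
                           barrier = NULL, ldd_rate = 0.02) {
  sources <- as.data.frame(sources)
  stopifnot(all(c("x", "y", "intro_year") %in% names(sources)))
  if (nrow(sources) < 1 || nrow(sources) > 10)
    stop("need 1 to 10 sources")
  if (detection_prob <= 0 || detection_prob > 1)
    stop("detection_prob must be in (0, 1]")
  if (ldd_rate < 0 || ldd_rate >= 0.5)
    stop("ldd_rate must be in [0, 0.5)")
  if (sigma_true < 0) stop("sigma_true must be >= 0")
  structure(list(sources = sources, sigma_true = sigma_true,
                 detection_prob = detection_prob, barrier = barrier,
                 ldd_rate = ldd_rate),
            class = "invasion_truth")
}

#' Simulate an invasion and its occurrence records
#'
#' Each source becomes an occupied point in its introduction year. Every
#' year, every occupied point spawns `Poisson(growth)` colonist points;
#' displacements are bivariate normal `N(0, sigma^2 I)` with probability
#' `1 - ldd_rate`, or from a 5x-scaled tail otherwise. Displacements
#' whose segment crosses the barrier are redrawn on the same side. Each
#' occupied point is reported as a record in a given year with
#' probability `detection_prob`. Deterministic under `seed`.
#'
#' @param truth an [invasion_truth()].
#' @param years integer vector of simulated calendar years.
#' @param seed integer RNG seed.
#' @param growth expected colonists per occupied point per year.
#' @param max_points cap on the occupied-point count (new colonists are
#'   not added beyond it), keeping runs at desk scale.
#' @return data frame of occurrence records (`id`, `x`, `y`, `year`,
#'   `verified`) with attribute `occupied` (final occupied points).
#' @export
simulate_invasion <- function(truth, years, seed, growth = 0.6,
                              max_points = 3000) {
  if (length(years) == 0) stop("empty year range")
  years <- sort(unique(as.integer(years)))
  if (!any(truth$sources$intro_year %in% years))
    stop("no source introduced within the simulated years")
  set.seed(as.integer(seed))
  occ_x <- numeric(0); occ_y <- numeric(0)
  rec <- list()
  sigma <- truth$sigma_true
  for (y in years) {
    new_src <- truth$sources[truth$sources$intro_year == y, , drop = FALSE]
    if (nrow(new_src) > 0) {
      occ_x <- c(occ_x, new_src$x); occ_y <- c(occ_y, new_src$y)
    }
    n_occ <- length(occ_x)
    if (n_occ == 0) next
    # colonisation
    n_new <- rpois(n_occ, growth)
    room <- max(0, max_points - n_occ)
    for (i in seq_len(n_occ)) {
      for (k in seq_len(min(n_new[i], room))) {
        for (attempt in 1:100) {
          scale <- if (runif(1) < truth$ldd_rate) 5 else 1
          dx <- rnorm(1, 0, sigma * scale); dy <- rnorm(1, 0, sigma * scale)
          a <- c(occ_x[i], occ_y[i]); b <- a + c(dx, dy)
          if (!.crosses_polyline(a, b, truth$barrier)) break
        }
        if (.crosses_polyline(a, b, truth$barrier)) next
        occ_x <- c(occ_x, b[1]); occ_y <- c(occ_y, b[2])
        room <- room - 1
      }
    }
    # detection
    det <- runif(length(occ_x)) < truth$detection_prob
    if (any(det))
      rec[[length(rec) + 1]] <- data.frame(x = occ_x[det], y = occ_y[det],
                                           year = y)
  }
  rec <- if (length(rec)) do.call(rbind, rec) else
    data.frame(x = numeric(0), y = numeric(0), year = integer(0))
  out <- data.frame(id = sprintf("occ%05d", seq_len(nrow(rec))),
                    x = rec$x, y = rec$y, year = as.integer(rec$year),
                    verified = TRUE, stringsAsFactors = FALSE)
  attr(out, "occupied") <- cbind(x = occ_x, y = occ_y)
  attr(out, "truth") <- truth
  out
}
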