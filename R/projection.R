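#' Project longitude/latitude to local planar metres
#'
#' Local equirectangular projection about a reference point. Over study
#' extents of a few tens of kilometres the distortion is far below the
#' buffer radii and dispersal scales used downstream, so all spatial math
#' in the package runs in planar metres.
#'
#' The forward map is `x = R * cos(lat0) * (lon - lon0)` and
#' `y = R * (lat - lat0)` with angles in radians and `R = 6371000` m.
#'
#' @param lonlat two-column matrix or data frame of (longitude, latitude)
#'   in decimal degrees.
#' @param reference numeric length-2 `(lon0, lat0)` in decimal degrees.
#' @return matrix with columns `x`, `y` in metres.
#' @seealso [unproject_coordinates()] for the inverse.
#' @export
project_coordinates <- function(lonlat, reference) {
  lonlat <- as.matrix(lonlat)
  if (ncol(lonlat) != 2) stop("lonlat must have two columns (lon, lat)")
  storage.mode(lonlat) <- "double"
  if (any(!is.finite(lonlat))) stop("non-finite coordinates")
  if (any(lonlat[, 2] < -90 | lonlat[, 2] > 90))
    stop("latitude out of range [-90, 90]")
  if (any(lonlat[, 1] < -360 | lonlat[, 1] > 360))
    stop("longitude out of range [-360, 360]")
  lon0 <- reference[1]
  lat0 <- reference[2]
  if (lat0 < -90 || lat0 > 90) stop("reference latitude out of range")
  d2r <- pi / 180
  x <- .R_EARTH * cos(lat0 * d2r) * (lonlat[, 1] - lon0) * d2r
  y <- .R_EARTH * (lonlat[, 2] - lat0) * d2r
  cbind(x = x, y = y)
}

#' Inverse of the local equirectangular projection
#'
#' @param xy two-column matrix of planar metres.
#' @param reference `(lon0, lat0)` in decimal degrees used in the forward
#'   projection.
#' @return matrix with columns `lon`, `lat` in decimal degrees.
#' @export
unproject_coordinates <- function(xy, reference) {
  xy <- as.matrix(xy)
  d2r <- pi / 180
  lon0 <- reference[1]
  lat0 <- reference[2]
  lon <- lon0 + xy[, 1] / (.R_EARTH * cos(lat0 * d2r)) / d2r
  lat <- lat0 + xy[, 2] / .R_EARTH / d2r
  cbind(lon = lon, lat = lat)
}

#' Parse degree-minute-second coordinate strings
#'
#' Converts strings like `51°08'38.8"N` to decimal degrees. Southern
#' latitudes and western longitudes are negated.
#'
#' @param x character vector of DMS strings.
#' @return numeric decimal degrees.
#' @export
dms_to_decimal <- function(x) {
  vapply(x, function(s) {
    nums <- as.numeric(regmatches(s, gregexpr("[0-9.]+", s))[[1]])
    if (length(nums) < 3) nums <- c(nums, rep(0, 3 - length(nums)))
    val <- nums[1] + nums[2] / 60 + nums[3] / 3600
    if (grepl("[SWsw]", s)) val <- -val
    val
  }, numeric(1), USE.NAMES = FALSE)
}
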