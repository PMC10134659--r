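#' Project geographic coordinates to local planar meters
#'
#' Equirectangular projection about the centroid of the input (or a supplied
#' origin). Adequate at city scale (tens of kilometres), where the distortion
#' of pairwise distances relative to great-circle distance is well below 1%.
#' All distance-based operations in the package assume planar coordinates in
#' meters; longitude/latitude input must pass through this projection first.
#'
#' @param lon,lat numeric vectors of geographic coordinates in decimal degrees.
#' @param origin optional `c(lon0, lat0)` projection origin; defaults to the
#'   midpoint of the input range.
#' @return A data.frame with columns `x` and `y` in meters, with the origin at
#'   `origin`, plus an `"origin"` attribute.
#' @examples
#' project_lonlat(c(59.5, 59.6), c(36.28, 36.33))
#' @export
project_lonlat <- function(lon, lat, origin = NULL) {
  if (length(lon) != length(lat)) stop_validation("lon and lat lengths differ")
  if (anyNA(lon) || anyNA(lat) || !all(is.finite(lon)) || !all(is.finite(lat))) {
    stop_validation("non-finite coordinates in lon/lat input")
  }
  if (any(abs(lat) > 90) || any(abs(lon) > 360)) {
    stop_validation("lon/lat outside valid ranges; are these already projected?")
  }
  origin <- origin %||% c(mean(range(lon)), mean(range(lat)))
  r_earth <- 6371008.8 # mean Earth radius, meters
  to_rad <- pi / 180
  out <- data.frame(
    x = r_earth * cos(origin[2] * to_rad) * (lon - origin[1]) * to_rad,
    y = r_earth * (lat - origin[2]) * to_rad
  )
  attr(out, "origin") <- origin
  out
}

#' Jitter coincident coordinates
#'
#' Distance-band weights are undefined for coincident points (1/d with d = 0).
#' This utility displaces every point involved in a duplicated location by a
#' uniform offset within +/- `amount` meters on each axis, leaving all other
#' points untouched. Intended as an explicit, seeded pre-processing step for
#' address-geocoded data where several patients share one building.
#'
#' @param points a data.frame with numeric columns `x` and `y` (meters).
#' @param amount maximal absolute displacement per axis, meters.
#' @param seed optional integer seed for reproducible jitter.
#' @return `points` with jittered coordinates; the number of displaced points
#'   is reported via a message.
#' @export
jitter_coincident <- function(points, amount = 0.5, seed = NULL) {
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  if (amount <= 0) stop_validation("`amount` must be positive")
  key <- paste(points$x, points$y)
  dup <- key %in% key[duplicated(key)]
  if (any(dup)) {
    nd <- sum(dup)
    with_seed(seed, {
      points$x[dup] <- points$x[dup] + runif(nd, -amount, amount)
      points$y[dup] <- points$y[dup] + runif(nd, -amount, amount)
    })
    message("jittered ", nd, " points at duplicated locations by up to ",
            amount, " m")
  }
  points
}
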