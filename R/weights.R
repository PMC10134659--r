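#' Inverse-distance spatial weights within a distance band
#'
#' Builds symmetric pairwise weights `w_ij = 1 / d_ij` for every pair of
#' units whose planar Euclidean distance satisfies `0 < d_ij <= radius`.
#' Units with no neighbour inside the band are kept and flagged as isolated,
#' never dropped: downstream operations decide how to handle them (see
#' [autocovariate()]).
#'
#' @param points a data.frame with numeric columns `x`, `y` in projected
#'   meters and optionally `unit_id` (unique identifiers; defaults to row
#'   index). A two-column matrix is also accepted.
#' @param radius band radius in meters. The default,
#'   [default_band_radius()], is the maximum nearest-neighbour distance of
#'   the point set, the smallest radius that leaves no unit isolated.
#' @return An object of class `distband_weights`: a list with elements
#'   `w` (sparse symmetric dgCMatrix of inverse-distance weights), `ids`,
#'   `coords`, `radius`, `neighbor_counts` and logical `isolated`.
#' @details Coincident points inside the band make `1/d` undefined and raise
#'   an error naming the offending pair; [jitter_coincident()] is the
#'   explicit remedy. Coordinates must be finite and ids unique.
#' @examples
#' pts <- data.frame(x = c(0, 1, 2), y = 0)
#' w <- build_weights(pts, radius = 2.5)
#' w$neighbor_counts
#' @export
build_weights <- function(points, radius = NULL) {
  pts <- as_pointset(points)
  n <- nrow(pts)
  if (n < 2L) stop_validation("at least 2 points are required to build weights")
  d <- as.matrix(dist(pts[, c("x", "y")]))
  zero <- which(d == 0 & upper.tri(d), arr.ind = TRUE)
  if (nrow(zero) > 0L) {
    stop_validation(
      "coincident points: units ", pts$unit_id[zero[1, 1]], " and ",
      pts$unit_id[zero[1, 2]],
      " share a location (1/d undefined); consider jitter_coincident()")
  }
  radius <- radius %||% default_band_radius(pts)
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0) {
    stop_validation("`radius` must be a single positive number of meters")
  }
  keep <- d > 0 & d <= radius
  w <- matrix(0, n, n)
  w[keep] <- 1 / d[keep]
  # general (not symmetric-triangle) storage: downstream code walks the
  # full neighbour set of every unit through the @p/@i/@x slots
  w <- methods::as(methods::as(Matrix::Matrix(w, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  counts <- as.integer(Matrix::rowSums(w > 0))
  out <- list(
    w = w,
    ids = pts$unit_id,
    coords = pts[, c("x", "y")],
    radius = radius,
    neighbor_counts = counts,
    isolated = counts == 0L
  )
  class(out) <- "distband_weights"
  out
}

#' Default distance-band radius
#'
#' The maximum nearest-neighbour distance over the point set: the smallest
#' band radius under which every unit has at least one neighbour.
#'
#' @inheritParams build_weights
#' @return radius in meters.
#' @export
default_band_radius <- function(points) {
  pts <- as_pointset(points)
  d <- as.matrix(dist(pts[, c("x", "y")]))
  diag(d) <- Inf
  max(apply(d, 1L, min))
}

# validate and normalize point input; enforces PointSet invariants
as_pointset <- function(points) {
  if (is.matrix(points)) {
    points <- data.frame(x = points[, 1], y = points[, 2])
  }
  if (!is.data.frame(points) || !all(c("x", "y") %in% names(points))) {
    stop_validation("`points` needs numeric columns `x` and `y`")
  }
  if (!all(is.finite(points$x)) || !all(is.finite(points$y))) {
    stop_validation("non-finite coordinates in `points`")
  }
  ids <- points$unit_id %||% seq_len(nrow(points))
  if (anyDuplicated(ids)) stop_validation("unit_id values must be unique")
  data.frame(unit_id = ids, x = points$x, y = points$y,
             stringsAsFactors = FALSE)
}

#' @export
print.distband_weights <- function(x, ...) {
  cat("Distance-band inverse-distance weights\n")
  cat(sprintf("  units: %d   radius: %.1f m\n", length(x$ids), x$radius))
  cat(sprintf("  stored pairs: %d (symmetric)   isolated units: %d\n",
              length(x$w@x), sum(x$isolated)))
  cat(sprintf("  neighbours per unit: median %.0f [%d, %d]\n",
              median(x$neighbor_counts), min(x$neighbor_counts),
              max(x$neighbor_counts)))
  invisible(x)
}

#' Extract the pair list of a weights object
#'
#' @param weights a `distband_weights` object.
#' @return data.frame with columns `i`, `j` (unit ids) and `w`; both (i,j)
#'   and (j,i) are present, mirroring the symmetric storage.
#' @export
weights_pairs <- function(weights) {
  stopifnot(inherits(weights, "distband_weights"))
  tw <- methods::as(weights$w, "TsparseMatrix")
  data.frame(i = weights$ids[tw@i + 1L], j = weights$ids[tw@j + 1L], w = tw@x)
}

# style "W": row-standardized inverse-distance (the default for irregular
# point data); "B": binary within-band indicators; "raw": stored 1/d.
# Isolated rows stay all-zero in every style.
style_weights <- function(weights, style = c("W", "B", "raw")) {
  style <- match.arg(style)
  w <- weights$w
  if (style == "B") {
    w <- methods::as((w > 0) * 1, "CsparseMatrix")
  } else if (style == "W") {
    rs <- Matrix::rowSums(w)
    w <- Matrix::Diagonal(x = ifelse(rs > 0, 1 / rs, 0)) %*% w
  }
  w
}
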