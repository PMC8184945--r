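#' Surface patch and topographic-map ROI
#'
#' A `surface_patch` is a set of 2-D vertex positions (millimetres) on the
#' flattened/smoothed cortical surface. An `roi_map` marks a topographic map
#' on a patch: the recording-site positions and two border polylines, one at
#' the lowest and one at the highest preferred numerosity.
#'
#' @param vertices Data.frame or matrix with columns `x_mm`, `y_mm`
#'   (>= 3 vertices, finite).
#' @return `surface_patch` returns an object of class `surface_patch`.
#' @export
surface_patch <- function(vertices) {
  v <- as.data.frame(vertices)
  if (!all(c("x_mm", "y_mm") %in% names(v))) {
    if (ncol(v) >= 2) names(v)[1:2] <- c("x_mm", "y_mm") else stopf("need x_mm and y_mm")
  }
  if (nrow(v) < 3) stopf("a patch needs at least 3 vertices")
  if (!all(is.finite(v$x_mm)) || !all(is.finite(v$y_mm))) stopf("coordinates must be finite")
  structure(list(vertices = v[, c("x_mm", "y_mm")]), class = "surface_patch")
}

#' @rdname surface_patch
#' @param sites Data.frame with site `id`, `x_mm`, `y_mm`.
#' @param low_border,high_border Polylines (matrices/data.frames of ordered
#'   x, y points, millimetres) marking the lowest- and highest-preference map
#'   edges.
#' @return `roi_map` returns an object of class `roi_map`.
#' @export
roi_map <- function(sites, low_border, high_border) {
  as_poly <- function(b) {
    m <- as.matrix(as.data.frame(b)[, 1:2])
    storage.mode(m) <- "double"
    if (nrow(m) < 1) stopf("borders must be non-empty")
    m
  }
  s <- as.data.frame(sites)
  if (!"id" %in% names(s)) s$id <- seq_len(nrow(s))
  stopifnot(all(c("x_mm", "y_mm") %in% names(s)))
  structure(list(sites = s[, c("id", "x_mm", "y_mm")],
                 low_border = as_poly(low_border),
                 high_border = as_poly(high_border)),
            class = "roi_map")
}

#' Distance from a point to the nearest point of a border polyline
#'
#' Minimum Euclidean distance from each site to any segment of the polyline
#' (a single-point "polyline" degenerates to point-to-point distance).
#'
#' @param points Matrix/data.frame of site positions (x, y in mm); a single
#'   point may be given as a length-2 vector.
#' @param border Polyline matrix of ordered (x, y) points.
#' @return Numeric vector of distances in millimetres.
#' @export
border_distance <- function(points, border) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  P <- as.matrix(as.data.frame(points)[, 1:2])
  B <- as.matrix(border)
  if (nrow(B) < 1) stopf("border polyline is empty")
  if (nrow(B) == 1) return(sqrt((P[, 1] - B[1, 1])^2 + (P[, 2] - B[1, 2])^2))
  d <- rep(Inf, nrow(P))
  for (s in seq_len(nrow(B) - 1)) {
    a <- B[s, ]; b <- B[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      ds <- sqrt((P[, 1] - a[1])^2 + (P[, 2] - a[2])^2)
    } else {
      t <- ((P[, 1] - a[1]) * ab[1] + (P[, 2] - a[2]) * ab[2]) / len2
      t <- pmin(pmax(t, 0), 1)
      ds <- sqrt((P[, 1] - (a[1] + t * ab[1]))^2 + (P[, 2] - (a[2] + t * ab[2]))^2)
    }
    d <- pmin(d, ds)
  }
  d
}

#' Normalized position between the map borders
#'
#' The ratio `d_low / (d_low + d_high)` of a site's distances to the
#' low- and high-preference borders: 0 on the low border, 1 on the high
#' border. It is invariant under rigid motions of the patch.
#'
#' @param d_low,d_high Distances (mm) to the low/high border.
#' @return Normalized position u in [0, 1].
#' @export
normalized_position <- function(d_low, d_high) {
  tot <- d_low + d_high
  if (any(tot <= 0)) stopf("site lies on both borders; normalized position undefined")
  d_low / tot
}

#' Cortical distance along the map
#'
#' Scales the normalized position by the mean ROI length (the mean over
#' sites of `d_low + d_high`), giving a distance in millimetres comparable
#' across sites.
#'
#' @param u Normalized positions.
#' @param mean_roi_length_mm Mean map length in mm (> 0).
#' @return Distances in millimetres.
#' @export
site_distance <- function(u, mean_roi_length_mm) {
  if (mean_roi_length_mm <= 0) stopf("mean ROI length must be > 0")
  u * mean_roi_length_mm
}

#' Per-site geometry of a topographic map
#'
#' Computes, for every recording site of an ROI, the distances to the low-
#' and high-preference borders, the normalized position, and the cortical
#' distance scaled by the mean ROI length.
#'
#' @param roi An [roi_map()].
#' @return Data.frame with columns `id`, `d_low_mm`, `d_high_mm`, `u`,
#'   `distance_mm`; the mean ROI length is attached as attribute
#'   `mean_length_mm`.
#' @export
site_geometry <- function(roi) {
  stopifnot(inherits(roi, "roi_map"))
  P <- as.matrix(roi$sites[, c("x_mm", "y_mm")])
  d_low <- border_distance(P, roi$low_border)
  d_high <- border_distance(P, roi$high_border)
  u <- normalized_position(d_low, d_high)
  len <- mean(d_low + d_high)
  out <- data.frame(id = roi$sites$id, d_low_mm = d_low, d_high_mm = d_high,
                    u = u, distance_mm = site_distance(u, len))
  attr(out, "mean_length_mm") <- len
  out
}

#' Bin values along the map
#'
#' Left-closed, right-open bins starting at 0 along cortical distance
#' (`bin_by_distance`, default 2 mm) or normalized position
#' (`bin_by_fraction`, default 10%). Empty bins are dropped; the standard
#' error is reported only for bins with at least two sites.
#'
#' @param values Quantity to bin (e.g. preferred numerosity).
#' @param distances Cortical distances in mm (`bin_by_distance`) or
#'   normalized positions (`bin_by_fraction`).
#' @param width Bin width (2 mm / 0.10 by default).
#' @return A `bin_series` data.frame: `bin_lo`, `bin_hi`, `mid` (nominal bin
#'   centre), `x_mean` (mean of the binning variable within the bin), `mean`,
#'   `se`, `n`.
#' @export
bin_by_distance <- function(values, distances, width = 2) {
  if (length(values) != length(distances)) stopf("values and distances differ in length")
  if (width <= 0) stopf("bin width must be > 0")
  idx <- floor(distances / width + 1e-9)   # tolerance for edge values hit by fp error
  idx[distances < 0] <- NA
  keep <- !is.na(idx)
  ids <- sort(unique(idx[keep]))
  out <- do.call(rbind, lapply(ids, function(b) {
    sel <- keep & idx == b
    v <- values[sel]
    data.frame(bin_lo = b * width, bin_hi = (b + 1) * width,
               mid = (b + 0.5) * width, x_mean = mean(distances[sel]),
               mean = mean(v), se = sem(v), n = length(v))
  }))
  structure(out, class = c("bin_series", "data.frame"))
}

#' @rdname bin_by_distance
#' @param u Normalized positions in [0, 1].
#' @export
bin_by_fraction <- function(values, u, width = 0.10) {
  # sites exactly at u = 1 belong to the last bin rather than a new one
  idx <- pmin(floor(u / width + 1e-9), ceiling(1 / width) - 1)
  bin_by_distance(values, idx * width + width / 2, width)
}
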