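# Contour geometry: closed planar polygons in calibrated (um) coordinates.
# A contour is an n x 2 matrix of (x, y) vertices, implicitly closed
# (first vertex follows the last), counterclockwise canonical orientation.

#' Construct and validate a closed contour
#'
#' Canonicalizes a polygon to counterclockwise orientation and checks the
#' contour invariants: at least 3 distinct vertices, positive enclosed area
#' and (optionally) simplicity (no self-intersection).
#'
#' @param xy n x 2 numeric matrix of (x, y) vertices in um; a duplicated
#'   closing vertex is dropped.
#' @param check_simple if TRUE (default), run the O(n^2) pairwise
#'   edge-intersection check and fail on self-intersecting input.
#' @return the canonicalized contour matrix.
#' @export
makeContour <- function(xy, check_simple = TRUE) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L) stop("contour must be an n x 2 matrix of (x, y) vertices")
  n <- nrow(xy)
  if (n >= 2L && all(xy[1, ] == xy[n, ])) xy <- xy[-n, , drop = FALSE]
  xy <- xy[c(TRUE, rowSums(abs(diff(xy))) > 0), , drop = FALSE]
  if (nrow(xy) < 3L) stop("contour needs at least 3 distinct vertices")
  a <- signedArea(xy)
  if (abs(a) < .Machine$double.eps * 100)
    stop("degenerate contour: enclosed area is zero")
  if (a < 0) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  if (check_simple && !isSimplePolygon(xy))
    stop("contour is self-intersecting")
  unname(xy)
}

signedArea <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x); j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Test whether a closed polygon is simple (non-self-intersecting)
#'
#' Pairwise proper-intersection test over all non-adjacent edge pairs.
#'
#' @param xy n x 2 vertex matrix (closed implicitly).
#' @return logical.
#' @export
isSimplePolygon <- function(xy) {
  n <- nrow(xy)
  p <- xy; q <- xy[c(2:n, 1L), , drop = FALSE]
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  # skip adjacent edges (sharing a vertex), incl. the wrap-around pair
  adj <- idx[, 2] - idx[, 1] == 1L | (idx[, 1] == 1L & idx[, 2] == n)
  idx <- idx[!adj, , drop = FALSE]
  if (!nrow(idx)) return(TRUE)
  a1 <- p[idx[, 1], , drop = FALSE]; a2 <- q[idx[, 1], , drop = FALSE]
  b1 <- p[idx[, 2], , drop = FALSE]; b2 <- q[idx[, 2], , drop = FALSE]
  cr <- function(o, a, b) (a[, 1] - o[, 1]) * (b[, 2] - o[, 2]) -
                          (a[, 2] - o[, 2]) * (b[, 1] - o[, 1])
  d1 <- cr(a1, a2, b1); d2 <- cr(a1, a2, b2)
  d3 <- cr(b1, b2, a1); d4 <- cr(b1, b2, a2)
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

#' Polygon area by the shoelace formula
#'
#' @param contour n x 2 vertex matrix in um (implicitly closed). Orientation
#'   is immaterial: the absolute area is returned.
#' @param check_simple if TRUE, reject self-intersecting polygons.
#' @return enclosed area in um^2.
#' @export
polygonArea <- function(contour, check_simple = FALSE) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 3L) stop("contour needs at least 3 vertices")
  if (check_simple && !isSimplePolygon(contour))
    stop("self-intersecting contour")
  abs(signedArea(contour))
}

#' Polygon perimeter
#'
#' @param contour n x 2 vertex matrix (implicitly closed).
#' @return perimeter length in um.
#' @export
polygonPerimeter <- function(contour) {
  contour <- as.matrix(contour)
  n <- nrow(contour)
  d <- contour[c(2:n, 1L), , drop = FALSE] - contour
  sum(sqrt(rowSums(d * d)))
}

#' Polygon centroid (area-weighted)
#'
#' @param contour n x 2 vertex matrix (implicitly closed).
#' @return (x, y) centroid in um.
#' @export
polygonCentroid <- function(contour) {
  contour <- as.matrix(contour)
  x <- contour[, 1]; y <- contour[, 2]
  n <- length(x); j <- c(2:n, 1L)
  w <- x * y[j] - x[j] * y
  a <- sum(w) / 2
  if (abs(a) < .Machine$double.eps * 100) return(colMeans(contour))
  c(sum((x + x[j]) * w), sum((y + y[j]) * w)) / (6 * a)
}

#' Circularity index of a contour
#'
#' The roundness measure 4 * pi * Area / Perimeter^2: equal to 1 when the
#' shape approximates a mathematically perfect circle and smaller for
#' elongated or irregular outlines. Contours traced from rasters can exceed
#' 1 by a small rasterization slack; values are returned raw (see
#' \code{clip}).
#'
#' @param contour n x 2 vertex matrix (implicitly closed).
#' @param clip if TRUE, clip values above 1 down to 1 (report convention);
#'   default FALSE returns the raw index.
#' @return unitless circularity.
#' @export
circularity <- function(contour, clip = FALSE) {
  a <- polygonArea(contour)
  p <- polygonPerimeter(contour)
  if (p <= 0) stop("degenerate contour: zero perimeter")
  ci <- 4 * pi * a / p^2
  if (clip) min(ci, 1) else ci
}

#' Feret (maximum caliper) diameter of a contour
#'
#' The largest pairwise distance between contour points, computed over the
#' convex hull vertices (the maximum is always attained on the hull).
#'
#' @param contour n x 2 vertex matrix.
#' @return Feret diameter in um.
#' @export
feretDiameter <- function(contour) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 2L) stop("contour needs at least 2 vertices")
  h <- contour[grDevices::chull(contour), , drop = FALSE]
  if (nrow(h) == 1L) return(0)
  d2 <- outer(h[, 1], h[, 1], "-")^2 + outer(h[, 2], h[, 2], "-")^2
  sqrt(max(d2))
}

#' Epithelium area from the bronchiole and lumen areas
#'
#' The epithelium area is the difference between the bronchiole area (within
#' the external, basal-membrane limit) and the lumen area (within the
#' internal limit). It may legitimately be smaller than the lumen area.
#'
#' @param bronchiole_area_um2 area within the external limit, um^2.
#' @param lumen_area_um2 area within the internal limit, um^2.
#' @return epithelium area in um^2.
#' @export
epitheliumArea <- function(bronchiole_area_um2, lumen_area_um2) {
  if (any(bronchiole_area_um2 < 0) || any(lumen_area_um2 < 0))
    stop("areas must be non-negative")
  out <- bronchiole_area_um2 - lumen_area_um2
  if (any(out < 0))
    stop("geometry inconsistency: lumen area exceeds bronchiole area ",
         "(internal contour not inside external contour?)")
  out
}

#' Point-in-polygon test (even-odd rule)
#'
#' @param px,py point coordinates (vectors).
#' @param contour n x 2 vertex matrix (implicitly closed).
#' @return logical vector.
#' @export
pointInPolygon <- function(px, py, contour) {
  contour <- as.matrix(contour)
  x <- contour[, 1]; y <- contour[, 2]
  n <- length(x); j <- c(2:n, 1L)
  inside <- logical(length(px))
  for (e in seq_len(n)) {
    x1 <- x[e]; y1 <- y[e]; x2 <- x[j[e]]; y2 <- y[j[e]]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside
}

# Intersect rays from a common origin with a polygon.
# origin: (x, y); angles: radians. Returns, per ray, the distance to the
# crossing nearest the origin (NA when the ray misses the polygon).
rayPolygonDistance <- function(origin, angles, contour) {
  contour <- as.matrix(contour)
  n <- nrow(contour)
  p1 <- contour
  p2 <- contour[c(2:n, 1L), , drop = FALSE]
  ex <- p2[, 1] - p1[, 1]; ey <- p2[, 2] - p1[, 2]
  rx <- p1[, 1] - origin[1]; ry <- p1[, 2] - origin[2]
  out <- rep(NA_real_, length(angles))
  for (k in seq_along(angles)) {
    dx <- cos(angles[k]); dy <- sin(angles[k])
    den <- dx * ey - dy * ex
    ok <- abs(den) > 1e-12
    # solve origin + t*d = p1 + s*e
    t <- (rx * ey - ry * ex) / den
    s <- (rx * dy - ry * dx) / den
    # inclusive both ends so crossings exactly at a vertex are never
    # dropped (duplicate hits are harmless: the minimum is taken)
    hit <- ok & t > 1e-9 & s >= -1e-9 & s <= 1 + 1e-9
    if (any(hit)) out[k] <- min(t[hit])
  }
  out
}

#' Epithelium thickness by radial ray casting
#'
#' Casts \code{n_rays} rays from the lumen centroid at uniform angles; per
#' ray the thickness is the distance between the crossing of the internal
#' (lumen) contour and the crossing of the external (basal membrane)
#' contour, taking the crossing nearest the origin on each contour. Rays
#' that fail to cross both contours are dropped. This yields the
#' hundreds-of-measures thickness panel entry: mean, standard deviation and
#' the number of valid measures.
#'
#' @param internal lumen contour, n x 2 um matrix.
#' @param external basal-membrane contour, n x 2 um matrix.
#' @param n_rays number of rays (>= 100; default 360, i.e. 1 degree spacing).
#' @return list with \code{mean}, \code{sd}, \code{n_measures},
#'   \code{reliable} (FALSE when fewer than 100 valid measures) and the raw
#'   per-ray \code{thickness_um} vector.
#' @export
epitheliumThickness <- function(internal, external, n_rays = 360L) {
  if (n_rays < 100L) stop("n_rays must be at least 100")
  origin <- polygonCentroid(internal)
  angles <- seq(0, 2 * pi, length.out = n_rays + 1L)[-(n_rays + 1L)]
  d_int <- rayPolygonDistance(origin, angles, internal)
  d_ext <- rayPolygonDistance(origin, angles, external)
  th <- d_ext - d_int
  th <- th[!is.na(th) & th >= 0]
  reliable <- length(th) >= 100L
  if (!reliable)
    warning("fewer than 100 valid thickness measures; result flagged unreliable")
  list(mean = if (length(th)) mean(th) else NA_real_,
       sd = if (length(th) > 1L) stats::sd(th) else 0,
       n_measures = length(th), reliable = reliable, thickness_um = th)
}

#' Trace sub-pixel object contours from a binary mask
#'
#' Boundaries are extracted by marching squares on a Gaussian-smoothed copy
#' of the mask at the 0.5 iso-level. The smoothing (default sigma 1.5 px)
#' suppresses the pixel-staircase perimeter inflation that would otherwise
#' make the circularity of a true circle undershoot systematically; with it,
#' a rasterized disc traces to circularity within 0.01 of 1.
#'
#' Pixel centers sit at (index - 0.5): a segment of k pixels measures
#' k * um_per_px. The first matrix dimension maps to contour x, the second
#' to contour y.
#'
#' @param mask logical or 0/1 numeric matrix.
#' @param um_per_px scale applied to the traced coordinates (default 1:
#'   pixel units).
#' @param sigma Gaussian smoothing sd in px before iso-contouring.
#' @return list of contour matrices (um), counterclockwise, one per closed
#'   boundary (outer boundaries and holes alike).
#' @export
traceContours <- function(mask, um_per_px = 1, sigma = 1.5) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  # zero-pad beyond the blur support: closes border-touching foreground and
  # keeps the FFT-based Gaussian filter's circular wrap-around away
  pad <- if (sigma > 0) as.integer(ceiling(3 * sigma)) + 2L else 1L
  mp <- matrix(0, nrow(m) + 2L * pad, ncol(m) + 2L * pad)
  mp[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] <- m
  if (sigma > 0) mp <- as.matrix(EBImage::gblur(mp, sigma = sigma))
  xs <- (seq_len(nrow(mp)) - pad - 0.5)  # un-pad: pixel centers at index - 0.5
  ys <- (seq_len(ncol(mp)) - pad - 0.5)
  cl <- grDevices::contourLines(xs, ys, mp, levels = 0.5)
  lapply(cl, function(ct) {
    xy <- cbind(ct$x, ct$y) * um_per_px
    makeContour(xy, check_simple = FALSE)
  })
}

# Scanline polygon rasterization: TRUE for pixels whose center lies inside.
# Pixel centers at (i - 0.5, j - 0.5) in px units; contour given in px units.
rasterizePolygon <- function(contour, nrow_px, ncol_px) {
  out <- matrix(FALSE, nrow_px, ncol_px)
  x <- contour[, 1]; y <- contour[, 2]
  n <- length(x); j <- c(2:n, 1L)
  ymin <- max(1L, ceiling(min(y) + 0.5)); ymax <- min(ncol_px, floor(max(y) + 0.5))
  if (ymax < ymin) return(out)
  for (cc in ymin:ymax) {
    yc <- cc - 0.5
    y1 <- y; y2 <- y[j]
    cross <- (y1 > yc) != (y2 > yc)
    if (!any(cross)) next
    xc <- x[cross] + (yc - y1[cross]) * (x[j][cross] - x[cross]) / (y2[cross] - y1[cross])
    xc <- sort(xc)
    for (k in seq(1L, length(xc) - 1L, by = 2L)) {
      lo <- ceiling(xc[k] + 0.5); hi <- floor(xc[k + 1L] + 0.5)
      if (hi >= lo) out[max(1L, lo):min(nrow_px, hi), cc] <- TRUE
    }
  }
  out
}
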