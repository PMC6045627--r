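# Automatic detection of small bronchioles: enclosed lumina surrounded by an
# epithelial tissue ring, with external/internal limit delineation.

# labels of connected components touching the image border
.border_labels <- function(lab) {
  unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
}

# sample a logical mask at continuous px coordinates (pixel centers at i-0.5);
# out-of-canvas samples are FALSE
.sample_mask <- function(mask, x, y) {
  i <- floor(x) + 1L; j <- floor(y) + 1L
  ok <- i >= 1L & i <= nrow(mask) & j >= 1L & j <= ncol(mask)
  out <- logical(length(x))
  out[ok] <- mask[cbind(i[ok], j[ok])]
  out
}

#' Detect bronchiole candidates on a tissue mask
#'
#' A candidate is an enclosed background region (the lumen) fully surrounded
#' by an epithelial tissue ring. Lumina are found as background components
#' that do not touch the image border on a morphologically gap-closed copy
#' of the tissue mask (closing radius \code{gap_close_um}), so rings with a
#' modest gap are still detected; \code{closed_ring} records whether the
#' lumen is also enclosed in the raw mask (TRUE = topologically closed
#' ring).
#'
#' The internal limit is traced on the lumen-tissue interface
#' (\code{\link{traceContours}}). The external limit is delineated by radial
#' ray casting from the lumen centroid: per ray, the contiguous tissue run
#' beyond the internal crossing, capped at \code{max_wall_um} to avoid
#' bleeding into parenchyma; the ray endpoints form the external contour.
#' Candidates touching the image border are discarded.
#'
#' @param masks \linkS4class{StainMasks} from an H&E image.
#' @param min_lumen_feret_um smallest lumen Feret considered (default 50 um;
#'   keeps alveolar airspaces out of the candidate pool).
#' @param max_wall_um cap on the epithelial wall growth (default 60 um).
#' @param gap_close_um morphological closing radius used for lumen
#'   enclosure (default 40 um; arc gaps up to roughly this width are
#'   bridged).
#' @param n_rays rays used to delineate the external limit.
#' @param min_wall_um,min_wall_coverage solid-wall gate: a candidate is kept
#'   only when at least \code{min_wall_coverage} of its rays meet a
#'   contiguous tissue wall of at least \code{min_wall_um} in the raw mask.
#'   This is what separates bronchiole/vessel lumina (solid wall) from
#'   alveolar airspaces (thin shared septa).
#' @param max_unbounded_frac bounded-wall gate: candidates where more than
#'   this fraction of rays never leave tissue within \code{max_wall_um}
#'   (no outer wall limit found) are rejected as parenchymal holes rather
#'   than ringed lumina.
#' @param max_wall_cv wall-regularity gate: maximum coefficient of variation
#'   (sd/mean) of the per-ray wall thickness. Genuine epithelial or vessel
#'   walls are nearly uniform around the lumen; merged parenchymal airspaces
#'   are surrounded by highly direction-dependent tissue spans.
#' @param wall_stop_mask optional logical mask treated as non-wall when
#'   growing the external limit (e.g. the PSR chromogen mask, so the basal
#'   membrane limit stops where peribronchial collagen starts).
#' @param section_id label stamped on the candidates.
#' @return list of \linkS4class{BronchioleCandidate} (possibly empty).
#' @export
detectLumina <- function(masks, min_lumen_feret_um = 50, max_wall_um = 60,
                         gap_close_um = 40, n_rays = 360L,
                         min_wall_um = 8, min_wall_coverage = 0.8,
                         max_unbounded_frac = 0.1, max_wall_cv = 0.35,
                         wall_stop_mask = NULL, section_id = "section") {
  stopifnot(is(masks, "StainMasks"))
  tissue <- masks@tissue
  upp <- masks@um_per_px
  if (!any(tissue)) return(list())
  closed <- .close_mask(tissue, gap_close_um / upp)
  wall_closed <- if (is.null(wall_stop_mask)) closed else closed & !wall_stop_mask
  wall_raw <- if (is.null(wall_stop_mask)) tissue else tissue & !wall_stop_mask
  nr <- nrow(tissue); nc <- ncol(tissue)
  rawlab <- EBImage::bwlabel(matrix(as.numeric(!tissue), nr, nc))
  raw_border <- .border_labels(rawlab)
  raw_encl <- setdiff(seq_len(max(rawlab)), raw_border)
  # closed rings: enclosed holes of the raw mask. Open rings: enclosed holes
  # of the gap-closed mask whose raw background connects to the border.
  closedlab <- EBImage::bwlabel(matrix(as.numeric(!closed), nr, nc))
  closed_encl <- setdiff(seq_len(max(closedlab)), .border_labels(closedlab))
  jobs <- lapply(raw_encl, function(lb)
    list(idx = which(rawlab == lb, arr.ind = TRUE), ring_closed = TRUE))
  for (lb in closed_encl) {
    idx <- which(closedlab == lb, arr.ind = TRUE)
    over <- setdiff(unique(rawlab[idx]), 0L)
    if (!length(over) || any(over %in% raw_encl)) next  # raw path covers it
    jobs[[length(jobs) + 1L]] <- list(idx = idx, ring_closed = FALSE)
  }
  if (!length(jobs)) return(list())
  min_lumen_px <- min_lumen_feret_um / upp
  max_wall_px <- max_wall_um / upp
  pad <- as.integer(ceiling(max_wall_px)) + 8L
  out <- list(); id <- 0L
  for (job in jobs) {
    idx <- job$idx
    ring_closed <- job$ring_closed
    # cheap bbox pre-filter before tracing
    if (sqrt(diff(range(idx[, 1]))^2 + diff(range(idx[, 2]))^2) <
        min_lumen_px - 2) next
    r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(nr, max(idx[, 1]) + pad)
    c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(nc, max(idx[, 2]) + pad)
    lum <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    lum[cbind(idx[, 1] - r0 + 1L, idx[, 2] - c0 + 1L)] <- TRUE
    cts <- traceContours(lum, um_per_px = 1)
    if (!length(cts)) next
    internal_px <- cts[[which.max(vapply(cts, polygonArea, 0))]]
    internal_px <- internal_px + rep(c(r0 - 1L, c0 - 1L), each = nrow(internal_px))
    if (feretDiameter(internal_px) * upp < min_lumen_feret_um) next
    origin <- polygonCentroid(internal_px)
    angles <- seq(0, 2 * pi, length.out = n_rays + 1L)[-(n_rays + 1L)]
    d_int <- rayPolygonDistance(origin, angles, internal_px)
    if (anyNA(d_int)) { ok <- !is.na(d_int); angles <- angles[ok]; d_int <- d_int[ok] }
    if (length(angles) < 3L) next
    # per-ray contiguous tissue run beyond the internal crossing (gap-closed
    # mask, so open rings still receive a bridged external limit)
    step <- 0.5
    ks <- seq(step / 2, max_wall_px, by = step)
    # tolerate up to ~2 px of sub-pixel mismatch between the traced internal
    # contour and the raster before the wall is considered to start
    slack <- 4L
    ray_run <- function(mask, a) {
      xx <- origin[1] + (d_int[a] + ks) * cos(angles[a])
      yy <- origin[2] + (d_int[a] + ks) * sin(angles[a])
      s <- .sample_mask(mask, xx, yy)
      first_in <- which(s)[1]
      if (is.na(first_in) || first_in > slack) return(0)
      after <- which(!s & seq_along(s) > first_in)[1]
      if (is.na(after)) max_wall_px else (after - 1L) * step
    }
    # solid-wall gate on the RAW mask: bronchiole/vessel lumina are backed by
    # a contiguous wall on most rays, alveolar airspaces only by thin septa
    runs_raw <- vapply(seq_along(angles), function(a) ray_run(wall_raw, a), 0)
    if (mean(runs_raw * upp >= min_wall_um) < min_wall_coverage) next
    # bounded-wall gate: a true epithelial/vessel wall has an outer limit;
    # rays escaping into thick parenchymal tissue hit the max_wall cap
    if (mean(runs_raw >= max_wall_px - step) > max_unbounded_frac) next
    # wall-regularity gate: a genuine wall has near-constant thickness all
    # around the lumen, unlike the direction-dependent tissue spans around a
    # parenchymal hole
    pos <- runs_raw[runs_raw > 0]
    if (length(pos) > 1L && stats::sd(pos) / mean(pos) > max_wall_cv) next
    # external limit: raw-mask wall runs for closed rings; for open rings the
    # gap-closed mask supplies a bridged basal-membrane contour
    runs <- if (ring_closed) runs_raw else
      vapply(seq_along(angles), function(a) ray_run(wall_closed, a), 0)
    external_px <- cbind(origin[1] + (d_int + runs) * cos(angles),
                         origin[2] + (d_int + runs) * sin(angles))
    # discard candidates touching the image border
    if (min(external_px) < 1 || max(external_px[, 1]) > nr - 1 ||
        max(external_px[, 2]) > nc - 1) next
    id <- id + 1L
    out[[id]] <- new("BronchioleCandidate", id = id, section_id = section_id,
                     external = external_px * upp, internal = internal_px * upp,
                     feret_um = feretDiameter(external_px) * upp,
                     closed_ring = ring_closed,
                     lumen_centroid = origin * upp)
  }
  out
}

#' Select small bronchioles by Feret diameter
#'
#' Retains candidates whose external Feret diameter lies in the inclusive
#' window [\code{min_feret_um}, \code{max_feret_um}] (default 100-500 um,
#' the small-bronchiole size range) and whose epithelial ring is closed.
#' Order is preserved; selection is idempotent.
#'
#' @param candidates list of \linkS4class{BronchioleCandidate}.
#' @param min_feret_um,max_feret_um inclusive Feret window in um.
#' @param keep_open_rings if TRUE, retain open-ring candidates too
#'   (circularity and thickness are ill-defined on open rings; off by
#'   default).
#' @return filtered list of candidates.
#' @export
selectBronchioles <- function(candidates, min_feret_um = 100,
                              max_feret_um = 500, keep_open_rings = FALSE) {
  if (min_feret_um > max_feret_um)
    stop("min_feret_um must not exceed max_feret_um")
  keep <- vapply(candidates, function(b) {
    b@feret_um >= min_feret_um & b@feret_um <= max_feret_um &
      (keep_open_rings || b@closed_ring)
  }, logical(1))
  candidates[keep]
}

#' Export bronchiole candidates as GeoJSON
#'
#' One Polygon feature per candidate (external limit as the outer ring, the
#' lumen as an inner ring), coordinates in um, with properties section_id,
#' id, feret_um and closed_ring.
#'
#' @param candidates list of \linkS4class{BronchioleCandidate}.
#' @param path output path (.geojson / .json).
#' @return the path, invisibly.
#' @export
writeCandidatesGeoJson <- function(candidates, path) {
  feat <- lapply(candidates, function(b) {
    closering <- function(m) rbind(m, m[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(section_id = b@section_id, id = b@id,
                           feret_um = b@feret_um, closed_ring = b@closed_ring),
         geometry = list(type = "Polygon",
                         coordinates = list(
                           unname(apply(closering(b@external), 1, as.list, simplify = FALSE)),
                           unname(apply(closering(b@internal), 1, as.list, simplify = FALSE)))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
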