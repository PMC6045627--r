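# Airspace-based emphysema quantification: parenchyma isolation, airspace
# enumeration and the three-parameter summary (density, Feret, count/mm^2).

.dilate_mask <- function(mask, radius_px) {
  if (radius_px < 1 || !any(mask)) return(mask)
  size <- 2L * as.integer(ceiling(radius_px)) + 1L
  brush <- EBImage::makeBrush(size, shape = "disc")
  as.matrix(EBImage::dilate(matrix(as.numeric(mask), nrow(mask), ncol(mask)),
                            brush)) > 0.5
}

#' Remove bronchi and vessels from a section, leaving parenchyma
#'
#' Every detected enclosed-lumen structure (candidate) is removed from the
#' analysis region: candidates inside the small-bronchiole window (closed
#' ring, Feret in \code{bronchiole_feret_um}, wall-to-lumen area ratio at
#' most \code{vessel_wall_ratio}) are logged as bronchioles, the rest as
#' vessel/large-airway structures. Removed regions are the external contours
#' dilated outward by \code{dilate_um}. The remaining analysis region is the
#' filled tissue footprint minus the removals; airspaces are its enclosed
#' background regions. Removal is idempotent.
#'
#' @param masks \linkS4class{StainMasks} of the H&E section.
#' @param candidates list of \linkS4class{BronchioleCandidate} from
#'   \code{\link{detectLumina}}.
#' @param dilate_um outward dilation of removed structures, um (default 10).
#' @param bronchiole_feret_um inclusive Feret window for the bronchiole
#'   class, um.
#' @param vessel_wall_ratio wall-to-lumen area ratio above which a closed,
#'   in-window ring is classified vessel rather than bronchiole.
#' @return list with \code{parenchyma} (logical mask of parenchymal tissue),
#'   \code{region} (analysis region: parenchymal tissue plus its enclosed
#'   airspaces), \code{removed} (removed mask), \code{log} (one row per
#'   removed structure: id, class, feret_um, reason) and \code{um_per_px}.
#' @export
removeBronchiVessels <- function(masks, candidates, dilate_um = 10,
                                 bronchiole_feret_um = c(100, 500),
                                 vessel_wall_ratio = 2) {
  stopifnot(is(masks, "StainMasks"))
  tissue <- masks@tissue
  upp <- masks@um_per_px
  d <- dim(tissue)
  region <- as.matrix(EBImage::fillHull(matrix(as.numeric(tissue), d[1], d[2]))) > 0.5
  removed <- matrix(FALSE, d[1], d[2])
  logs <- list()
  for (b in candidates) {
    ext <- rasterizePolygon(b@external / upp, d[1], d[2])
    removed <- removed | .dilate_mask(ext, dilate_um / upp)
    la <- polygonArea(b@internal)
    wall_ratio <- (polygonArea(b@external) - la) / la
    in_window <- b@feret_um >= bronchiole_feret_um[1] &
      b@feret_um <= bronchiole_feret_um[2]
    cls <- if (in_window && b@closed_ring && wall_ratio <= vessel_wall_ratio)
      "bronchiole" else "vessel"
    reason <- if (cls == "bronchiole") "feret in window, closed ring"
      else if (!in_window) "feret outside window"
      else if (!b@closed_ring) "open ring"
      else "wall-to-lumen ratio above threshold"
    logs[[length(logs) + 1L]] <- data.frame(id = b@id, class = cls,
                                            feret_um = b@feret_um,
                                            reason = reason,
                                            stringsAsFactors = FALSE)
  }
  region <- region & !removed
  list(parenchyma = tissue & region, region = region, removed = removed,
       log = if (length(logs)) do.call(rbind, logs) else
         data.frame(id = integer(), class = character(),
                    feret_um = numeric(), reason = character()),
       um_per_px = upp)
}

# Feret diameter of a pixel set: convex hull of pixel centers expanded to
# the pixel corners, then max pairwise distance (accounts for pixel extent).
.pixel_feret <- function(coords) {
  if (nrow(coords) == 1L) return(sqrt(2))
  h <- coords[grDevices::chull(coords), , drop = FALSE]
  corners <- rbind(h + rep(c(-0.5, -0.5), each = nrow(h)),
                   h + rep(c(-0.5, 0.5), each = nrow(h)),
                   h + rep(c(0.5, -0.5), each = nrow(h)),
                   h + rep(c(0.5, 0.5), each = nrow(h)))
  h2 <- corners[grDevices::chull(corners), , drop = FALSE]
  sqrt(max(outer(h2[, 1], h2[, 1], "-")^2 + outer(h2[, 2], h2[, 2], "-")^2))
}

#' Enumerate airspaces in the parenchyma
#'
#' Each enclosed background region inside the analysis region becomes one
#' airspace record (alveoli and ducts pooled). Regions touching the image
#' border or abutting a removed bronchus/vessel are excluded to avoid
#' truncation bias; regions below \code{min_area_um2} are dropped as
#' artifacts.
#'
#' @param parenchyma result of \code{\link{removeBronchiVessels}} (or a list
#'   with \code{parenchyma}, \code{region}, \code{removed}, \code{um_per_px}).
#' @param min_area_um2 minimum airspace area kept, um^2 (default 20).
#' @return \code{data.frame}: airspace_id, area_um2, feret_um,
#'   centroid_x_um, centroid_y_um.
#' @export
enumerateAirspaces <- function(parenchyma, min_area_um2 = 20) {
  upp <- parenchyma$um_per_px
  air <- parenchyma$region & !parenchyma$parenchyma
  empty <- data.frame(airspace_id = integer(), area_um2 = numeric(),
                      feret_um = numeric(), centroid_x_um = numeric(),
                      centroid_y_um = numeric())
  if (!any(air)) return(empty)
  lab <- EBImage::bwlabel(matrix(as.numeric(air), nrow(air), ncol(air)))
  drop <- .border_labels(lab)
  if (any(parenchyma$removed)) {
    touch <- .dilate_mask(parenchyma$removed, 1.5) & air
    drop <- c(drop, unique(lab[touch]))
  }
  labs <- lab[lab > 0]
  sizes <- tabulate(labs)
  keep <- setdiff(which(sizes >= min_area_um2 / upp^2), drop)
  if (!length(keep)) return(empty)
  idx <- which(lab > 0, arr.ind = TRUE)
  lv <- lab[lab > 0]
  sel <- lv %in% keep
  by_lab <- split.data.frame(idx[sel, , drop = FALSE], lv[sel])
  rows <- lapply(seq_along(by_lab), function(i) {
    co <- as.matrix(by_lab[[i]])
    # sub-pixel Feret from the traced boundary; pixel-corner fallback for
    # regions too small to trace
    feret_px <- if (nrow(co) >= 5L) {
      r0 <- min(co[, 1]) - 3L; c0 <- min(co[, 2]) - 3L
      loc <- matrix(FALSE, max(co[, 1]) - r0 + 4L, max(co[, 2]) - c0 + 4L)
      loc[cbind(co[, 1] - r0 + 1L, co[, 2] - c0 + 1L)] <- TRUE
      cts <- traceContours(loc, um_per_px = 1)
      if (length(cts))
        feretDiameter(cts[[which.max(vapply(cts, polygonArea, 0))]])
      else .pixel_feret(co)
    } else .pixel_feret(co)
    data.frame(airspace_id = i,
               area_um2 = nrow(co) * upp^2,
               feret_um = feret_px * upp,
               centroid_x_um = mean(co[, 1] - 0.5) * upp,
               centroid_y_um = mean(co[, 2] - 0.5) * upp)
  })
  do.call(rbind, rows)
}

#' Summarize emphysema parameters for a section
#'
#' The three emphysema parameters: (i) airspace density, the ratio of total
#' airspace area to parenchymal tissue area; (ii) the airspace Feret
#' diameter distribution (mean and 5/25/50/75/95 percent quantiles); (iii)
#' the number of airspaces per mm^2 of parenchymal tissue. The alternative
#' density convention airspace / (airspace + tissue) is reported alongside
#' as \code{density_fraction}.
#'
#' @param records airspace \code{data.frame} from
#'   \code{\link{enumerateAirspaces}}.
#' @param tissue_area_mm2 parenchymal tissue area in mm^2 (> 0).
#' @param section_id section label.
#' @return an \linkS4class{EmphysemaSummary}.
#' @export
summarizeEmphysema <- function(records, tissue_area_mm2,
                               section_id = "section") {
  if (!is.numeric(tissue_area_mm2) || length(tissue_area_mm2) != 1L ||
      !is.finite(tissue_area_mm2) || tissue_area_mm2 <= 0)
    stop("tissue_area_mm2 must be a single positive number")
  total_air <- sum(records$area_um2)
  tissue_um2 <- tissue_area_mm2 * 1e6
  n <- nrow(records)
  new("EmphysemaSummary", section_id = section_id, n_airspaces = n,
      airspace_density = total_air / tissue_um2,
      density_fraction = total_air / (total_air + tissue_um2),
      mean_feret_um = if (n) mean(records$feret_um) else NA_real_,
      feret_quantiles_um = if (n)
        stats::quantile(records$feret_um, c(.05, .25, .5, .75, .95)) else
        stats::setNames(rep(NA_real_, 5),
                        c("5%", "25%", "50%", "75%", "95%")),
      airspaces_per_mm2 = n / tissue_area_mm2,
      tissue_area_mm2 = tissue_area_mm2,
      total_airspace_area_um2 = total_air)
}

#' Full emphysema pipeline for one H&E section
#'
#' Detects enclosed-lumen structures, removes bronchi and vessels,
#' enumerates airspaces and summarizes the three emphysema parameters.
#'
#' @param masks \linkS4class{StainMasks} of the H&E section.
#' @param section_id section label.
#' @param min_area_um2 minimum airspace area, um^2.
#' @param ... passed to \code{\link{detectLumina}}.
#' @return list with \code{summary} (\linkS4class{EmphysemaSummary}),
#'   \code{airspaces} (records), \code{parenchyma} (removal result) and
#'   \code{candidates}.
#' @export
runEmphysema <- function(masks, section_id = "section", min_area_um2 = 20,
                         ...) {
  cand <- detectLumina(masks, section_id = section_id, ...)
  par <- removeBronchiVessels(masks, cand)
  rec <- enumerateAirspaces(par, min_area_um2 = min_area_um2)
  tissue_mm2 <- sum(par$parenchyma) * par$um_per_px^2 / 1e6
  list(summary = summarizeEmphysema(rec, tissue_mm2, section_id),
       airspaces = rec, parenchyma = par, candidates = cand)
}
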