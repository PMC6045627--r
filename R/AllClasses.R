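#' @import methods
#' @importFrom stats sd quantile aov kruskal.test pairwise.t.test pairwise.wilcox.test rnorm runif
#' @importFrom grDevices contourLines chull rgb2hsv
#' @importFrom utils write.csv read.csv
NULL

#' Calibrated histology image
#'
#' An 8-bit RGB raster together with its physical calibration (micrometres
#' per pixel) and a stain label. All downstream measurements are reported in
#' micrometres, converted from pixels through \code{umPerPx}.
#'
#' @slot pixels numeric array \code{rows x cols x 3}, values in [0, 255].
#' @slot um_per_px physical scale in micrometres per pixel (> 0). The default
#'   used throughout the package is 0.452 um/px, the pixel size of a x20
#'   whole-slide scan.
#' @slot stain one of \code{"HE"} (haematoxylin-eosin) or \code{"PSR"}
#'   (picrosirius red).
#' @slot section_id opaque section label carried into all output tables.
#' @exportClass CalibratedImage
setClass("CalibratedImage",
  representation(pixels = "array", um_per_px = "numeric",
                 stain = "character", section_id = "character"),
  prototype(um_per_px = 0.452, stain = "HE", section_id = "section"))

setValidity("CalibratedImage", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L) msg <- c(msg, "pixels must be rows x cols x 3")
  if (length(d) == 3L && (d[1] < 1L || d[2] < 1L)) msg <- c(msg, "raster is empty")
  if (length(object@um_per_px) != 1L || !is.finite(object@um_per_px) ||
      object@um_per_px <= 0) msg <- c(msg, "um_per_px must be a single value > 0")
  if (!object@stain %in% c("HE", "PSR")) msg <- c(msg, "stain must be 'HE' or 'PSR'")
  if (any(object@pixels < 0 | object@pixels > 255)) msg <- c(msg, "pixel values outside [0, 255]")
  if (length(msg)) msg else TRUE
})

#' Tissue and chromogen masks
#'
#' Boolean rasters congruent with the source image: \code{tissue} marks
#' stained tissue (vs bright slide background); \code{chromogen} marks
#' PSR-positive (red, collagen) pixels and is only defined for picrosirius
#' red images -- for H&E images it is an empty (0 x 0) matrix. The chromogen
#' mask is always a subset of the tissue mask.
#'
#' @slot tissue logical matrix, TRUE on tissue.
#' @slot chromogen logical matrix, TRUE on PSR-positive pixels, or 0 x 0.
#' @slot um_per_px calibration inherited from the source image.
#' @exportClass StainMasks
setClass("StainMasks",
  representation(tissue = "matrix", chromogen = "matrix", um_per_px = "numeric"))

setValidity("StainMasks", function(object) {
  msg <- character()
  if (!is.logical(object@tissue)) msg <- c(msg, "tissue mask must be logical")
  if (length(object@chromogen)) {
    if (!is.logical(object@chromogen)) msg <- c(msg, "chromogen mask must be logical")
    if (!identical(dim(object@chromogen), dim(object@tissue)))
      msg <- c(msg, "chromogen mask dimensions differ from tissue mask")
    else if (any(object@chromogen & !object@tissue))
      msg <- c(msg, "chromogen mask must be contained in tissue mask")
  }
  if (length(msg)) msg else TRUE
})

#' A detected bronchiole candidate
#'
#' Paired contours delineating one small airway: the external contour follows
#' the basal-membrane limit of the epithelium, the internal contour the lumen
#' limit of the epithelial cells. Contours are closed polygons in calibrated
#' micrometre coordinates, counterclockwise, with the internal contour
#' strictly inside the external one.
#'
#' @slot id integer candidate id within the section.
#' @slot section_id section label.
#' @slot external n x 2 matrix of (x, y) vertices in um; basal-membrane limit.
#' @slot internal n x 2 matrix of (x, y) vertices in um; lumen limit.
#' @slot feret_um largest caliper diameter of the external contour, um.
#' @slot closed_ring TRUE when the epithelial ring is topologically closed in
#'   the raw tissue mask (the lumen is a hole fully surrounded by tissue).
#' @slot lumen_centroid (x, y) centroid of the lumen, um.
#' @exportClass BronchioleCandidate
setClass("BronchioleCandidate",
  representation(id = "integer", section_id = "character",
                 external = "matrix", internal = "matrix",
                 feret_um = "numeric", closed_ring = "logical",
                 lumen_centroid = "numeric"))

setValidity("BronchioleCandidate", function(object) {
  msg <- character()
  for (nm in c("external", "internal")) {
    ct <- slot(object, nm)
    if (ncol(ct) != 2L || nrow(ct) < 3L) msg <- c(msg, paste(nm, "contour needs >= 3 (x, y) vertices"))
  }
  if (length(object@feret_um) != 1L || object@feret_um <= 0) msg <- c(msg, "feret_um must be > 0")
  if (length(msg)) msg else TRUE
})

#' Per-section emphysema summary
#'
#' Aggregates a list of airspace records into the three emphysema parameters:
#' airspace density (total airspace area over parenchymal tissue area), the
#' airspace Feret-diameter distribution, and the number of airspaces per
#' square millimetre of parenchymal tissue.
#'
#' @slot section_id section label.
#' @slot n_airspaces number of enumerated airspaces.
#' @slot airspace_density unitless: total airspace area / parenchymal tissue
#'   area. The alternative convention airspace / (airspace + tissue) is kept
#'   in \code{density_fraction}.
#' @slot density_fraction airspace area / (airspace + tissue area).
#' @slot mean_feret_um mean airspace Feret diameter, um.
#' @slot feret_quantiles_um named quantiles (5/25/50/75/95 percent) of Feret, um.
#' @slot airspaces_per_mm2 count / parenchymal tissue area in mm^2.
#' @slot tissue_area_mm2 parenchymal tissue area, mm^2.
#' @slot total_airspace_area_um2 summed airspace area, um^2.
#' @exportClass EmphysemaSummary
setClass("EmphysemaSummary",
  representation(section_id = "character", n_airspaces = "integer",
                 airspace_density = "numeric", density_fraction = "numeric",
                 mean_feret_um = "numeric", feret_quantiles_um = "numeric",
                 airspaces_per_mm2 = "numeric", tissue_area_mm2 = "numeric",
                 total_airspace_area_um2 = "numeric"))

setValidity("EmphysemaSummary", function(object) {
  msg <- character()
  if (object@tissue_area_mm2 <= 0) msg <- c(msg, "tissue_area_mm2 must be > 0")
  if (object@airspace_density < 0 || object@airspaces_per_mm2 < 0)
    msg <- c(msg, "density and count per mm^2 must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Synthetic phantom specification
#'
#' Declarative description of a synthetic histology scene with exact ground
#' truth: annular bronchioles (epithelium ring around a lumen, optionally
#' with an arc gap), thick-walled vessels, peribronchial collagen bands (for
#' the PSR palette) and a foam-like alveolar parenchyma. The seed fully
#' determines the rasterized output.
#'
#' @slot canvas_px integer (rows, cols) canvas size in pixels.
#' @slot um_per_px scale, um per pixel.
#' @slot stain "HE" or "PSR" palette.
#' @slot bronchioles list of lists with fields \code{center_um} (x, y),
#'   \code{lumen_r_um}, \code{wall_um}, optional \code{gap_deg} and
#'   \code{gap_center_deg} for an open-ring arc gap.
#' @slot vessels list of lists with \code{center_um}, \code{lumen_r_um},
#'   \code{wall_um}.
#' @slot collagen list of lists with \code{bronchiole} (index),
#'   \code{band_um} (band thickness) and \code{coverage} (arc fraction).
#' @slot foam list with \code{region_um} (xmin, xmax, ymin, ymax),
#'   \code{n}, \code{diam_range_um}, \code{septum_um}; or empty list.
#' @slot noise_sd additive Gaussian pixel noise sd on the 0-255 scale
#'   (0 disables; when enabled a typical value is 5).
#' @slot seed integer RNG seed.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(canvas_px = "integer", um_per_px = "numeric",
                 stain = "character", bronchioles = "list", vessels = "list",
                 collagen = "list", foam = "list", noise_sd = "numeric",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@canvas_px) != 2L || any(object@canvas_px < 8L))
    msg <- c(msg, "canvas_px must be two integers >= 8")
  if (object@um_per_px <= 0) msg <- c(msg, "um_per_px must be > 0")
  if (!object@stain %in% c("HE", "PSR")) msg <- c(msg, "stain must be 'HE' or 'PSR'")
  if (object@noise_sd < 0) msg <- c(msg, "noise_sd must be >= 0")
  lim <- object@canvas_px * object@um_per_px
  for (b in c(object@bronchioles, object@vessels)) {
    r <- b$lumen_r_um + b$wall_um
    if (b$center_um[1] - r < 0 || b$center_um[1] + r > lim[1] ||
        b$center_um[2] - r < 0 || b$center_um[2] + r > lim[2])
      msg <- c(msg, "bronchiole/vessel extends beyond the canvas")
    if (b$lumen_r_um <= 0 || b$wall_um < 0) msg <- c(msg, "non-positive geometry")
    off <- b$lumen_offset_um
    if (!is.null(off) && sqrt(sum(off^2)) > b$wall_um)
      msg <- c(msg, "lumen offset pushes the lumen outside the outer disc")
  }
  if (length(msg)) unique(msg) else TRUE
})

setMethod("show", "CalibratedImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("CalibratedImage '%s': %d x %d px, %.4g um/px (%.0f x %.0f um), stain %s\n",
              object@section_id, d[1], d[2], object@um_per_px,
              d[1] * object@um_per_px, d[2] * object@um_per_px, object@stain))
})

setMethod("show", "StainMasks", function(object) {
  d <- dim(object@tissue)
  cat(sprintf("StainMasks: %d x %d px, tissue %.1f%%", d[1], d[2],
              100 * mean(object@tissue)))
  if (length(object@chromogen))
    cat(sprintf(", chromogen %.1f%%", 100 * mean(object@chromogen)))
  cat("\n")
})

setMethod("show", "BronchioleCandidate", function(object) {
  cat(sprintf("BronchioleCandidate #%d (%s): Feret %.1f um, %s ring\n",
              object@id, object@section_id, object@feret_um,
              if (object@closed_ring) "closed" else "open"))
})

setMethod("show", "EmphysemaSummary", function(object) {
  cat(sprintf(paste0("EmphysemaSummary '%s': %d airspaces, density %.3f, ",
                     "mean Feret %.1f um, %.1f airspaces/mm^2 (tissue %.3f mm^2)\n"),
              object@section_id, object@n_airspaces, object@airspace_density,
              object@mean_feret_um, object@airspaces_per_mm2,
              object@tissue_area_mm2))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d x %d px at %.4g um/px, stain %s, %d bronchiole(s), %d vessel(s), foam n=%s, seed %d\n",
              object@canvas_px[1], object@canvas_px[2], object@um_per_px,
              object@stain, length(object@bronchioles), length(object@vessels),
              if (length(object@foam)) object@foam$n else 0L, object@seed))
})

# ---- accessors ----

#' Accessors for airwaymorph S4 containers
#'
#' @param x a \linkS4class{CalibratedImage}, \linkS4class{StainMasks},
#'   \linkS4class{BronchioleCandidate} or \linkS4class{EmphysemaSummary}.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("umPerPx", function(x) standardGeneric("umPerPx"))
#' @rdname accessors
#' @export
setMethod("umPerPx", "CalibratedImage", function(x) x@um_per_px)
#' @rdname accessors
#' @export
setMethod("umPerPx", "StainMasks", function(x) x@um_per_px)

#' @rdname accessors
#' @export
setGeneric("imagePixels", function(x) standardGeneric("imagePixels"))
#' @rdname accessors
#' @export
setMethod("imagePixels", "CalibratedImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("stainType", function(x) standardGeneric("stainType"))
#' @rdname accessors
#' @export
setMethod("stainType", "CalibratedImage", function(x) x@stain)

#' @rdname accessors
#' @export
setGeneric("sectionId", function(x) standardGeneric("sectionId"))
#' @rdname accessors
#' @export
setMethod("sectionId", "CalibratedImage", function(x) x@section_id)

#' @rdname accessors
#' @export
setGeneric("tissueMask", function(x) standardGeneric("tissueMask"))
#' @rdname accessors
#' @export
setMethod("tissueMask", "StainMasks", function(x) x@tissue)

#' @rdname accessors
#' @export
setGeneric("chromogenMask", function(x) standardGeneric("chromogenMask"))
#' @rdname accessors
#' @export
setMethod("chromogenMask", "StainMasks", function(x) x@chromogen)

#' @rdname accessors
#' @export
setGeneric("externalContour", function(x) standardGeneric("externalContour"))
#' @rdname accessors
#' @export
setMethod("externalContour", "BronchioleCandidate", function(x) x@external)

#' @rdname accessors
#' @export
setGeneric("internalContour", function(x) standardGeneric("internalContour"))
#' @rdname accessors
#' @export
setMethod("internalContour", "BronchioleCandidate", function(x) x@internal)

#' @rdname accessors
#' @export
setGeneric("feretUm", function(x) standardGeneric("feretUm"))
#' @rdname accessors
#' @export
setMethod("feretUm", "BronchioleCandidate", function(x) x@feret_um)

#' @rdname accessors
#' @export
setGeneric("closedRing", function(x) standardGeneric("closedRing"))
#' @rdname accessors
#' @export
setMethod("closedRing", "BronchioleCandidate", function(x) x@closed_ring)

#' Coerce an emphysema summary to a one-row data frame
#'
#' @param x an \linkS4class{EmphysemaSummary}.
#' @param row.names,optional,... passed for generic compatibility, unused.
#' @return one-row \code{data.frame} mirroring the per-section summary CSV.
#' @export
as.data.frame.EmphysemaSummary <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(section_id = x@section_id,
             n_airspaces = x@n_airspaces,
             airspace_density = x@airspace_density,
             density_fraction = x@density_fraction,
             mean_feret_um = x@mean_feret_um,
             airspaces_per_mm2 = x@airspaces_per_mm2,
             tissue_area_mm2 = x@tissue_area_mm2,
             total_airspace_area_um2 = x@total_airspace_area_um2,
             stringsAsFactors = FALSE)
}
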