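# Reading/writing calibrated rasters and separating stains into masks.

#' Default whole-slide calibration: um per pixel at x20 magnification
#'
#' Pixel size of a x20 whole-slide scan, 0.452 um/px.
#' @export
DEFAULT_UM_PER_PX <- 0.452

#' Load a calibrated histology image
#'
#' Reads a 2-D RGB raster (PNG or TIFF, tiled or stripped) and attaches the
#' physical calibration and stain label. Pixels are canonicalized to 8-bit
#' (0-255); deeper inputs (e.g. 16-bit TIFF) are linearly rescaled so the
#' full input range maps onto 0-255. Grayscale input is expanded to three
#' identical channels; an alpha channel, if present, is dropped.
#'
#' @param path file path (PNG or TIFF).
#' @param um_per_px calibration in um per pixel (> 0); defaults to the x20
#'   scan pixel size 0.452 um/px.
#' @param stain "HE" or "PSR".
#' @param section_id section label; defaults to the file name.
#' @return a \linkS4class{CalibratedImage}.
#' @export
loadImage <- function(path, um_per_px = DEFAULT_UM_PER_PX, stain = c("HE", "PSR"),
                      section_id = NULL) {
  stain <- match.arg(stain)
  if (!is.numeric(um_per_px) || length(um_per_px) != 1L || !is.finite(um_per_px) ||
      um_per_px <= 0)
    stop("um_per_px must be a single positive number")
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("failed to decode image '", path,
                                           "': ", conditionMessage(e)))
  a <- EBImage::imageData(img)  # [x = width, y = height(, channels)], 0..1
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (length(dim(a)) != 3L) stop("not a 2-D image: ", path)
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] != 3L) stop("image is not RGB (", dim(a)[3], " channels): ", path)
  # EBImage reads [x, y]; canonical storage is [row, col, channel]
  px <- aperm(a, c(2L, 1L, 3L)) * 255
  newCalibratedImage(px, um_per_px, stain,
                     section_id %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a CalibratedImage from an in-memory raster
#'
#' @param pixels rows x cols x 3 array, values 0-255.
#' @param um_per_px scale in um/px.
#' @param stain "HE" or "PSR".
#' @param section_id section label.
#' @return a \linkS4class{CalibratedImage}.
#' @export
newCalibratedImage <- function(pixels, um_per_px = DEFAULT_UM_PER_PX,
                               stain = "HE", section_id = "section") {
  new("CalibratedImage", pixels = pixels, um_per_px = um_per_px,
      stain = stain, section_id = as.character(section_id))
}

#' Save a calibrated image (or a mask) to PNG/TIFF
#'
#' @param img a \linkS4class{CalibratedImage}, or a logical matrix (written
#'   as a single-channel 0/255 mask).
#' @param path output path; format from the extension (.png or .tif/.tiff).
#' @return the path, invisibly.
#' @export
saveImage <- function(img, path) {
  if (is(img, "CalibratedImage")) {
    a <- aperm(img@pixels, c(2L, 1L, 3L)) / 255
    e <- EBImage::Image(a, colormode = "Color")
  } else if (is.matrix(img)) {
    e <- EBImage::Image(t(matrix(as.numeric(img), nrow(img), ncol(img))))
  } else stop("unsupported object for saveImage")
  EBImage::writeImage(e, path)
  invisible(path)
}

#' Construct stain masks directly
#'
#' @param tissue logical tissue matrix.
#' @param chromogen logical chromogen matrix or NULL (undefined, for H&E).
#' @param um_per_px calibration.
#' @return a \linkS4class{StainMasks}.
#' @export
newStainMasks <- function(tissue, chromogen = NULL, um_per_px = DEFAULT_UM_PER_PX) {
  new("StainMasks", tissue = tissue,
      chromogen = if (is.null(chromogen)) matrix(logical(0), 0, 0) else chromogen,
      um_per_px = um_per_px)
}

# morphological closing with a disc brush; radius in px (0 = no-op)
.close_mask <- function(mask, radius_px) {
  if (radius_px < 1) return(mask)
  size <- 2L * as.integer(ceiling(radius_px)) + 1L
  brush <- EBImage::makeBrush(size, shape = "disc")
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  as.matrix(EBImage::closing(m, brush)) > 0.5
}

# drop connected components below min_px pixels
.drop_specks <- function(mask, min_px) {
  if (min_px <= 1 || !any(mask)) return(mask)
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

.segment_tissue_core <- function(px, bg_min_channel, closing_radius_px) {
  bg <- pmin(px[, , 1], px[, , 2], px[, , 3]) > bg_min_channel
  .close_mask(!bg, closing_radius_px)
}

#' Segment tissue from bright slide background
#'
#' A pixel is background when its darkest channel exceeds
#' \code{bg_min_channel} (default 220 of 255): stained tissue always pulls
#' at least one channel down, while bare glass is bright in all three. The
#' raw mask is cleaned with a morphological closing (disc radius 2 px) and
#' connected components smaller than \code{min_object_um2} are dropped as
#' specks.
#'
#' Large sections can be processed tile-wise (\code{tile_px}) with a 64-px
#' overlap; thresholding and closing are local operations, so tiled and
#' whole-image results agree (speck removal runs globally after merging).
#'
#' @param img a \linkS4class{CalibratedImage}.
#' @param bg_min_channel background threshold on min(R, G, B), 0-255.
#' @param closing_radius_px morphological closing radius in px.
#' @param min_object_um2 minimum object area kept, um^2 (default 50).
#' @param tile_px optional tile edge in px for tile-wise processing.
#' @return a \linkS4class{StainMasks} with the tissue mask filled and the
#'   chromogen mask empty. Warns (not errors) on a fully background image.
#' @export
segmentTissue <- function(img, bg_min_channel = 220, closing_radius_px = 2,
                          min_object_um2 = 50, tile_px = NULL) {
  stopifnot(is(img, "CalibratedImage"))
  px <- img@pixels
  if (is.null(tile_px)) {
    tissue <- .segment_tissue_core(px, bg_min_channel, closing_radius_px)
  } else {
    overlap <- 64L
    nr <- dim(px)[1]; nc <- dim(px)[2]
    tissue <- matrix(FALSE, nr, nc)
    r0 <- seq(1L, nr, by = tile_px)
    c0 <- seq(1L, nc, by = tile_px)
    for (r in r0) for (cc in c0) {
      ri <- max(1L, r - overlap):min(nr, r + tile_px - 1L + overlap)
      ci <- max(1L, cc - overlap):min(nc, cc + tile_px - 1L + overlap)
      sub <- .segment_tissue_core(px[ri, ci, , drop = FALSE],
                                  bg_min_channel, closing_radius_px)
      ri_core <- r:min(nr, r + tile_px - 1L)
      ci_core <- cc:min(nc, cc + tile_px - 1L)
      tissue[ri_core, ci_core] <- sub[ri_core - ri[1] + 1L, ci_core - ci[1] + 1L]
    }
  }
  min_px <- min_object_um2 / img@um_per_px^2
  tissue <- .drop_specks(tissue, min_px)
  if (!any(tissue)) warning("no tissue detected: image appears fully background")
  newStainMasks(tissue, NULL, img@um_per_px)
}

#' Separate picrosirius-red chromogen from a PSR image
#'
#' Flags red-dominant pixels (collagen) inside the tissue mask by
#' color-space thresholding: hue inside a window around red (default -20 to
#' +25 degrees) with saturation above \code{sat_min} (default 0.25).
#' Desaturated (gray) pixels are never chromogen-positive.
#'
#' @param img a \linkS4class{CalibratedImage} with stain "PSR".
#' @param hue_min,hue_max hue window in degrees around red (0 = pure red;
#'   negative values wrap below 360).
#' @param sat_min minimum HSV saturation.
#' @param masks optional precomputed \linkS4class{StainMasks} (tissue);
#'   computed with default settings when missing.
#' @param ... passed on to \code{\link{segmentTissue}} when \code{masks} is
#'   missing.
#' @return a \linkS4class{StainMasks} with both tissue and chromogen masks;
#'   the chromogen mask is always contained in the tissue mask.
#' @export
separatePsr <- function(img, hue_min = -20, hue_max = 25, sat_min = 0.25,
                        masks = NULL, ...) {
  stopifnot(is(img, "CalibratedImage"))
  if (img@stain != "PSR")
    stop("stain mismatch: separatePsr requires a PSR image, got ", img@stain)
  if (is.null(masks)) masks <- segmentTissue(img, ...)
  px <- img@pixels
  d <- dim(px)
  hsv <- grDevices::rgb2hsv(rbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
                                  as.vector(px[, , 3])), maxColorValue = 255)
  hue <- hsv[1, ] * 360
  # fold into signed degrees around red so a [-20, 25] window is contiguous
  hue_signed <- ifelse(hue > 180, hue - 360, hue)
  red <- hue_signed >= hue_min & hue_signed <= hue_max & hsv[2, ] > sat_min
  chrom <- matrix(red, d[1], d[2]) & masks@tissue
  newStainMasks(masks@tissue, chrom, img@um_per_px)
}
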