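# Peribronchial collagen quantification on picrosirius-red sections.

#' Peribronchial analysis band around a bronchiole
#'
#' The annular region between the external (basal membrane) limit and its
#' outward offset by \code{band_width_um}, rasterized on the image grid,
#' optionally clipped to tissue and excluding other bronchioles' interiors.
#' Collagen inside the epithelium itself never counts: only the surrounding
#' band does.
#'
#' @param external external contour in um (n x 2 matrix).
#' @param band_width_um outward band width, um (> 0).
#' @param dim_px canvas dimensions c(rows, cols) in px.
#' @param um_per_px calibration.
#' @param tissue optional logical tissue mask to clip the band to.
#' @param exclude optional logical mask of regions to exclude (e.g. the
#'   union of other bronchioles' external regions).
#' @return logical band mask (rows x cols).
#' @export
peribronchialBand <- function(external, band_width_um, dim_px, um_per_px,
                              tissue = NULL, exclude = NULL) {
  if (band_width_um <= 0) stop("band_width_um must be > 0")
  poly_px <- as.matrix(external) / um_per_px
  region <- rasterizePolygon(poly_px, dim_px[1], dim_px[2])
  if (!any(region)) stop("external contour rasterizes to an empty region")
  # distance from each outside pixel to the bronchiole region
  dm <- as.matrix(EBImage::distmap(matrix(as.numeric(!region), dim_px[1], dim_px[2])))
  band <- !region & dm <= band_width_um / um_per_px
  if (!is.null(tissue)) band <- band & tissue
  if (!is.null(exclude)) band <- band & !exclude
  band
}

#' Peribronchial collagen percentage
#'
#' The collagen content around a small bronchiole expressed in percent: the
#' ratio of the peribronchial picrosirius-red-positive area to the sum of
#' the epithelium area and that peribronchial PSR area,
#' 100 * psr / (epithelium + psr).
#'
#' @param psr_area_um2 peribronchial PSR-positive area, um^2 (>= 0).
#' @param epithelium_area_um2 epithelium area, um^2 (>= 0).
#' @return percentage in [0, 100].
#' @export
collagenPercent <- function(psr_area_um2, epithelium_area_um2) {
  if (any(psr_area_um2 < 0) || any(epithelium_area_um2 < 0))
    stop("areas must be non-negative")
  if (any(psr_area_um2 + epithelium_area_um2 == 0))
    stop("undefined collagen percentage: PSR and epithelium areas both zero")
  100 * psr_area_um2 / (epithelium_area_um2 + psr_area_um2)
}

#' Quantify peribronchial collagen on a PSR section
#'
#' For each bronchiole, measures the PSR-positive (chromogen) area inside
#' the peribronchial band and reports the collagen percentage
#' 100 * psr / (epithelium + psr). Bronchioles can be supplied from a serial
#' H&E section (optionally mapped onto the PSR frame by an affine
#' transform), or detected directly on the PSR image (same-image mode) when
#' \code{candidates} is NULL.
#'
#' @param psr_img a \linkS4class{CalibratedImage} with stain "PSR".
#' @param candidates list of \linkS4class{BronchioleCandidate}, or NULL to
#'   detect and select them on the PSR image itself.
#' @param band_width_um peribronchial band width, um (default 25; the
#'   dominant free parameter of the measurement).
#' @param transform optional 2 x 3 affine matrix mapping serial-section um
#'   coordinates (x, y, 1) onto the PSR frame.
#' @param masks optional precomputed \linkS4class{StainMasks} with the
#'   chromogen mask (from \code{\link{separatePsr}}).
#' @param ... passed to \code{\link{detectLumina}} /
#'   \code{\link{selectBronchioles}} in same-image mode.
#' @return \code{data.frame}, one row per bronchiole: bronchiole_id,
#'   epithelium_area_um2, peribronchial_psr_area_um2, collagen_percent,
#'   band_width_um. Empty (zero-row) when no bronchioles.
#' @export
quantifyCollagen <- function(psr_img, candidates = NULL, band_width_um = 25,
                             transform = NULL, masks = NULL, ...) {
  stopifnot(is(psr_img, "CalibratedImage"))
  if (is.null(masks)) masks <- separatePsr(psr_img)
  if (is.null(candidates)) {
    chrom <- masks@chromogen
    cand <- detectLumina(masks, section_id = psr_img@section_id,
                         wall_stop_mask = if (length(chrom)) chrom else NULL)
    candidates <- selectBronchioles(cand, ...)
  } else if (!is.null(transform)) {
    stopifnot(identical(dim(transform), c(2L, 3L)))
    apply_tf <- function(m) t(transform %*% rbind(t(m), 1))
    candidates <- lapply(candidates, function(b) {
      b@external <- apply_tf(b@external)
      b@internal <- apply_tf(b@internal)
      b
    })
  }
  empty <- data.frame(bronchiole_id = integer(), epithelium_area_um2 = numeric(),
                      peribronchial_psr_area_um2 = numeric(),
                      collagen_percent = numeric(), band_width_um = numeric())
  if (!length(candidates)) return(empty)
  upp <- psr_img@um_per_px
  d <- dim(psr_img@pixels)[1:2]
  # union of all bronchiole interiors: excluded from every band
  interiors <- lapply(candidates, function(b)
    rasterizePolygon(b@external / upp, d[1], d[2]))
  all_int <- Reduce(`|`, interiors)
  chrom <- masks@chromogen
  if (!length(chrom)) chrom <- matrix(FALSE, d[1], d[2])
  rows <- lapply(seq_along(candidates), function(i) {
    b <- candidates[[i]]
    exclude <- all_int & !interiors[[i]]
    band <- peribronchialBand(b@external, band_width_um, d, upp,
                              tissue = masks@tissue, exclude = exclude)
    psr_area <- sum(chrom & band) * upp^2
    epi <- epitheliumArea(polygonArea(b@external), polygonArea(b@internal))
    data.frame(bronchiole_id = b@id, epithelium_area_um2 = epi,
               peribronchial_psr_area_um2 = psr_area,
               collagen_percent = collagenPercent(psr_area, epi),
               band_width_um = band_width_um)
  })
  do.call(rbind, rows)
}
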