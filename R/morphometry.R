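# The six-parameter morphometric panel per selected bronchiole.

#' Morphometric panel for one bronchiole
#'
#' Computes, from the external (basal membrane) and internal (lumen) limits:
#' the bronchiole area (within the external limit), the lumen area (within
#' the internal limit), the epithelium area (their difference, exactly), the
#' epithelium thickness (mean/sd over hundreds of radial measures all around
#' the epithelium), the circularity of the epithelium and of the lumen, and
#' the Feret diameter.
#'
#' @param candidate a \linkS4class{BronchioleCandidate}.
#' @param n_rays thickness rays (default 360, i.e. 1 degree spacing).
#' @return one-row \code{data.frame} with columns section_id, bronchiole_id,
#'   bronchiole_area_um2, lumen_area_um2, epithelium_area_um2,
#'   thickness_mean_um, thickness_sd_um, n_measures, thickness_reliable,
#'   circ_epithelium, circ_lumen, feret_um, closed_ring. Circularities are
#'   stored raw (rasterization can push them marginally above 1); see
#'   \code{\link{writeMorphometryCsv}} for the clipped report convention.
#' @export
measureBronchiole <- function(candidate, n_rays = 360L) {
  stopifnot(is(candidate, "BronchioleCandidate"))
  ba <- polygonArea(candidate@external)
  la <- polygonArea(candidate@internal)
  ea <- epitheliumArea(ba, la)
  th <- epitheliumThickness(candidate@internal, candidate@external, n_rays)
  data.frame(section_id = candidate@section_id,
             bronchiole_id = candidate@id,
             bronchiole_area_um2 = ba,
             lumen_area_um2 = la,
             epithelium_area_um2 = ea,
             thickness_mean_um = th$mean,
             thickness_sd_um = th$sd,
             n_measures = th$n_measures,
             thickness_reliable = th$reliable,
             circ_epithelium = circularity(candidate@external),
             circ_lumen = circularity(candidate@internal),
             feret_um = candidate@feret_um,
             closed_ring = candidate@closed_ring,
             stringsAsFactors = FALSE)
}

#' Morphometric panel for a list of bronchioles
#'
#' @param candidates list of \linkS4class{BronchioleCandidate} (typically
#'   the output of \code{\link{selectBronchioles}}).
#' @param n_rays thickness rays per bronchiole.
#' @return \code{data.frame}, one row per bronchiole (zero rows when empty).
#' @export
measureBronchioles <- function(candidates, n_rays = 360L) {
  if (!length(candidates))
    return(measureBronchiole(.empty_candidate())[0, ])
  do.call(rbind, lapply(candidates, measureBronchiole, n_rays = n_rays))
}

.empty_candidate <- function() {
  sq <- cbind(c(0, 120, 120, 0), c(0, 0, 120, 120))
  new("BronchioleCandidate", id = 0L, section_id = "empty",
      external = sq, internal = sq * 0.5 + 30,
      feret_um = feretDiameter(sq), closed_ring = TRUE,
      lumen_centroid = c(60, 60))
}

#' Write the per-bronchiole morphometry CSV
#'
#' Mirrors the panel columns; circularities above 1 (rasterization slack)
#' are clipped to 1 in the written report unless \code{clip_circularity} is
#' FALSE.
#'
#' @param panel data.frame from \code{\link{measureBronchioles}}.
#' @param path output CSV path.
#' @param clip_circularity clip reported circularities at 1 (default TRUE).
#' @return the path, invisibly.
#' @export
writeMorphometryCsv <- function(panel, path, clip_circularity = TRUE) {
  if (clip_circularity) {
    panel$circ_epithelium <- pmin(panel$circ_epithelium, 1)
    panel$circ_lumen <- pmin(panel$circ_lumen, 1)
  }
  utils::write.csv(panel, path, row.names = FALSE)
  invisible(path)
}
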