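# Synthetic histology phantoms with exact geometric ground truth. The
# palettes are chosen to exercise the stain-separation thresholds: H&E --
# epithelium pink-purple, parenchymal septa pink, background white; PSR --
# collagen saturated red, other tissue pale yellow.

.PALETTES <- list(
  HE = list(background = c(255, 255, 255), epithelium = c(195, 110, 175),
            septa = c(235, 170, 190), vessel = c(185, 95, 110)),
  PSR = list(background = c(255, 255, 255), epithelium = c(235, 220, 150),
             septa = c(235, 220, 150), vessel = c(235, 220, 150),
             collagen = c(200, 35, 45)))

#' Describe one phantom bronchiole
#'
#' @param center_um (x, y) center in um.
#' @param lumen_r_um lumen radius, um.
#' @param wall_um epithelium wall thickness, um.
#' @param gap_deg optional ring-gap arc in degrees (0 = closed ring).
#' @param gap_center_deg direction of the gap center, degrees.
#' @param lumen_offset_um (dx, dy) offset of the lumen center from the
#'   bronchiole center, um: produces an eccentric annulus whose wall
#'   thickness varies from \code{wall_um - |offset|} to
#'   \code{wall_um + |offset|}. The lumen must stay inside the outer disc.
#' @return list entry for the \code{bronchioles} slot of a
#'   \linkS4class{PhantomSpec}.
#' @export
phantomBronchiole <- function(center_um, lumen_r_um, wall_um, gap_deg = 0,
                              gap_center_deg = 0, lumen_offset_um = c(0, 0)) {
  list(center_um = center_um, lumen_r_um = lumen_r_um, wall_um = wall_um,
       gap_deg = gap_deg, gap_center_deg = gap_center_deg,
       lumen_offset_um = lumen_offset_um)
}

#' Describe one phantom vessel (thick-walled annulus)
#'
#' @param center_um (x, y) center in um.
#' @param lumen_r_um lumen radius, um.
#' @param wall_um wall thickness, um.
#' @return list entry for the \code{vessels} slot.
#' @export
phantomVessel <- function(center_um, lumen_r_um, wall_um) {
  list(center_um = center_um, lumen_r_um = lumen_r_um, wall_um = wall_um)
}

#' Construct a phantom specification
#'
#' @param canvas_px (rows, cols) canvas in px.
#' @param um_per_px scale (default the x20 scan pixel size, 0.452 um/px).
#' @param stain "HE" or "PSR" palette.
#' @param bronchioles list of \code{\link{phantomBronchiole}} entries.
#' @param vessels list of \code{\link{phantomVessel}} entries.
#' @param collagen list of lists \code{(bronchiole = index, band_um,
#'   coverage)}: a PSR-red band of the given thickness hugging the outside
#'   of the referenced bronchiole over the given arc fraction.
#' @param foam list \code{(region_um = c(xmin, xmax, ymin, ymax), n,
#'   diam_range_um, septum_um)} describing a foam-like alveolar parenchyma:
#'   \code{n} non-overlapping circular airspaces with diameters drawn
#'   uniformly from \code{diam_range_um}, separated by at least
#'   \code{septum_um} of septal tissue. Empty list = no foam.
#' @param noise_sd additive Gaussian pixel noise sd (0-255 scale; 0 = off).
#' @param seed integer RNG seed; fully determines the output.
#' @return a \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(canvas_px, um_per_px = DEFAULT_UM_PER_PX,
                        stain = c("HE", "PSR"), bronchioles = list(),
                        vessels = list(), collagen = list(), foam = list(),
                        noise_sd = 0, seed = 1L) {
  stain <- match.arg(stain)
  new("PhantomSpec", canvas_px = as.integer(canvas_px),
      um_per_px = um_per_px, stain = stain, bronchioles = bronchioles,
      vessels = vessels, collagen = collagen, foam = foam,
      noise_sd = noise_sd, seed = as.integer(seed))
}

# evaluate an expression under a temporary, seed-determined RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# set pixels of `mask` inside a disc/annulus, windowed for speed.
# r_in = 0 gives a full disc; gap_deg > 0 cuts an arc out of the annulus.
.paint_annulus <- function(mask, center_px, r_out_px, r_in_px = 0,
                           gap_deg = 0, gap_center_deg = 0) {
  nr <- nrow(mask); nc <- ncol(mask)
  i0 <- max(1L, floor(center_px[1] - r_out_px)); i1 <- min(nr, ceiling(center_px[1] + r_out_px) + 1L)
  j0 <- max(1L, floor(center_px[2] - r_out_px)); j1 <- min(nc, ceiling(center_px[2] + r_out_px) + 1L)
  if (i1 < i0 || j1 < j0) return(mask)
  xs <- (i0:i1) - 0.5 - center_px[1]
  ys <- (j0:j1) - 0.5 - center_px[2]
  d2 <- outer(xs^2, ys^2, "+")
  sel <- d2 <= r_out_px^2 & d2 > r_in_px^2
  if (gap_deg > 0) {
    ang <- atan2(outer(rep(1, length(xs)), ys), outer(xs, rep(1, length(ys))))
    dang <- (ang * 180 / pi - gap_center_deg + 180) %% 360 - 180
    sel <- sel & abs(dang) > gap_deg / 2
  }
  mask[i0:i1, j0:j1] <- mask[i0:i1, j0:j1] | sel
  mask
}

# rejection-sample non-overlapping foam airspace discs; returns data.frame
# center_x_um, center_y_um, r_um. Structures (bronchioles/vessels) are
# avoided with `clearance_um` slack.
.place_foam <- function(spec, clearance_um = 15, extra_margin_um = 0) {
  foam <- spec@foam
  if (!length(foam)) return(NULL)
  reg <- foam$region_um
  septum <- foam$septum_um %||% 4
  drange <- foam$diam_range_um %||% c(30, 60)
  structures <- c(spec@bronchioles, spec@vessels)
  sc <- if (length(structures))
    cbind(t(vapply(structures, function(s) s$center_um, numeric(2))),
          vapply(structures, function(s) s$lumen_r_um + s$wall_um, 0)) else NULL
  .with_seed(spec@seed, {
    cx <- cy <- rr <- numeric(foam$n)
    for (k in seq_len(foam$n)) {
      placed <- FALSE
      for (try in seq_len(5000L)) {
        r <- stats::runif(1, drange[1], drange[2]) / 2
        m <- r + septum + extra_margin_um
        x <- stats::runif(1, reg[1] + m, reg[2] - m)
        y <- stats::runif(1, reg[3] + m, reg[4] - m)
        if (k > 1L) {
          d <- sqrt((cx[seq_len(k - 1L)] - x)^2 + (cy[seq_len(k - 1L)] - y)^2)
          if (any(d < rr[seq_len(k - 1L)] + r + septum)) next
        }
        if (!is.null(sc)) {
          ds <- sqrt((sc[, 1] - x)^2 + (sc[, 2] - y)^2)
          if (any(ds < sc[, 3] + r + clearance_um)) next
        }
        cx[k] <- x; cy[k] <- y; rr[k] <- r; placed <- TRUE
        break
      }
      if (!placed)
        stop("phantom spec error: could not place ", foam$n,
             " non-overlapping airspaces in the foam region")
    }
    data.frame(center_x_um = cx, center_y_um = cy, r_um = rr)
  })
}

.check_structure_overlap <- function(spec) {
  structures <- c(spec@bronchioles, spec@vessels)
  n <- length(structures)
  if (n < 2L) return(invisible())
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- structures[[i]]; b <- structures[[j]]
    d <- sqrt(sum((a$center_um - b$center_um)^2))
    if (d < (a$lumen_r_um + a$wall_um) + (b$lumen_r_um + b$wall_um) + 1)
      stop("phantom spec error: overlapping bronchioles/vessels")
  }
  invisible()
}

.generate_impl <- function(spec, foam_placement, foam_scale = 1,
                           allow_overlap = FALSE) {
  upp <- spec@um_per_px
  nr <- spec@canvas_px[1]; nc <- spec@canvas_px[2]
  pal <- .PALETTES[[spec@stain]]
  blank <- matrix(FALSE, nr, nc)
  septa <- epi <- vessel <- collagen <- airspace <- foamreg <- blank

  if (!is.null(foam_placement)) {
    reg <- spec@foam$region_um / upp
    ri <- max(1L, floor(reg[1]) + 1L):min(nr, ceiling(reg[2]))
    ci <- max(1L, floor(reg[3]) + 1L):min(nc, ceiling(reg[4]))
    foamreg[ri, ci] <- TRUE
    for (k in seq_len(nrow(foam_placement)))
      airspace <- .paint_annulus(airspace,
        c(foam_placement$center_x_um[k], foam_placement$center_y_um[k]) / upp,
        foam_placement$r_um[k] * foam_scale / upp)
    airspace <- airspace & foamreg
    septa <- foamreg & !airspace
  }
  for (b in spec@bronchioles) {
    g <- b$gap_deg %||% 0
    off <- b$lumen_offset_um %||% c(0, 0)
    if (all(off == 0)) {
      epi <- .paint_annulus(epi, b$center_um / upp,
                            (b$lumen_r_um + b$wall_um) / upp,
                            b$lumen_r_um / upp, g, b$gap_center_deg %||% 0)
    } else {
      # eccentric annulus: full outer disc, lumen cleared below
      epi <- .paint_annulus(epi, b$center_um / upp,
                            (b$lumen_r_um + b$wall_um) / upp, 0,
                            g, b$gap_center_deg %||% 0)
    }
  }
  for (v in spec@vessels)
    vessel <- .paint_annulus(vessel, v$center_um / upp,
                             (v$lumen_r_um + v$wall_um) / upp,
                             v$lumen_r_um / upp)
  if (spec@stain == "PSR") for (cb in spec@collagen) {
    b <- spec@bronchioles[[cb$bronchiole]]
    R <- b$lumen_r_um + b$wall_um
    cover <- cb$coverage %||% 1
    collagen <- .paint_annulus(collagen, b$center_um / upp,
                               (R + cb$band_um) / upp, R / upp,
                               gap_deg = 360 * (1 - cover),
                               gap_center_deg = 180)
  }
  # structures overwrite foam; lumina stay background
  lumen_clear <- blank
  for (s in c(spec@bronchioles, spec@vessels))
    lumen_clear <- .paint_annulus(lumen_clear,
                                  (s$center_um + (s$lumen_offset_um %||% c(0, 0))) / upp,
                                  s$lumen_r_um / upp)
  epi <- epi & !lumen_clear
  vessel <- vessel & !lumen_clear
  septa <- septa & !epi & !vessel & !collagen & !lumen_clear
  collagen <- collagen & !epi & !vessel

  px <- array(0, dim = c(nr, nc, 3))
  for (ch in 1:3) {
    m <- matrix(pal$background[ch], nr, nc)
    m[septa] <- pal$septa[ch]
    m[epi] <- pal$epithelium[ch]
    m[vessel] <- pal$vessel[ch]
    if (spec@stain == "PSR") m[collagen] <- pal$collagen[ch]
    px[, , ch] <- m
  }
  if (spec@noise_sd > 0)
    px <- .with_seed(spec@seed + 1L, {
      pmin(pmax(px + stats::rnorm(length(px), 0, spec@noise_sd), 0), 255)
    })
  img <- newCalibratedImage(px, upp, spec@stain,
                            sprintf("phantom-seed%d", spec@seed))

  truth <- .ground_truth(spec, foam_placement, foam_scale,
                         list(septa = septa, epi = epi, vessel = vessel,
                              collagen = collagen, airspace = airspace,
                              foamreg = foamreg))
  list(image = img, truth = truth)
}

.ground_truth <- function(spec, foam_placement, foam_scale, masks) {
  upp <- spec@um_per_px
  gt <- list(um_per_px = upp, stain = spec@stain, masks = masks)
  if (length(spec@bronchioles)) {
    gt$bronchioles <- do.call(rbind, lapply(seq_along(spec@bronchioles), function(i) {
      b <- spec@bronchioles[[i]]
      R <- b$lumen_r_um + b$wall_um
      la <- pi * b$lumen_r_um^2
      ba <- pi * R^2
      off <- b$lumen_offset_um %||% c(0, 0)
      data.frame(id = i, center_x_um = b$center_um[1], center_y_um = b$center_um[2],
                 lumen_r_um = b$lumen_r_um, wall_um = b$wall_um,
                 gap_deg = b$gap_deg %||% 0,
                 lumen_offset_x_um = off[1], lumen_offset_y_um = off[2],
                 lumen_area_um2 = la, bronchiole_area_um2 = ba,
                 epithelium_area_um2 = ba - la, feret_um = 2 * R,
                 thickness_um = b$wall_um,
                 closed_ring = (b$gap_deg %||% 0) == 0)
    }))
  }
  if (length(spec@vessels)) {
    gt$vessels <- do.call(rbind, lapply(seq_along(spec@vessels), function(i) {
      v <- spec@vessels[[i]]
      data.frame(id = i, lumen_r_um = v$lumen_r_um, wall_um = v$wall_um,
                 feret_um = 2 * (v$lumen_r_um + v$wall_um))
    }))
  }
  if (length(spec@collagen) && spec@stain == "PSR") {
    gt$collagen <- do.call(rbind, lapply(spec@collagen, function(cb) {
      b <- spec@bronchioles[[cb$bronchiole]]
      R <- b$lumen_r_um + b$wall_um
      cover <- cb$coverage %||% 1
      psr <- cover * pi * ((R + cb$band_um)^2 - R^2)
      epi <- pi * (R^2 - b$lumen_r_um^2)
      data.frame(bronchiole = cb$bronchiole, band_um = cb$band_um,
                 coverage = cover, psr_area_um2 = psr,
                 epithelium_area_um2 = epi,
                 expected_percent = 100 * psr / (epi + psr))
    }))
  }
  if (!is.null(foam_placement)) {
    air <- masks$airspace
    lab <- EBImage::bwlabel(matrix(as.numeric(air), nrow(air), ncol(air)))
    rr <- foam_placement$r_um * foam_scale
    reg <- spec@foam$region_um
    tissue_um2 <- sum(masks$septa) * upp^2
    air_um2 <- sum(air) * upp^2
    gt$foam <- list(
      airspaces = transform(foam_placement, r_um = rr, feret_um = 2 * rr),
      n_placed = nrow(foam_placement),
      n_components = max(lab),
      analytic_airspace_area_um2 = sum(pi * rr^2),
      raster_airspace_area_um2 = air_um2,
      raster_tissue_area_um2 = tissue_um2,
      density = air_um2 / tissue_um2,
      mean_feret_um = mean(2 * rr),
      airspaces_per_mm2 = max(lab) / (tissue_um2 / 1e6))
  }
  gt
}

#' Generate a synthetic histology phantom with exact ground truth
#'
#' Rasterizes the scene described by a \linkS4class{PhantomSpec} in the
#' chosen stain palette and returns the calibrated image together with the
#' exact geometric ground truth (per-object contour parameters, areas,
#' thicknesses, Feret diameters, expected collagen percentages, airspace
#' count/density/Feret summary, and the drawn component masks). The same
#' seed and spec always yield byte-identical output.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with \code{image} (\linkS4class{CalibratedImage}) and
#'   \code{truth} (ground-truth list; see Details in the package vignette).
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  .check_structure_overlap(spec)
  .generate_impl(spec, .place_foam(spec))
}

#' Generate a dilation series of a foam phantom
#'
#' The same scene with all airspace radii scaled by each factor (airspace
#' merging is allowed and handled in the ground truth via connected
#' components). This drives the emphysema direction property: dilation
#' increases airspace density and Feret diameter while the airspace count
#' decreases once neighbours merge.
#'
#' @param spec a \linkS4class{PhantomSpec} with a foam block.
#' @param factors numeric vector of scale factors, all >= 1, increasing.
#' @return list of \code{list(image, truth)}, one per factor; factor 1
#'   reproduces \code{generatePhantom(spec)} exactly.
#' @export
dilationSeries <- function(spec, factors) {
  stopifnot(is(spec, "PhantomSpec"))
  if (!length(spec@foam)) stop("dilationSeries needs a foam phantom")
  if (any(factors < 1)) stop("dilation factors must be >= 1")
  if (is.unsorted(factors, strictly = FALSE)) stop("factors must be increasing")
  .check_structure_overlap(spec)
  # reserve room so dilated airspaces are never clipped by the region edge
  extra <- (max(factors) - 1) * max(spec@foam$diam_range_um %||% c(30, 60)) / 2
  placement <- .place_foam(spec, extra_margin_um = extra)
  lapply(factors, function(f)
    .generate_impl(spec, placement, foam_scale = f, allow_overlap = f > 1))
}
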