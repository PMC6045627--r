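# Shared fixtures, built in code and memoized across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# single closed annulus: lumen r 80 um, wall 20 um, at the x20 scan scale
annulusPhantom <- function() fixture("annulus", function() {
  generatePhantom(phantomSpec(c(900, 900), 0.452, "HE",
    bronchioles = list(phantomBronchiole(c(200, 200), 80, 20)), seed = 7L))
})

# PSR phantom: same annulus plus a full-coverage 20-um collagen band
collagenPhantom <- function() fixture("collagen", function() {
  generatePhantom(phantomSpec(c(900, 900), 0.452, "PSR",
    bronchioles = list(phantomBronchiole(c(200, 200), 80, 20)),
    collagen = list(list(bronchiole = 1, band_um = 20, coverage = 1)),
    seed = 3L))
})

# foam-only parenchyma: 120 airspaces, 30-60 um, in a 0.8 x 0.8 mm region
foamPhantom <- function() fixture("foam", function() {
  generatePhantom(phantomSpec(c(900, 900), 1, "HE",
    foam = list(region_um = c(50, 850, 50, 850), n = 120,
                diam_range_um = c(30, 60), septum_um = 5), seed = 11L))
})

# mixed scene: bronchiole + thick-walled vessel + foam
mixedPhantom <- function() fixture("mixed", function() {
  generatePhantom(phantomSpec(c(1200, 1200), 1, "HE",
    bronchioles = list(phantomBronchiole(c(250, 250), 90, 25)),
    vessels = list(phantomVessel(c(900, 280), 60, 55)),
    foam = list(region_um = c(450, 1150, 450, 1150), n = 90,
                diam_range_um = c(30, 60), septum_um = 5), seed = 21L))
})

diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# regular n-gon approximating a circle (exact polygon geometry, no raster)
circlePoly <- function(r, center = c(0, 0), n = 720L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# analytic distance from `origin` to a circle (center, R) along angle theta;
# used as the dense-ray thickness oracle for offset annuli
rayCircleDist <- function(origin, theta, center, R) {
  ox <- origin[1] - center[1]; oy <- origin[2] - center[2]
  b <- ox * cos(theta) + oy * sin(theta)
  disc <- b^2 - (ox^2 + oy^2 - R^2)
  -b + sqrt(disc)  # origin inside the circle: one positive root
}

# constructed candidate with an exact Feret diameter (unit-square scaled)
exactFeretCandidate <- function(feret_um, closed_ring = TRUE) {
  ext <- circlePoly(feret_um / 2, c(0, 0), 256L)
  new("BronchioleCandidate", id = 1L, section_id = "synthetic",
      external = ext, internal = ext * 0.6,
      feret_um = feret_um, closed_ring = closed_ring,
      lumen_centroid = c(0, 0))
}

# three non-touching annuli on one section
threeAnnuli <- function() fixture("three_annuli", function() {
  generatePhantom(phantomSpec(c(1100, 1100), 0.452, "HE",
    bronchioles = list(phantomBronchiole(c(130, 130), 80, 20),
                       phantomBronchiole(c(360, 130), 60, 15),
                       phantomBronchiole(c(240, 360), 100, 25)),
    seed = 5L))
})

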