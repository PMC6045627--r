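test_that("all annuli are found with contours within 2 px of ground truth", {
  ph <- threeAnnuli()
  cand <- detectLumina(segmentTissue(ph$image), section_id = "s1")
  expect_length(cand, 3L)
  gt <- ph$truth$bronchioles
  tol <- 2 * 0.452
  for (b in cand) {
    ctr <- gt[which.min((gt$center_x_um - b@lumen_centroid[1])^2 +
                        (gt$center_y_um - b@lumen_centroid[2])^2), ]
    r_int <- sqrt(rowSums(sweep(b@internal, 2,
                                c(ctr$center_x_um, ctr$center_y_um))^2))
    r_ext <- sqrt(rowSums(sweep(b@external, 2,
                                c(ctr$center_x_um, ctr$center_y_um))^2))
    # circular ground truth: Hausdorff distance is the worst radial error
    expect_lt(max(abs(r_int - ctr$lumen_r_um)), tol)
    expect_lt(max(abs(r_ext - (ctr$lumen_r_um + ctr$wall_um))), tol)
    expect_true(b@closed_ring)
  }
})

test_that("every internal contour lies strictly inside its external contour", {
  ph <- threeAnnuli()
  cand <- detectLumina(segmentTissue(ph$image))
  for (b in cand)
    expect_true(all(pointInPolygon(b@internal[, 1], b@internal[, 2],
                                   b@external)))
})

test_that("detection on a blank section returns an empty list", {
  blank <- newStainMasks(matrix(FALSE, 200, 200), NULL, 1)
  expect_length(detectLumina(blank), 0L)
  solid <- newStainMasks(matrix(TRUE, 200, 200), NULL, 1)
  expect_length(detectLumina(solid), 0L)
})

test_that("a ring with an arc gap is detected but flagged open", {
  sp <- phantomSpec(c(900, 900), 0.452, "HE",
    bronchioles = list(phantomBronchiole(c(200, 200), 80, 20, gap_deg = 30)),
    seed = 4L)
  ph <- generatePhantom(sp)
  cand <- detectLumina(segmentTissue(ph$image))
  expect_length(cand, 1L)
  expect_false(closedRing(cand[[1]]))
  # open rings are excluded from selection unless explicitly kept
  expect_length(selectBronchioles(cand), 0L)
  expect_length(selectBronchioles(cand, keep_open_rings = TRUE), 1L)
})

test_that("selection retains the inclusive 100-500 um Feret window", {
  cand <- lapply(c(60, 150, 300, 450, 600), exactFeretCandidate)
  sel <- selectBronchioles(cand)
  expect_equal(vapply(sel, feretUm, 0), c(150, 300, 450))
  # boundary values are retained (inclusive bounds); just-outside are not
  expect_length(selectBronchioles(list(exactFeretCandidate(100))), 1L)
  expect_length(selectBronchioles(list(exactFeretCandidate(500))), 1L)
  expect_length(selectBronchioles(list(exactFeretCandidate(99.99))), 0L)
  expect_length(selectBronchioles(list(exactFeretCandidate(500.01))), 0L)
  # idempotent, order-preserving, empty-safe
  expect_equal(selectBronchioles(sel), sel)
  expect_length(selectBronchioles(list()), 0L)
  expect_error(selectBronchioles(cand, min_feret_um = 600, max_feret_um = 100),
               "must not exceed")
})

test_that("measured Feret is invariant to translation and ring rotation", {
  base <- phantomSpec(c(700, 700), 0.452, "HE",
    bronchioles = list(phantomBronchiole(c(160, 160), 80, 20)), seed = 2L)
  moved <- phantomSpec(c(700, 700), 0.452, "HE",
    bronchioles = list(phantomBronchiole(c(155.3, 162.7), 80, 20)), seed = 2L)
  f1 <- feretUm(detectLumina(segmentTissue(generatePhantom(base)$image))[[1]])
  f2 <- feretUm(detectLumina(segmentTissue(generatePhantom(moved)$image))[[1]])
  expect_equal(f1, f2, tolerance = 0.01)
  # rotating the gap of an open ring leaves the bridged Feret within 1%
  g1 <- phantomSpec(c(700, 700), 0.452, "HE",
    bronchioles = list(phantomBronchiole(c(160, 160), 80, 20,
                                         gap_deg = 25, gap_center_deg = 0)),
    seed = 2L)
  g2 <- phantomSpec(c(700, 700), 0.452, "HE",
    bronchioles = list(phantomBronchiole(c(160, 160), 80, 20,
                                         gap_deg = 25, gap_center_deg = 117)),
    seed = 2L)
  h1 <- feretUm(detectLumina(segmentTissue(generatePhantom(g1)$image))[[1]])
  h2 <- feretUm(detectLumina(segmentTissue(generatePhantom(g2)$image))[[1]])
  expect_equal(h1, h2, tolerance = 0.01)
})

test_that("a 100-um bronchiole at the window floor is still detectable", {
  sp <- phantomSpec(c(500, 500), 0.452, "HE",
    bronchioles = list(phantomBronchiole(c(110, 110), 30, 20)), seed = 1L)
  cand <- detectLumina(segmentTissue(generatePhantom(sp)$image),
                       min_lumen_feret_um = 40)
  expect_length(cand, 1L)
  expect_equal(feretUm(cand[[1]]), 100, tolerance = 0.01)
})

test_that("candidates touching the image border are discarded", {
  sp <- phantomSpec(c(450, 450), 1, "HE",
    bronchioles = list(phantomBronchiole(c(225, 380), 40, 15)), seed = 1L)
  ph <- generatePhantom(sp)
  # shift the structure onto the border by cropping the raster
  px <- ph$image@pixels[, 1:400, ]
  img <- newCalibratedImage(px, 1, "HE")
  expect_length(detectLumina(segmentTissue(img)), 0L)
})

test_that("GeoJSON export carries one polygon feature per bronchiole", {
  ph <- threeAnnuli()
  cand <- detectLumina(segmentTissue(ph$image), section_id = "s1")
  path <- withr::local_tempfile(fileext = ".geojson")
  writeCandidatesGeoJson(cand, path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 3L)
  f <- gj$features[[1]]
  expect_equal(f$geometry$type, "Polygon")
  expect_length(f$geometry$coordinates, 2L)  # outer ring + lumen hole
  expect_true(all(c("section_id", "feret_um", "closed_ring") %in%
                  names(f$properties)))
})
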