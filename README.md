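# airwaymorph

Automated, observer-independent histomorphometry of the small airways and
lung parenchyma on calibrated 2-D histology images.

Semi-quantitative scoring of lung injury is subjective and coarse. This
package implements a fully automatic numerical alternative for three
readouts used in rodent models of airway disease (ozone exposure, smoke,
allergen):

1. **Small-airway remodeling** — small bronchioles are detected on an H&E
   section as enclosed lumina surrounded by an epithelial ring, selected by
   their Feret diameter *F* (the largest caliper diameter) in the inclusive
   window 100 µm ≤ *F* ≤ 500 µm, and measured with a six-parameter panel:
   bronchiole area *A_b* (within the external, basal-membrane limit), lumen
   area *A_l* (within the internal limit), epithelium area
   *A_e = A_b − A_l*, epithelium thickness (mean ± SD over 360 radial
   measures all around the wall), circularity *C = 4πA/P²* of both limits
   (*C* = 1 for a perfect circle), and *F*.
2. **Peribronchial collagen** — on a picrosirius-red (PSR) serial section,
   collagen is the red chromogen in a band of width *w* (default 25 µm)
   hugging the outside of each bronchiole, reported as
   *100 · A_PSR / (A_e + A_PSR)* percent.
3. **Emphysema** — after automatic removal of bronchi and vessels, every
   enclosed parenchymal airspace (alveoli and ducts pooled) is delineated
   and the section is summarized by airspace density (airspace area /
   parenchymal tissue area), the airspace Feret-diameter distribution, and
   the number of airspaces per mm² of parenchymal tissue — replacing the
   classical mean-linear-intercept measurement.

All measurements are reported in micrometres through a per-image
calibration (default 0.452 µm/px, the pixel size of a ×20 whole-slide
scan). A synthetic phantom generator (`phantomSpec()`/`generatePhantom()`)
draws annular bronchioles, vessels, collagen bands and foam-like alveolar
parenchyma with exact geometric ground truth, so the entire pipeline is
testable without slide data.

## Worked example

```r
library(airwaymorph)

# a synthetic H&E section: one bronchiole (lumen radius 80 um, wall 20 um)
sp <- phantomSpec(c(900, 900), um_per_px = 0.452, stain = "HE",
                  bronchioles = list(phantomBronchiole(c(200, 200), 80, 20)),
                  seed = 7)
ph <- generatePhantom(sp)

masks <- segmentTissue(ph$image)
sel   <- selectBronchioles(detectLumina(masks, section_id = "s1"))
panel <- measureBronchioles(sel)
t(panel[, c("bronchiole_area_um2", "lumen_area_um2", "epithelium_area_um2",
            "thickness_mean_um", "circ_epithelium", "feret_um")])
#> bronchiole_area_um2 31418.78   # truth: pi * 100^2 = 31415.93
#> lumen_area_um2      20094.62   # truth: pi *  80^2 = 20106.19
#> epithelium_area_um2 11324.15   # truth: 11309.73
#> thickness_mean_um      20.03   # truth: 20 (wall width)
#> circ_epithelium         0.99   # 1 = perfect circle
#> feret_um              200.64   # truth: 200
```

The bronchiole is recovered with sub-percent area error, the wall thickness
to 0.2 %, and the circularity of the circular phantom within 0.02 of 1.

An emphysema run on a 120-airspace foam phantom:

```r
spf <- phantomSpec(c(900, 900), 1, "HE",
  foam = list(region_um = c(50, 850, 50, 850), n = 120,
              diam_range_um = c(30, 60), septum_um = 5), seed = 11)
res <- runEmphysema(segmentTissue(generatePhantom(spf)$image), "foam")
res$summary
#> EmphysemaSummary 'foam': 120 airspaces, density 0.377, mean Feret 42.6 um,
#> 258.2 airspaces/mm^2 (tissue 0.465 mm^2)
```

All 120 airspaces are found (count exact); density and mean Feret agree
with the generated truth within 1 %.

Group statistics follow the field's convention: per-object measurements are
averaged within animal, groups are compared by one-way ANOVA with
Bonferroni-adjusted pairwise tests (or Kruskal–Wallis), and pairs are
starred at p < 0.05 / 0.01 / 0.001 / 0.0001 — see `aggregateByAnimal()` and
`compareGroups()`.

A command-line front end over the same functions lives in
`inst/cli/airwaymorph.R` with subcommands `detect`, `collagen`,
`emphysema`, `phantom` and `report`.

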