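# ductmorph

Morphometric features for grading pancreatic duct histology.

Pancreatic ductal adenocarcinoma (PDAC) is diagnosed and graded from the
morphology of ducts in H&E sections: normal ducts have a convex lumen
ringed by cuboidal epithelium with regularly placed nuclei, while
carcinomatous ducts grow papillary projections, irregular contours,
columnar epithelium and nuclei that have lost their polarity. `ductmorph`
turns a single-duct image crop into numbers that capture those changes,
for image-analysis researchers who want a complete, testable
reimplementation of this style of duct-morphometry pipeline.

The pipeline segments three objects — the lumen (maximum-entropy
binarization, direction-cumulative-map seeding, seeded region growing),
all nuclei (k-means colour clustering, hole filling, watershed), and the
epithelial subset (nearest nucleus to each lumen-boundary point) — and
computes per image:

* twelve classical morphometrics per object (area, perimeter, bounding
  box, best-fit-ellipse axes, circularity, Feret diameter, aspect ratio,
  intensity skewness, roundness, solidity);
* the **ideal lumen boundary** `B^I`: the convex hull of the lumen
  boundary rescaled by `s = sqrt(Area(R^O)/Area(R^C))` so its area equals
  the lumen area — the duct's atypia-free reference shape;
* the **atypia-amplitude signature** `A(t)`: the signed orthogonal
  distance from each point of `B^I` to the actual boundary (+ outside,
  − inside), plotted against arc length `L(t)`;
* **RMSAA** = `sqrt(mean(A(t)^2))`; **TSAV**, the total turning angle at
  the signature's perceptually important points (recursive
  vertical-distance bisection with threshold `T`, near-collinear points
  pruned); **AtypiaRatio** and **#AtypiaRegions**, the area fraction and
  supra-300 µm² count of the components of the symmetric difference
  between the lumen and its ideal region, split by `B^I`;
* **CytoplasmLength** (mean epithelial nucleus-to-lumen distance) and its
  population SD, a proxy for loss of nuclear polarity.

A phantom generator renders synthetic ducts (bright lumen, textured
stroma, columnar epithelial ring, scattered stromal nuclei, papillae with
an analytically known atypia-region count) so the whole pipeline is
testable without any real slides, and an SVM bootstrap protocol (RBF
kernel, printed C/gamma grids, 10-fold grid search, stratified 60/40
splits, 10 repetitions) evaluates the published feature-set compositions
(CNF, CLF, PLF, ..., ATF) with confusion metrics, ROC/AUC and ANOVA/LSD
feature screening.

## A worked example

```r
library(ductmorph)

cfg <- phantomConfig(lumen_radius = 220, n_lobes = 3, lobe_area_um2 = 2000,
                     n_epithelial = 60, n_stromal = 120,
                     cytoplasm_offset_mean = 12, rng_seed = 1)
ph  <- generateDuctPhantom(cfg)
row <- runPipeline(ph$image, pipelineConfig(), resolution = cfg$resolution)
round(unlist(row[c("RMSAA", "TSAV", "AtypiaRatio", "NumAtypiaRegions",
                   "CytoplasmLength", "CytoplasmLength_SD")]), 2)
#>            RMSAA             TSAV      AtypiaRatio NumAtypiaRegions
#>            16.58           331.27             0.11             3.00
#>  CytoplasmLength CytoplasmLength_SD
#>            12.29               0.43
```

The duct was generated with three 2000 µm² papillae and a 12 µm
epithelial offset; the pipeline recovers exactly 3 supra-threshold atypia
regions and a mean cytoplasm length of 12.3 µm, and the papillae drive an
RMSAA of ≈ 17 µm where a convex duct measures below 0.5 µm
(`n_lobes = 0` gives RMSAA = 0.21, #AtypiaRegions = 0).

A three-grade cohort with realistic effect sizes, and its evaluation:

```r
cohort <- generateCohort(80, gradePhantomConfigs(), seed = 1)
feats  <- cohortFeatureTable(cohort)          # 240 rows x 42 features + label
specs  <- featureSetSpecs()
g12    <- feats[feats$label != "Normal", ]
ev     <- trainEvalBootstrap(as.matrix(g12[, specs$PDF]),
                             factor(ifelse(g12$label == "Grade1", -1, 1)),
                             svmProtocol(seed = 7))
ev$mean[c("ACC", "AUC")]
```

There is also a thin CLI (`inst/cli/ductmorph.R`) with `phantom`,
`segment`, `features`, `pipeline` and `classify` subcommands.

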