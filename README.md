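# imcpheno

Single-cell analysis of multiplexed imaging mass cytometry (IMC) data for
tumor-immune microenvironment studies.  IMC rasters a tissue section with a
UV laser at ~1 µm resolution and detects metal-tagged antibodies by
time-of-flight mass spectrometry, yielding one intensity channel per marker
(~23 markers in a typical mouse tumor-immune panel).  `imcpheno` turns such
channel stacks into annotated single cells and study-level statistics:

* **Segmentation** — nuclear/membrane/combined composite images, quantile
  auto-thresholding of in-cell pixels (targeting the 40–55% in-cell
  window), prominence-filtered maxima seeding and seeded-watershed
  particle segmentation.
* **Quantification** — per-cell total marker intensities (the
  cell-by-protein matrix) with centroids and areas, then
  `ln(1 + x)` followed by z-scoring across cells and across markers.
* **Phenotyping** — K-means with many random restarts (desk default 100,
  production 100,000), a one-vs-one differential-marker rule (a marker is
  differential for a cluster when it is significantly upregulated in at
  least k − 3 of its k − 1 pairwise comparisons — 17 of 19 at k = 20),
  marker-list cluster names, and ordered annotation rules (neutrophils:
  S100A8/S100A9; macrophages: F4/80; tumor cells: Vimentin/CD44; otherwise
  "unidentified").
* **Spatial statistics** — per-sample median nearest-neighbor distance of
  each immune cell type from tumor cells.
* **Differential state** — per-(cluster, marker) contrasts of sample-level
  medians between conditions with Benjamini–Hochberg adjustment.
* **Metastatic burden** — serial-section lesion scoring by diameter bins
  (<1, 1–3, 3–5, >5 mm → scores 1–4) summed per sample.
* **Synthetic data** — a generator of multichannel scenes, cell tables and
  lesion series with known ground truth, so the full pipeline is testable
  without acquisition data.

See `vignettes/imcpheno-methods.Rmd` for the model, parameter and design
details.

## Worked example

```r
library(imcpheno)

panel <- default_panel()                       # 23-marker nuclear/membrane panel
scene <- make_scene(scene_spec(seed = 1), panel)

seg <- segment_image(scene$image, panel)       # composite -> threshold -> seeds -> watershed
100 * attr(seg$threshold, "achieved_fraction") # 47.5  (inside the 40-55% window)
n_cells(seg$mask)                              # 181   (200 cells simulated)

tab <- quantify(scene$image, seg$mask, panel, sample_id = "ROI1")
nm  <- normalize_intensities(tab)              # log + double z-score
km  <- kmeans_cluster(nm, k = 6, n_restarts = 50, seed = 1)
dm  <- differential_markers(nm, km$assignments, panel = panel)
annotate_clusters(dm)
#>              1              2              3              4              5              6
#> "unidentified"  "neutrophils"  "macrophages"  "neutrophils"  "tumor cells" "unidentified"

name_clusters(dm)[5]                           # "Ki67/CD44/PanCK/Vimentin"

tab$annotation <- annotate_clusters(dm)[as.character(km$assignments)]
summarize_median_distance(tab, immune_types = c("neutrophils", "macrophages"))
#>   sample_id   cell_type n_cells median_distance_um reference_type
#> 1      ROI1 neutrophils      36           14.87726    tumor cells
#> 2      ROI1 macrophages      39           17.74554    tumor cells

score_lesion(c(0.5, 2, 4, 7))                  # 1 2 3 4
```

The achieved threshold fraction says 47.5% of composite pixels were flagged
in-cell; the recovered cell count is within 10% of the simulated truth
(adjacent membrane-bright cells occasionally merge, the method's known
failure mode); the annotated clusters recover the simulated populations,
with mixed/low-count clusters falling back to "unidentified"; the median
distances quantify how far neutrophils and macrophages sit from tumor
cells in this region of interest.

An end-to-end run (simulate → segment → quantify → normalize → phenotype →
annotate → spatial → ds → score) with all artifacts and a manifest:

```r
run_pipeline(default_pipeline_config(seed = 1), "out/")
```

or from a shell: `Rscript inst/scripts/imc-pipeline.R --out out/ --seed 1`.

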