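# tsrquant

Automated quantification of the **tumor-to-stroma ratio (TSR)** in
immunohistochemically stained tissue cores, for digital-pathology and
translational-oncology work on prostate cancer (and other solid tumors
where the ratio of tumor to intratumoral stroma carries prognostic
information). Tumor cells are stained brown with a DAB chromogen
(anti-EpCAM), stroma is counterstained blue with hematoxylin; `tsrquant`
turns a batch of such RGB photomicrographs into per-core TSR values,
per-patient low/high categories, and the cohort statistics used to relate
TSR to time to biochemical recurrence.

## Method

For each 8-bit RGB tissue-core image:

1. **Optical density.** Beer–Lambert conversion per channel,
   `OD = −log10(max(I, 1) / I0)` with `I0 = 255`.
2. **Color deconvolution** (Ruifrok–Johnston). The OD vector of every pixel
   is solved against a 3×3 H-DAB stain basis — hematoxylin
   (0.650, 0.704, 0.286), DAB (0.269, 0.568, 0.778), residual = their cross
   product — giving hematoxylin and DAB concentration maps, re-rendered as
   8-bit pseudo-transmittance channels `255·10^(−c)`.
3. **Masking.** Each channel is median-filtered (disc radius 2 px). The
   tumor mask is the DAB channel thresholded by **Tsai's moment-preserving
   method**; the stroma mask is the hematoxylin channel thresholded by
   **Otsu's method** (stain-positive = dark, `value ≤ t`). Stroma
   overlapping tumor is removed (pixel-wise by default, or whole 8-connected
   components).
4. **QC.** A core is informative only if tumor reaches all four sides of the
   field (north/south/east/west edge bands), the tumor-area fraction is at
   least 1% (otherwise flagged EpCAM-negative for manual scoring), and the
   stroma mask is non-empty.
5. **TSR and aggregation.** `TSR = tumor area / stroma area` per core; per
   patient the minimum and maximum over informative cores are kept and the
   maximum is dichotomized at the cut-off: **low** if `TSR < 1`, **high** if
   `TSR ≥ 1`.

Cohort helpers cover category proportions, chi-square / Fisher's exact 2×2
association tests, Kaplan–Meier estimates and the log-rank (Mantel–Cox)
test. A synthetic renderer draws gland-like tissue layouts with known
tumor/stroma/lumen ground truth through the forward Beer–Lambert model, and
a cohort simulator draws TSR-dependent recurrence times, so the whole
pipeline is testable without clinical slides.

## Worked example

```r
library(tsrquant)

dir <- file.path(tempdir(), "demo")
sim <- simulate_dataset(dir, n_patients = 4, cores_per_patient = 2,
                        size = 192, seed = 42)           # renders 8 PNG cores
res <- run_quantify(sim$sheet, file.path(dir, "results"))
res$cores[, c("core_id", "patient_id", "tumor_area_px",
              "stroma_area_px", "tsr", "informative")]
```

```
   core_id patient_id tumor_area_px stroma_area_px   tsr informative
1 P0001_c1      P0001         26923           2816 9.561        TRUE
2 P0001_c2      P0001         27829           3232 8.610        TRUE
3 P0002_c1      P0002         20453          12328 1.659        TRUE
...
```

Each row is one scored core: the mask areas in pixels, their ratio (the
TSR), and whether the core passed QC. Patient-level aggregation keeps the
min/max over informative cores and dichotomizes the maximum at 1:

```r
res$patients
```

```
  patient_id n_informative_cores tsr_min tsr_max tsr_mean tsr_median category
1      P0001                   2   8.610   9.561    9.086      9.086     high
2      P0002                   2   1.199   1.659    1.429      1.429     high
3      P0003                   2   3.127   4.684    3.905      3.905     high
4      P0004                   2   5.507   6.490    5.998      5.998     high
```

Against the rendered ground-truth ratios of this toy set the recovered TSR
values have a median relative error of 1.17%. With a follow-up table,
`survival_report(res$patients, read_followup(sim$followup))` adds
Kaplan–Meier curves per category and the log-rank comparison.

A command-line wrapper with `quantify`, `aggregate`, `survival` and
`simulate` subcommands is installed under `inst/cli/tsrquant.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/tsrquant.R", package="tsrquant"))')" \
    quantify --sheet cores.csv --out-dir results/
```

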