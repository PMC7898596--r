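# fibremetrics

Quantification of fibrillar network patterns in 2-D microscopy images.

Tissue remodelling — in fibrosis, wound healing and cancer — changes how
extracellular matrix (ECM) fibres are laid out: isotropic, curly meshworks
become aligned, linear tracts; density, branching and the size of
matrix-free gaps all shift. These patterns are visible in picrosirius-red
or trichrome histology, fibronectin-stained cell-derived matrices and
second-harmonic collagen imaging, but they are hard to score by eye.
`fibremetrics` turns one image into one row of interpretable numbers, so
pattern differences can be tested statistically and related to outcome
data. The same machinery applies to any filamentous network image —
cytoskeleton, vasculature, hyphae.

## What it computes

Fibre centrelines are extracted by Steger-style curvilinear ridge
detection (Gaussian-derivative Hessian at a scale matched to the stated
line width, subpixel localisation, hysteresis linking, branch pruning,
optional multi-width mask amalgamation). From the resulting fibre network
and mask:

| metric | definition |
|---|---|
| end points `E`, branch points `B` | free fibre termini; distinct junction loci |
| total length `L` | sum of fibre polyline lengths (µm if calibrated) |
| hyphal growth unit | `L/E`, length per end point |
| average fibre length | `L / 0.5(E + B)` |
| fibre thickness | HDM area / `L` |
| curvature | mean turning angle (degrees) between successive chords of a stated window, swept over a window range |
| alignment | structure-tensor coherency `(λmax − λmin)/(λmax + λmin)` ∈ [0, 1] |
| HDM | fraction of pixels at or above an intensity threshold (high-density matrix) |
| fractal dimension | box-counting slope of log N(ε) vs log(1/ε), ∈ [1, 2] for fibre masks |
| lacunarity | gliding-box `\|s²/μ² − 1\|`, averaged over box sizes |
| gap sizes | maximal inscribed circles in matrix-free space, all radii reported |
| normalised metrics | `E/L`, `B/L`, `L/area` — the size-independent columns to compare across studies |

Colour deconvolution (Ruifrok–Johnston, user-defined stain vectors from
three reference regions) is available for counterstained histology. A
deterministic synthetic-scene generator with exact ground truth underpins
the test suite and lets users validate parameter choices.

## Worked example

```r
library(fibremetrics)
# a reproducible synthetic field: 20 aligned fibres, width 4 px, 5 deg jitter
scene <- render_scene(scene_spec(image_size_px = 256, n_fibres = 20,
                                 orientation_mode = "aligned", jitter_deg = 5,
                                 fibre_width_px = 4, min_separation_px = 12,
                                 length_px = c(60, 140), seed = 1))
params <- parameter_set(line_width_min_px = 4, line_width_max_px = 4,
                        gap_analysis = TRUE, min_gap_diameter_px = 8)
res <- process_image(scene$image, params, image_id = "aligned_demo")
round(res$record[c("endpoints", "branchpoints", "total_length",
                   "avg_fibre_length", "alignment", "hdm", "fractal_dim",
                   "lacunarity", "norm_endpoints", "norm_length",
                   "gap_count")], 4)
#>   endpoints branchpoints total_length avg_fibre_length alignment    hdm
#> 1        40            0     1861.483          93.0741     0.926 0.1002
#>   fractal_dim lacunarity norm_endpoints norm_length gap_count
#> 1       1.148      2.062         0.0215      28.404       155
```

All 20 fibres are recovered (40 end points, no spurious branches; the
generator's truth is E = 40, L = 1695.8 px — detected length slightly
exceeds truth because ridge responses extend marginally past fibre tips).
The coherency of 0.93 reflects the 5° orientation jitter; the fractal
dimension of 1.15 and lacunarity of 2.06 describe a sparse, gappy mask,
and the 155 inscribed circles list every matrix gap of diameter ≥ 8 px.
An isotropic field of the same density scores coherency below about 0.15,
which is the contrast the alignment metric is designed to capture.

For a directory of images, `run_batch(input_dir, params, output_dir)`
writes one summary CSV row per image (raw and normalised columns), a
fibre mask and HDM image per input, per-image gap CSVs and a run log. The
same pipeline is scriptable from a shell via `inst/cli/fibremetrics`
(`run`, `fixtures`, `params` subcommands), with parameters in a flat
`key = value` file that is saved alongside outputs for reproducibility.

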