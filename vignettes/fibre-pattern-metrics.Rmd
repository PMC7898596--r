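---
title: "Quantifying fibrillar matrix patterns: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fibrillar matrix patterns: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`fibremetrics` quantifies the architecture of fibrillar networks —
extracellular matrix in stained tissue sections, cell-derived matrices,
second-harmonic collagen images, cytoskeletal or vascular networks — from
single 2-D images. The pipeline has three stages: (i) preprocessing to a
canonical grayscale raster, (ii) extraction of fibre centrelines by
curvilinear ridge detection, and (iii) a panel of per-fibre and global
pattern metrics with size normalisations. Everything downstream of
preprocessing is deterministic: fixed inputs and parameters give identical
outputs.

# Preprocessing

Images are reduced to 8-bit grayscale (Rec. 601 luminance for RGB input;
16-bit data are rescaled linearly). Two user-facing conventions follow:

* **Polarity.** The pipeline's internal convention is fibres bright on a
  dark background, as in fluorescence; histology images with dark fibres on
  a light background are inverted (`dark_lines = TRUE`).
* **Contrast saturation.** An affine stretch that clips a stated percentage
  of pixels (half at each histogram tail) and maps the rest onto [0, 255].
  The default, 0.35%, is the conventional enhance-contrast setting for
  microscopy; it fixes the intensity scale that both the high-density-matrix
  threshold and the detector's contrast thresholds refer to. A constant
  image is returned unchanged with a warning, as the stretch is undefined.

The **high-density matrix** (HDM) fraction is the proportion of pixels at
or above `hdm_threshold` (default 185 on the post-saturation scale; Otsu's
method is available as an automatic alternative). HDM is the one metric
computed on the grayscale image rather than the fibre mask.

For histochemical stains with a counterstain (picrosirius red with
haematoxylin, trichrome stains), optional colour deconvolution separates
stains in optical-density space. OD is computed as `-log10((I + 1)/256)`;
the `+1` offset avoids `log(0)` at intensity 0 and costs at most 0.2% of
the OD scale. Stain vectors are estimated from three user-chosen regions
(matrix stain, counterstain, background), and per-pixel OD vectors are
projected onto that basis by inverting the 3×3 stain matrix; negative
concentrations are clamped to zero and channels are mapped onto [0, 255]
by the fixed full OD scale `log10(256)`, keeping channel values comparable
across images. Deconvolution is explicitly opt-in and never automatic.
When it is used, HDM is computed after deconvolution on the matrix
channel; whether to threshold before or after unmixing is a genuinely open
choice, and the package's position (after) is stated here so users can
compare accordingly.

# Ridge detection

Fibres are treated as curvilinear ridges. For a target line width $w$ the
image is differentiated with Gaussian-derivative filters at scale
$\sigma = w/(2\sqrt{3}) + 0.5$ — the smallest scale at which a bar profile
of width $w$ retains a single response maximum at its centre, plus a
conditioning margin. At each pixel the Hessian is eigen-decomposed; the
eigenvector of the most negative eigenvalue $\lambda_2$ points across the
line, and a second-order Taylor step along it localises the ridge to
subpixel accuracy. A pixel is a ridge candidate when $\lambda_2 < 0$ and
the interpolated extremum falls within 0.6 px of the pixel centre (the
margin beyond the nominal 0.5 keeps lines that run midway between two
pixel rows, where both neighbours place the extremum just outside their
boundary; duplicate twins are retired during linking).

Two quality gates distinguish lines from blobs and saddles: candidates
require $|\lambda_1| \le 0.8\,|\lambda_2|$, and *seeds* (points allowed to
start a line) require $|\lambda_1| \le 0.3\,|\lambda_2|$. On an ideal line
the along-line eigenvalue $\lambda_1$ is near zero; at line end caps and
crossing plateaus the two eigenvalues are comparable, which is how those
artefacts are kept from seeding phantom fibres while genuine lines may
still be traced through them.

**Hysteresis.** The user-facing thresholds `contrast_high`/`contrast_low`
(defaults 100/30) are intensity contrasts on the saturated 8-bit scale.
They are converted internally to second-derivative response thresholds
through the response model of a smoothed bar profile,
$R(h) = 2 h a \, e^{-a^2/2\sigma^2} / (\sqrt{2\pi}\,\sigma^3)$ with
$a = w/2$, so the same parameter file works across line widths. Ridges at
least as strong as `contrast_high` seed lines; lines extend through ridge
points at least as strong as `contrast_low`, stepping to the best
orientation-compatible neighbour (under 45° of turn per step; ties broken
by smaller orientation change, then lexicographic pixel order, so output
is deterministic). An absolute response floor (0.5 intensity units/px²)
prevents numerical noise on flat backgrounds from ever becoming a
candidate.

**Junctions versus continuations.** When a growing line meets an existing
one in its interior, the contact is a branch: a junction is recorded and
the met fibre is split there, so every fibre is internally junction-free.
When traces meet end-to-end the contact is a continuation the tracer broke
(crossing plateaus interrupt candidates): ends are re-merged when they
nearly touch (≤3 px, small overlaps allowed) and point along each other.
Where three or more substantial fibre ends meet in one small
neighbourhood, that cluster is a junction instead — this is what resolves
an X-crossing approached from all four arms. A short look-ahead
(≈ half the line width) lets a trace attach across a crossing plateau to a
line already traced.

**Branch pruning.** Fibres that end in a free end point and are shorter
than `min_branch_px` are removed, junctions left with fewer than three
attachments are dissolved (two survivors merge into a through-fibre), and
the process repeats to stability. Degenerate micro-loops at fibre ends are
pruned with the twigs. The default of 10 px suits fibres up to ~5 px wide;
for thicker fibres a value of about twice the line width is appropriate,
since end-cap artefacts scale with the detection kernel.

**Multi-width sweeps.** When a width range is given, detection runs at
`min, min+5, …` (the maximum is always included even off the 5-px grid)
and the per-width 1-px masks are amalgamated by pixel-wise union. Network
metrics are always computed from a single stated width — by default the
minimum — never from the amalgam, whose union of 1-px traces may be
locally thicker than one pixel; the amalgam serves the mask-based pattern
metrics and visual verification. Responses near the border are kept;
replicate padding (not reflection) avoids phantom fibres parallel to the
edge.

# Per-fibre metrics

With $E$ end points, $B$ branch points and $L$ the summed polyline length
(µm when a pixel size is provided, else px):

* **End points** are fibre termini not within 1.5 px of a junction — the
  small tolerance absorbs subpixel linking gaps; a terminus that close to
  a junction counts as attached. Closed loops have no termini.
* **Branch points** are distinct junction loci; a 4-way crossing counts
  once. (Whether a reference count would split it into two 3-way events is
  ambiguous; users comparing absolute counts should check that
  convention.)
* **Hyphal growth unit** is returned as $L/E$ — length per end point, the
  classical definition in filamentous growth analysis — so that the
  normalised end-point metric $E/L$ is literally its inverse. The
  reciprocal convention is available via an argument.
* **Average fibre length** is $L / 0.5(E + B)$, assuming one fibre begins
  at each branch; **fibre thickness** is HDM area divided by $L$.
* **Curvature** resamples each fibre at chord steps of the curvature
  window (successive samples exactly `window` px apart in straight-line
  distance) and reports the mean absolute turning angle between
  consecutive chords, in degrees. On an arc of radius $r$ this gives
  exactly $2 \arcsin(w/2r)$, which is the closed form the tests pin. The
  pooled mean weights every chord pair equally, so long fibres contribute
  proportionally; a per-fibre mean is available by flag. Fibres shorter
  than two chords contribute nothing. Small windows sense fine waviness,
  large windows coarse bends — sweeping a window range (default 10–40 px,
  step 10) reports one column per window, and the ordering of two wavy
  fibres can legitimately reverse between small and large windows.

**Normalisations.** Raw $E$, $B$, $L$ scale with image size; the reported
ratios $E/L$, $B/L$ and $L/\text{area}$ (the latter per 1000 px² for
readable magnitudes, a formatting convention stated in the CSV header
metric list) remove that dependence and are the quantities to compare
across studies. When images carry a pixel calibration the ratios are
physical densities and are directly comparable across magnifications.

# Global pattern metrics

* **Alignment** is the coherency of the global gradient structure tensor
  $J$: Gaussian-derivative gradients at $\sigma = 1$ px, averaged with a
  uniform weight over the whole field of view (a Gaussian region-of-
  interest weight is available), then
  $a = (\lambda_{max} - \lambda_{min})/(\lambda_{max} + \lambda_{min})
  \in [0, 1]$, with 0 complete isotropy and 1 perfect alignment. A blank
  image is defined as coherency 0. Alignment is computed on the grayscale
  image by default (a flag allows mask-based computation).
* **Fractal dimension** is the box-counting dimension of the mask: counts
  of occupied boxes at dyadic sides 2, 4, …, up to a quarter of the
  smaller image dimension (so at least 4×4 boxes always span the image),
  grid anchored at the origin, and the least-squares slope of
  $\log N(\epsilon)$ against $\log(1/\epsilon)$. Filled masks give 2.0 and
  single 1-px lines 1.0 exactly; sparse short-fibre masks can fall
  slightly below 1, which is a property of finite-scale box counting, not
  an error.
* **Lacunarity** uses gliding boxes (stride half the box side, dyadic
  sizes 4 … min(dim)/4 by default) over the mask, with per-box mass the
  enclosed foreground count: $\Lambda = |s^2/\mu^2 - 1|$ per size,
  averaged over sizes. Note the absolute value: a perfectly uniform
  pattern scores 1 while $s = \mu$ scores 0, inverting the conventional
  gliding-box ordering at the low end. The formula is implemented as
  stated deliberately; `convention = "plus_one"` switches to the
  conventional $1 + s^2/\mu^2$. Users comparing against published values
  should verify which convention those used. A grayscale mode exists since
  the definition speaks of grey level; the default operates on the mask,
  consistent with all mask-derived metrics.
* **Gap analysis** fits maximal inscribed circles into the matrix-free
  space: repeatedly take the Euclidean-distance-transform maximum of the
  background (fibres, previously placed circles, and — by default — the
  image border as obstacles), place a circle of that radius, and stop when
  the diameter falls below `min_gap_diameter_px`. Treating the border as
  an obstacle keeps gaps truncated by the field of view from being
  overstated (a flag disables this for tiled imagery). Ties at the
  distance maximum break to the smallest (row, col). Circles are
  rasterised conservatively into the obstacle set, so the returned set is
  pairwise non-overlapping with radii non-increasing. All gap sizes are
  written per image so users can study means, distribution shapes, or
  tails.

# The synthetic scene generator

All tests and validation inputs are generated, with machine-checkable
ground truth: random fibre fields (aligned with orientation jitter, or
isotropic), straight/sine/arc waveforms, controlled width, optional
minimum separation (rejection sampling) when crossing-free truth is
needed, plus analytic patterns (gratings, concentric rings, Sierpinski
carpets, grids, masks with circular holes) whose metric values are known
in closed form. Fibres are anti-aliased by 4× supersampling so "width"
has an exact geometric meaning; a `scale` argument re-renders the
identical layout at a multiple of the base resolution, emulating the same
field imaged at a different pixel size. Noise is additive Gaussian with
s.d. 25 on the 8-bit scale by default — a realistic single-image
approximation of detector noise — and every generator is
seed-deterministic.

What the generator does *not* emulate: uneven illumination, stain
variability, out-of-focus planes, fibre bundling and width variation along
a fibre, and the dense multi-scale texture of real matrix. Passing tests
therefore demonstrate correctness of the algorithms on controlled
geometry, not end-to-end performance on tissue; parameter guidance for
real images (line width near the dominant fibre width, branch pruning
scaled to it, consistent acquisition settings) matters more than any
default here.

A note on resolution robustness: on these clean scenes detection is
essentially exact, so endpoint and branch counts are identical across
renders of the same scene at different resolutions, and the normalised
metrics are resolution-invariant via the physical calibration. In real
images, raw counts themselves grow with pixel count because finer texture
fragments into more detected filaments; the normalised ratios are what
remains comparable, which is why they are the recommended columns.

# Numerical choices and problem sizes

Degenerate inputs are handled explicitly: constant images warn and pass
through saturation; blank images give empty networks, zero totals and
missing-value pattern metrics (never silent zeros); $E = 0$ makes HGU
missing, $E + B = 0$ makes average fibre length missing; empty masks make
fractal dimension and lacunarity missing.

The validation suite runs on 128–512 px images with 5–60 fibres, and the
resolution-invariance check renders one scene at 1024² and 2048²; these
sizes keep the full suite to a few minutes on one CPU while leaving every
geometric effect (subpixel placement, staircases, caps, crossings)
represented. Detection on a 2048² image takes on the order of ten
seconds.

# Known limitations

* Strictly 2-D: fibres crossing in depth project onto apparent junctions;
  consistent section thickness matters.
* Per-fibre width is summarised only through HDM-based mean thickness;
  there is no per-fibre width profiling.
* The alignment metric is a single global score; it does not produce
  local orientation maps.
* Texture metrics of the grey-level co-occurrence family are deliberately
  out of scope.
* Very dense mats (fibre spacing below the detection kernel) merge into
  single ridges; counts there reflect the resolvable network.
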