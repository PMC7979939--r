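---
title: "Refractive-index mapping and morphological dilation for terahertz margin delineation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refractive-index mapping and morphological dilation for terahertz margin delineation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thzmargin)
```

## The measurement model and its assumptions

A reflection-mode terahertz time-domain imager scans excised tissue held on
a sapphire substrate of thickness $d$ and complex index
$\hat n_s = n_s - j\kappa_s$. Against the reference field $E_r(\omega)$
recorded from a metal plate, the time-gated substrate–tissue echo of a
pixel with tissue index $\hat n_t$ has the transfer function

$$T(\omega) \propto T_{as}\,R_{st}\,T_{sa}\,P_s^2(\omega, d), \qquad
T_{ab} = \frac{2\hat n_a}{\hat n_a + \hat n_b},\;
R_{ab} = \frac{\hat n_a - \hat n_b}{\hat n_a + \hat n_b},\;
P_a = e^{-j\omega d \hat n_a / c}.$$

Assumptions baked into `candidate_transfer()`:

* **Normal incidence.** The instrument's maximum incidence angle is about
  10°, for which the normal-incidence Fresnel forms err by under 1.5%; we
  implement the printed normal-incidence forms exactly and accept that
  error rather than introduce polarization-resolved coefficients.
* **Ideal mirror reference.** The metal-plate response is modelled as a
  reflection coefficient of $-1$ at the substrate's front face
  (`mirror_sign = -1`, switchable to $+1$). The choice only flips a global
  phase, which the magnitude objective ignores entirely.
* **Single gated echo.** Only the substrate–tissue echo is modelled; the
  air–substrate front-surface reflection is assumed gated out in time, and
  no Fabry–Pérot multiples beyond the double pass $P_s^2$ are included.
* **Air is $\hat n = 1 - 0j$**, and the substrate index is an input
  (`substrate_spec`), not a constant: `default_sapphire()` (2 mm,
  $n = 3.07$, $\kappa = 0.005$, frequency-flat) is a synthetic stand-in of
  realistic magnitude for the instrument-specific calibration curve, which
  `characterize_substrate()` can fit from a bare-substrate trace.

## The inverse problem

Per pixel, the measured transfer $T_s = E_s/E_r$ is compared with
candidates over the exhaustive grid $n \in [1.5, 3]$ step $0.01$ (151
values) and $\kappa \in [0, 1]$ step $0.001$ (1001 values), endpoints
included, by minimizing the log-magnitude objective
$\chi(\omega) = \ln^2\!\left(|T_s|/|T_c|\right)$ at the operating
frequency.

**550 GHz** is the default operating frequency: the benign/malignant index
contrast is largest roughly between 300 and 700 GHz, and 550 GHz trades
signal-to-noise against spatial resolution. The minimization uses the
nearest frequency bin; a band-averaged $\chi$ is deliberately out of scope
(single-frequency is what the classification uses).

**Degeneracy and the two modes.** At a single frequency, one magnitude
constrains two unknowns, so the $\chi$ minimizer set is a one-dimensional
level curve in $(n, \kappa)$. We provide both readings:

* `mode = "magnitude"` — the objective exactly as printed, with a
  deterministic tie-break (smallest $\kappa$, then smallest $n$; the
  candidate table is laid out in that order so the first minimum wins).
* `mode = "complex"` (default) — adds the squared phase residual
  $[\arg T_s - \arg T_c]^2$, wrapped to $[-\pi, \pi)$, which makes the
  problem well-posed and noise-free on-grid recovery exact. The candidate
  waveform construction the method builds on implies the full complex
  waveform is available, so this is the natural default for recovery work.

Pixels whose reference magnitude falls below a relative SNR floor
(`floor_rel`, default $10^{-6}$ of the reference peak) or whose trace is
non-finite are masked — never interpolated — and reported in a message.

## Segmentation

`threshold_map()` uses a strict inequality (index *higher than* the
threshold is malignant); ties at exactly $t$ stay benign. One pass of
binary Minkowski dilation follows:
$\partial_\Lambda(P) = (P \oplus \Lambda) \cap S$, where $S$ is the tissue
support derived from the sample contour, so dilation never creates
malignant pixels outside the sample. The pass is single by contract —
newly added pixels exert no influence, and the API never iterates.

The classifier family is a nested sequence of origin-symmetric discrete
disks: $\Lambda^0 = \{(0,0)\}$ (no dilation), $\Lambda^1$ the 3×3 cross
(5 offsets), $\Lambda^2$ the 3×3 square plus $(\pm 2, 0), (0, \pm 2)$
(13 offsets), $\Lambda^3$ the disk of Euclidean radius 2.5 (21 offsets).
The published figures do not print coordinates, only that the elements act
"in the close vicinity" and "with the same impact in all directions";
any alternative reading is a drop-in via a JSON offsets file
(`read_structuring_element()`), subject to the same origin-membership and
point-symmetry invariants. Offsets falling outside the image are discarded
(no wraparound or padding).

The contour level for the support mask is an operator choice; the default
is the midpoint between the two modes of the field histogram (a 1-D
two-means split), with interior holes filled.

## Registration

The pathology mask and the terahertz frame differ in resolution and
orientation. Registration is feature-based on contours only: extract the
sample isoline on each side, resize the pathology side bicubically (Keys
kernel, $a = -1/2$, 16-neighbour; constants and affine ramps reproduced
exactly, borders handled by linear extrapolation) to the terahertz shape,
then search rotations over a grid (default $\pm 45°$ step 1°) maximizing
the Pearson correlation between the two contour matrices; ties go to the
smallest angle magnitude. Rotation uses bilinear resampling about the
feature centroid followed by re-binarization at 0.5. Correlation is
computed on filled masks by default (smoother objective); outline-only is
a switch. The manual "progressive twist" of the original workflow is the
explicit `coarse_angle` parameter. The terahertz image is never resampled.

A practical identifiability point, measured during development: the
rotation is only determined as finely as the feature's boundary lever arm
allows. Registering the small tumour annotation directly leaves roughly
1.5° of intrinsic angular noise at 4× scale, while the whole-sample
outline (the feature the original flow contours) resolves rotations to
within the 1° search step on a 64×64 frame. `register_images()` therefore
estimates the transform on the outline and can carry any other
pathology-frame mask through it via `apply_to`.

## Evaluation

Only pixels where *both* classifications carry tissue are evaluable; the
rest are "not applicable" and excluded from counting. The pathology mask
defines the positives — on disagreement the pathologist prevails, and
predictions never reweight counts. From the confusion counts,
$\mathrm{TPR} = \mathrm{TP}/(\mathrm{TP}+\mathrm{FN})$ and
$\mathrm{FPR} = \mathrm{FP}/(\mathrm{FP}+\mathrm{TN})$. (The prose of the
source's FPR definition contradicts its own printed formula; the formula
is implemented.) ROC curves sweep the threshold grid (default $[1.5, 3]$
step 0.1, configurable down to the inversion step 0.01); because dilated
curves need not be monotone in the threshold, AUC sorts points by FPR and
anchors $(0,0)$ and $(1,1)$ before trapezoidal integration — the standard
convention, as the integration rule is not otherwise specified. Classifier
selection maximizes $\mathrm{TPR} - \mathrm{FPR}$; ties prefer higher
specificity, then the lower threshold; the best two thresholds per
classifier are reported, with sensitivity/specificity as percentages.

## The phantom: what it emulates, and what a green test proves

No clinical field cubes or pathology slides are public, so the package
ships a forward-model phantom (`generate_phantom()`) whose defaults state
the simulated world once:

* **Geometry** — a 32×32 frame holding an elongated tissue slice
  (adipose ellipse, 0.45·h × 0.30·w radii) containing a fibrous region and
  an anisotropic tumour. Elongation is realistic for excised strips and
  makes the sample outline an identifiable registration feature; a
  circular footprint would leave the rotation mathematically undetermined.
* **Class indices at 550 GHz** — adipose $n = 1.90$, fibrous $2.20$,
  tumour $2.60$ ($\kappa$ = 0.10/0.15/0.20), all inside the search range
  and consistent with the 2.1–2.6 span of useful thresholds; they sit on
  the grid so noise-free recovery can be bit-exact. They are modelling
  choices, not literature values.
* **Low-density tumour margin** — a 2 px ring (class `tumour_margin`,
  $n = 2.25$, $\kappa = 0.160$) that is malignant in the truth mask but
  nearly indistinguishable from fibrous tissue in index. This encodes the
  stated failure mode of bare thresholding — tumour edges sparsely
  populated with cancer cells read as healthy — and is what gives
  dilation something real to recover. Without it, a symmetric blur leaves
  a perfect separating threshold at the class midpoint and no dilation
  could ever help.
* **Diffraction surrogate** — Gaussian blur of the index maps, default
  FWHM 2 px, reflective boundary (mass-conserving).
* **Noise** — i.i.d. complex Gaussian per frequency and pixel, scaled so
  the 550 GHz signal-to-noise ratio per pixel equals `snr_db`
  (default 30 dB), deterministic given `seed`.
* **Reference pulse** — raised-cosine magnitude over 0.2–2 THz with linear
  phase; its shape cancels in the transfer ratio and exists to exercise
  the SNR floor realistically.
* **Pathology pair** — the truth mask and the sample footprint,
  nearest-neighbour upscaled 4×, rotated 12° about the shared footprint
  centroid, re-binarized.

What the phantom does *not* emulate: histology artefacts (folds, cracks,
tissue loss), deformable shrinkage, correlated noise, frequency-dependent
tissue dispersion beyond the single operating frequency, and echo overlap
in the time domain. A green end-to-end test therefore establishes the
pipeline's internal consistency (forward model inverted exactly, dilation
and registration recover injected structure, evaluation formulas correct)
— not clinical performance, which requires the real data this package
cannot ship.

## Numerical choices

* Grid endpoints are inclusive; candidate counts are exactly 151 × 1001.
* Tie-breaks everywhere are deterministic and documented (inversion:
  smallest $\kappa$ then $n$; rotation: smallest $|$angle$|$; thresholds:
  higher specificity then lower threshold).
* Phase residuals wrap to $[-\pi, \pi)$; the half-open side is immaterial
  under squaring except on a measure-zero set of the grid.
* Bicubic resizing returns the input object unchanged (bit-equal) when the
  target shape equals the source shape.
* Degenerate inputs fail loudly with classed conditions
  (`thz_domain_error`, `thz_empty_band`, `thz_empty_region`,
  `thz_degenerate_media`, `thz_shape_error`, `thz_undefined_rate`) rather
  than returning sentinels; masked pixels are the one sanctioned sentinel
  (NA in the index map, FALSE in its support).
* Coordinates are row-major with the origin at the top-left pixel centre
  (0-based in contour output); angles are in degrees.

## Known limitations

* The magnitude-mode inversion is honest to the printed objective and
  therefore degenerate in $\kappa$ at a single frequency; use complex mode
  for parameter recovery, magnitude mode to reproduce the printed method.
* Registration handles rigid rotation + uniform scale only — no
  translation search (centroids are aligned implicitly) and no elastic
  correction of histology artefacts, which the source explicitly declined
  to attempt.
* Rotation recovery saturates near the 1° grid step when the registration
  feature is small (see the identifiability note above).
* The CLI reads whole cubes into memory; fine for the phantom scale this
  package targets (up to ~128×128×37), not for production instrument
  dumps.

## File formats

Field cubes serialize to JSON (frequency axis plus real/imaginary arrays),
masks and index maps to CSV with a JSON sidecar carrying the frequency,
grid and objective mode, ROC tables to CSV, summaries and provenance to
JSON. Plain-text formats keep every artifact inspectable and
diff-friendly; binary containers were deliberately avoided.
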