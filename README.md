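# thzmargin

Terahertz refractive-index mapping and morphological dilation for breast
tumour margin delineation.

## The problem

During breast-conserving surgery the surgeon needs to know whether malignant
cells reach the edge of the excised volume. Histopathology answers this
days later; reflection-mode terahertz (THz) time-domain imaging can answer
it in the operating theatre, because malignant breast tissue shows a higher
refractive index `n` than healthy tissue in the 0.2–2 THz band. The
difficulty is that a far-field THz imager is diffraction-limited (~0.3 mm at
1 THz) and tumour edges are sparsely populated with cancer cells, so the
index measured at a tumour margin looks deceptively healthy, and classifying
each pixel by its index alone under-segments the tumour.

`thzmargin` implements the full pixel-classification pipeline for this
setting, for THz spectroscopists and image-analysis researchers:

1. **Forward model** — the sample sits on a sapphire substrate (thickness
   `d`, index `n̂_s`) and is measured against a metal-plate reference. The
   time-gated substrate–tissue echo has transfer function

   ```
   T(ω) ∝ T_as(ω) · R_st(ω) · T_sa(ω) · P²_s(ω, d)
   T_ab = 2n̂_a / (n̂_a + n̂_b),  R_ab = (n̂_a − n̂_b) / (n̂_a + n̂_b),
   P_a(ω, d) = exp(−j ω d n̂_a / c),   n̂ = n − jκ
   ```

2. **Inversion** — per pixel, the measured transfer `T_s = E_s/E_r` is
   compared with candidates over an exhaustive grid
   `n ∈ [1.5, 3] (Δn = 0.01)`, `κ ∈ [0, 1] (Δκ = 0.001)` by minimizing
   `χ(ω) = ln²(|T_s|/|T_c|)` at the 550 GHz operating frequency
   (optionally adding the squared wrapped phase residual, which makes the
   single-frequency problem well-posed).

3. **Segmentation** — threshold the index map (`n > t` ⇒ malignant), then
   apply exactly one pass of binary Minkowski dilation `P ⊕ Λ` with a
   structuring element Λ⁰ (identity) … Λ³ (discrete disk, 21 offsets),
   clipped to the sample contour so no malignant pixel leaves the tissue.

4. **Registration** — bring the high-resolution pathology mask into the THz
   frame: isoline contouring, bicubic resizing, and a rotation search
   maximizing the Pearson correlation of the sample outlines.

5. **Evaluation** — pixelwise confusion counts against the pathology truth
   (the pathologist prevails on disagreement; pixels outside either tissue
   support are "not applicable"), ROC curves per structuring element,
   trapezoidal AUC, and best/second-best threshold selection by
   `TPR − FPR`.

6. **Phantom** — a forward-model simulator that generates everything the
   clinical study would supply: a tissue map (adipose / fibrous /
   low-density tumour margin / tumour), the simulated field cube with
   diffraction blur and complex Gaussian noise, and a 4×-resolution,
   rotated "pathology" mask pair. Every stage of the pipeline is validated
   against it.

## Worked example

```r
library(thzmargin)

# default phantom: 32x32 frame, 2 px blur FWHM, 30 dB noise, seed 1
ph  <- generate_phantom(phantom_spec())
map <- extract_map(ph$cube, ph$reference, default_sapphire(),
                   support = ph$truth$support)

ev <- evaluable_mask(map$support, ph$truth$support)
for (r in 0:3) {
  cv <- roc_curve(map, ph$truth$truth_mask, ev, make_structuring_element(r))
  bt <- best_thresholds(cv, 1)
  cat(sprintf("rank %d  AUC %.4f  best t %.1f  TPR-FPR %.4f  sens %.1f%%  spec %.1f%%\n",
              r, roc_auc(cv), bt$threshold, bt$youden,
              bt$sensitivity_pct, bt$specificity_pct))
}

reg <- register_images(ph$truth$support, ph$pathology_support,
                       apply_to = ph$pathology_mask)
cat(sprintf("registration: angle %.0f deg, scale %.2f, r = %.3f\n",
            reg$result$angle, reg$result$scale, reg$result$correlation))
```

prints

```
rank 0  AUC 0.9794  best t 2.2  TPR-FPR 0.8906  sens 98.0%  spec 91.0%
rank 1  AUC 0.9880  best t 2.3  TPR-FPR 0.8911  sens 89.1%  spec 100.0%
rank 2  AUC 0.9958  best t 2.3  TPR-FPR 0.9343  sens 100.0%  spec 93.4%
rank 3  AUC 0.9969  best t 2.4  TPR-FPR 0.9514  sens 96.0%  spec 99.1%
registration: angle 12 deg, scale 0.25, r = 0.988
```

Reading the output: the bare-threshold classifier Λ⁰ peaks at a low
threshold (2.2) because the blurred, low-density tumour margin is invisible
above it; the wide element Λ³ pairs a *higher* threshold (2.4) with
dilation that spreads the confidently detected core over the margin,
improving `TPR − FPR` from 0.89 to 0.95 and AUC from 0.979 to 0.997 — the
wider the structuring element, the higher the optimal index threshold. The
registration line shows the injected 12° twist and 4× resolution of the
synthetic pathology mask being recovered exactly (correlation 0.988).

## Command line

Each stage is also a CLI subcommand (results identical to the library
calls):

```sh
Rscript inst/cli/thzmargin.R simulate --out run/sim --shape 32 --snr-db 30 --blur-fwhm 2 --seed 1
Rscript inst/cli/thzmargin.R extract  --cube run/sim/cube.json --out run/ext --support run/sim/support.csv
Rscript inst/cli/thzmargin.R classify --map run/ext --out run/cls --thresholds 2.2,2.4 --ranks 0,3
Rscript inst/cli/thzmargin.R evaluate --map run/ext --out run/ev \
    --pathology run/sim/pathology_mask.csv --pathology-support run/sim/pathology_support.csv
```

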