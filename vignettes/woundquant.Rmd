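---
title: "Quantifying single-cell wound repair: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-cell wound repair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundquant)
```

# The biological setting and the measurement problem

Laser wounding of a single large cell — here modeled on the *Drosophila*
syncytial embryo filmed under a cortical actin reporter — triggers a
stereotyped repair program: the wound first *expands* as membrane tension is
released and a membranous plug forms, an *actomyosin ring* then assembles at
the wound edge (flanked on the outside by a diffuse actin *halo*), the ring
*translocates inward* to close the wound, and finally the cortex is
*remodeled* back to its unwounded state. Comparing genotypes or drug
treatments requires turning each movie into a handful of numbers: how much
the wound expanded, how fast it closed, and how wide and how bright the
ring was. This package computes those numbers deterministically from
time-lapse stacks, replacing the manual Fiji workflow, and bundles the
statistics used on the accompanying wounded-versus-unwounded expression
screen.

# The repair metrics

Given the traced area series $A(t)$ (one pre-wound frame, $t = 0$ at
wounding):

* **Expansion fold** $= \max_t A(t) / A(t_0)$ with $t_0$ the first
  post-wound frame. We read "initial wound size" as the first measured
  post-wound area rather than the ablation-target area, because the target
  is an instrument setting, not a measurement; a different initial area can
  be supplied explicitly if wanted.
* **$t_{\max}$** is the earliest time attaining the maximal area (ties go to
  the earlier frame — a deliberate, reproducible rule; ties are measure-zero
  events in practice). **$t_{1/2}$** is the earliest time at or after
  $t_{\max}$ with $A \le f \cdot A(t_{\max})$. The fraction $f$ is
  configurable in $[0.35, 0.5]$ with default $0.5$: the slope of the area
  curve changes after this point, and the earliest-crossing reading at the
  top of the stated range is the most reproducible choice.
* **Contraction rate** $= (A(t_{\max}) - A(t_{1/2}))/(t_{1/2} - t_{\max})$,
  reported as a positive magnitude (a speed). Written with the time
  difference the other way round the expression is negative; since the
  quantity is an average closure speed we report its magnitude.
* **Ring geometry** is evaluated at the frame nearest a reference time of
  120 s post-wounding (configurable; e.g. 135 s is appropriate for membrane
  lipid reporters). The *inner* and *outer* edges of the ring are the first
  and last half-maximum crossings of the radial mean-intensity profile
  around the wound centroid — halfway between the far-field cortex baseline
  and the ring peak. No published criterion exists for where the ring
  "edge" lies; half-maximum is symmetric, robust to intensity scaling, and
  exact on a top-hat profile (gradient-extrema edges are a noted
  alternative we did not implement). Each edge encloses a filled region;
  **ring width** $= (\text{outer Feret} - \text{inner Feret})/2$ and
  **ring mean intensity** $= (\Sigma_{\text{outer}} - \Sigma_{\text{inner}})
  / (n_{\text{outer}} - n_{\text{inner}})$, the mean over the annulus.
* **Relative ring intensity** divides the ring mean by the *unwounded
  baseline*: the mean of a centered 50×50 px window of the pre-wound frame.
  This makes the quantity invariant to detector gain.

**Feret diameter.** The maximum caliper width of a region is computed as
the largest pairwise distance between *boundary-pixel centers*, via the
convex hull of the boundary set. Under the pixel-center convention a single
pixel has Feret 0 and a run of 11 pixels has Feret 10 — one pixel less than
Fiji's convention, which adds the pixel footprint. We chose centers because
the definition then has an exact brute-force counterpart (the $O(n^2)$
pairwise maximum) against which the implementation is verified identically
in the tests.

# Segmentation

The wound interior is dark (plug-filled) and enclosed by the bright ring,
so segmentation is: Gaussian blur (σ = 1 px) → intensity inversion → Otsu
threshold → discard components that touch the image border (the wound is
enclosed by construction) or are smaller than 5 px (noise specks) → refine
the accepted component's boundary to the half-level between its interior
intensity and the surrounding ring peak → fill holes, 3 px morphological
closing. The refinement step matters for accuracy: Otsu places the cut
wherever the histogram valley happens to fall, while the rendered (and
physical) wound edge is the mid-transition between dark interior and bright
ring; anchoring the boundary at the half-level makes the recovered area
essentially unbiased. A refined region is accepted only if its mean
intensity is below 0.6× the frame median — on a closed, remodeled cortex
nothing qualifies, which is how closure is detected without temporal
heuristics. Closure is flagged once the area stays below 1 μm² for two
consecutive frames.

Tracing is a *per-frame* operation by default (so results are independent
of frame order and of neighboring frames); an optional tracking mode
restricts each frame's threshold search to the previous mask dilated by
5 μm, for crowded fields. All masks use 0-based pixel counting — areas are
pixel counts times the pixel area, matching Fiji-style measurement, with no
sub-pixel contour integration.

The practical resolution limit: wounds below roughly 2 μm radius (≈ 9 px
diameter at 0.22 μm/px) start to be washed out by the 1 px blur and may be
reported as closed one frame early; the closure threshold and the area
tests in this package are set with that in mind.

# Profiles and kymographs

Line profiles average `width_px = 10` parallel pixel lines through the
wound center and report, per position, the mean with a 95% confidence
interval $\bar x \pm t_{0.975,\,n-1}\, s/\sqrt{n}$ computed across the
width samples, treated as independent. With only 10 samples the normal
1.96 multiplier would cover at ~92% rather than 95%, so the Student-t
quantile is used; the tests verify ~95% empirical coverage on i.i.d.
Gaussian frames. The default axis is horizontal through the wound centroid;
a vertical option matches profiles whose left-to-right order corresponds to
image top-to-bottom. An optional moving-average smoother (window 3) exists
for display but is disabled everywhere results are asserted.

Kymographs average a 5.3 μm-wide, 94.9 μm-long band across its width into
one spatial column per frame. One column per frame is used regardless of
the cadence change from 30 s to 60 s sampling; `uniform_time = TRUE`
repeats columns onto a uniform grid when a visually linear time axis is
wanted. When a configured band exceeds a (small, simulated) field of view,
the pipeline driver clamps it to the frame and logs the fact; the
`kymograph()` operation itself treats an out-of-frame ROI as an error.

# The synthetic wound movie

The simulator is phenomenological — it renders the *geometry and
photometry* that the metrics consume, not actin mechanics:

* **Trajectory**: $A(t) = 0$ for $t<0$; a half-cosine ramp from
  $\pi r_0^2$ at $t=0$ to $F \pi r_0^2$ at $t_{\max}$ (smooth, monotone,
  two parameters); then linear decay at the closure rate, clamped at zero.
  Linear decay makes the secant-slope estimator exact, so recovery errors
  measure the imaging pipeline, not the trajectory model. An optional
  shallower second segment after the half point exercises the rationale for
  stopping the secant at $t_{1/2}$.
* **Radial photometry** per frame: ≈0 inside the wound, a ring of the true
  width and amplitude abutting the edge, a wider dimmer halo outside it,
  cortex baseline beyond; all transitions are logistic with a 0.15 μm
  softness. The ring travels with the wound edge (treadmilling is not
  modeled — only geometry and intensity are needed).
* **Remodeling**: ring and halo amplitudes scale with
  $\min(1, A(t)/50\,\mu m^2)$, so the structures fade as the wound closes
  and a closed frame is uniform cortex. Scaling with *area* (linear in time
  near closure) rather than radius keeps the rendered movie free of
  square-root steepening at closure; with 1 s sampling no frame-to-frame
  total-intensity change exceeds 2%.
* **Acquisition**: the default frame grid is one pre-wound frame at −30 s,
  then every 30 s to 900 s, then every 60 s to 2400 s, mirroring the
  assay's imaging cadence. The default pixel size of 0.22 μm/px is typical
  of a 63×/1.4 NA spinning-disk setup (it is not dictated by the assay) and
  is configurable. The default initial radius (6 μm) matches the scale of a
  16 × 15.5 μm ablation target.
* **Noise**: Gaussian with σ = 5% of the ring amplitude by default
  (Poisson with configurable gain available). Frames are clamped at zero
  and quantized to uint16 on writing.

Ground truth records the per-frame radii and the *implied* metrics; for
ring intensity the implied value is the closed-form mean of the continuous
radial profile between its own half-maximum crossings, i.e. exactly what an
ideal measurement of the rendered image would return.

What the simulator does **not** emulate — non-circular wounds, uneven
cortical background, bleaching, focus drift, camera fixed-pattern noise,
multiple wounds — bounds what the passing tests show: they demonstrate that
the pipeline recovers the truth under the stated imaging model, not that it
is robust to every artifact of real microscopy. The per-module operations
(Feret, secant slopes, profile CIs, the statistics below) are, however,
model-free.

# The expression statistics

The screen design is four independent wounded-versus-unwounded replicates
on ~8000-gene two-channel arrays. The pipeline implements:

* **Spot filter** — remove a spot if foreground ≤ background + 3 SD in a
  channel, if background-subtracted signal < 100 in *both* channels, or if
  QC-flagged; a removal log names the first rule that fired.
* **Per-gene statistics** — a plain one-sample two-sided t test of the
  replicate log₂ ratios against zero. This is an explicitly labeled
  stand-in used for synthetic studies: production array analyses use
  moderated statistics and loess normalization, which this package does not
  re-implement — real per-gene p-values are ingested directly by
  `de_filter()` via column mapping. Zero-variance genes get the limiting
  p-values (1 at mean 0, else 0).
* **Significance filter** — Benjamini–Hochberg FDR at 5% *and*
  |log₂ ratio| ≥ 0.585 (±1.5-fold), both required; BH is the cited standard
  FDR procedure. The tests verify the selection against a brute-force BH
  oracle and verify false-call control under the global null.
* **TAD enrichment** — the TAD × (regulated, unaffected) contingency over
  genes on the array, tested with Fisher's exact test of independence:
  exact hypergeometric enumeration (two-sided, probability ordering) for
  2×2; for R×2 a Monte-Carlo p conditional on the margins (Patefield
  sampling via `r2dtable`, ≥10⁴ tables, probability ordering, the +1
  correction) with its Monte-Carlo standard error reported. An exact
  network algorithm for R×2 was considered out of scope; the MC estimate is
  unbiased and its error is quantified. Genes without a TAD assignment are
  excluded and counted.
* **Gene-size bootstrap** — sample median with a percentile (2.5%, 97.5%)
  CI from 1000 resamples, seed-deterministic. The percentile variant was
  chosen as the simplest interval consistent with "bootstrap CI"; both the
  median and the mean per call class are emitted, since figure-level
  "average size" summaries are sometimes means.
* **ΔΔCq** — technical replicates averaged first, then
  $\Delta Cq = Cq_{target} - Cq_{ref}$ per condition,
  $\Delta\Delta Cq$ their difference, knockdown % $= (1 - 2^{-\Delta\Delta Cq}) \cdot 100$.

## The synthetic expression study

Planted effects are uniform in ±[0.7, 1.4] log₂ units (bracketing the
observed top fold-changes of such screens), replicate noise is i.i.d.
Gaussian with σ = 0.15, gene sizes are log-normal (sdlog 0.6) with class
medians 2.5 kb (unaffected — the average transcript size in the syncytial
embryo), 3.7 kb (up) and 1.9 kb (down), and genes map contiguously onto
1169 TADs; defaults plant 80 up- and 173 down-regulated genes among 7977.
A flag concentrates planted genes into a few TADs to exercise the
enrichment test.

One property of the defaults deserves emphasis: with four replicates,
σ = 0.15 and ~8000 genes, a plain t test (3 degrees of freedom) has limited
power at the BH threshold, so the filter recovers only the stronger ~60% of
planted effects. This is a faithful feature of small-replicate designs, not
a defect of the filter — the power-oriented tests therefore either use
σ = 0.1 with effects ≥ 1 (where recovery is complete) or assert direction
correctness and error control rather than raw counts.

# Numerical choices and degenerate inputs

* Seeds: every stochastic component takes an explicit seed and restores the
  caller's RNG state; identical seeds give bit-identical stacks and tables.
* Ring detection requires a radial peak exceeding the far-field baseline by
  5% (relative); otherwise a "no ring detected" error is thrown (e.g. ring
  amplitude zero). A ring touching the frame edge is an error, not a
  truncated measurement.
* An all-constant frame segments to an *empty* mask (not an error); an
  empty mask is an *error* for Feret and ring detection (nothing to
  measure).
* `expansion_fold` errors when the first post-wound area is zero (fold
  undefined); `find_tmax_thalf` errors when the wound never contracts to
  the requested fraction.
* Stage failures in the pipeline drivers keep partial outputs and write an
  error manifest naming the failed stage (e.g. a missing pre-wound frame
  names the unwounded-baseline stage).

# Problem sizes used by the test-suite and acceptance script

Simulated movies are 192×192 px (112×112 px in unit tests) with 57 (22)
frames; parameter recovery uses 20 movies spanning fold 1–2, closure rate
0.1–1 μm²/s and ring width 1–4 μm at 5% noise; coverage checks use ≥1000
profile positions, 200 null studies of 400 genes, and 500 bootstrap
datasets of 200 sizes. These sizes give stable estimates (Monte-Carlo
errors well inside the asserted tolerances) while keeping a full run in the
low minutes on one CPU.

# Known limitations

* Single wound per field; no drift or bleaching correction; 2D only.
* The ring-edge regions are radial (disk-shaped) constructions around the
  wound centroid; strongly non-circular rings would need contour-based
  edges.
* The plain t statistic is a stand-in, not a replacement, for moderated
  array statistics.
* The R×2 Fisher p is Monte-Carlo, with its standard error reported rather
  than eliminated.
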