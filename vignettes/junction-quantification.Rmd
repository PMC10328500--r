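---
title: "Quantifying junctional intensity, tension and actin-binding competition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying junctional intensity, tension and actin-binding competition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(junctension)
```

## The measurement problem

In compartmentalized epithelia one half of the tissue can be genetically
manipulated while the other half remains wild type, giving every image its
own internal control. The readout is then a ratio: how much does a
junctional protein's level change in the manipulated (posterior)
compartment relative to the control (anterior) one? `junctension`
implements that readout — masked, block-averaged intensity heat maps and a
per-disc posterior/anterior (P/A) ratio — together with the companion
measurements used to interpret it: ablation recoil velocity as a tension
proxy, masked Pearson colocalization, and in vitro co-sedimentation
quantification with an explicit competitive-binding model. Every stage has
a synthetic generator with known ground truth, so correctness is
established by parameter recovery, not inspection.

## Heat maps and the P/A ratio

The procedure, stage by stage:

1. **Masking.** Quantification is restricted to junctional pixels, defined
   by thresholding the reference (E-cadherin) channel. The thresholding
   rule in published pipelines of this kind is usually unstated, so three
   are exposed and recorded in the output: Otsu (default — parameter-free
   and well suited to bimodal junction/background images), percentile, and
   fixed. Connected components below 5 px are removed to suppress speckle
   (configurable). The analogous mask on thin z-stacks is 3D; on the 2D
   apical projections this package operates on, it is 2D.
2. **Block averaging.** The grid of `block_size_um` (default 3 µm,
   the conventional scale of 2–3 cell diameters) squares is anchored so
   the annotated disc center lies on a block *corner*, making the four
   center-adjacent blocks symmetric about it; `center_index` names the
   block up-and-left of the anchor. Block edges are placed at
   `floor(center + k·block_px)`; partial edge blocks are dropped, not
   rescaled. Per block the value is the mean of the channel over masked
   pixels only; a block with no masked pixels is missing (`NA`), never
   zero — zeros would drag compartment means toward zero in sparsely
   junctional regions.
3. **Normalization.** `ratio_to_reference` divides signal and reference
   maps each by its own mean over non-missing blocks and then takes the
   elementwise ratio; the result is invariant to rescaling either channel
   (acquisition gain cancels). `self_mean` divides the signal map by its
   own mean only (mean of the non-missing output is exactly 1); it answers
   a different question — redistribution of the protein rather than change
   relative to junctional material.
4. **Multi-disc averaging.** Maps are aligned on their center block,
   smaller maps are padded with missing values to the largest extent on
   each side, and each block is averaged only if at least `min_count`
   discs (default 3) contribute; otherwise it is missing. The averaged map
   is for display.
5. **P/A ratio.** Mean of non-missing posterior blocks over mean of
   non-missing anterior blocks. It is computed *per disc* and then
   summarized across discs (matching how per-disc points are plotted and
   tested in this literature); computing it on the averaged map is also
   possible but mixes discs with unequal coverage. The compartment
   boundary is the line through the annotated center; because the grid is
   corner-anchored, the line falls on a block edge and no block straddles
   it. For hand-built grids where the center sits inside a block, that
   block row/column is excluded. A per-pixel marker image (e.g. an RFP
   compartment label) may replace the geometric rule, labeling each block
   by majority vote of its (masked) pixels.

Numerical conventions are fixed and documented: pixel coordinates are
0-based, row-major, origin top-left; µm→px conversion floors block edge
positions; blocks where the reference is zero become missing and are
counted.

## What the disc generator emulates — and what it does not

`generate_disc()` builds a Voronoi tessellation (uniform seeds, one Lloyd
relaxation step to avoid sliver cells), takes the ~2-px boundary skeleton
dilated to `junction_width_px` as the junction set, and assigns channel
levels: reference `ref_level` on junctions, signal `signal_level`
(anterior) or `signal_level × posterior_multiplier` (posterior) on
junctions, `background_level` elsewhere, plus zero-truncated Gaussian
noise (cameras report nonnegative counts). Junction pixels carry the
junctional level outright rather than level-plus-background; this keeps
the ground truth exact — the masked-pixel mean ratio equals the multiplier
to machine precision in the noiseless case — at the cost of a slightly
idealized background model. Defaults describe a 40 × 40 µm field at
0.2 µm/px with ~150 cells (apical diameters around 3 µm, typical of
columnar imaginal-disc epithelia), 100 a.u. junctions over 10 a.u.
background, and 10% noise.

The generator's compartment boundary is a straight line through the field
center; real anterior/posterior boundaries are curved, which is why the
marker-based labeling route exists. Not emulated: 3D tissue curvature and
surface extraction (inputs are already apical projections), point-spread
blur, photobleaching, junctional heterogeneity such as vertex-enriched
puncta (supported nowhere in the model because no quantitative description
was available to parameterize it). A green recovery test therefore
establishes that the pipeline measures what the model puts in — not that
it is robust to every artifact of real microscopy.

## Recoil velocity

Post-ablation vertex separation is modeled as
$L(t) = L_0 + A\,(1 - e^{-t/\tau}) + \varepsilon$, the saturating recoil
of a viscoelastic cortex, sampled every 0.2 s. The tension proxy is the
initial recoil velocity over the first second: by default the *endpoint*
estimate — separation at the last frame with $t \le 1$ s minus separation
at the cut, over elapsed time — with a least-squares slope
(`linear_fit`) as robustness check; the two agree within 2% when
$\tau \gg$ window. The endpoint reading of "displacement over the first
second" was chosen over interpolation to exactly 1 s because it only uses
observed frames; with 0.2 s sampling the last frame *is* t = 1 s and the
distinction vanishes. Anterior/posterior comparison uses Student's t
(pooled variance, the conventional report; Welch behind a flag) and the
posterior/anterior mean ratio as effect size. Kelvin–Voigt parameter
inference is deliberately out of scope — only the initial velocity is
reported.

## Colocalization

Pearson correlation of two channels over the junction mask. Masked, not
full-frame, by default: full-frame correlation on junctional images is
dominated by the shared junction/background contrast and overstates
colocalization; a `full_frame` flag restores it for comparison. Perfectly
collinear inputs report exactly ±1 (a numerical guard snaps |r| within
1e-14 of 1). No Manders coefficients or Costes randomization — Pearson is
the score this kind of study reports. Published r values from original
microscopy data are context for magnitude, not reproduction targets.

## Co-sedimentation and competition

Bound ligand under single-site binding with ligand depletion is the
physical root of $b^2 - (L+S+K)b + LS = 0$, evaluated in the stable form
$b = 2LS/\big((L+S+K) + \sqrt{(L+S+K)^2 - 4LS}\big)$ (no cancellation for
weak binding). Two ligands sharing one site class (the minimal model when
two proteins have overlapping, mutually exclusive footprints on F-actin)
are solved by a bounded scalar root on the free-site concentration — the
left side of $F + \frac{L_A F}{K_A+F} + \frac{L_B F}{K_B+F} = S$ is
strictly increasing, so the root is unique — followed by a short Newton
polish to hold site conservation below 1e-9 µM. Cooperativity and
autoinhibited-conformation states (which would raise the effective
myosin $K_D$ far above the micromolar range) are documented limitations,
not parameters.

Fraction bound is expressed per titrated protein, matching how
co-sedimentation quantifications are plotted. $K_d$ fitting is
least-squares under the depletion model, multi-started over a log-spaced
$K_d$ grid ($10^{-3}$–$10^{3}$ µM) because the objective flattens for
tight binding; a fit at the grid edge is flagged `at_boundary` — a
stoichiometric titration cannot identify $K_d$, only the site count.

The gel generator draws two Gaussian bands per lane (supernatant ∝ free,
pellet ∝ bound) whose *discrete trapezoid* areas equal the model
concentrations exactly, so band-area conservation holds to machine
precision before noise; noise is multiplicative log-normal, the usual
densitometry behavior. Default titration spans the 0–12 µM range over
2 µM sites. A lane with zero tracked ligand carries no signal and its
bound fraction is undefined (0/0); the direct-titration default therefore
starts at the lowest nonzero point, while competition-style runs (tracked
ligand constant, competitor titrated from zero) quantify every lane.

## Group statistics

`summarize_groups()` reports mean ± t-based 95% CI. `compare_groups()`
covers the three designs this literature uses: Student's t for two
groups, one-way ANOVA with Dunnett adjustment against a named control,
and Tukey HSD for all pairs (via `ptukey`). Dunnett-adjusted p-values are
computed exactly: conditioning on the control-group deviate and on the
pooled SD reduces $P(\max_j |T_j| \ge t)$ to a product of normal CDFs
under a two-dimensional numerical integral. No multivariate-t package is
required; a seeded Monte-Carlo max-|t| sampler is retained as an
alternative route and doubles as the independent oracle in the test
suite. Adjusted p-values are clamped to be at least the raw ones.

## Design choices that were genuinely open

- **Center anchoring**: "starting from the center" admits either
  center-of-block or corner-of-block anchoring; corner anchoring was
  chosen so the four center-adjacent blocks are symmetric and the
  compartment line never splits a block.
- **Per-disc vs averaged-map P/A**: both implemented; per-disc is the
  default because per-disc points are what gets plotted and tested.
- **Unmasked pixels in block means**: excluded (blocks are means over
  masked pixels only); including them as zeros would bias compartment
  means by local junction density.
- **Zero-ligand lanes**: see above; undefined rather than imputed.
- **Whether P/A ratios are tested against 1.0 or between genotypes**:
  both supported (`compare_groups` two-sample, or a one-sample t via
  `summarize_groups` CIs); the caller reports which was run.

## Limitations

Synthetic validation bounds what green tests mean: the pipeline recovers
known fold-changes from the stated image model, recovers $K_d$ within
stated tolerance from the stated noise model, and matches independent
oracles for its numerics. It does not segment junctions per cell, detect
vertices, track ablation movies, model tissue curvature, or fit binding
kinetics; inputs at those boundaries (annotated centers, separation time
series, 1D lane profiles) are taken as given.
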