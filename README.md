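# junctension

Quantification toolkit for apical-junction biology in epithelial tissues,
built around four measurements that recur whenever a genetic manipulation is
driven in one compartment of a tissue (classically the posterior compartment
of the *Drosophila* wing imaginal disc) while the other compartment serves as
internal control:

1. **Block-averaged junctional intensity heat maps** with a
   posterior/anterior (P/A) ratio statistic. A junction mask is built from an
   E-cadherin reference channel; the image is split into square blocks
   (default 3 × 3 µm²) anchored at a manually annotated disc center; per
   block the mean masked intensity is recorded; signal and reference maps are
   each normalized by their own mean and divided; maps from several discs are
   aligned on the center, NaN-padded, and averaged under a minimum-count rule
   (default 3 discs per block). The per-disc P/A ratio is
   `mean(posterior blocks) / mean(anterior blocks)`.
2. **Laser-ablation recoil velocity**, the standard junctional-tension proxy:
   vertex displacement over the first second after the cut, compared between
   anterior and posterior cuts by Student's t-test.
3. **Masked Pearson colocalization** between two channels.
4. **Co-sedimentation binding quantification**: supernatant/pellet
   densitometry, the single-site ligand-depletion equilibrium
   (`bound² − (L+S+K)·bound + L·S = 0`, physical root), two-ligand
   competition for a shared site class on F-actin, least-squares K_d fitting,
   and percent displacement by a competitor.

Every analysis stage is paired with a ground-truthed synthetic generator
(Voronoi-tessellated two-compartment epithelium images, saturating-exponential
recoil traces `L(t) = L0 + A(1 − e^{−t/τ})`, Gaussian-band gel lane profiles
driven by the equilibrium model), so the whole pipeline is validated by
parameter recovery rather than by eye. Group statistics (mean ± 95% CI,
Student's t, one-way ANOVA with Dunnett or Tukey adjustment — Dunnett by exact
numerical integration) round out the reporting.

## Worked example

```r
library(junctension)

# a 40x40 um synthetic disc: posterior junctional signal x1.5, 10% noise
d <- generate_disc(synth_disc_params(posterior_multiplier = 1.5,
                                     noise_sd_frac = 0.1, seed = 1))
ann <- disc_annotation(d$center_px, "right")        # posterior to the right
msk <- build_mask(d$image)                          # Otsu on the E-cad channel
hm  <- normalize_heatmap(block_quantify(d$image, msk, ann, "signal"),
                         block_quantify(d$image, msk, ann, "ecad"))
pa_ratio(hm, split_compartments(hm, ann))
#> P/A ratio = 1.4968 (posterior n=71, anterior n=72 blocks)

# recoil: noiseless trace recovers the closed form 2(1 - e^-2) = 1.72933
tr <- generate_recoil_trace(synth_recoil_params(amplitude_um = 2, tau_s = 0.5,
                                                noise_sd_um = 0))
recoil_velocity(tr, window_s = 1)$v_um_per_s
#> [1] 1.729329

# binding: 0-12 uM titration over 2 uM F-actin sites, Kd 5 uM, then refit
g <- generate_gel(synth_gel_params(kd_uM = 5, site_conc_uM = 2))
frac <- vapply(g$lanes, function(l) as.numeric(quantify_lane(l)), 0)
fit_binding(binding_series(g$truth$titrant_uM, frac), sites_total_uM = 2)
#> binding fit: Kd = 5 uM, sites = 2 uM, rss = 3.41e-24
```

The P/A ratio estimate (1.4968) recovers the generator's true 1.5 fold-change
from a noisy image; the recoil velocity and K_d match their analytic truths.

## Command line

```sh
inst/cli/junctension simulate disc --config cfg.json --out out/ --seed 1
inst/cli/junctension heatmap --images out/disc.json --annotations ann.json \
    --block-um 3 --min-count 3 --mode ratio --out out/hm
inst/cli/junctension recoil --traces traces.csv --window 1.0 --method endpoint
inst/cli/junctension cosed quantify --in lanes.csv --out frac.csv
inst/cli/junctension stats --values values.csv --design vs_control --control ctrl
```

Each run writes a JSON run manifest (inputs, config, seed, versions).

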