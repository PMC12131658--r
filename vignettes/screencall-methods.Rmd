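---
title: "Methods: hit calling and imaging quantification in screencall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hit calling and imaging quantification in screencall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screencall)
```

# The screening problem

Genome-wide RNAi modifier screens for alpha-synuclein (aSyn) toxicity use
differentiated dopaminergic neurons in which moderate aSyn overexpression
kills roughly half the cells. Each 384-well plate carries library wells
(one esiRNA pool per gene), a positive control (esiRNA against aSyn
itself, best attainable survival), a negative transfection control
(esiRNA against firefly luciferase, F-Luc, a sequence the cells do not
carry), and mock-transfected wells. The readout is image cytometry:
Hoechst counts all nuclei, propidium iodide (PI) marks dead cells, and a
well's survival is the fraction of nuclei without PI.

`screencall` implements the full analysis around that readout: survival
normalization, library-referenced Z-statistics, a three-tier hit cascade,
the statistical machinery those tiers need, the microscopy quantifications
used to validate hits, and synthetic-data generators that make every stage
testable with known ground truth.

# Survival Z-statistics

For well $w$ with survival $s_w$, the Z-score is
$z_w = (s_w - \bar{s}_L)/\hat\sigma_L$, where $\bar{s}_L$ and
$\hat\sigma_L$ (with the $n-1$ denominator) are taken over the *library*
wells of the normalization scope only — controls are scored against the
library distribution, never against themselves. The default scope pools
the library wells of one screening run (`scope = "per_run"`); per-plate
and global scoping are available. Published control summaries cannot
distinguish these choices, and per-run scoping guards against batch
drift while still referencing "the whole library" of a run; this is a
deliberate, documented choice rather than a derived fact.

Wells with zero nuclei carry no measurement; they are flagged by
`validate_dataset()` and excluded from all statistics rather than
raising errors, because real screens contain failed wells. Comparisons
to the hit threshold (default $z > 2.4$) are strict in both directions:
a well exactly at the threshold is a non-hit and counts toward the
below-threshold tally of the negative controls.

# The three-tier cascade

1. **Primary** (`call_primary()`): a gene is called when its per-run
   mean Z exceeds the threshold in at least `min_runs = 2` runs. Genes
   with fewer usable runs are reported uncallable, never called.
2. **Annotation filter** (`filter_annotations()`): only protein-coding
   hits proceed; pseudogenes, non-coding RNAs and unmatched reagents
   are excluded with the reason recorded.
3. **Secondary** (`call_secondary()`): candidate survivals (all
   replicate wells over three runs) are compared to the F-Luc control
   by a one-way ANOVA gate followed by Dunnett many-to-one comparisons;
   a call requires an adjusted $p < \alpha$, a positive mean shift
   (protection, not toxicity) and a passing gate.
4. **Tertiary** (`call_tertiary()`): candidates are re-screened in
   aSyn-overexpressing and GFP-expressing arms. Survival is expressed
   relative to each arm's F-Luc mean (in percent) — an inference from
   how such results are conventionally displayed, with raw-survival
   comparison behind `relative = FALSE`. Per candidate, Welch's t
   compares the arms; step-down Sidak adjustment runs across
   candidates. A final hit must be significant after adjustment *and*
   more protected under aSyn, i.e. specific to the insult.

Monotone nesting (final $\subseteq$ secondary $\subseteq$ filtered
primary) holds by construction and is asserted in the test suite.

# Statistical procedures

All procedures the cascade uses are implemented in the package.

* **Dunnett comparisons.** With treatments $i = 1..k$ sharing a control,
  $T_i = (\bar{x}_i - \bar{x}_0)/(s_p\sqrt{1/n_i + 1/n_0})$ and the
  two-sided adjusted p-value is $P(\max_j |T_j| \ge |t_i|)$ under the
  joint multivariate t with $\rho_{ij} = \lambda_i\lambda_j$,
  $\lambda_i = \sqrt{n_i/(n_i+n_0)}$. The CDF is evaluated by the
  one-factor reduction: conditional on the pooled-SD variate (scaled
  chi, integrated by Gauss–Legendre on the probability scale through
  its quantile function) and the shared control variate (Gauss–Hermite),
  the components are independent and the integrand is a product of
  normal probabilities. Node counts double until successive evaluations
  agree below `tol` (default $10^{-7}$ successive-difference, well
  inside the $10^{-6}$ design tolerance); p-values are therefore
  deterministic. Monte-Carlo evaluation exists only as an independent
  oracle in the tests. Sidedness is two-sided with a post-hoc direction
  filter in `call_secondary()` — the conservative reading when only
  "significantly better survival" is reported. A single comparison is
  exactly the pooled t-test and is returned as such.
* **Tukey HSD** uses the classical studentized-range double integral
  with the same quadrature scheme, and the Tukey–Kramer harmonic form
  for unbalanced pairs; $k = 2$ reduces exactly to the pooled t-test
  (the $q = |t|\sqrt{2}$ identity).
* **Welch t** with Satterthwaite df; degenerate zero-variance inputs
  return flagged boundary values rather than NaNs.
* **Step-down Sidak (Holm-Sidak)** is the default tertiary correction:
  the tool conventionally used for "multiple T-tests" applies it by
  default, but the original description does not name the method, so
  this is a documented assumption with Bonferroni–Holm behind a flag.
* **D'Agostino–Pearson** $K^2$ combines the standard skewness and
  kurtosis normalizing transforms; it requires $n \ge 8$.
* The ANOVA F p-value is computed through the regularized incomplete
  beta function (`pbeta`).

# Synthetic screens

`generate_screen()` models death on the logit scale:
$p_\text{death} = \mathrm{logit}^{-1}(\mathrm{logit}(d_0) - e + r + p + \varepsilon)$
with baseline death $d_0 = 0.5$, gene/control effect $e$, run and plate
offsets, and well noise; nuclei are Poisson (mean 1500) and PI-positive
counts Binomial — the counting readout's natural model. One integer
seed drives everything; per-plate substreams make output independent of
generation order, and identical config + seed is bit-identical.

No noise decomposition is published, so the constants are *calibrated*:
control effect distributions (aSyn $\mathcal{N}(1.23, 0.70)$, F-Luc
$\mathcal{N}(0.385, 0.24)$, mock $\mathcal{N}(-0.127, 0.10)$ on the
logit scale) and noise SDs (well 0.30, plate 0.05, run 0.05) were fit
once against the published control Z summaries ($3.3 \pm 1.8$,
$1.2 \pm 1.2$, $-0.4 \pm 1.0$) at full library scale (16,744 genes,
two runs) and frozen. Run-level noise is kept small because per-run
standardization is designed to absorb it and the published control SDs
bound the total dispersion. The calibration check runs at full scale:
with ~770 positive-control wells the Monte-Carlo error of a class mean
(~0.07) sits well inside the 0.2 comparison band, which a 1,000-gene
screen (48 control wells) could not guarantee. Planted protectors draw
effects uniformly from (1.2, 1.8), bracketing the calibrated positive
control. The published library size appears as both 16,744 and 16,774
in different places; `n_genes` is simply a parameter.

What the generator does *not* emulate: spatial plate artifacts
(edge effects, gradients — no B-score correction exists here, by
design), reagent-specific off-target structure, and real annotation
biology (biotypes are sampled). Passing closed-loop tests therefore
demonstrates the *pipeline's* correctness on data obeying its model,
not robustness to artifacts the model omits.

# Imaging metrics

* **Otsu threshold**: 256 histogram bins spanning the value range,
  maximizing between-class variance; the chosen bin's upper edge is
  returned so foreground is strictly above threshold. "Automatic"
  thresholding in the motivating workflow is unnamed; Otsu is the
  package's choice, and Costes-style thresholding is out of scope.
* **Thresholded Manders** $M1_t$: fraction of channel-A intensity above
  A's threshold lying where channel B exceeds B's threshold ($M2_t$
  symmetric); invariant to positive rescaling of either channel.
* **Line profiles** are sampled by bilinear interpolation at unit-pixel
  steps, averaged across the ROI width. `inside_fraction()` subtracts
  the profile minimum as background (a documented choice, switchable
  off), integrates trapezoidally with the interval endpoints inserted
  into the grid, and returns AUC-in over total AUC. Per-cell work
  conventionally averages four ROI lines; condition summaries should
  pool at least 50 cells. The in/out boundary is an explicit input —
  in the motivating assay it is a visually drawn compartment margin.
* **TGN morphology**: Otsu segmentation, 8-connected components; the
  principal component passes the *ring test* when it encloses a
  background hole of at least `min_hole_px = 20` pixels (background
  labeled 4-connected; hole components touch the ring but not the
  border). Ring present and satellites < 10% of foreground area:
  `normal`; ring with satellites $\ge$ 10%: `scattered`; no ring:
  `fragmented`. `min_hole_px` and `sat_frac` are free constants of this
  package, chosen to separate the generator's archetypes. The diameter
  is the maximum Feret diameter of the foreground union (normal and
  scattered only); whether a Feret or profile-based diameter was used
  originally is not stated.
* **Neurite metrics**: Otsu binarization, removal of components below
  16 px (noise at any realistic neurite scale), Zhang–Suen thinning to
  a 1-px skeleton. Length sums orthogonal steps at the pixel size and
  diagonal steps at $\sqrt{2}\times$, skipping diagonal pairs bridged
  by an orthogonal skeleton pixel (counting both sides of such a
  triangle would double the path); this step rule is rotation-robust,
  unlike raw pixel counts. Junction pixels ($\ge 3$ skeleton
  neighbors) are clustered by adjacency; a cluster is a *quadruple
  point* iff exactly four branches leave it — clusters with five or
  more branches are counted separately, a deliberate convention where
  the source is silent.
* **Nuclear signal / LDH**: per-nucleus mean intensity inside label
  masks with reference-condition normalization; LDH release as the OLS
  decline rate of NADH absorbance at 340 nm with relative cytotoxicity
  against a reference rate.

## Synthetic images

Generators render TGN archetypes (annulus; dim annulus plus satellite
blobs; blobs only) with Gaussian blur and Poisson photon noise; channel
pairs with an exactly planted above-background overlap fraction;
dilated polylines with optional isolated X-crossings; and disk nuclei
with planted mean signals. Free line ends are extended before
rasterization by up to half-width + 2 px (scaled by direction, zero for
diagonal tips) because thinning erodes flat line ends by that amount —
with the cap, the planted skeleton length equals the geometric polyline
length. A blank canvas stays blank (noise models acquisition noise on a
specimen), keeping the empty case well defined for auto-thresholding.

# Numerical and design notes

* Rates are reported to two decimals; the publication-comparison view
  rounds half away from zero to integer percent.
* Quadrature refinement starts at 32 Gauss nodes per axis (16 when the
  caller requests simulation-grade tolerance $\ge 10^{-4}$) and doubles
  at most three times.
* Degenerate inputs (zero variances, empty masks, constant images,
  empty profiles) return flagged values or named errors, as listed in
  each function's documentation.
* Pipeline configs are YAML: a robust parser is available and YAML is
  the de-facto standard for pipeline configuration in this ecosystem.
* Problem sizes in the test suite are the package's choices: FWER
  simulations use 500 replicates of a 1,000-gene, 3-run null screen
  (bounding the family-wise error by $0.05 + 2\sqrt{0.05\cdot0.95/500}$);
  statistical oracles use $2\times10^6$–$10^7$ Monte-Carlo draws;
  archetype classification is checked across 100 seeds.

# Known limitations

* The cascade assumes the well-table readout is already segmented and
  counted; no screen-scale image-to-count segmentation is included.
* No spatial normalization (B-score/median polish) — a possible
  extension, deliberately not part of the analysis.
* The Dunnett/Tukey quadrature targets small-to-moderate $k$ at high
  accuracy and large $k$ at simulation accuracy; extremely large
  families with highly unbalanced designs increase runtime through the
  per-unique-size product terms.
* Tertiary specificity inherits Welch-t small-sample behavior when only
  2–3 replicate wells per arm are available.
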