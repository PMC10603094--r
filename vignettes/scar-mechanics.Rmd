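---
title: "Quantifying the mechanics and proteome of CNS lesion sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the mechanics and proteome of CNS lesion sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scarmech)
```

`scarmech` bundles the quantitative analyses used in multimodal studies of
spinal cord lesion sites — label-free proteomics of the injury extracellular
matrix (ECM), Brillouin microscopy of tissue compressibility, cross-polarized
OCT of tissue structure, AFM nanoindentation of tissue viscoelasticity, and
the per-animal statistics layer that ties them together. Every input modality
has a seeded synthetic generator, so the full pipeline runs and is tested
without access to primary imaging or mass-spectrometry data. This vignette
explains the models, the defaults, and the design choices.

## Differential protein abundance with permutation FDR

Label-free quantification (LFQ) intensities arrive as a proteinGroups-style
table, are log2-transformed, and zeros become missing values
(`load_protein_groups()`). Quality filtering removes reverse-database hits,
contaminants, and proteins only identified by site. The valid-value rule then
keeps a protein only if it is quantified in every sample — with one
deliberate exception: proteins fully missing in exactly one condition and
fully quantified in the other are retained and flagged as *presence/absence*
proteins. These are exactly the biologically interesting cases (e.g. a
protein undetectable in uninjured tissue but abundant after injury), and
dropping them would censor the strongest effects. Their missing side is
imputed from a down-shifted normal distribution per sample
(mean − 1.8·SD, width 0.3·SD, the Perseus-style convention) with a seeded
RNG, because a moderated t-statistic needs finite values on both sides. A
`"strict"` mode (drop any row with any missing value) is provided for
overexpression-style comparisons where absence calls are not wanted.

Testing uses the s0-moderated statistic
$t_{s_0} = (\bar{x}_B - \bar{x}_A)/(s + s_0)$ with $s$ the pooled two-sample
standard error and $s_0 = 0.1$ by default; $s_0$ damps the spuriously large
statistics of near-zero-variance proteins while leaving $t_{s_0} = t$ at
$s_0 = 0$ (an identity the suite checks to 1e−12). Significance is assessed
by label permutation: all distinct balanced splits are enumerated when few
(20 for a 3-vs-3 design), otherwise a seeded random subset is drawn. For a
threshold placed at each observed $|t_{s_0}|$, the estimated FDR is the
summarized permutation call count divided by the observed call count, and a
protein's q-value is the smallest FDR at which it would be called.

Two details of the FDR estimator were decided empirically:

* **The observed labeling (and, in balanced designs, its mirror) is excluded
  from the permutation null.** Both reproduce the observed statistics
  exactly; keeping them either destroys power (mean summary: the top protein
  can never clear an FDR below 2/20) or contributes nothing (median).
* **The call count is summarized by its mean, not the median.** On small
  balanced designs the median of 18 integer counts is very often zero at the
  top thresholds, which makes the estimator markedly anticonservative: on
  all-null simulated tables (1000 proteins, 3 vs 3) the median variant makes
  at least one call in roughly half the runs, the mean variant in roughly a
  fifth — consistent with the irreducible 1/10 floor set by the ten
  distinct split classes of a 3-vs-3 design. The median variant remains
  available via `estimator = "median"` for comparability.

Calls are classified by `classify_regulation()`: *up* requires significance
and log2FC ≥ log2(1.3). The 1.3 threshold is stated on the linear scale but
applied on the log2 scale, the standard convention for log-transformed LFQ
data. Downstream, `annotate_matrisome()` joins a user-supplied matrisome
list (division, category, mammalian ortholog), `zscore_rows()` standardizes
rows for heatmaps, `cross_species_screen()` buckets ortholog pairs into
discordant/concordant regulation classes, and `ora_enrichment()` performs
hypergeometric over-representation tests with Bonferroni correction — a
deliberately exact and reproducible replacement for web-service enrichment
tools, which use proprietary multiple-testing corrections.

## Brillouin shift to longitudinal modulus

The Brillouin frequency shift of backscattered light,
$$\nu_B = \frac{2 n \sqrt{M'}}{\lambda_0 \sqrt{\rho}} \sin\frac{\vartheta}{2},$$
links the measured shift (GHz) to the longitudinal modulus $M'$ through the
refractive index $n$ and mass density $\rho$ of the tissue in the focal
volume. All defaults correspond to the backscattering configuration:
$\lambda_0 = 780.24$ nm, $\vartheta = 180°$ so $\sin(\vartheta/2) = 1$.
`longitudinal_modulus()` inverts the relation,
$M' = \rho\,(\nu_B \lambda_0 / 2n)^2$, and attaches the longitudinal
compressibility $\kappa_L = 1/M'$ (exactly reciprocal, by construction).

Density is not measured directly; it comes from the refractive index via a
two-component (fluid + dry mass) model: the dry-mass concentration is
$c = (n - n_f)/\alpha$ and the absolute density
$\rho = \rho_f + (1 - \theta \rho_f)\,c$. Here $\alpha = 0.1919$ mL/g is
the refractive-index increment of proteins and nucleic acids,
$\theta = 0.73$ mL/g the canonical partial specific volume of protein dry
mass, and the fluid phase is water-like ($\rho_f = 1000$ kg/m³). The fluid
refractive index, $n_f = 1.340298$, was fixed by a one-time least-squares
calibration (`tools/calibrate-density-model.R`) requiring four independently
measured (shift, refractive index) → modulus condition means from lesion
tissue to be reproduced jointly; they agree to better than 0.01%, well
inside the 0.5% consistency band the acceptance suite enforces. This joint
reproduction over-determines the model and is the package's primary numeric
cross-check.

Measurement uncertainty propagates to the modulus by first-order Gaussian
propagation with analytic partial derivatives over all six inputs
($\nu_B$, $n$, $\alpha$, $\theta$, $n_f$, $\rho_f$);
`propagate_uncertainty()` returns the per-input variance budget and an
optional seeded Monte-Carlo cross-check. For input coefficients of
variation at or below 1% the analytic and 10⁶-draw Monte-Carlo estimates
agree within 2% (acceptance suite); beyond that the first-order
approximation degrades, which is a known limitation.

ROI statistics follow the study convention: a 40 × 20 µm rectangle placed
over the lesion center, ventral edge 5 µm dorsal to the notochord landmark
(`roi_from_notochord()`), on maps with 0.5 µm step size. A pixel belongs to
the ROI iff its *center* lies in the closed rectangle — an unambiguous rule
that is stable under sub-pixel grid shifts. Invalid (`NA`) pixels are
excluded from the mean and counted; no saturation or low-SNR exclusion
rule is applied beyond the validity mask — flagging such pixels `NA`
upstream is the caller's responsibility.

## CP-OCT reflectivity and co-polarization ratio

From co-registered co- and cross-polarized amplitude stacks,
$R = \sqrt{A_{co}^2 + A_{cross}^2}$ and
$\delta = A_{co}/(A_{co} + A_{cross})$, computed on the averaged intensity
projection of the stack ("project first"; a
per-slice-then-project option exists). $\delta$ is bounded in [0, 1];
pixels with zero total amplitude are masked invalid. Formulas operate on
amplitudes as given, without log compression — the amplitude-vs-intensity
ambiguity of the quantification is resolved in favor of amplitudes, which
is what the defining equations use. `mean_threshold_area()` reproduces the
automated mean-grey-level binarization of fluorescence images; foreground
is *strictly greater* than the ROI mean, so a uniform image
deterministically yields zero foreground (ImageJ-style mean thresholding
leaves the tie case unspecified).

## AFM force-indentation fitting

Force curves are fitted with two contact models, both with the contact
point and a baseline force offset as free parameters:

* **Hertz sphere** — $F = \frac{4}{3}\frac{E}{1-\nu^2}\sqrt{R}\,\delta^{3/2}$,
  restricted to indentation depths ≤ 3 µm past the fitted contact point
  (the validity limit used for this tissue), with $\nu = 0.5$
  (incompressible) and $R = 18.5$ µm (a 37 µm polystyrene bead) by default.
* **Kelvin–Voigt–Maxwell (KVM)** — the package's constant-speed approach
  solution for Hertzian sphere geometry with a viscous element,
  $$F = \frac{4\sqrt{R}}{3(1-\nu^2)}\Big(E\,\delta^{3/2} +
  \tfrac{3}{2}\,\eta\,v\,\delta^{1/2}\Big),$$
  where $v$ is the approach speed (7 µm/s default). It yields the apparent
  Young's modulus $E$ and apparent viscosity $\eta$ and reduces exactly to
  the Hertz law as $\eta \to 0$. Published viscoelastic indentation models
  differ in minor variants of this form; the synthetic generator and the
  fitter share one explicit forward model, so parameter-recovery tests
  close the loop exactly. Only the constant-speed approach segment is
  modelled — dwell and retract are out of scope.

Both fits exploit that, for a fixed contact point, the model is *linear* in
(baseline, $E$[, $\eta$]): the fit profiles the residual sum of squares over
a 120-point contact-point grid, refines the minimum by golden-section
search, and solves the conditional linear least-squares problem exactly.
This is equivalent to bounded nonlinear least squares with multi-start over
the contact point, but with no convergence failures by construction.
Negative-viscosity solutions are rejected and refitted in the elastic limit
(flagged `eta_clamped`). Standard errors are conditional on the fitted
contact point, with design columns rescaled to unit norm before inversion
(the raw normal matrix mixes scales of 1 and ~1e−10 and is numerically
singular). `contact_point_estimate()` adds a profile-curvature confidence
interval and rejects curves whose modulus is not resolved above noise
(E/SE < 3) or whose pre-contact baseline covers less than 5% of samples.

## Effect sizes and the boundary decision rule

All per-animal comparisons pass through a Shapiro–Wilk gate at 0.05 per
group: Student's t (paired when pairing ids exist) if all groups pass,
Mann–Whitney otherwise, and Kruskal–Wallis followed by Dunn's tie-corrected
multiple comparisons (Bonferroni over the performed family) for more than
two groups. Exact Mann–Whitney p-values are used for tie-free samples and
are checked against full enumeration for n ≤ 8 per group. The Dunn family
defaults to all pairs, with an all-vs-control option for designs where
every treatment is compared to one reference group.

Effect sizes accompany every test: Cohen's d (pooled SD, classical
definition; Hedges' correction available) with its asymptotic standard
error, and the common-language effect size
$\theta = P(a > b) + \frac{1}{2}P(a = b)$ with a DeLong-style
placement-variance standard error. The final significance decision requires
p < 0.05 *and* an effect-size criterion relative to the boundary
($d_c = 1$, $\theta_c = 0.5$). A "boundary within the
uncertainty" rule admits two readings; the default (`rule = "exclude"`)
treats a boundary inside the estimate ± uncertainty interval as
disqualifying, the alternative (`rule = "beyond"`) only asks the point
estimate to lie beyond the boundary. Both are implemented; the choice is
a flag, not a constant.

## What the synthetic generators emulate — and what they do not

`simulation_spec()` fixes the study conditions once: 3 replicates per
condition, 5% regulated proteins at |log2FC| = 2, MNAR dropout below a
soft threshold 1.8 SD under the sample mean (width 0.3 SD), imaging grids
at 0.5 µm step with lesion/background Brillouin shifts of 5.324/5.40 GHz
and refractive indices 1.3636/1.3680, CP-OCT ratio 0.709, and AFM truth
E = 500 Pa at 0.1 nN force noise, 500 samples per approach at 7 µm/s to a
12 nN setpoint. Each generator draws from its own RNG stream derived from
the master seed by stable sub-seeding, so outputs are byte-identical given
a spec and adding a generator never perturbs the others.

The generators reproduce the *statistical structure* the analyses assume —
log-normal abundances, abundance-dependent dropout, two-region images with
Gaussian pixel noise, ideal contact-model force curves. They do not emulate
correlated replicate effects, batch structure, spatial noise correlation,
optical aberrations, cantilever drift, or adhesion. Passing the
property-based suites therefore demonstrates correctness of the estimators
under their stated models, not robustness to every artifact of real data.
Cohort-scale animal results (e.g. counts of regulated proteins in a full
deposited dataset) require primary data and are deliberately out of
scope.

## Problem sizes and numerical choices

The test and acceptance suites use 1000-protein tables with exhaustive
20-split permutation nulls (50 seeded repetitions for the null-control
property), 10⁶ Monte-Carlo draws for the uncertainty cross-check, and 50
seeded force curves per noise condition — sizes chosen so the full suite
runs in seconds while keeping Monte-Carlo error well below the tested
tolerances. Tie-breaks and degenerate inputs are handled deterministically
throughout: constant rows are an error for Z-scores, zero-total pixels are
masked rather than divided, constant force signals raise "no contact", and
uniform images threshold to zero foreground.
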