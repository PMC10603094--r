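# scarmech

Quantitative analysis of the mechano-structural and proteomic properties of
CNS lesion sites, for researchers studying why some vertebrates regenerate
spinal axons and others scar. After spinal cord injury, fibroblast-derived
extracellular matrix (ECM) fills the lesion; its composition (e.g. small
leucine-rich proteoglycans) and its mechanics (compressibility, stiffness,
viscosity) together shape whether axons regrow. `scarmech` implements the
four quantitative arms such studies combine, plus seeded synthetic
generators for every input modality so the whole pipeline is testable
without primary data:

* **Proteomics** — s0-moderated differential abundance of label-free (LFQ)
  intensity tables with SAM-style permutation FDR
  (t_s0 = Δmean / (s + s0), s0 = 0.1, FDR < 0.1, |FC| ≥ 1.3), the
  presence/absence valid-value rule with down-shifted imputation, matrisome
  annotation, row Z-scores, a cross-species regulation screen, and
  hypergeometric over-representation tests with Bonferroni correction.
* **Brillouin mechanics** — conversion of Brillouin frequency-shift maps to
  longitudinal modulus via ν_B = 2n√M′/(λ0√ρ)·sin(ϑ/2), with mass density
  from a two-component refractive-index model
  (c = (n−n_f)/α, ρ = ρ_f + (1−θρ_f)c) and full first-order Gaussian
  uncertainty propagation with a Monte-Carlo cross-check.
* **CP-OCT structure** — reflectivity R = √(A_co² + A_cross²) and
  co-polarization ratio δ = A_co/(A_co+A_cross) from polarized amplitude
  stacks, ROI means, and mean-threshold area quantification.
* **AFM viscoelasticity** — Hertz sphere fits
  (F = (4/3)·E/(1−ν²)·√R·δ^{3/2}, 3 µm indentation limit) and
  Kelvin–Voigt–Maxwell fits returning apparent Young's modulus and
  apparent viscosity, with free contact point and baseline.
* **Group statistics** — Shapiro–Wilk-gated test selection, exact
  Mann–Whitney, Kruskal–Wallis + Dunn, Cohen's d and common-language effect
  size θ with uncertainties and the boundary decision rule (d_c = 1,
  θ_c = 0.5), percent change, and ΔΔCt fold changes.

## Worked example

```r
library(scarmech)

# --- proteomics on a synthetic lesioned-vs-control table -------------------
spec <- simulation_spec(seed = 7)        # 1000 proteins, 3 vs 3, 5% regulated
lfq <- generate_lfq_table(spec)
lfq
#> Abundance matrix: 1000 proteins x 6 samples (control n=3, lesioned n=3)
#>   4.2% missing; flags: 5 reverse, 7 contaminant, 8 only-site

res <- diff_abundance(lfq, seed = 7)     # filter -> permutation FDR -> classes
table(res$class)
#>   up down   ns
#>   25   23  848

# --- Brillouin shift to longitudinal modulus -------------------------------
u <- propagate_uncertainty(5.324, 1.3636, sigma_nu_B = 0.004, sigma_n = 0.0005)
sprintf("M' = %.3f +/- %.3f GPa", u$M_prime, u$sigma_M)
#> [1] "M' = 2.396 +/- 0.004 GPa"

# --- KVM fit of a synthetic viscoelastic indentation curve -----------------
cv <- generate_force_curve(simulation_spec(seed = 7, E_true_Pa = 500,
                                           eta_true_Pa_s = 3))
kvm_fit(cv)
#> KVM fit: E = 498.0 Pa (SE 1.7), eta = 3.54 Pa.s (SE 0.26)
#>   contact point 2.006 um, n = 500, RSS 4.97e-18
```

The differential-abundance run makes 48 calls at FDR < 0.1, of which 41
are truly regulated by construction (the generator spiked 50 proteins;
some fall to QC filtering or dropout) — an empirical false-discovery
proportion of 15%, in line with the nominal 10% target for a single
3-vs-3 table. The modulus line converts a measured shift of 5.324 GHz and
refractive index 1.3636 into M′ = 2.396 GPa at 1032.8 kg/m³ tissue
density; the uncertainty is dominated by the shift measurement. The KVM
fit recovers the elastic modulus to well under 1% at the default 0.1 nN
force noise; the apparent viscosity is intrinsically noisier (here 3.54
vs a truth of 3 Pa·s from a single curve) and is best reported as a
median over replicate curves.

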