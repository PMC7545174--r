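# fibrilmech

Post-processing toolkit for steered-pulling studies of fibrillin-1
calcium-binding EGF-like (cbEGF) domains — the protein domains mutated in
Marfan syndrome. It is aimed at structural bioinformaticians who have (or
want to emulate) ensembles of constant-velocity pulling work profiles and
need the downstream analysis: equilibrium free-energy profiles, force
curves, conformational stiffness, calcium-binding observables, and
mutation-cohort statistics.

The package implements four analyses around one estimator core:

* **Jarzynski free-energy reconstruction.** From nonequilibrium work
  profiles $W_i(z)$ of $n$ pulling replicates, the potential of mean force
  is

  $$\Delta G(z) = -kT \log \frac{1}{n}\sum_{i=1}^{n} e^{-W_i(z)/kT},$$

  computed with a max-shifted log-sum-exp. Force profiles are the distance
  derivative of the PMF (1 kcal/mol/Å = 69.48 pN), smoothed with a moving
  average whose extension width corresponds to a 10 ns time window at the
  protocol's pull speed. Scalar summaries: $\Delta G$ at a strain
  (`delta_g_at_strain`), windowed mean forces and the global peak
  (`summarize_forces`), integer-percent changes versus a reference
  (`report_relative_change`).

* **Conformational metrics.** Two-domain length (twice the inter-domain
  centre-of-mass distance), straightness $-(\hat u\cdot\hat v)$, and the
  apparent stiffness modulus from length fluctuations,
  $K = kT\,L / \langle (L_0 - L)^2\rangle$, in pN; Welch/pooled t-tests and
  a symmetric two-sided F-test for the standard comparisons.

* **Calcium-binding observables.** Calcium–oxygen contacts under a strict
  4.0 Å cutoff, single-atom Shrake–Rupley SASA on a deterministic Fibonacci
  lattice (isolated calcium ion: 105.7 Å² = 100%), and work-weighted
  ensemble averaging with the Jarzynski weights
  $w_i \propto e^{-W_i/kT}$.

* **Mutation-cohort statistics.** Keyword filtering of disease labels into
  neonatal (nMFS) and classical (cMFS) Marfan cohorts, domain assignment,
  classification into calcium-binding / disulfide-cysteine (bonds C1–C3,
  C2–C4, C5–C6) / other residues, percentages with binomial standard
  errors, and 2×2 chi-squared comparisons.

A synthetic steered-Langevin generator (overdamped dynamics in analytically
solvable potentials), a toy two-domain bead structure with a bound calcium
ion, and a synthetic mutation-cohort generator supply every input, so the
pipeline runs and is tested without MD output, PDB downloads or database
access.

## Worked example

Reconstruct the PMF of a harmonic toy system (stiffness 1 kcal/mol/Å²,
analytic endpoint ½·κ·z² = 12.5 kcal/mol) from 100 noisy pulling replicates:

```r
library(fibrilmech)

pot <- potential_spec("harmonic", stiffness = 1)
pr  <- steering_protocol(spring_constant = 100, pull_speed = 0.1,
                         total_distance = 5, output_interval = 2.5)
cfg <- langevin_config(temperature = 300, timestep = 0.005, seed = 42,
                       n_replicates = 100)

ens <- generate_work_ensemble(pot, pr, cfg, l_ref = 10)
pmf <- jarzynski_pmf(ens)
tail(pmf, 3)
#> # A tibble: 3 × 3
#>   extension strain delta_g
#>       <dbl>  <dbl>   <dbl>
#> 1      4.5    45      9.99
#> 2      4.75   47.5   11.1
#> 3      5      50     12.4

delta_g_at_strain(pmf, 50)
#> [1] 12.3581
```

The estimate lands within 0.15 kcal/mol (a quarter of kT) of the analytic
12.5, the residual being the stiff-spring offset plus estimator noise. The
endpoint-work histogram and the smoothed force summaries:

```r
glance(fit_deltag_histogram(ens, strain = 50))
#> # A tibble: 1 × 4
#>       n strain  mean    sd
#>   <int>  <dbl> <dbl> <dbl>
#> 1   100     50  12.8 0.703

force <- force_profile(pmf, window = 1)
summarize_forces(force, windows = list(c(0, 20), c(20, 50)))$windows
#> # A tibble: 2 × 5
#>      lo    hi mean_pn sd_pn     n
#>   <dbl> <dbl>   <dbl> <dbl> <int>
#> 1     0    20    62.5  34.7     8
#> 2    20    50   210.   41.0    12
```

The mean endpoint work (12.8) sits above the free energy (12.4) — the
dissipation the exponential average removes. Percent-change reporting uses
the integer convention of the study summaries, e.g. a calcium-free
ΔG₅₀ of 36 kcal/mol against the calcium-bound 51 kcal/mol:

```r
report_relative_change(51, 36)
#> [1] 29
```

`autoplot()` methods exist for work ensembles, PMF and force profiles and
cohort summaries; `tidy()`/`glance()` for the fitted objects;
`run_pipeline()` chains generation → PMF → forces → observables (→ mutation
statistics) with full seed provenance.

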