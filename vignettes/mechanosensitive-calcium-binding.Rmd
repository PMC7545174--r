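---
title: "Methods: pulling free energies, stiffness and mutation statistics for cbEGF domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pulling free energies, stiffness and mutation statistics for cbEGF domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(fibrilmech)
library(dplyr)
```

fibrilmech post-processes constant-velocity pulling experiments on tandem
calcium-binding EGF-like (cbEGF) domain pairs of fibrillin-1, the
extracellular-matrix protein mutated in Marfan syndrome. The package covers
four analyses that in the original workflow sit downstream of large
molecular-dynamics engines and a clinical mutation database: free-energy
reconstruction from nonequilibrium work, equilibrium conformational metrics,
mechanosensitive calcium-binding observables, and mutation-cohort
classification statistics. A steered-Langevin generator with analytically
known free-energy profiles supplies every input, so the whole pipeline is
testable at desk scale.

## The synthetic pulling model

The generator replaces all-atom dynamics with a single overdamped (Brownian)
degree of freedom $x$ in a chosen potential $V(x)$, pulled by a harmonic
steering spring of stiffness $k_s$ whose centre moves at constant speed $v$:

$$dx = \frac{-V'(x) + k_s\,(z(t) - x)}{\gamma}\,dt
      + \sqrt{\tfrac{2 k T\,dt}{\gamma}}\,\xi, \qquad z(t) = x_0 + v t.$$

Euler–Maruyama integration is used, with the documented stability bound
`timestep * (k_s + max|V''|) / friction <= 1` enforced at simulation entry.
External work accumulates with the left-endpoint rule
$dW = k_s\,v\,(z - x)\,dt$, and the analytic comparisons in the tests use the
same convention. Two consequences of the overdamped limit are worth stating
plainly:

* Dissipation never vanishes at finite speed: even in a flat potential the
  spring performs drag work $\gamma v z$, exactly reproduced by the
  integrator. "Zero work against no opposing force" is recovered only in the
  quasi-static limit $v \to 0$, and that is how the property is tested.
* In the stiff-spring regime the reconstructed free energy is that of the
  combined particle-plus-trap system,
  $\tfrac12\,\kappa k_s/(\kappa + k_s)\,z^2$ for a harmonic potential of
  stiffness $\kappa$ — within 1% of $\tfrac12 \kappa z^2$ once
  $k_s \ge 100\,\kappa$.

Replicate seeds are derived as `master_seed + replicate`, so ensembles are
bit-reproducible and any single replicate can be regenerated in isolation.
Inertial dynamics, explicit solvent and force fields are deliberately out of
scope: the generator's purpose is to preserve the *statistics* of
nonequilibrium work that the estimators consume, not molecular detail.

The protocol defaults are the study conditions of the domain-pair system: a
7.4 kcal/mol/Å² spring pulled at 0.1 Å/ns over 30 Å (0–50% strain against
the ~60 Å calcium-bound equilibrium length), 300 K, 100 replicates, and a
100 kcal/mol/Å² terminal restraint recorded in metadata. The original
restraint length is quoted inconsistently in the source material (a "56 nm"
figure that is presumably 56 Å, and differs from the measured 59.60 Å mean
length), so the strain reference `l_ref` is an explicit parameter defaulting
to 60 Å rather than a hard-coded constant.

## Jarzynski reconstruction and force profiles

`jarzynski_pmf()` estimates the potential of mean force grid point by grid
point from $n$ work profiles $W_i(z)$:

$$\Delta G(z) = -kT \,\log \frac{1}{n} \sum_i e^{-W_i(z)/kT},$$

evaluated as a max-shifted log-sum-exp so that works of thousands of $kT$
neither overflow nor collapse the average; a single astronomically
dissipative replicate changes the estimate only through the $1/n$
normalisation ($kT \ln\frac{n+1}{n}$), which the tests assert. The estimator
is exactly zero at zero extension, invariant under replicate permutation,
equal to the single profile at $n = 1$, and bounded above by the mean work
everywhere (Jensen's inequality) — each a tested invariant. `kT` at 300 K is
anchored to 0.5962 kcal/mol and 1 kcal/mol/Å = 69.48 pN; both live in
`mech_constants`.

Force profiles are the distance derivative of the PMF: the PMF is smoothed
with a centred moving average, differentiated by central finite differences,
converted to pN, and smoothed once more with the same window. The
time-domain smoothing window of 10 ns is converted to an extension window of
`pull_speed * 10 ns` (1 Å at 0.1 Å/ns) because profiles here are functions
of extension; whether the original display smoothed once or twice is not
recoverable, so smoothing twice with one window is this package's fixed
choice. Windowed summaries (`summarize_forces()`) use half-open strain
windows $[lo, hi)$, and `report_relative_change()` rounds
$100\,(\mathrm{ref} - \mathrm{cmp})/\mathrm{ref}$ to integer percent,
positive meaning a decrease — the printed convention of the summaries it
reproduces.

`fit_deltag_histogram()` reports per-replicate endpoint works with a normal
moment fit (mean, sample SD). These are raw endpoint works, not jackknifed
estimator replicates; the source material does not say which entered its
histograms, and the raw works are the more elementary, clearly labelled
choice.

## Conformational metrics

Length is twice the distance between the mass-weighted centres of mass of
the two domains (free termini are not used). Straightness is
$-(\hat u \cdot \hat v)$ for unit vectors from the combined centre of mass
to each domain's centre. The combined centre is taken over the *whole
frame*: the union of exactly two domains has its centre of mass on the
segment joining the two sub-centres, which would make the metric identically
+1; bound ions and other particles shift it off-axis and make the metric
informative (this also explains how straightness below 1 can be observed at
all with this definition).

The apparent stiffness modulus converts equilibrium length fluctuations into
a force scale:

$$K = \frac{kT}{\langle (L_0 - L)^2 \rangle}\,L,$$

with the population (divide-by-$n$) variance as the default reading of the
ensemble brackets and an `population = FALSE` switch for the $n-1$
convention. Mean comparisons default to Welch's $t$ (the accompanying
$F$-test on variances can reject equal variances, making the pooled test
self-inconsistent; `pooled = TRUE` is available). The variance comparison
places the larger variance in the numerator and doubles the upper tail, so
it is symmetric in its arguments by construction.

## Calcium-binding observables

Contacts are partner atoms strictly closer than 4.0 Å to the calcium ion,
counting oxygen atoms by default (calcium coordination is through oxygen;
`partners = "all"` is available). SASA uses Shrake–Rupley sampling on a
deterministic Fibonacci lattice (default 960 points — reproducible without
randomness), with the calcium radius fixed at 1.5 Å so that the
isolated-ion area $4\pi(1.5 + 1.4)^2 = 105.68$ Å² reproduces the 105.7 Å²
reference that defines the 100% normalisation. Quadrature error for buried
geometries oscillates with the cap boundary at $O(1/N)$, so convergence is
validated against the two-sphere spherical-cap closed form averaged over
separations rather than at a single geometry.

Work-weighted averaging implements the Boltzmann weights of the Jarzynski
identity, $w_i \propto e^{-W_i/kT}$, computed per strain point from that
point's works (each strain point's weights use $W_i$ at that strain — the
only reading that uses the work profile consistently along the axis);
`global = TRUE` applies one endpoint-derived weight per replicate instead.
Weights are shift-invariant, sum to one, and reduce to the arithmetic mean
for equal works.

The toy structure places binding-pocket oxygens on fixed lattice directions
around the ion, split into "loop" and "hairpin" sets; strain inflates all
oxygen distances but the hairpin set three times faster, mimicking the
hairpin displacement that opens the binding pocket under tension. With zero
noise this makes contacts non-increasing and normalised SASA non-decreasing
along any monotone strain grid — the level at which "calcium binding is
mechanosensitive" is literally testable. What passing these tests shows is
that the *estimators and observables behave correctly on data with known
structure*; they say nothing about force fields, water, or real unfolding
pathways, which are explicitly not modelled.

## Mutation-cohort statistics

Disease labels are matched exactly and case-sensitively, neonatal keywords
("neonatal MFS", "intantil MFS" — the database's spelling, accepted
verbatim alongside "infantile MFS") before the classical set
("Classical MFS", "MFS"), because the generic label is a member of both
lists and precedence is the only consistent reading. Every record lands in
exactly one of nMFS / cMFS / excluded.

The full-length fibrillin-1 domain map shipped in `fbn1_domain_map()` is
*synthetic*: domain counts (43 cbEGF, 7 TB, 2 hybrid), the exact
cbEGF12 (D1070–M1112) and cbEGF13 (D1113–I1154) ranges, and plausible
lengths elsewhere. Within every cbEGF domain the six cysteines sit at
offsets +4, +11, +16, +25, +33, +41 from the domain start and the
calcium-binding residues at +0 (D), +18 (N), +19 (T), +22 (D/S); these
offsets reproduce every named residue of the study system (C1074, C1081,
C1086, C1111; C1117, C1124, C1138; N1088/T1089/D1092; N1131/T1132/S1135),
which is what the worked examples and round-trip tests rely on. Disulfide
bonds follow the conserved C1–C3, C2–C4, C5–C6 arrangement; a mutation of
either partner cysteine counts toward its bond. Note the source material
itself is internally inconsistent about residue 1138 (one caption places it
in cbEGF12, the body text in cbEGF13); the map follows the residue range,
which puts it in cbEGF13 as bond 2.

Cohort generation apportions class counts by largest remainder (floors
first, then largest fractional remainders, ties by class order), so
requested totals are exact. Chi-squared comparisons on 2×2 tables default to
no continuity correction, with `yates = TRUE` available since the original
analysis environment is not documented on this point. The uniform baseline
is analytic (each domain type's share of residues) with an optional
Monte-Carlo draw for error bars.

## Problem sizes and numerical tolerances

The validation suite runs entirely on synthetic systems sized for a single
CPU: the harmonic reference uses $\kappa = 1$ kcal/mol/Å², $k_s = 100$,
$v = 0.1$ Å/ns over 5 Å at `dt = 0.005` ns with 100 replicates (mean
dissipation $\gamma v L \approx 0.8\,kT$, where the $n = 100$ estimator bias
is small); the full-curve RMSE against the analytic profile is required to
stay under 0.5 kT, and across twenty master seeds the mean endpoint bias at
$v = 1$ must not fall below that at $v = 0.1$ (dissipation ordering —
a property of expectations, asserted on seed averages, not per run).
Property sweeps use 1000 random ensembles for the Jensen bound, $10^5$
Gaussian draws for the stiffness estimator (within 5% of the closed form),
and an exhaustive sweep of all 2×2 tables with cells 1–10 against the
closed-form chi-squared. The weighted average must agree with direct
evaluation to $10^{-10}$ relative.

## Known limitations

* The generator is one-dimensional and overdamped; it validates estimator
  statistics, not molecular mechanism. Quantities that depend on real
  structure (absolute free energies, rupture forces in pN) are not
  comparable to experimental systems.
* The domain map outside cbEGF12/13 is schematic; analyses keyed to real
  database coordinates require supplying a user map through
  [domain_map()].
* SASA is single-target (the calcium ion); per-residue decomposition is out
  of scope.
* The PMF error model is limited to the endpoint-work histogram; no
  bidirectional or umbrella-sampling estimators are provided.
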