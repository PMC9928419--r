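---
title: "Models and methods behind rpitriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rpitriage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpitriage)
```

`rpitriage` covers four stages of a small-molecule campaign against an
RNA-binding protein: a molecular-dynamics (MD) filter score, absolute
binding free energy (ABFE) bookkeeping, NMR chemical-shift analytics,
and high-content plate scoring for a microtubule-tethering (MT-bench)
assay. This vignette explains each model, its assumptions, the
parameters that matter, and the numerical choices made where the design
was genuinely open. No empirical claim is made here beyond what the
package's own tests and `scripts/acceptance.R` compute.

## The trajectory filter

A docked ligand that survives a short explicit-solvent MD refinement is
scored on two observables. The enthalpic one is the per-frame
difference between ligand–protein and ligand–water interaction
energies, ΔΔH = H_LP − H_LW, averaged over the trajectory: a negative
mean says the pocket outcompetes the water network trying to extract
the ligand. The geometric one is the contact ratio c = (unique
ligand–protein atomic contacts) / (ligand atoms in contact), computed
on the MD-refined structure; c ≥ 1 whenever any contact exists, and
larger values indicate ligand atoms that each engage several pocket
atoms. The score is S = w_c·c + w_ΔΔH·mean(ΔΔH) with default weights
w_c = 4 and w_ΔΔH = −1, so both a dense contact network and a
pocket-favouring enthalpy push S up.

Classification: `left_pocket` if the ligand did not stay bound during
the refinement (a flag supplied upstream — trajectory geometry is out
of scope here); `hit` if S > 0; otherwise `possible` when the
statistical error rescues the score. The rescue rule has two published
phrasings that differ slightly; the operative default is S ≤ 0 and
S + σ(ΔΔH) > 0 (the error-adjusted score turns positive), with the
alternative — σ(ΔΔH) > |mean(ΔΔH)| — available via
`possible_policy = "sd_exceeds_mean"`.

Numerical notes: the internal energy unit is kcal/mol (traces tagged
kJ/mol are divided by 4.184 on construction); the SD is the plain
sample (n−1) standard deviation with **no autocorrelation correction**,
a documented limitation — fluctuations of drug-sized ligands typically
fall between 2 and 7 kcal/mol, and correlated frames make the SD of
the *mean* optimistic, which only affects the `possible` boundary.

## Absolute binding free energies

### BAR

Each λ window contributes bidirectional work samples: `du_forward`
holds U(next) − U(current) sampled in the current state and
`du_reverse` holds U(current) − U(next) sampled in the next, i.e. each
set is the work in its own sampling direction. The Bennett acceptance
ratio estimate solves

Σ_F f(M + w_f − C) = Σ_R f(−M + w_r + C),   f(x) = 1/(1+e^x),  M = ln(n_F/n_R)

for the reduced free-energy difference C. The left side increases and
the right side decreases in C, so the root is unique; it is bracketed
and solved to 10⁻⁸ kcal/mol. The error is Bennett's asymptotic
variance in the pooled form 1/Σ 1/(2+2cosh t) − (1/n_F + 1/n_R).
Windows whose Fermi weights collapse to numerical zero on either side
(no phase-space overlap) are flagged, given an infinite error sentinel
and a warning rather than a silent number. Window free energies add
linearly; errors add in quadrature under the independent-window
assumption of the 40-window protocol.

### Restraint correction

Decoupling a ligand inside a complex requires one distance, two angle
and three dihedral harmonic restraints (potentials K/2·(x−x₀)²). Their
free-energy cost relative to the 1 M standard state (V₀ = 1.6606 nm³)
has the closed form implemented in `restraint_correction()`, with
defaults K_r = 1000 kcal·mol⁻¹·nm⁻² and 10 kcal·mol⁻¹·rad⁻² for the
five angular terms. The closed form evaluates the harmonic
configurational integral with the geometric Jacobian r²·sinθ_A·sinθ_B
frozen at the restraint minimum (the stiff-spring limit).
`restraint_correction_quadrature()` evaluates the same object
numerically — the six-dimensional integral is separable, so a product
of one-dimensional quadratures is exact — and independently checks
every constant, power and sign. With `jacobian = "full"` it instead
carries the r² and sinθ weights through the integrals; at the default
angular stiffness the difference is ≈ RT²(1/K_θA + 1/K_θB) ≈ 0.035
kcal/mol, which quantifies the intrinsic stiff-spring approximation
error of the closed form and is well below typical sampling errors of
the alchemical legs.

### Cycle, thresholds, Kd

Sign convention, fixed in one place: with both legs expressed as
decoupling free energies, ΔG_bind = −ΔG_complex + ΔG_solv + ΔG_r.
Binding free energies are negative by construction, so hit thresholds
compare magnitudes: |ΔG| ≥ 5.5 kcal/mol, escalated to 6.5 kcal/mol for
ligands that only passed the filter as `possible`. Conversion to a
dissociation constant is the exact Boltzmann relation
K_d = exp(ΔG/RT)·1 M with R = 1.98720425×10⁻³ kcal·mol⁻¹·K⁻¹ and
default T = 298.15 K; `kd_to_dg()` is its exact inverse. (A note on
error bands: a ±0.5 kcal/mol uncertainty multiplies/divides K_d by
exp(0.5/RT) ≈ 2.3; quoted bands that differ from this are a matter of
rounding in the source, and the package implements only the exact
relation.)

### ITC

`fit_one_site()` fits the single-site Wiseman isotherm to injection
heats. Cell concentrations use a constant-volume overflow model: each
injection of volume v dilutes the well-mixed cell contents by
(1 − v/V₀) before the new titrant is added, and the heat of injection
i is the enthalpy of newly formed complex net of complex expelled.
The bound-ligand concentration comes from the exact quadratic mass
balance, so the model is valid on both sides of the c = [M]/K_d
transition. Instrument vendors apply proprietary corrections that are
not published; the overflow model is the standard open approximation
and recovers planted parameters to a few percent under the default
design (0.2 mL cell, 14 µM protein, 26 × 1.5 µL of 200 µM titrant, 1%
noise). Flat heat curves are flagged non-identifiable instead of
returning arbitrary parameters.

## NMR analytics

### CSP

The weighted-average chemical-shift perturbation combines ¹H and ¹⁵N
displacements with the conventional 0.14 nitrogen weight. The default
is the root form √(0.5·[ΔδH² + (0.14·ΔδN)²]), which has ppm units and
matches the ~0.01–0.05 ppm magnitudes this kind of titration produces;
the squared variant (identical ranking, ppm² units) is available via
`form = "literal"` for comparison with sources that print the
expression without the root. Unmatched residues are reported, never
silently dropped; side-chain entries are ordinary rows with their own
identifiers (e.g. `W65sc`).

A ligand is called a binder when its mean pocket CSP exceeds the mean
plus one SD of the non-pocket residues — a within-spectrum background
definition chosen because no universal ppm threshold exists across
proteins and field strengths; the multiplier is configurable, and at
least three non-pocket residues are required to estimate the
background.

### PCA mining

`pca_mine()` centres columns without variance scaling (all cells share
ppm units; scaling is optional), retains `n_components` (default 6),
and reports per-sample SPE (residual) and Hotelling T² (within-model)
statistics. SPE uses the Jackson–Mudholkar chi-square approximation
from the discarded eigenvalues. For T² the textbook F-distribution
limit applies to *new* observations; for samples that were used to fit
the model, T²·n/(n−1)² follows a Beta(k/2, (n−k−1)/2) distribution,
and with 15 samples and 6 components the F limit actually exceeds the
attainable maximum (n−1)²/n, so no outlier could ever fire. The
package therefore uses the in-model Beta limit. Clustering of the
retained scores uses k-means with k = 5 and 50 restarts under a
caller-supplied seed (restored afterwards, so library calls never
perturb the session RNG).

### Competition statistic

For each residue, three displacement vectors from the apo crosspeak
are formed in the scaled (¹H, 0.14·¹⁵N) plane: u (ligand only), v (RNA
only), w (RNA + ligand). The scalar product SP = (v−w)·(u−w) is
negative when the ternary peak sits between the two binary peaks —
the geometry produced when ligand and RNA pull the residue's
environment in opposite directions, i.e. competition — and positive
when the two effects add (w ≈ u+v with u·v > 0). Values within ±10⁻⁶
(scaled ppm²) are `indeterminate`. SP is symmetric in u and v and
scales quadratically under a common rescaling of all three vectors;
raw (unnormalised) vectors are used, since positive normalisation
cannot change the sign. Note that when w = u + v exactly, SP reduces
to u·v, so an "additive" call additionally requires the two binary
displacements to point within 90° of each other — the synthetic
generator enforces this for its planted additive residues.

### STD and titration linearity

STD quantities follow the fractional-transfer definitions
A_STD = (I_off − I_on)/I_off and STD_AF = A_STD·[L]/[E], with relative
percentages normalised to the strongest proton (exactly 100 whenever
any transfer occurred). Titration trajectories are assessed by total
least squares in the scaled shift plane: under 1:1 fast exchange the
observed peak interpolates linearly between free and bound positions,
so the first principal axis captures R² ≈ 1 of the variance; R² <
0.98 (configurable) flags curvature, the signature of a second binding
mode, and residues moving less than 0.005 scaled ppm in total are
`not-shifting` rather than force-classified.

## MT-bench plate scoring

The assay tethers a GFP-tagged RNA-binding protein to microtubules so
that endogenous mRNA enrichment along filaments reports binding.
`detect_spots()` thresholds the bait channel at background + 3 SD
(median/MAD background estimates, robust to the sparse bright spots),
labels connected components with `EBImage::bwlabel()`, and derives each
component's length and width as 4·√(eigenvalues of the second-moment
matrix) — the axes of the constant-intensity ellipse with equal
moments, computed on pixel-centred coordinates with a 1/12-pixel
variance floor so one-pixel-wide lines keep a finite width. Spots are
kept when width/length < 0.22 — strictly, so a boundary spot is
excluded — and when the spot's bait mean exceeds twice the cytoplasmic
bait level (the enrichment cutoff is unstated in the source protocol;
2× is the package's choice and is configurable).

Per well, mRNA enrichment (spot/cytoplasm intensity ratio) is
regressed on bait intensity by OLS; the slope is the well's binding
score, with a t-based 95% CI. Wells need ≥ 30 spots (a floor that
guards degenerate synthetic cases; real wells carry hundreds of cells
at 10–50 spots each) and nonzero bait variance. Plate normalisation
maps the mean bait-free (GFP-only) control slope to 0 and the mean
DMSO-bait slope to 1 — chosen because screens report treated scores as
fractions of the untreated score, with untreated near 1 and bait-free
near 0; the source does not state a formula. SSMD defaults to the
standard (μ⁺−μ⁻)/√(σ⁺²+σ⁻²); a pooled-SD variant is provided (they
differ by √2 at equal SDs), because "the standard deviation" in prose
is ambiguous. Hit calls use a two-tailed paired t-test per compound
against the DMSO wells, paired by replicate index, significant only
for decreases at raw p < 0.05 — no multiple-testing correction by
default, matching screens that call hits at raw p over ~40 compounds;
Benjamini–Hochberg is one argument away. Dose–response uses a
four-parameter logistic on log-concentration fitted with
`minpack.lm::nlsLM`, with `fit_ok = FALSE` for flat responses or
EC50s escaping the tested range.

## Synthetic data: what it emulates, and what it does not

Each generator reproduces the statistical structure one estimator
assumes, with ground truth returned beside the data and stage-split
seeded streams (adding a call to one stage never changes another's
draws):

* `sim_energy_trace()`: Ornstein–Uhlenbeck fluctuations around planted
  channel means (default ΔΔH mean −5, SD 3 kcal/mol, inside the
  typical 2–7 kcal/mol fluctuation band).
* `sim_bar_windows()`: per-window Gaussian work pairs satisfying the
  Crooks fluctuation theorem — forward N(ΔF + σ²/2RT, σ²), reverse
  N(−ΔF + σ²/2RT, σ²) — over 40 windows at 5000 samples/side; the
  default σ = 2.5 kcal/mol puts the summed-leg uncertainty near 0.3
  kcal/mol, the scale reported for converged ABFE legs.
* `sim_csp_matrix()`: 15×20 ligand-by-residue matrices with four
  cluster prototypes on disjoint signature residues plus one
  large-amplitude outlier row.
* `sim_competition()` / `sim_titration()`: planted competitive
  (w interior to u,v) and additive (w = u+v, acute u,v) regimes; 1:1
  fast-exchange shifts with fraction bound from the exact quadratic
  mass balance (16 points, 50 µM protein, 10–1000 µM ligand).
* `sim_itc()`: Wiseman heats under the default injection schedule with
  proportional noise.
* `sim_plate()` / `sim_image_plate()`: per-well spot tables or
  rendered bar/disk images with enrichment = intercept + slope·bait +
  noise, 10–50 spots per cell, role-dependent planted slopes; image
  spots are placed with a minimum separation so they remain distinct
  components. Test problem sizes (tens of cells per well, 192–256 px
  fields, 20-well plates) are chosen so the whole suite runs in
  seconds while preserving ≥ 500 spots per well where coverage is
  measured.

What passing these tests does **not** show about real data: the
generators contain no segmentation errors, no uneven illumination or
focus drift, no well-to-well biological variability (so a simulated
spot-level plate separates controls far more sharply than a real one —
plate-quality claims are therefore tested at the well level with
`sim_control_wells()`, which plants the standardised difference
directly), no NMR peak overlap or assignment mistakes, no slow-exchange
or intermediate-exchange line broadening, and no correlated-frame
effects beyond the OU process. They validate estimator correctness,
not robustness to every experimental pathology.

## Degenerate inputs and tie-breaks

Empty contact sets return a flagged zero ratio (unbound ligand) with a
warning; single-frame traces, empty λ windows, missing cycle terms,
non-overlapping BAR windows, flat ITC and dose curves, all-zero STD
tables, zero-variance wells and missing control sets each produce an
explicit error, warning or `*_ok = FALSE` flag rather than a silent
number. Classification boundaries are: S > 0 (strict) for filter hits,
|ΔG| ≥ threshold (inclusive) for affinity hits, width/length < 0.22
(strict) for spot shape, and ±10⁻⁶ dead-band for SP regimes.

## Known limitations

* No autocorrelation correction in the filter SD (documented above).
* BAR assumes independent samples within a window; correlated MD
  output inflates confidence.
* The restraint correction inherits the stiff-spring approximation of
  its closed form (~0.03 kcal/mol at default angular stiffness).
* The binder-call threshold (background mean + 1 SD) is a pragmatic
  default, not a significance test.
* The paired t-test at n = 4 replicates has limited power; effects
  smaller than ~1/SSMD of the control separation are undetectable by
  design.
* The image detector assumes a single plane, roughly uniform
  background and non-touching spots; it is a scoring-stage component,
  not a general segmentation tool.
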