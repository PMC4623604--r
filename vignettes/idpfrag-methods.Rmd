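---
title: "Methods: models, parameters and design choices in idpfrag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in idpfrag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpfrag)
```

idpfrag reimplements, as a tested pipeline, the bespoke computations of an
NMR fragment screen against an intrinsically disordered protein (IDP)
target — the kinase inhibitory domain of the cell-cycle regulator p27^Kip1^
and its Cdk2-binding D2 sub-domain. This vignette explains each model, its
assumptions, the tunable parameters, and the choices made where the design
was genuinely open. Every empirical statement here is computed by the test
suite or the acceptance script; nothing is quoted from external data.

## Fragment-library curation

The curation module reproduces a scaffold-centric selection algorithm for
building a fragment library whose ring systems are well sampled in a large
high-throughput-screening (HTS) collection:

1. **Sanitisation** (`sanitize_library()`): entries are rejected as
   *isotope* (isotope-labelled atoms), *inorganic* (elements outside the
   organic whitelist H, B, C, N, O, F, P, S, Cl, Br, I) or *invalid*
   (unparseable). Parsing and physicochemical descriptors (MW, clogP,
   topological PSA, H-bond donors/acceptors) come from OpenBabel through
   ChemmineR/ChemmineOB. Rotatable bonds are counted on the bond graph as
   acyclic single bonds between non-terminal heavy atoms, and ring count is
   the circuit rank — both documented here because OpenBabel's property
   interface does not expose them.
2. **Murcko scaffolds with alpha atoms** (`murcko_scaffold()`): the
   framework (ring systems plus linkers) is obtained by iteratively pruning
   terminal heavy atoms; atoms directly bonded to the framework (*alpha
   atoms*) are preserved when `keep_alpha = TRUE`. Scaffolds are
   canonicalised so identical frameworks merge; acyclic molecules yield the
   empty scaffold.
3. **Filter cascade** (`apply_scaffold_filters()`): a scaffold passes iff
   it has zero reactive-substructure matches, at most 3 rotatable bonds, at
   least 10 heavy atoms, at least one ring, more than one ring substitution
   for single-ring systems, and an HTS-collection frequency of at least 8.
   Boundary semantics are exactly as stated (strict `< 300` only for the
   Rule-of-Three molecular weight). Frequency tables are keyed by the bare
   framework (no alpha atoms), since a "molecules containing this scaffold"
   count is indifferent to attachment-atom decoration.
4. **Rule of Three** (`check_ro3()`): MW < 300 Da, HBD ≤ 3, HBA ≤ 3,
   clogP ≤ 3, evaluated on the parent compound.
5. **Complexity ranking** (`rank_by_complexity()`): candidates are ranked
   by a structural complexity score. The original selection cites an
   external complexity metric without defining it, so the score here is a
   documented additive surrogate — weighted ring count, heteroatom count,
   heavy atoms and rotatable bonds — and the scorer is pluggable
   (`score_fn`), because only the *ranking* behaviour matters downstream.

Open choices resolved here: the reactive-substructure list ships as a
17-pattern SMARTS file (classic electrophile/unstable classes: acyl and
sulfonyl halides, aldehydes, Michael acceptors, peroxides, epoxides,
azides, ...) that is fully user-overridable, since the original pattern
collections are cited but not listed. Whether the size/flexibility rules
apply to the scaffold or the parent molecule is ambiguous in the source
wording; they are applied to the scaffold (`filter_on = "scaffold"`), with
a config switch. SMARTS matching runs through the `obabel` command-line
tool.

## Chemical-shift-perturbation significance

For a residue observed in reference and perturbed ¹H-¹⁵N spectra, the
perturbation is Δδ = |δ_perturbed − δ_reference| per dimension, reported in
ppm and Hz (Hz = ppm × nucleus Larmor frequency; 0.01 ppm in ¹H at 800 MHz
is 8.0 Hz, and the ¹⁵N dimension converts at ~81 MHz). Significance is
**per dimension** and dual:

> Δδ is significant iff Δδ > resolution floor **and** Δδ > Δδ_ave + 2σ,

both inequalities strict, with Δδ_ave and σ computed over all residues
observed in that dimension. The combined-shift collapse
(√((Δδ_H² + (0.14 Δδ_N)²)/2)) is deliberately **off** by default — in this
weak-binding regime the ¹H dimension carries the discriminating signal and
a combined value would dilute it — but is available via `combined_csp()`.

Two ambiguities are resolved as follows. "Standard deviation of the mean"
versus the printed `+2σ` formula: the formula wins, so σ is the sample SD
by default; `stat = "sem"` substitutes the standard error. The resolution
floors default to 2.4 Hz (¹H) and 1.7 Hz (¹⁵N), the digital resolutions of
the 800 MHz titration experiments; the 600 MHz screening values (3.5/5.7
Hz) can be passed instead.

Side-chain tryptophan indole NH resonances ride along as rows keyed
`"s-<residue>"`; they enter the statistics when present in both lists and
count toward their parent residue's sub-region during classification.

**Binding-site classification** (`classify_binding_pattern()`) buckets a
flagged profile by where its significant residues fall among three
sub-regions of the D2 sub-domain. The source names the sub-regions only by
marker residues (W60/N61; E75/W76/Q77; F87/Y88/Y89), so the default ranges
extend the markers symmetrically — D2.1 = 58–70, D2.2 = 71–81,
D2.3 = 85–90 — and are overridable. Hits confined to D2.3 are `group1`;
D2.3 plus at least one tryptophan sub-region is `group2`; no flags is
`nonbinder`; anything else (including flags outside D2) is `ambiguous`.

## Global K_d fitting

Under fast exchange the observed shift displacement of residue *r* at
ladder point *i* is

$$\Delta\delta_{r,i} = \Delta\delta_{\max,r}\; f_b(L_i;K_d), \qquad
f_b = \frac{(P+L+K_d) - \sqrt{(P+L+K_d)^2 - 4PL}}{2P},$$

the exact 1:1 ligand-depletion bound fraction (`fraction_bound()`, solved
in the cancellation-stable conjugate form). Residues passing the endpoint
significance screen (`select_fit_residues()`) are fitted **globally**: one
shared K_d, one amplitude per trajectory, where a trajectory is a
residue/dimension combination — by default both the ¹H and ¹⁵N trajectories
inform the fit. Observations are weighted by their reported position
uncertainty, linewidth/SNR (`peak_position_error()`).

Two numerical choices matter:

* **Profiling.** The amplitudes (and baselines, below) enter linearly, so
  for fixed K_d they have closed-form weighted-least-squares solutions and
  χ²(K_d) is exact. The global fit is therefore a one-dimensional search: a
  50-point log-spaced grid spanning 10⁻² to 10³ × P_tot localises the
  minimum (a boundary minimum warns), then golden-section refinement on
  log₁₀K_d. The asymptotic SE comes from the χ² curvature.
* **Reference-point refinement.** Displacements are measured relative to
  the ligand-free spectrum, but that reference is recorded with the same
  position noise as every other point. Fixing the free-state position at
  the noisy reference biases the fit; profiling a small per-trajectory
  baseline offset is the closed-form generalised-least-squares treatment of
  that shared error and removed both the bias and roughly 40% of the K_d
  scatter in recovery experiments. This refinement is the default
  (`refine_baseline = TRUE`); disabling it reproduces the strict
  fixed-reference convention.

**Monte-Carlo uncertainty** (`monte_carlo_kd_error()`): each of `n_iter`
(default 500) replicates rescales every ligand total by an independent
Gaussian factor with 10% coefficient of variation (a single shared factor
is available via `shared_conc`), jitters every observed position by its own
reported uncertainty, re-references, and refits; the SD of replicate K_d
estimates is the reported uncertainty. Replicates re-search within one
decade of the base fit (initialisation, not a constraint — the base fit
always uses the full grid). More than 20% failed replicates is an error.

## Displacement and functional assays

* **Ratiometric displacement** (`free_population()`,
  `displacement_profile()`, `displacement_call()`): for residues showing
  free/bound peak doublets, p_f = I_free/(I_free+I_bound). The per-residue
  ratios R_f = p_f(with)/p_f(without) and R_b = p_b(with)/p_b(without)
  carry first-order propagated replicate SDs; *displaced* requires R_f > 1
  and R_b < 1, each beyond `n_sd` (default 1) propagated SDs. Ratios
  deviating from 1 within their error are *indeterminate*; exact unity (or
  significant movement the wrong way) is *not displaced*.
* **Direct-binding anisotropy** (`fit_direct_binding()`):
  r = r_free + (r_bound − r_free)·f_b(L; K_d) with the probe held at its
  total concentration — the depletion quadratic, not the hyperbolic
  approximation, although with a 20 nM probe and ~70 nM K_d the two are
  nearly identical. Weighted Levenberg–Marquardt (minpack.lm). No
  quantum-yield correction is applied (no intensity-change data to support
  one). A ladder that does not approach saturation warns.
* **Dose-response** (`fit_ic50()`): four-parameter logistic
  bottom + (top − bottom)/(1 + (x/IC₅₀)^h) with floating Hill slope
  (constrainable asymptotes), fitted to the replicate average; a
  non-monotone trend (|Kendall τ| < 0.5) warns.
* **Ternary competition** (`solve_ternary()`): mass-action equilibria
  C+D⇌CD, D+L⇌DL and optionally C+L⇌CL, parameterised throughout by
  dissociation constants and solved by damped fixed-point iteration on the
  free concentrations to a 10⁻¹⁰ relative mass-balance residual.
  `predict_displacement_ic50()` locates the half-displacement competitor
  concentration by bisection. A regression test documents the model
  discrepancy this enables: with the NMR-fitted probe–ligand affinity and
  *no* direct receptor–ligand binding, the predicted displacement IC₅₀ is
  more than an order of magnitude above the measured value — consistent
  with the interpretation that the compound also binds the kinase.
* **Activity changes** (`activity_analysis()`): relative change
  = 100·(treated − baseline)/baseline, classified as activation or
  inhibition.

## Trajectory distance states

`extract_distances()` reads multi-model PDB (bio3d) and computes Euclidean
Cβ–Cβ distances per frame for configured residue pairs (default: the three
pairs among W60, W76, Y88; numbering is full-length human p27, with a
`resno_offset` for truncated constructs). `window_average()` takes
non-overlapping block means (default 1 ns at a 2 ps stride; a trailing
partial block is averaged and flagged). `distance_statistics()` reports
per-pair moments, fixed-bin histograms (0.5 Å over 0–50 Å) and, given
state labels, per-state components.

**Compact/extended classification** (`classify_frames()`): the source rule
— compact iff two of the three aromatic residues are within 20 Å — is
ambiguous because the W60–W76 distance is almost always below 20 Å, so the
literal any-pair reading would label nearly every frame compact and erase
the two-state structure the distance histograms display. The default
therefore keys on the hub residue's contacts: compact iff
min(d(W60,Y88), d(W76,Y88)) < 20 Å, strict. The literal rule remains
available (`rule = "any"`). Raising the cutoff can only grow the compact
set (tested monotonicity). Note that window-averaging and classification
do not commute — block means smooth over state switches — which the test
suite asserts as a documented non-property.

`contact_cooccurrence()` reports, for each pair of distance traces, the
fraction of frames in which both are simultaneously below the cutoff, the
product of marginal contact fractions (the independence expectation), the
Pearson trace correlation (undefined-and-flagged for constant traces), and
the all-pairs simultaneous-contact fraction — the quantity that shows the
hub residue contacting one tryptophan at a time rather than both.

## What the synthetic generators emulate — and what they do not

All generators are seeded and bit-reproducible, and attach their ground
truth so recovery can be scored.

**Titrations** (`simulate_titration()`): defaults are the study
conditions — 100 µM protein, the sixteen molar ratios 1:0, 1:0.1, 1:1.5,
…, 1:30, additive Gaussian position noise at the 2.4/1.7 Hz digital
resolutions, reported uncertainties of linewidth/SNR (20 Hz/50 and
15 Hz/50). Free choices, made once: the responsive set is the eight-residue
group-2 footprint (60, 61, 75, 76, 77, 87, 88, 89) plus the two indole
side-chain rows (`s-60`, `s-76`), embedded in an otherwise flat construct
spanning residues 23–104; maximum ¹H shift changes span 60–160 Hz so that
endpoint displacements fall in the few-tens-of-Hz range that per-residue
binding isotherms display at these affinities, with ¹⁵N amplitudes at 30%
of ¹H. Ligand totals are exact in simulation; the 10% concentration error
exists only inside the Monte-Carlo resampler, mirroring how the original
uncertainty analysis imposed it. Not emulated: lineshapes, exchange
broadening, peak overlap, relaxation — the generator produces peak
*positions*, so passing tests say nothing about peak picking on crowded
spectra.

**Two-state trajectories** (`simulate_two_state_trajectory()`): the hidden
state follows a symmetric two-state Markov chain in discrete frames
(expected dwell 5,000 frames = 10 ns at the 2 ps stride — nanosecond-scale
residence consistent with secondary-structure elements that persist on
short time-scales and interconvert over longer ones); distances are drawn
per frame from the active state's Gaussian. Per-state defaults: W60–W76
samples one narrow range (16.5 ± 2.3 Å in both states); W60–Y88 uses
15.9 ± 2.8 Å (compact) / 25.1 ± 3.2 Å (extended) and W76–Y88 16.3 ± 2.0 Å
/ 22.9 ± 2.6 Å, chosen once so the equal-occupancy mixtures reproduce the
reported marginal statistics (20.5 ± 5.5 Å and 19.6 ± 4.0 Å). Because
state residence is long relative to the frame interval, the realised
occupancy of a finite trajectory fluctuates; recovery tests therefore
compare against the state-conditional mean under the realised occupancy.
Not emulated: distance autocorrelation within a state, force-field
physics, or any coupling between the three pair distances beyond the
shared state.

**Libraries** (`simulate_library()`): combinatorial scaffold × substituent
SMILES with exact per-scaffold multiplicities, a frequency table whose
counts equal those multiplicities, and decoys (invalid/inorganic/isotope)
at a requested fraction of the emitted library
(`round(f/(1−f)·n_members)` decoys, so a 0.2 fraction on 40 members adds
exactly 10). Substituents attach by SMILES concatenation and therefore
must be written attachment-atom-last.

**Assays** (`simulate_anisotropy()`, `simulate_dose_response()`,
`simulate_displacement()`): exact model curves (depletion isotherm at
probe 20 nM/K_d 73 nM; 4PL) plus Gaussian noise proportional to the
response range, replicate-averaged — the statistical structure the fitting
stages assume, nothing more.

## Problem sizes and numerical tolerances

The suites run at sizes chosen to keep stochastic checks sharp: 20 seeded
replicates per compound for K_d recovery (with the full 500-iteration
Monte-Carlo per replicate), 200,000-frame trajectories for the distance
roundtrip, 1,000 random triples for the bound-fraction oracle comparison
(agreement to 10⁻⁸ against an independent bisection solver), and
200+ random draws for ternary mass-balance residuals (< 10⁻⁸ relative).
The K_d recovery at 4.8 mM is intrinsically the hardest check: that
isotherm reaches only ~36% saturation at the top of the ladder, so the
±27% recovery band sits close to the estimator's statistical limit under
the stated noise; the 2.2 mM case has comfortable margin.

## Known limitations

* Fast-exchange, single-site 1:1 binding only; no exchange-regime or
  multi-site models.
* The complexity score is a surrogate for the cited (undefined) metric;
  absolute scores are not comparable to other software, only rankings
  within a run are meaningful.
* H-bond acceptor counts follow OpenBabel's convention (e.g. fluorine
  counts), which can differ from other toolkits at the Ro3 boundary.
* The ternary solver assumes 1:1 stoichiometry in every equilibrium.
* Peak assignment, peak picking and spectral processing are upstream of
  this package; inputs are tabular peak lists.
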