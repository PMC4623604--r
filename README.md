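# idpfrag

Analysis toolkit for NMR-based fragment screening against intrinsically
disordered protein (IDP) targets, built around the screening campaign
workflow for the disordered cell-cycle regulator p27^Kip1^: fragment-library
curation, chemical-shift-perturbation (CSP) significance mapping, global
dissociation-constant fitting with Monte-Carlo uncertainty, displacement and
functional-assay analysis, and two-state classification of aromatic-cluster
distance dynamics from molecular-dynamics trajectories. Every stage has a
seeded synthetic-data generator that emulates its input, so the whole
pipeline is testable without spectrometers, plate readers or trajectories.

It is written tidyverse-style: functions take data frames and return
tibbles, fitted objects have `tidy()`/`glance()` methods, and result types
have `autoplot()` methods.

## Who it is for

Structural biologists and chemical biologists running ligand-observed /
protein-observed NMR screens against disordered targets, and method
developers who need a reference implementation of the analysis chain with
explicit statistical conventions.

## The models at the core

**CSP significance.** Per residue and dimension, Δδ = |δ_pert − δ_ref|
(ppm and Hz). A perturbation is significant iff it strictly exceeds both
the digital resolution floor of that dimension and Δδ_ave + 2σ over all
observed residues. Dimensions are kept separate (no combined-shift
collapse) because in the weak-binding regime the amide ¹H dimension carries
the signal. Binding footprints classify as group 1 (aromatic-cluster
sub-region D2.3 only) or group 2 (D2.3 plus the tryptophan sub-regions
D2.1/D2.2).

**Global K_d.** Fast-exchange 1:1 binding with ligand depletion:

    Δδ_{r,i} = Δδ_max,r · f_b(L_i; K_d),
    f_b = [(P+L+K_d) − √((P+L+K_d)² − 4PL)] / 2P

fitted globally over all significant resonances (shared K_d, per-trajectory
amplitude, inverse-variance weights = (linewidth/SNR)⁻²). Amplitudes are
profiled out in closed form, making the fit a 1-D search in K_d.
Uncertainty comes from a Monte-Carlo resampler that imposes a 10% ligand
concentration error and the per-point position error, then refits.

**Assays.** Ratiometric free/bound populations p_f = I_f/(I_f+I_b) with
displacement calls from the ratios R_f, R_b; direct-binding anisotropy via
the depletion isotherm; four-parameter logistic IC₅₀; exact mass-action
ternary competition (C+D⇌CD, D+L⇌DL, optional C+L⇌CL).

**Distance states.** Cβ–Cβ pair distances per trajectory frame; frames are
compact iff the hub aromatic (Y88) is strictly within 20 Å of a tryptophan
partner (the literal any-pair rule is available); block averages,
histograms, per-state components and contact co-occurrence.

## Worked example

Simulate a 16-point titration at the screening conditions (100 µM protein,
molar ratios 1:0 … 1:30, truth K_d = 2.2 mM, position noise at the 2.4/1.7
Hz digital resolutions), screen for significant resonances, fit globally,
and attach Monte-Carlo errors:

```r
library(idpfrag)

series <- simulate_titration(titration_sim_spec(kd_true_mM = 2.2, seed = 7))
sel <- select_fit_residues(series)
sel
#> [1] "76"   "77"   "87"   "88"   "89"   "s-60" "s-76"

fit <- fit_global_kd(series, residues = sel)
fit
#> Global 1:1 K_d fit (7 residues, dimension(s) H+N)
#>   K_d = 2.26e+03 uM (asymptotic SE 20)
#>   chi2 = 5911 on 195 df

monte_carlo_kd_error(series, residues = sel, n_iter = 500, seed = 7)
#> Monte-Carlo K_d uncertainty: SD = 346 uM over 500 replicates (0 failed)
```

The screen found the strong responders (including the tryptophan indole
side-chain rows `s-60`, `s-76`); the fitted K_d of 2.26 mM recovers the
2.2 mM truth well within the ±0.35 mM Monte-Carlo uncertainty, which is
dominated by the imposed 10% ligand-concentration error.

The endpoint CSP footprint classifies the simulated compound's binding
mode:

```r
lists <- titration_peak_lists(series)
prof <- flag_significant(compute_csp(lists$reference, lists$perturbed))
classify_binding_pattern(prof)
#> # A tibble: 1 × 7
#>   class  n_significant n_d2_1 n_d2_2 n_d2_3 n_outside significant
#>   <chr>          <int>  <int>  <int>  <int>     <int> <list>
#> 1 group2             7      1      3      3         0 <chr [7]>
```

Hits in D2.3 plus the tryptophan sub-regions: a group-2 pattern. And the
distance-dynamics roundtrip at full trajectory size:

```r
traj <- simulate_two_state_trajectory(two_state_spec(n_frames = 200000, seed = 7))
distance_statistics(traj, config = state_config())$summary
#> # A tibble: 3 × 4
#>   pair    mean_A  sd_A      n
#>   <chr>    <dbl> <dbl>  <int>
#> 1 W60_W76   16.5  2.30 200000
#> 2 W60_Y88   20.5  5.49 200000
#> 3 W76_Y88   19.6  4.04 200000
```

The W60–W76 pair samples one narrow range (16.5 ± 2.3 Å) while both Y88
distances are bimodal mixtures whose marginals match their configured
statistics; `classify_frames()` then splits frames into compact/extended
states by the hub-contact rule.

For library curation, `curate_library()` chains sanitisation → Murcko
scaffolds (alpha atoms preserved) → the filter cascade (reactive
substructures = 0, rotatable bonds ≤ 3, heavy atoms ≥ 10, rings ≥ 1, ring
substitutions > 1 for single rings, HTS frequency ≥ 8) → Rule of Three →
complexity ranking, returning per-compound verdicts with reasons.

## Documentation

The methods vignette (`vignettes/idpfrag-methods.Rmd`) documents every
model, parameter default, numerical choice and known limitation, including
what the synthetic generators do and do not emulate.
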