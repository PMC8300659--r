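---
title: "Models and methods behind zincys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind zincys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zincys)
```

`zincys` quantifies the chemistry of a single reactive protein cysteine —
its thiol pK_a, the protection of that thiol by divalent cations, the
protein's apparent zinc affinity, and the geometric feasibility of
cysteine crosslinks. This vignette documents the models, their
assumptions, every tunable parameter that matters, and the design
decisions taken where the methodology was genuinely open.

## 1. The alkylation-kinetics model

### Rate law

Alkylation of a thiol by an electrophilic probe is pseudo-first-order at
fixed pH, and only the thiolate anion reacts appreciably. The package
models the observed rate as a baseline plus one Henderson–Hasselbalch term
per ionizable site:

$$k_{obs}(\mathrm{pH}) = k_0 + \sum_i \frac{k_{max,i}}{1 + 10^{\,pK_{a,i} - \mathrm{pH}}}.$$

Each term is the site's limiting rate scaled by its thiolate fraction;
the curve is monotone non-decreasing in pH for non-negative rates, and its
inflexion points coincide with the pK_a values when sites are separated by
more than about 2 pH units (`fit_pka()` warns below that separation).
`true_kobs()` evaluates this law exactly and serves as the internal ground
truth for the generator.

### Fluorescence curve family

The probe becomes fluorescent upon conjugation, so a well's fluorescence
rises from a bottom plateau $F_o$ (non-alkylated protein plus background)
to a top plateau when the thiol pool is exhausted. The generator and the
per-well fit both use logistic growth anchored at the first time point,

$$F(t) = \frac{F_{max}}{1 + \left(\tfrac{F_{max}-F_o}{F_o}\right)e^{-kt}},$$

whose log-curve $\ln F(t)$ has slope $k\,(1 - F/F_{max})$: early in the
reaction, while $F \ll F_{max}$, $\ln(F_t/F_o)$ is linear in $t$ with
slope $k$. This makes the classical estimator — the OLS slope of
$\ln(F_t/F_o)$ over the early phase — consistent in the early-phase limit.
A saturating-exponential alternative
(`kinetics_preset(curve_family = "exponential")`) is provided to probe the
estimator's robustness to a curve whose log-slope differs from $k$
everywhere except at $t = 0$.

Note an inherent property of the linearised estimator: on a logistic
curve its expectation is slightly below $k$ (by roughly the average of
$F/F_{max}$ over the analysis window), so it is exact only far from
saturation. The per-trace tests therefore grant the estimator a small
relative tolerance (2% far from saturation, up to ~8% for wells that
approach the plateau), while exact (1e-3) parameter-recovery checks are
applied where they are mathematically attainable: `fit_pka()` on exact
rate-law values, the competition fit, and the gel ratios, all on
noiseless inputs. This bias is nearly uniform across pH and therefore
moves the fitted pK_a values only marginally — which the end-to-end
recovery tests quantify.

### Per-well processing

* `fit_time_sigmoid()` fits the three free parameters (bottom, top, rate)
  by Levenberg–Marquardt with a multistart over initial rates
  (0.005–0.15 min⁻¹) and positivity bounds; the half-rise `midpoint` is
  derived. Two degenerate cases are handled explicitly: exactly constant
  traces return `bottom = top = mean`, and a fitted rise smaller than
  twice the residual SD is collapsed to the flat solution — otherwise a
  noise-fitted sigmoid on a background well donates a spurious bottom
  plateau and window. If no start converges, the bottom falls back to the
  first quartile and the fit is flagged.
* `estimate_kobs()` computes the OLS slope of $\ln(F_t/F_o)$ on the
  early-phase window: the leading run of points below
  `f0 + window_frac * (top − f0)` with `window_frac = 0.3` (the logistic
  log-slope has deviated by ≤30% at the window edge, and in practice the
  window average sits much closer to $k$), expanded to the first 6 points
  when fewer than 4 qualify. When the caller supplies fitted values, the
  window is cut on the *fitted* curve, so measurement noise cannot
  collapse it; the slope always comes from the observed data.
  Non-positive fluorescence points are dropped with a warning; negative
  slopes are clipped to zero because a negative pseudo-first-order rate is
  not physical.
* `build_titration_curve()` background-corrects by subtracting the mean
  *slope* of same-pH background wells (not raw fluorescence — background
  wells lack the protein signal scale), then summarises replicates per
  measured pH (`ph_final`), which is the x-axis everywhere. The curve is
  invariant to row order and to duplication of a background well.

### Titration fitting, model selection, pooling

`fit_pka()` fits the rate law by weighted nonlinear least squares with a
pK_a grid multistart (3–11, step 1; ordered pairs for two sites) and
bounds pK_a ∈ [2, 12], rates ≥ 0. **Weighting** is a deliberate design
choice: raw 1/SEM² weights computed from three replicates are extremely
unstable — a chance near-zero SEM can carry a billion-fold weight and
drag the fit by more than a pH unit. The package therefore uses moderated
weights $1/(\mathrm{SEM}^2 + \tilde{s}^2)$ with $\tilde{s}$ the median SEM
of the curve, preserving heteroscedasticity information while bounding any
single point's influence; curves with zero or missing SEMs fall back to
unweighted least squares.

`select_model()` compares the 0-, 1- and 2-site fits by AICc, breaking
ties (ΔAICc < 2) towards fewer sites; a model that fails to converge is
simply excluded. `pool_experiments()` averages per-experiment fits
(sites matched by ascending pK_a), reporting mean ± SD across experiments
rather than refitting globally — matching how replicate titrations are
conventionally reported. Whether the two pK_a values should instead come
from one global fit across experiments was an open choice; per-experiment
fitting was selected because it yields the across-experiment SD directly
and tolerates experiment-to-experiment scale differences.

## 2. The gel-densitometry model

Per-lane ratios (biotin/vimentin for modification, oligomer/monomer for
crosslinking) are computed first and then averaged — the per-lane
convention of densitometry figures — and percent inhibition is
$(1 - \bar r_{treated}/\bar r_{control}) \times 100$. Negative values
(enhancement, as magnesium produces with DBB) are reported unclipped.
Group comparisons use two-sided Student's t-tests (unpaired Welch by
default, paired on request) at the conventional p < 0.05, with no
multiple-testing correction (none is applied in the source experiments;
reports note this). Background subtraction is assumed upstream in the
densitometry software.

`protection_vs_spacer()` joins protection results to the crosslinker
registry (DBB 4.88 Å, TMEA 10.3 Å, BMH 13.0 Å thiol; DST 6.4 Å amine;
diamide and H₂O₂ as disulfide-forming oxidants) and reports the Spearman
rank correlation of inhibition against spacer length; all-tied inputs
give an undefined correlation, reported as trend `"flat"` rather than an
error.

## 3. The competitive-binding model

The chelator competition assay is modelled as the minimal explicit
equilibrium supporting an affinity inference: 1:1 Zn:Zincon stoichiometry
and $n$ independent, identical protein sites. For free zinc $z$,

$$\mathrm{Zn}_{tot} = z + Z_{tot}\frac{z}{K_Z + z} + n P_{tot}\frac{z}{K_P + z},$$

solved by `uniroot()` on $[0, \mathrm{Zn}_{tot}]$ (the left side is
strictly increasing in $z$, so the bracket always holds) followed by up to
four Newton steps that push the mass-balance residual below
$10^{-10}\max(1, \mathrm{Zn}_{tot})$. Absorbance is linear in the
Zn–Zincon complex: $A_{620} = b + s\,[\mathrm{ZnZincon}]$.

`fit_binding()` estimates in two stages, mirroring assay practice: the
protein-free curve (whose species depend only on the fixed
$K_Z$ = 214 nM) calibrates $b$ and $s$ by linear regression, decoupling
the optical scale from $K_P$ — fitting them jointly confounds scale with
affinity. The with-protein curve then determines $\log_{10} K_P$ (and
optionally $n$) by Levenberg–Marquardt over the solver with a multistart
across $\log_{10} K_P \in \{-2 \dots 3\}$ and bounds $[10^{-4}, 10^{4}]$ µM.
When the fitted model predicts a competition effect below 2% of the
protein-free dynamic range, the fit is flagged `non_competing` and $K_P$
is pinned at the upper bound instead of erroring: an affinity that weak is
simply not measurable in this assay. No published protein K_D exists for
this system — the assay supports an affinity *range* (nanomolar to
micromolar) — so correctness is established by parameter recovery on
synthetic curves, not by reproducing a printed constant.

Units: all concentrations are carried in µM internally; dissociation
constants are accepted with explicit unit tags (`kd_zincon_nM`,
`kd_protein_uM`).

## 4. Structure geometry

`read_pdb()`/`write_pdb()` implement a fixed-column PDB dialect with
MODEL/ENDMDL trajectory frames, element inference from columns 77–78
falling back to atom-name heuristics (two-letter metals only for HETATM
records — a protein `CA` is an alpha carbon, not calcium), and strict
error contracts (inconsistent atom counts name the offending frame;
multi-character chain ids and out-of-field coordinates are rejected).
Multi-frame *writing* is required by the trajectory fixtures, which is why
the dialect is implemented here; the test suite cross-checks the parser
against an independent PDB reader.

`cys_sg_distances()` reports inter-chain cysteine SG–SG Euclidean
distances per frame, with no alignment or superposition — the distances
are internal and rigid-motion invariant (property-tested with random
rotations).

`classify_crosslink_feasibility()` calls a thiol crosslinker feasible iff
`distance ≤ spacer_arm + slack`. The default slack of **1.12 Å** is chosen
so that the shortest crosslinker (DBB, 4.88 Å) reproduces exactly the 6 Å
cutoff conventionally used for oxidative or chemical crosslinking of a
cysteine pair: 4.88 + 1.12 = 6.00. Disulfide (oxidant) feasibility is
`distance < 6 Å`; amine-reactive crosslinkers are "not applicable" for a
cysteine pair. Feasibility is monotone in distance by construction.

`ion_contact_persistence()` computes, per HETATM ion, the fraction of
frames whose minimum ion-to-protein-atom distance is within the cutoff.
The default cutoff of **3.0 Å** covers the 2.5 Å Zn–S coordination bond
with a vibration margin; "protein atoms" means all ATOM records, not only
side chains (both configurable). Persistence is *strictly* greater than
the 0.9 threshold, matching the "more than 90% of the simulation time"
convention; a contact fraction of exactly 0.9 is not persistent.
Reproducing any particular published count of persistent ions requires
the original trajectories and is deliberately out of scope; the statistic
is validated by oracle equivalence (a brute-force frame-by-atom double
loop) on synthetic fixtures.

## 5. The synthetic-data generator

The generator exists so that every analysis is testable end to end with
known ground truth. What it emulates, and what it does not:

* **Kinetics plates** (`make_kinetics_plate()`): triplicate sample wells
  per pH over the 17-point buffer grid pH 3–10.8, sampled every 3 min to
  90 min; one protein-free background well per pH, flat at the bottom
  plateau; measured `ph_final` simulated once per buffer as
  nominal + N(0, 0.03). The wild-type preset uses the reported two-site
  titration (pK_a 4.61 and 7.39); the cysteine-free control is
  baseline-only. Free choices, fixed once: plateaus $F_o = 50$,
  $F_{max} = 500$ AU (a 10-fold fluorogenic rise is typical of
  bimane-type probes), limiting rates 0.015 and 0.030 min⁻¹ with baseline
  0.002 min⁻¹ (rates that neither saturate the fastest wells before a few
  samples nor leave the slowest indistinguishable from background over
  90 min), and additive Gaussian noise with SD 2 AU (≈0.4% of the top
  plateau, a realistic plate-reader noise floor; the value is recorded in
  the plate's `preset` attribute since no published noise magnitude
  exists). At this design the pipeline's median absolute pK_a error is
  below 0.15 pH units per experiment — the calibration the recovery tests
  enforce.
* **Gel tables** (`make_gel_table()`): the reference band (monomer or
  vimentin) is lognormal around a fixed 1000 AU; the quantified band is
  the reference times a lognormal ratio whose expectation is
  `baseline_ratio × (1 − true_inhibition)`, so the observed per-lane ratio
  is unbiased for the design target at any noise level. Multiplicative
  lognormal noise (CV 0.08) is the standard model for densitometry
  intensities. The `figure6A` preset encodes the published spacer-length
  selectivity (76% DBB, 56% TMEA, 0% BMH and DST at 500 µM ZnCl₂); the
  other presets encode only published *directions* (concentration-dependent
  zinc protection; no magnesium protection at ≤50 µM and enhancement of
  DBB crosslinking at 500 µM; increased crosslinking after salt
  polymerisation) with illustrative magnitudes, because no numbers are
  printed for them. No gel images are synthesised — intensities only.
* **Competition curves** (`make_competition_curves()`): paired titrations
  (0 and 5 µM protein, 40 µM Zincon) over 0–80 µM total zinc, generated
  through the same mass-balance solver the fit inverts, plus Gaussian
  absorbance noise (default SD 0.01 AU against a ≈0.8 AU dynamic range;
  scale 0.02 AU/µM and baseline 0.05 AU are plausible for a 620 nm dye
  readout).
* **Structures** (`make_structure_fixture()`): two ALA–CYS–ALA stubs
  (chains A/B, residues 327–329, 1-based numbering, coordinates in Å)
  with the inter-chain SG–SG separation set exactly to 4 Å ("nearby") or
  22 Å ("distant") in frame 1; Gaussian jitter in later frames; pinned
  ions at exactly the 2.5 Å Zn–S coordination distance from the chain-A
  sulfur in every frame; random-walk ions that stay far from the protein.
  The stubs have plausible local geometry but make no claim to
  stereochemistry — distances are the only structural property the
  analyses consume.

Passing tests on these simulations demonstrate that the estimators
recover the truth *under the generator's assumptions* — additive/lognormal
noise, a known curve family, no pipetting drift, no inner-filter effects,
no gel background. They do not certify performance on real instrument
exports with systematic artefacts; the CSV schemas are the boundary where
such data would enter.

## 6. Numerical choices and degenerate inputs

* Nonlinear fits use `minpack.lm` (Levenberg–Marquardt) with explicit
  bounds and multistarts; best-of-starts is chosen on the weighted
  objective. The lower-level `nls.lm` interface is used for the titration
  and binding fits because converged solutions with a zero rate have a
  singular Jacobian that the `nls`-object wrapper refuses.
* AICc is computed from the Gaussian profile log-likelihood of the
  (weighted) RSS with the residual variance counted as a parameter;
  only differences between models on the same data are meaningful.
* Flat titration curves fit at `n_sites = 1` return a near-zero rate and
  wide covariance rather than an error; the pK_a is unidentifiable and
  selection prefers the baseline model.
* Identical groups in `compare_conditions()` return p = 1 and t = 0;
  constant groups with different means return p = 0 with an infinite
  statistic — both cases have no variance for a t distribution.
* `solve_species(0, …)` returns all-zero species without invoking the
  root finder.
* Simulation problem sizes in the test suite (seed counts of 12–50 for
  recovery sweeps, 1000 draws for the solver-oracle comparison) were
  chosen to estimate each property's statistic stably; the methods they
  validate are size-independent.

## 7. Known limitations

* The two-site titration fit assumes independent ionizations; strongly
  coupled sites (separation < 2 pH units) make inflexion points diverge
  from pK_a values, and the fit can only warn.
* The ln(F_t/F_o) estimator is biased low near saturation (Section 1);
  studies needing unbiased absolute rates at high conversion should fit
  the full curve instead.
* The binding model treats protein sites as independent and identical; it
  cannot resolve site-class mixtures, and `n_sites` trades off against
  $K_P$ when the titration does not bracket the protein's capacity.
* The PDB dialect covers the fixed-column subset the fixtures use; mmCIF
  and exotic records are out of scope.
* Molecular dynamics, docking, electrostatics and structure-based pK_a
  prediction are explicitly not re-implemented; the geometry module
  post-processes coordinates it is given.
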