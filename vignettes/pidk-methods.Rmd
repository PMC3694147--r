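---
title: "Primary ion depletion kinetics: models, parameters and validation"
author: "pidkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Primary ion depletion kinetics: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pidkit)
```

# The method

PTR-MS ionizes an analyte M by proton transfer from hydronium,
H3O+ + M -> MH+ + H2O, in a drift tube at a reduced field E/N of roughly
90–140 Td. Under routine conditions the reagent ion vastly outnumbers
the analyte ("swamping"), the kinetics are pseudo-first order in M, and
MH+ is linear in the analyte concentration. A primary ion depletion
kinetics (PIDK) run inverts this: enough analyte is introduced to
consume essentially all reagent ions, and the analyte is then diluted
away exponentially (headspace dilution, `[M]_c = M0 exp(-c/tau)` over
cycles c). Two phases result: (a) primary ion depleted and the product
MH+ pinned at the total reagent budget, then (b) primary ion restored
and MH+ declining log-linearly with the dilution constant. Minor
channels reveal their chemistry through their trajectory across those
phases: isotopologues stay proportional to MH+; fragment ions that can
re-donate their proton to the abundant analyte are suppressed under
depletion; and adducts whose formation needs two analyte molecules peak
during replenishment and decay with order 2 in the normal phase.

The package implements (i) a drift-tube simulator that reproduces this
phenomenology from elementary reactions, (ii) the analysis pipeline that
extracts it from measured ion-count traces, and (iii) a seeded generator
that ties the two together with complete ground truth.

# Kinetic model and assumptions

The drift tube is treated as a plug-flow reactor: one transit of
duration `t_r` per measurement cycle, integrated as mass-action ODEs in
the ion densities with all neutrals held constant within a transit
(ion densities, ~1e4 cm^-3, are negligible against any relevant neutral
concentration; the slow dilution lives entirely in the per-cycle
schedule). Every supported reaction carries exactly one charged species
on each side — proton transfer, charge transfer, effective termolecular
association (second order in the neutral, buffer stabilization folded
into the rate coefficient), unimolecular dissociation — so total ion
density is conserved identically. Element balance is enforced at build
time whenever formulas are supplied, and proton-affinity-gated reactions
are active only when `PA(acceptor) >= PA(donor)`.

Key parameters, units and defaults:

| parameter | default | meaning |
|---|---|---|
| `k_PT` | 2.0e-9 cm³ s⁻¹ | collision-limited proton transfer, the standard PTR-MS assumption |
| `t_r` | 1.0e-4 s | ion residence time per transit |
| `L` | 9.2 cm | drift length, typical for the high-sensitivity instrument class; never printed on spec sheets, so it is explicit in every E/N computation |
| p, T, U_D | 2.1 mbar, 333.15 K, 600 V | nominal drift conditions of the presets; with `L` these give E/N = 142.8 Td, the "about 140 Td" operating point. The instrument class is specified as 2.0–2.1 mbar; 2.1 mbar is the preset's single nominal value |
| gain | 300 cps per cm⁻³ | detector mapping; puts the primary ion at ~3e6 cps, the reduced-SEM regime these studies run in |
| dwell | 0.5 s | per-cycle integration time for Poisson counting |

E/N is always derived, never hard-coded: `E/N = (U_D/L)/n` with
`n = p/(k_B T)`, expressed in Townsend (1 Td = 1e-17 V cm²).

## The two depletion mechanisms

Both proposed explanations of depletion-dependent fragmentation are
implemented as independent switches, and neither is on by default (with
both off the naive expectation holds: fragments parallel to MH+).

**Mechanism 1 — secondary proton transfer.** Reactions tagged
`secondary` (`F1H+ + M -> MH+ + F1`, PA-gated) are activated. Under
depletion the fragment ion meets analyte at huge concentration and is
consumed; under normal conditions the loss is negligible. The presets
use an *effective* fragment-ion loss rate of 8e-8 cm³ s⁻¹ to the
analyte — deliberately above a single binary collision-limited channel,
standing for the sum of all loss channels a small fragment ion suffers
under swamping conditions. The choice is phenomenological: with the loss
at the bare collision limit the simulated fragment trace peaks *during*
replenishment (its survival improves faster than its production falls),
whereas the reported class-2 behaviour — lowest under depletion, highest
under non-depleted conditions — is the strong-sink regime in which the
fragment keeps being consumed until the analyte is nearly gone. The rate
is a preset value, configurable per reaction. Because the strong sink is
an effective description of swamping conditions, the stripping generator
(no depletion anywhere) deactivates `secondary` reactions unless
mechanism 1 is explicitly requested.

**Mechanism 2 — reduced internal energy.** Under deep depletion the
primary ion reacts at the tube entrance before the drift field has
heated it, and the cold protonation fragments less. This is modelled
spatially: the transit is integrated along the tube axis and channels
flagged `soft` route protonation events with a branching scale rising
linearly from `betaCold` at z = 0 to the nominal branching at `zTh`
(defaults 0 and 0.5). With a flat ramp the spatial integrator reproduces
the homogeneous one to 1e-8 relative; in the low-depletion limit
(uniform protonation along z) the fragment fraction equals the
z-average of the ramp, `1 - zTh/2` of nominal for `betaCold = 0`.

## The adduct channel

The replenishment-peak phenomenology cannot come from a bare termolecular
channel on H3O+: with all reagent consumed either way, any production
term that grows with [M] is maximal at the start of the run. The presets
therefore model the adduct as a weakly bound cluster formed on the
*hydrated* hydronium reagent (`W1H+ + 2M -> adduct`, effective rate
2e-21 cm⁶ s⁻¹) and destroyed by collision-induced dissociation in the
drift field (1.2e5 s⁻¹, i.e. only adducts formed in roughly the last
tenth of the transit survive). Under deep depletion the cluster reagent
never reaches the tube exit and the adduct signal is near zero; during
replenishment the product `[M]² x [surviving reagent]` peaks; in the
normal phase the reagent is constant and the yield is cleanly second
order in M (doubling M at low depletion multiplies the yield by 4.0,
tested to 2%). The weak binding of the adduct is also why it is so
sensitive to the energetic conditions — the same argument that makes
adduct abundance fall steeply with E/N.

## Why protonation branching sits on every reagent channel

Fragment and dehydrogenation branching fractions are applied to the
cluster-reagent proton-transfer channels (`W1H+ + M`, `W2H+ + M`) with
the same fractions as the H3O+ channel. If they were not, the
fragment-to-MH+ ratio would drift between phases simply because MH+
aggregates all reagents while the fragment drew on one of them — a
spurious deviation the isotopologue analysis would flag. Chemically the
branching belongs to the protonated analyte, not to the proton donor.

# Analysis pipeline: decision rules and numerics

**Phase segmentation.** The plateau is the median of the last quartile
of the primary-ion trace (the run must end non-depleted; last-quartile
CV < 20%). Depletion is the maximal prefix below `f_dep = 0.10` of the
plateau, normal the maximal suffix above `f_norm = 0.90`, replenishment
the remainder. Thresholding is applied to a running-median-smoothed
trace (window 5): the suffix rule is otherwise fragile to a single low
count excursion late in the run, which can displace the normal boundary
by tens of cycles.

**Classification.** Rules are applied in order: (1)
parallel-isotopologue if the per-cycle ratio to the parent has CV below
10%; else (2) replenishment-peak if the global maximum lies inside
replenishment and exceeds both phase-boundary values by at least 20%
relative prominence; else (3) depletion-minimum if the depletion-phase
mean is smallest; otherwise the channel is reported unclassified rather
than force-assigned. All rules operate on the same lightly
median-smoothed traces; since medians commute with positive scaling,
classification is invariant under rescaling of any trace, and exact
proportionality is preserved. The thresholds are unspecified by the
methodology itself; the defaults reproduce the qualitative published
behaviours on the shipped presets and are all arguments.

**Isotopologue deviation.** For each family trace, OLS of log10(trace)
on log10(reference); slope expected 1, offset expected log10 of the
theoretical ratio. A deviation is flagged when the mean absolute
residual over the top-decile reference cycles exceeds 3x the residual SD
of the remaining cycles *and* an absolute floor of 0.01 log10 units
(~2.3%) — without the floor, noise-free inputs with numerically tiny
residual SD would flag meaningless curvature. Base-10 logs and OLS
throughout; nonpositive cycles are trimmed with a warning.

**Decomposition.** A composite channel is modelled as
`target = a * max(0, P - parasitic) + b * ref`, with P the parasitic
plateau median, `b` the median target/ref ratio over a tail window
inside the normal phase, and `a >= 0` by least squares. The amplitude
`a` is this package's formalization of the published "inverse of the
parasitic recovery" scaling, which is stated only graphically. A caveat
the user should know: in the normal phase *both* components decline
proportionally to [M], so the tail estimator attributes any residual
charge-transfer signal there to the satellite. The decomposition is
quantitative when the tail is satellite-dominated, which holds in the
presets because the charge-transfer reagent is a small source (O2+ at
5 cm⁻³ equivalent, charge-transfer rate 1e-10 cm³ s⁻¹ — fully depleted
during the run, negligible at the tail).

**Reaction order.** Slope of log10(fragment) vs log10(parent) over a
window in the normal phase, where the parent is linear in [M]. Windows
shorter than 10 cycles are refused; zero-count cycles are excluded with
a warning. Order studies want a slow dilution: over a 60-cycle window an
order-2 channel spans the square of the parent's decline, so the preset
order study runs at tau = 40 cycles to keep the adduct above the
counting floor across the whole window.

**Slope confirmation (stripping).** Inert-gas stripping gives every true
fragment the parent's log-linear decay slope. The package formalizes
"identical slope" as a two-sided z-test on two OLS slopes with pooled
standard error, confirming when p >= alpha (default 0.05). The test is
calibrated (type-I error within 1.5 points of alpha over 1000 seeded
null replicates) and powerful (>= 99% rejection at 5x pooled-stderr
slope differences). With two exactly noiseless fits the comparison
degenerates to exact equality.

**Integration accuracy.** The stiff solver (`deSolve::lsoda`) runs at
relative tolerance 1e-9 and absolute tolerance 1e-6 cm⁻³. An absolute
tolerance of order 1 cm⁻³ — natural-looking for densities of 1e4 — is
too loose to demonstrate the analytic pseudo-first-order limit to 1e-6
relative, which these tests require. Because every reaction conserves
total ion density exactly, the final state is additionally projected
back onto the initial total; charge conservation therefore holds to
floating-point accuracy rather than integrator accuracy.

# Isotope patterns and composition search

Patterns are computed by per-element multinomial convolution over integer
mass shifts, normalized to base peak = 100 and truncated at 0.01% by
default; the monoisotopic mass subtracts the electron mass for cations
(irrelevant at 2-decimal rounding). The shipped abundance table is the
IUPAC representative set, overridable by CSV — published isotopologue
tables computed with desktop calculators can differ by up to ~0.1
percentage point in M+1 depending on the 13C abundance their tables
carry, which is why comparisons against such tables use an absolute
0.2-point tolerance. The composition search enumerates all formulas in
the bounds (default C 0–10, H 0–30, S 0–5) at the target nominal mass;
the optional even-electron-cation valence filter keeps
`RDBE = C + N/2 - H/2 + 1 >= 0` (divalent S, O contribute nothing) and
is off by default. Both are verified against exhaustive enumeration
oracles in the tests.

# What the generator emulates — and what it does not

`generatePIDK` emulates: quasi-logarithmic analyte dilution; depletion
and replenishment of H3O+, its water clusters and O2+; isotopologue
splitting of every ion species across its pattern; water-cluster
overlap channels riding on fragment m/z; mass-dependent transmission
(linear interpolation of a coefficient table); a constant per-channel
background (no background correction is applied in any default
workflow, matching the method's practice); and Poisson counting noise
on integrated counts per dwell. The primary ion is monitored through
its heavy-oxygen isotopologue at m/z 21, which falls out of the isotope
split automatically. `generateStripping` adds stepped drift voltages
(E/N schedule), exponential gas-phase stripping with an optional final
flux boost, E/N-dependent branching through interpolated tables, and an
optional constant-source contaminant channel as a negative control.

Not emulated: detector aging and dead time, pressure transients at
sample injection, space charge, ion mobility and diffusion, accurate
collision-energy distributions, and real instruments' drifting
backgrounds. Passing tests therefore demonstrate correctness of the
algorithms under the stated statistical model — Poisson counting on top
of deterministic kinetics — not robustness to every artefact of real
spectra. Preset species lists, proton affinities and rate constants are
representative values for the compound class, not reconstructions of
any specific instrument's calibration.

# Validation studies and problem sizes

The package ships two seeded validation utilities used by the tests:

* `classifierSweep()` — randomized PIDK scenarios (three compound
  presets, secondary proton transfer on, dilution constant 12.5–15
  cycles, initial concentration scaled 0.8–1.25x, 135 cycles, overlap
  channels off so every labelled channel has unambiguous ground truth),
  classifying every channel with a clean truth label and plateau >= 100
  cps. The acceptance suite runs 200 scenarios and requires >= 95%
  recovery across all three classes.
* `slopeTestCalibration()` — Poisson replicates of a decaying
  exponential (plateau 1e4 cps, slope -0.01 per cycle, 60 cycles);
  1000 null replicates for type-I calibration and 300 at a 5x
  pooled-stderr offset for power.

These sizes were chosen as the smallest that pin the claimed rates with
useful Monte-Carlo resolution.

# Known limitations

* The decomposition's tail estimator lumps any normal-phase
  charge-transfer remnant into the satellite coefficient (see above);
  it quantifies cleanly only when the parasitic source is small.
* Classification thresholds are heuristics tuned to the shipped presets'
  qualitative behaviours; pathological traces (e.g. overlap-dominated
  channels whose satellite survives the analyte) are deliberately
  reported unclassified.
* The effective strong fragment-ion sink (mechanism 1) and the
  cluster-mediated adduct channel are phenomenological models chosen to
  reproduce the observed class behaviours with defensible chemistry;
  they are not fitted to any measured rate data.
* Scenario YAML merging is shallow for list fields: to *remove* a field
  such as `overlaps`, assign it directly on the loaded scenario rather
  than passing an empty list through `overrides`.
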