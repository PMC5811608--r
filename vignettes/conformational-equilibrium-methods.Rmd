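---
title: "Methods: quantifying the closed-open equilibrium of prothrombin"
author: "protconf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the closed-open equilibrium of prothrombin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`protconf` packages four complementary analyses around one scientific
question: in what conformation does prothrombin spend its time in
solution, and how does that conformation steer its activation to thrombin?
This vignette explains the models behind each stage, the parameters that
matter, what the synthetic-data generators do and do not emulate, and the
numerical choices a user may want to revisit.

## 1. Burst-level smFRET with pulsed interleaved excitation

Freely diffusing, dual-labelled molecules cross a confocal volume and emit
photon bursts. Each photon carries a detection channel (donor or acceptor
emission) and an excitation slot (donor or acceptor laser of the
alternating scheme). We represent the interleaved excitation purely by the
per-photon slot label; nanosecond lifetimes are out of scope.

**Burst search.** `find_bursts()` implements the all-photon burst search:
a photon is inside a burst region when the window of width 0.5 ms centred
on it contains at least `m = 10` photons; maximal runs of in-burst photons
closer than one window are merged, and only bursts with *strictly more
than* 35 photons are kept. The window (0.5 ms) and the total-count
threshold (35) are the instrument-calibrated values this analysis was
built around; the local threshold `m` is not published for this
instrument, so it is exposed as a parameter and recorded in the run
manifest. Whether "integration time 0.5 ms" denotes the search window or
a binning time is ambiguous in the source material; we adopt the search
window reading, and `m` together with `window_ms` lets a user reproduce
the binned-counting variant as well.

**Corrections.** Per burst, `compute_es()` applies the standard
PIE corrections with defaults `Lk = 0.08` (donor leakage into the acceptor
channel), `DE = 0.15` (direct acceptor excitation by the donor laser) and
`γ = 0.85` (detection-efficiency/quantum-yield imbalance):

$$F_{corr} = F_{DA} - Lk\,F_{DD} - DE\,F_{AA}, \qquad
  E = \frac{F_{corr}}{F_{corr} + \gamma F_{DD}}, \qquad
  S = \frac{F_{corr} + \gamma F_{DD}}{F_{corr} + \gamma F_{DD} + F_{AA}}.$$

Corrected E may fall slightly outside [0, 1]; that is expected and the
histogram range (−0.1 to 1.1 by default) accommodates it. The
stoichiometry gate `0.25 ≤ S ≤ 0.75` (boundaries inclusive — a recorded
convention, ties are measure-zero) removes donor-only and acceptor-only
molecules. Donor emission under acceptor excitation carries no FRET
information and is reported only as a diagnostic count.

## 2. Population analysis

`build_histogram()` bins gated efficiencies (default width 0.025 over
−0.1…1.1; out-of-range values are clipped into the end bins and counted).
`fit_mixture()` fits a sum of k Gaussians to the bin counts — histogram
least squares, the same level of description used by desktop
curve-fitting programs for these data — and `select_by_aicc()` picks k by
the corrected Akaike criterion

$$\mathrm{AICc} = n \ln(\mathrm{RSS}/n) + 2p + \frac{2p(p+1)}{n-p-1},
  \qquad p = 3k + 1,$$

with n the number of bins between the first and last populated bin (empty
tails carry no information and are excluded; padding the range therefore
does not change the fit, which is tested). Occupancies are Gaussian area
shares, `amplitude·sigma / Σ amplitude·sigma`; reporting areas rather
than amplitudes is a deliberate convention, since widths differ between
populations.

Two numerical choices deserve explanation:

* **Shot-noise weighting.** Bin counts are Poisson; residuals are weighted
  by `1/sqrt(max(count, 1))` so that a 600-count peak bin and a 6-count
  tail bin are compared on a common variance scale. Plain least squares is
  available (`weighting = "none"`).
* **Minimum component separation (0.1).** Centers are parameterised as a
  first center plus non-negative gaps bounded below by 0.1 efficiency
  units — the same resolution this analysis uses to call a difference
  between experimental and structure-predicted efficiencies significant.
  Without this constraint a second, concentric Gaussian can always absorb
  the small kurtosis that shot noise imprints on a single-state peak
  (burst sizes vary, so the peak is a scale mixture of binomial widths),
  and AICc would select it at large burst numbers. Components closer than
  the resolution limit are not interpretable as distinct conformational
  states, so we exclude them a priori.

Even so, the corrected-E estimator is a nonlinear ratio of counts: with
the full (Lk, DE, γ) corruption embedded, its distribution is measurably
left-skewed, and with several thousand bursts a Gaussian mixture resolves
that skew as a real extra component. We verified the selection machinery
is consistent — with undistorted streams, the generating k ∈ {1, 2, 3} is
selected in ≥95% of replicates at 5000 bursts — and we quantify
equilibrium fractions from a fixed two-component fit when the system is
known to be two-state, exactly as a double-Gaussian fit is used for the
prothrombin/meizothrombin comparison. The residual ~0.02–0.04 upward bias
of the minor low-FRET component's fitted center under embedded
corrections is a documented limitation of Gaussian decomposition, not of
the corrections themselves (the pooled corrected efficiency round-trips
the embedded truth to <0.001).

## 3. Synthetic photon streams

The generator (`sim_config()`, `simulate_bursts()`,
`simulate_photon_stream()`) is burst-based: bursts arrive as a Poisson
process (default 25 /s), each carries a log-normal photon total (mean 60,
log-sd 0.45 — brightness distributions are not published for this
instrument, so the law and both parameters are configurable), photons
split ~50/50 between excitation slots, and each burst belongs to one
conformational state of the configured mixture or to a donor-only /
acceptor-only species. No 3-D diffusion is simulated: the downstream
analysis only ever sees photon clusters, so burst-level generation is the
faithful minimal model. Background photons are Poisson per
channel-excitation combination (defaults of a few hundred per second).

The forward corruption is chosen so the inverse corrections of
`compute_es()` undo it *exactly in expectation*: the FRET partition is a
binomial draw at the state efficiency; acceptor-path photons are thinned
by γ; leakage photons are spawned as `Binomial(F_DD, Lk)` extra
acceptor-channel counts; direct-excitation photons as
`Binomial(F_AA, DE)`. What the generator deliberately omits: blinking and
bleaching, detector dead time and afterpulsing, diffusion-path brightness
profiles, and inter-molecule photophysical heterogeneity. Passing the
round-trip and recovery tests therefore demonstrates correctness of the
analysis chain, not robustness to every artifact of real measurements.

## 4. Accessible-volume FRET prediction

`compute_av()` re-implements the single-radius geometric dye model: on a
0.9 Å lattice around the attachment atom (Cβ when present, else Cα — the
labelled residues are surface serines/cysteines), a lattice point is a
valid dye position if it lies within geodesic distance L of the
attachment and the dye sphere does not clash with any protein atom
(van der Waals radius + dye radius). The geodesic is computed by
label-correcting flood fill through points with linker clearance
(vdW + w/2) using a 5×5×5 chamfer stencil; the wider stencil keeps the
lattice-metric overestimate below ~2% (a 26-neighbour metric errs by up
to ~8%, which visibly shrinks unobstructed clouds). Defaults L = 20 Å,
w = 4.5 Å, r = 3.5 Å are conventional for maleimide-linked AF555/AF647;
all are configurable and recorded. The linker-width tunnel requirement is
a simplification of the full three-radius dye model and is documented as
such.

`mean_fret()` averages `E = 1/(1+(R/R₀)⁶)` over donor-acceptor point
pairs — the dynamic-averaging convention, appropriate because dyes
explore their clouds fast relative to a ~1 ms burst; `E(⟨R⟩)` is not what
an intensity-based measurement reports. R₀ defaults to 51 Å for
AF555/AF647 (a literature convention, not a measured value for this
instrument pair) and every prediction records the R₀ used. Pair
enumeration is exhaustive up to `n_samples` pairs, Monte-Carlo beyond,
seeded and reproducible.

## 5. Surface areas and SAXS

`sasa()` is a direct Shrake–Rupley implementation (960 golden-spiral
sphere points per atom, probe 1.4 Å); `buried_surface_area()` reports the
two-sided ΔSASA, `SASA(A) + SASA(B) − SASA(A∪B)`, plus the one-sided
areas, because the convention behind a published "buried area" number is
often unstated and the two differ by a factor ~2.

`debye_profile()` computes the orientation-averaged scattering of one
uniform bead per residue (Cα positions); no excluded-volume or hydration
terms, which is sufficient for ranking compact versus elongated models in
the q ≤ 0.3 Å⁻¹ range used here — absolute χ values against real
measured curves would require the fuller form-factor treatment and are
out of scope. `chi_fit()` finds the least-squares scale in closed form
and reports `χ = sqrt(mean(((I_exp − c·I_mod)/σ)²))`; experimental points
are interpolated onto the model grid linearly and extrapolation is
refused.

## 6. Activation kinetics

The continuous chromogenic assay couples two reactions. At 10 nM
prothrombin — far below the activation KM — activation is pseudo-first
order and only the specificity constant matters:
`T(t) = S₀(1 − exp(−(kcat/KM)·E₀·t))` with E₀ = 2.5 pM prothrombinase.
The thrombin produced hydrolyses 24 µM chromogenic substrate with
Michaelis–Menten kinetics (`dC/dt = −kcat_c·T·C/(KM_c + C)`, integrated
with `lsoda` at tight tolerance), and absorbance is
`ε·ℓ·(C₀ − C) + baseline`. Early in the reaction the curve is parabolic,
`A ≈ ½ ε ℓ v_c (kcat/KM) E₀ S₀ t²`, which provides both a sanity check
and the `initial_slope` estimation method. The thrombin turnover
constants on the reporter substrate (`kcat_c = 50 s⁻¹`, `KM_c = 10 µM`)
and `ε·ℓ = 9920 M⁻¹` are placeholders documented as such — they cancel
out of the fit only partially, so real analyses should supply calibrated
values. A multiplicative `activity_factor` on `kcat_c` models variants
whose product hydrolyses the reporter poorly (for example when a
covalently attached fragment obstructs the active site); fitting with the
wrong factor biases kcat/KM proportionally, which is tested.

`fit_specificity_constant()` fits the single kinetic parameter on a log
scale (positivity) with the baseline co-fitted, weights by `1/σ` when
uncertainties are present, and reports a Jacobian-based standard error.
Full-curve fitting is the default; the initial-slope lineariser is kept
for comparison and agrees within ~10% on well-sampled curves.

## 7. Problem sizes, determinism, degenerate inputs

The shipped tests and the acceptance script use 100-replicate oracle
comparisons for the burst search, 100 replicates × 5000 bursts for
selection consistency, 3000–5000-burst datasets for recovery studies, and
240 s simulated measurements for the end-to-end equilibrium recovery —
sizes chosen so each study carries enough statistics for its stated
tolerance while the whole suite runs in minutes on one CPU. Every
stochastic step takes an explicit seed and restores the caller's RNG
state; reruns are byte-identical. Degenerate inputs fail loudly: empty
photon streams yield empty burst lists (not errors), bursts with no
corrected signal are flagged and excluded, fully occluded labelling sites
name the residue, disjoint q-ranges and overlapping residue groups are
refused, and a flat progress curve returns a zero rate flagged
unreliable.

## 8. Known limitations

* Histogram-level Gaussian fitting cannot represent shot-noise skew; see
  §2 for the consequences and mitigations.
* The AV model is geometric: no dye-protein interactions, no weighting of
  positions by linker conformational entropy.
* The Debye forward model omits solvent terms, so χ values are comparable
  between models but not against published absolute fits of measured
  profiles.
* Activation is modelled strictly pseudo-first-order in the zymogen,
  which is valid only well below the activation KM (the regime of the
  10 nM assay); saturating substrate regimes are not supported.
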