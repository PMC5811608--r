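# protconf

Prothrombin — the zymogen of thrombin — circulates in blood as an
equilibrium between a **closed** conformation, in which kringle-1 collapses
onto the protease domain, and an elongated **open** conformation. The
closed form dominates in solution (~80%) and dictates where the
prothrombinase complex cleaves first, and therefore which activation
pathway (meizothrombin vs prethrombin-2) produces thrombin. `protconf`
implements the computational analyses by which that equilibrium is
established and quantified:

* **Burst analysis of single-molecule FRET with pulsed interleaved
  excitation (PIE).** All-photon burst search (0.5 ms sliding window,
  bursts with more than 35 counts), partition of each burst into
  `F_DD`/`F_DA`/`F_AA` channel counts, and the corrected FRET efficiency
  and stoichiometry

  `F_corr = F_DA − Lk·F_DD − DE·F_AA`,
  `E = F_corr / (F_corr + γ·F_DD)`,
  `S = (F_corr + γ·F_DD) / (F_corr + γ·F_DD + F_AA)`

  with leakage `Lk = 0.08`, direct excitation `DE = 0.15`, `γ = 0.85` and a
  stoichiometry gate `0.25 ≤ S ≤ 0.75` as defaults.
* **Population analysis.** Efficiency histograms, sums of Gaussians fitted
  by shot-noise-weighted least squares, the number of populations selected
  by the corrected Akaike information criterion (AICc), and occupancies as
  Gaussian area fractions.
* **Structure-based FRET prediction.** Accessible-volume (AV) dye
  simulation on a lattice: the cloud of sterically allowed dye positions
  given linker length L = 20 Å, width 4.5 Å, dye radius 3.5 Å, and the
  predicted efficiency `⟨E⟩ = ⟨1/(1 + (R/R₀)⁶)⟩` averaged over
  donor–acceptor pair distances (R₀ = 51 Å for the AF555/AF647 pair).
* **Structural measurements.** Shrake–Rupley solvent-accessible surface
  area, buried interface area between residue groups, Cα–Cα distances.
* **SAXS model discrimination.** Debye-formula forward profiles
  (`I(q) = Σᵢⱼ fᵢfⱼ sin(q rᵢⱼ)/(q rᵢⱼ)`, one bead per residue) and
  scale-fitted χ ranking of candidate structures against a measured curve.
* **Activation kinetics.** The coupled chromogenic prothrombinase assay —
  thrombin generated as `T(t) = S₀(1 − exp(−(kcat/KM)·E₀·t))`, feeding
  Michaelis–Menten hydrolysis of a reporter substrate — and weighted
  nonlinear least-squares estimation of the specificity constant kcat/KM.
* **Synthetic data with ground truth** for every input: PIE photon streams
  from a configurable conformational mixture with embedded corrections and
  background, two-domain toy structures with exact labelled-site
  distances, noisy Debye scattering curves, and progress curves.

## Worked example

```r
library(protconf)

# an 80/20 closed/open mixture, measured for 4 minutes
cfg <- sim_config(duration = 240, burst_rate = 25,
                  states = data.frame(fraction = c(0.8, 0.2),
                                      E = c(0.58, 0.16)), seed = 1)
sim    <- simulate_photon_stream(cfg)
bursts <- find_bursts(sim$stream)                       # APBS, >35 counts
es     <- compute_es(integrate_bursts(sim$stream, bursts))
gated  <- filter_stoichiometry(es)                      # S in [0.25, 0.75]
fit    <- fit_mixture(build_histogram(gated), k = 2, seed = 1)
population_fractions(fit)
#>      center      sigma  fraction
#> 1 0.1894639 0.12510406 0.2386189
#> 2 0.5787778 0.09240667 0.7613811
```

The two Gaussian populations recover the generating equilibrium: a
dominant high-FRET (closed) population at E ≈ 0.58 occupying ~76% and a
minor low-FRET (open) population at low E. On the structural side:

```r
toy <- generate_toy_structure(separation = 54, seed = 2)  # 54 Å dumbbell
ca_distance(toy, 1, 41)       # the two labelled sites
#> [1] 54
mean_fret(compute_av(toy, 1, atom = "CA"),
          compute_av(toy, 41, atom = "CA"), R0 = 51)
#> fret_prediction: <E> = 0.538, <R> = 50.0 A (R0 = 51.0 A, Monte-Carlo, 200000 pairs)
```

The dye clouds reach toward each other across the 54 Å gap, so the mean
inter-dye distance (50 Å) is slightly shorter than the Cα separation and
the predicted efficiency sits just above one half.

Deposited coordinates can be analysed the same way
(`read_structure()`, `buried_surface_area(model, c(65, 143), c(285, 579))`
for the kringle-1/protease interface, `fetch_pdb("6C2W")` when a network
is available).

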