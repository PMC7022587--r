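# einshdx

Tools for quantifying the dynamics of proteins and protein-lipid assemblies
(lipoproteins in particular) from two complementary experiments:

- **Elastic incoherent neutron scattering (EINS)** — how soft or rigid is the
  particle as a whole? The package extracts the hydrogen mean-square
  displacement `<u²>(T)` from the Q²-dependence of elastic intensities under
  the Gaussian approximation, and converts segmented MSD-versus-temperature
  slopes into effective force constants (resilience).
- **Hydrogen-deuterium exchange mass spectrometry (HDX-MS)** — how mobile is
  each part of the protein backbone? The package computes random-coil
  (intrinsic) amide exchange rates, deconvolves bimodal isotopic envelopes
  into coexisting slow- and fast-exchanging populations, fits stretched
  exponential uptake kinetics, derives protection factors, pools peptides
  into chain populations (helical dimer vs hairpin monomer) by relative
  abundance, and resolves residue-level protection factors from overlapping
  peptides by iterative permutation.

Both arms ship with synthetic-data generators that produce elastic scans and
deuterated isotopic peak lists with known ground truth, so every stage of the
analysis can be validated by round trip.

## The models in brief

**EINS.** The elastic intensity obeys the Gaussian approximation

    I_el(Q, ω = 0 ± ΔE) ≈ I₀ exp(−⟨u²⟩ Q² / 6),

valid while `⟨u²⟩Q² ≲ 2`, so a weighted regression of `ln I` on `Q²` gives
`⟨u²⟩ = −6 · slope` per temperature. The MSD(T) curve of hydrated
protein/lipid powders typically shows three linear domains (slope changes
near 200 and 250 K); per-segment resilience is

    ⟨k⟩ = 0.00276 / (d⟨u²⟩/dT)   [N/m, with ⟨u²⟩ in Å² and T in K].

Small `⟨k⟩` means a soft, flexible particle; large `⟨k⟩` a rigid one.

**HDX-MS.** Deuterium incorporation (DI) is read from the isotopic-envelope
centroid against 0% and maximally (80%) deuterated controls, which also
corrects back exchange. Peptides that exist in two conformations or
environments show *bimodal* envelopes; these are deconvolved into a slow and
a fast population (mixture of isotope-pattern-convolved deuteration
distributions), and the minor/major abundance ratio at the first time point
classifies each peptide's origin (ratio ≈ 1 → dimer pool, ratio < 1 →
monomer pool; unimodal peptides join both). Per population, uptake is fitted
with stretched exponentials `DI(t) = Σ_p N_p (1 − exp(−(k_p t)^β_p))`, and
the protection factor of a phase is `Pf = k_rc / k_obs`, the factor by which
structure slows exchange relative to the unstructured chain (`k_rc` from the
poly-DL-alanine reference rates with side-chain, terminal, pD and Arrhenius
temperature corrections). Residue-level Pf values are obtained by permuting
each peptide's Pf multiset across its exchangeable residues until overlapping
peptides agree; classes are mapped red (Pf < 10), orange (10–100), green
(100–1000), blue (≥ 1000), black (proline), grey (undetermined).

## Worked example

```r
library(einshdx)

# --- EINS: simulate a stepped 20-305 K scan and refit it -------------------
ds     <- make_elastic_dataset(in13_config(),
                               msd_model(force_constants = c(1.00, 0.25, 0.15)))
series <- fit_msd_series(ds)
tail(series, 2)
#>    temperature    msd    msd_sigma valid_fraction
#> 24         300 2.0188 1.066085e-16         0.3125
#> 25         305 2.1108 8.859453e-17         0.3125

fit_force_constants(series)
#> Effective force constants (resilience) per temperature segment
#>      20 -   200 K: <k> = 1 +/- 1.7e-16 N/m (slope 0.00276 A^2/K, n = 12)
#>     200 -   250 K: <k> = 0.25 +/- 3.3e-16 N/m (slope 0.01104 A^2/K, n = 6)
#>     250 -   305 K: <k> = 0.15 +/- 5.9e-17 N/m (slope 0.0184 A^2/K, n = 9)

# --- HDX: average random-coil rate of an apoA-I peptide --------------------
cond <- exchange_conditions(pD = 7.2, temperature = 273.15)
average_rc_rate(peptide_record("EDLRQGLLPVL", 212, 222), cond)
#> Stretched-exponential fit: k_avg = 0.09206 /s, beta = 0.546 (N = 8, resid 2)
```

The MSD reaches 2.11 Å² at 305 K and the three refitted force constants
return the generating resilience values exactly; the 11-mer peptide has 8
exchangeable amides (two N-terminal residues excluded, one proline) and an
average intrinsic rate of 0.092 s⁻¹ at pD 7.2, 0 °C, with β < 1 reflecting
the spread of per-residue rates. `run_pipeline(run_config())` runs both arms
end to end and writes MSD/force tables, a per-peptide fit report, the
residue-level Pf map and a run log.

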