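---
title: "Models and methods: resilience from elastic scans and protection factors from HDX-MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(einshdx)
```

This vignette documents the models the package implements, the tunable
parameters and their defaults, the numerical choices behind each fit, what
the synthetic-data generators do and do not emulate, and the design
decisions taken where the methodology left the choice open.

## 1. Elastic incoherent neutron scattering

### Model

Neutrons scattered with no energy exchange report on the averaged motion of
hydrogen atoms, whose incoherent cross-section dominates in biological
samples. In the Gaussian approximation the elastic intensity at momentum
transfer $Q$ is

$$ I_{el}(Q, \omega = 0 \pm \Delta E) \approx I_0 \exp(-\tfrac{1}{6} \langle u^2 \rangle Q^2), $$

strictly valid as $Q \to 0$ and usable up to $\langle u^2 \rangle Q^2 \approx 2$.
`fit_msd()` therefore regresses $\ln I$ on $Q^2$ and reports
$\langle u^2 \rangle = -6 \times \text{slope}$, with the uncertainty propagated from
the fit covariance. Weights are $1/\sigma^2$ with $\sigma_{\ln I} = \sigma_I / I$;
when every $\sigma$ is zero (noise-free synthetic data) the fit is unweighted, which is
exact there. Degenerate inputs error out: fewer than 3 points, non-positive
intensities, or an all-equal $Q$ design.

The temperature dependence of the MSD carries the resilience information.
Hydrated protein/lipid powders show approximately piecewise-linear
$\langle u^2 \rangle(T)$ with slope changes near the dynamical transition
(~200 K) and a second, lipid-associated transition (~250 K). Per segment,

$$ \langle k \rangle = \frac{0.00276}{\mathrm{d}\langle u^2 \rangle / \mathrm{d}T} \quad [\mathrm{N/m}], $$

with $\langle u^2 \rangle$ in Å² and $T$ in K. **Orientation of this relation:**
written as a product it would make the steepest MSD slope the *largest*
constant; the published resilience tables do the opposite (the softest
regime, with the largest slope, carries the smallest constant, e.g.
0.067 N/m above 250 K for the discoidal particle). The package therefore
implements the quotient form throughout, and the generator parameterises its
piecewise MSD model by force constants so the round trip is exact.

### Parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| Q window | 0.52–2.06 (thermal), 0.54–1.85 (cold) | Å⁻¹ | instrument windows where ln I is linear in Q² |
| breakpoints | 200, 250 | K | published inflection points; user-configurable, `search_breakpoints()` offers an exhaustive grid search |
| bin width (ramp) | 5 | K | matches binning of continuous 0.3 K/min ramps |
| validity limit | `msd * Q^2 <= 2` | — | Gaussian-approximation bound; warn-only policy, the fixed window is retained |

Breakpoint temperatures belong to both adjoining segments, consistent with a
continuous piecewise-linear curve; a segment with non-positive slope is
flagged `rigid/undefined` rather than converted to a (negative) constant.
Ramp binning anchors bins at the lowest scan temperature,
$[T_0 + 5n, T_0 + 5(n+1))$, averages intensities per Q point, combines
uncertainties in quadrature over $n$, and reports the bin centre.

### What the generator emulates

`make_elastic_dataset()` produces one scan per protocol temperature
(stepped: 20–160 K by 20, 170–280 K by 10, 285–305 K by 5; ramp: one scan
per 0.3 K) with exact Gaussian-approximation intensities plus optional
Gaussian noise of per-point standard deviation
$\mathrm{noise} \times \sqrt{I/I_{max}} \times I_{max}$ — counting-statistics-like and
seeded. It does **not** emulate multiple scattering, absorption geometry
(normalisation accepts a scalar transmission instead of Paalman–Pings
coefficients), detector efficiency maps, or quasi-elastic broadening, so
passing round trips validate the estimator chain, not a full instrument
simulation.

## 2. Intrinsic (random-coil) exchange rates

Backbone amide exchange in an unstructured chain follows acid-, base- and
water-catalysed channels:

$$ k_{rc} = k_A 10^{-pD} A_L A_R + k_B 10^{pD - pK_D} B_L B_R + k_W B_L B_R, $$

with reference rates from the poly-DL-alanine calibration (protium protein
into D₂O: $\log_{10} k_A = 1.62$, $\log_{10} k_B = 10.18$ per M per min,
$\log_{10} k_W = -1.5$ per min at 293.15 K, $pK_D = 15.05$), side-chain
factors $A, B$ (a residue's own $\lambda$ and its left neighbour's $\rho$,
in log₁₀ units), free-amine and carboxylate terminal factors, and Arrhenius
scaling with activation energies 14/17/19 kcal/mol for the acid/base/water
channels. Titratable side chains (Asp, Glu, His; pK in D₂O 4.48, 4.93,
7.42) mix their protonated and deprotonated factors by the standard
log-space interpolation, as does the C-terminal carboxyl (pK 3.66). The
constant table is versioned (`exchange_constants()$version`) and swappable.
$pK_D$ is held fixed with temperature; only the channel rate constants carry
Arrhenius scaling. At the 273.15 K working temperature this convention is
self-consistent between generator and analysis, which is what the recovery
targets exercise.

Rates are computed in the *peptide* frame (the peptide's own termini carry
the terminal factors), matching how digested peptides are usually analysed;
passing the full protein as one `peptide_record` gives the protein-frame
rates instead. Prolines have no amide and carry `NA`. The first two
residues are excluded by default (`n_term_excluded = 2`): residue 1 has no
amide proper and residue 2 back-exchanges faster than the earliest
measurable time point, so `N_exch = length − 2 − #prolines`.

**Average rate and adaptive grid.** `average_rc_rate()` fits
$DI(t) = N(1 - \exp(-(k t)^\beta))$ to the analytic multi-exponential curve on 30
log-spaced times between the curve's 1% and 99% average-completion times.
Anchoring the grid to completion makes the fit exactly scale-equivariant:
dividing all rates by $c$ divides the fitted $k$ by $c$ and leaves $\beta$
unchanged. This is the property that makes protection-factor recovery by
ratio of fitted rates exact for uniformly protected domains, and it is the
procedure used for the headline Pf recovery computations (which come back
at the generating values of 14 and 1 to ~10 significant digits).

## 3. Envelopes, bimodality and deconvolution

Isotopic fine structure is computed from residue elemental compositions by
aggregated-variant convolution truncated at $10^{-4}$ relative abundance;
deuteration adds 1.00628 Da per D. Deuterated envelopes are the fine
structure convolved with the distribution of exchanged-site counts — the
exact Poisson–binomial of the per-site probabilities
$p_i = f_D (1 - e^{-k_i t})(1 - bx)$ in the generator.

`deconvolve_bimodal()` fits an observed envelope as a mixture of two
components built from the measured 0% envelope shape. Two component
families are available:

- **Binomial** (default): $\mathrm{Binom}(N_{exch}, p)$ deuteration, the
  natural choice when nothing is known beyond the peptide's site count.
- **Rate-informed** (used by the pipeline): the random-coil site-rate
  pattern slowed by a single effective protection, i.e. the
  Poisson–binomial of $r(1 - e^{-k_i \tau})$ with $\tau$ root-found so the
  mean equals the component's $p$, and $r$ the deuterium retention from the
  80% control. On rate-heterogeneous peptides the binomial family
  systematically misallocates mixture weight (we measured ~0.12 weight bias
  on a realistic 12-mer); the rate-informed family removes this bias while
  adding no free parameters.

Fitting proceeds by a coarse grid over component deuterations (step 0.02)
with the closed-form conditional weight per pair, Nelder–Mead refinement of
$(p_1, p_2, w)$, and three coordinate-polish sweeps (exact weight, then 1-D
refits of each $p$ at tolerance $10^{-10}$ — these matter when a component
sits at $p = 0$). Envelope comparison happens on a 0.01 m/z grid with
linear intensity sharing between adjacent bins, so the objective is
continuous in m/z and immune to bin-edge rounding. One- versus
two-component selection is a BIC-style test with a conservative
$\Delta BIC > 10$ threshold; near-degenerate fits (component separation
< 0.25 D or a weight < 0.02) collapse to unimodal. Relative abundance is
read at the earliest bimodal time point, where centroids are maximally
separated; if the first point is unimodal the earliest bimodal one is used
and flagged.

## 4. Kinetics, pooling and residue-level assignment

`fit_biphasic()` models one population's corrected uptake as one or two
stretched-exponential phases with the amplitudes constrained to
$N_{exch}$ ($N_{fast} + N_{slow} = N_{exch}$, split fitted through a logistic
transform or fixed via `n_fast`). $\beta \in [0.3, 1]$ guards against degenerate
stretches on sparse experimental grids. Phase count is chosen by corrected
AIC; with 6 time points and 5 parameters the AICc correction is undefined,
so plain AIC is used there (residuals floored at $10^{-12}$ so noise-free
fits cannot produce infinite evidence). Initialisation is a seeded
multistart over rate scales bracketing the mid-uptake crossing time.

Protection factors are $Pf = k_{rc}/k_{obs}$ — protected means $Pf \ge 1$.
(The methodology description this follows can be read as the inverse ratio,
but reported protection values in the thousands for slow exchange require
this orientation.) Phase site counts are rounded to integers by largest
remainder, constrained to sum to $N_{exch}$; remainder ties resolve by
first occurrence.

**Pooling.** Bimodal peptides with minor/major ratio below the 0.75 cutoff
send their major population (abundance 1) to the helical-dimer pool and the
minor one to the hairpin-monomer pool; ratios at or above the cutoff are
treated as "abundance ≈ 1" — both populations go to the dimer pool flagged
ambiguous. Unimodal peptides join both pools. The cutoff is configurable;
observed ratios cluster near 1 and near 0.5, so any boundary between those
clusters behaves identically.

**Residue-level assignment.** Each pool peptide carries a Pf multiset (each
phase's Pf repeated by its site count) over its exchangeable residues.
Starting from a seeded random placement, within-peptide swap moves — which
preserve the multiset by construction, asserted on every accepted move —
greedily reduce the inconsistency cost: the sum over covered residues of
the variance of the assigned values across covering peptides. Agreement is
judged at colour-class level by default (`level = "exact"` compares log₁₀
Pf), because peptide-level average Pf values for the same residue
legitimately differ within a class. Termination: cost 0, or 200 proposals
without improvement; 20 seeded restarts. Instances whose total arrangement
space is ≤ 10⁵ are solved exhaustively instead, which is also the
independent oracle used in the tests. If no zero-cost assignment exists the
best map is returned with conflicting residues reported and marked grey —
never silently.

## 5. What the HDX generator does and does not emulate

Emulated: overlapping digests (generic random cut model around a mean
length with gap filling to ≥ 95% coverage), per-residue protection for two
chain pools, one- or two-population mixtures at set abundance, isotopic
fine structure, uniform back exchange (default 12%, the reported average)
with 0% and 80% controls, labeling at pD 7.2 and 0 °C with time points
{30, 100, 300, 1000, 3000, 10000} s, and seeded counting-like intensity
noise. Envelope peak m/z widths are idealised (stick spectra): the source
instrument's resolution was not reported, so envelope width is a free
emulation parameter and the package works on centroided peak lists.

Not emulated: chromatographic peak shapes and retention-time alignment,
charge-state interference, EX1/EX2 mechanistic switching (protection
factors are static per pool), pD-gradient quench kinetics, and
side-chain/labile-proton exchange. Passing tests therefore validate the
estimator chain against its own forward model — they do not certify
performance on raw instrument files, which enter through the peak-list TSV
interface (mzML import is a documented extension point).

## 6. Problem sizes and reproducibility

The test suite and the acceptance script run at the sizes the analyses
naturally have: full 25-temperature stepped scans and 967-sample ramps
binned to 58 points for the EINS arm; single- and two-peptide HDX datasets
at the six experimental time points for deconvolution and kinetics; a
150-peptide digest of the 243-residue protein for coverage properties; and
a two-peptide 66-residue protein for the end-to-end pipeline determinism
check (chosen so the exhaustive assignment oracle stays enumerable). All
randomness flows from explicit integer seeds; fixed seeds give
byte-identical output files.

## 7. Known limitations

- Back-exchange correction is peptide-uniform (two-point control mapping),
  not residue-resolved.
- Per-phase Pf uses the peptide-average random-coil rate, so a single
  residue with an unusually slow *intrinsic* rate can surface as an
  apparently protected slow phase; the residue-level permutation step
  inherits this convention.
- The dimer/monomer pool labels encode the abundance logic of a
  three-chain (dimer + hairpin) particle; other stoichiometries need their
  own pooling rule.
- `search_breakpoints()` minimises total weighted RSS over two
  breakpoints only.
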