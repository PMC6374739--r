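---
title: "Quantifying dimer/monomer FRET: the model behind fretquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dimer/monomer FRET: the model behind fretquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretquant)
```

## The measurement problem

A homodimerizing photoreceptor such as the plant UV-B receptor UVR8 changes
its oligomeric state with light: the dimer dissociates into signaling-active
monomers under UV-B, and the population settles into a photo-equilibrium
between the two forms. Tagging the protein with a GFP donor and an mCherry
acceptor turns that state change into a Förster resonance energy transfer
(FRET) signal that a confocal microscope can read out in live tissue.

`fretquant` implements the two classical confocal readouts of that signal —
the sensitized-emission intensity ratio and the acceptor-photobleaching
donor-dequenching percent increase — together with a physics-based synthetic
image generator. The generator exists so that every stage of the
quantification can be validated by parameter recovery: we render fields whose
ground-truth transfer efficiency is known exactly, run the same estimators a
microscopist would run, and check that they return the truth.

## The two-source transfer model

Transfer efficiency of a single donor–acceptor pair follows the Förster law

$$E(r) = \frac{R_0^6}{R_0^6 + r^6},$$

with `R0` the Förster radius (default 5.0 nm, the GFP–mCherry scale). Two
labelling schemes are modelled:

* **Dual-tag, single molecule** (`construct = "NcCg"`): the acceptor sits at
  the N-terminus and the donor at the C-terminus of every molecule. A
  monomer's donor has one pathway (intramolecular, efficiency `E_intra`). A
  dimer's donor has two: intramolecular plus a cross-monomer pathway
  (`E_inter`). Competing first-order depopulation pathways combine by *rate*
  additivity: with odds $o_i = e_i/(1-e_i)$, the combined per-donor
  efficiency is $\sum o_i / (1 + \sum o_i)$. The probabilistic-OR
  alternative $1 - \prod(1-e_i)$ overcounts (it gives the donor several
  independent chances to transfer) and is retained only behind
  `rule = "or"` for sensitivity analysis.
* **Co-expressed homotags** (`construct = "TwoInOne"`): donor-only-tagged and
  acceptor-only-tagged molecules co-expressed 1:1 from one vector. Dimers
  assort binomially into donor/donor, donor/acceptor and acceptor/acceptor
  species ($p^2, 2p(1-p), (1-p)^2$); only the mixed dimer transfers, via
  `E_inter`. Monomers cannot transfer at all, which is what makes this
  scheme a pure reporter of dimerization.

The observable consequences per pixel are (donor-weighted mean efficiency
$\bar E$, molecule density $\rho$):

* donor channel (488 nm excitation, 500–535 nm): $g_d\,\rho_d\,(1-\bar E)$ —
  the recorded donor intensity is the *post-transfer* value;
* FRET channel (488 nm excitation, 590–645 nm):
  $g_a\,\rho_d\,\bar E + \beta\,I_{donor} + \alpha\,g_a\,\rho_a$, where
  $\beta$ (`beta_bleed`, default 0.05) is donor emission bleeding into the
  acceptor band and $\alpha$ (`alpha_direct`, default 0.02) is direct
  acceptor excitation by the 488 nm line — the two classical false-positive
  artifacts;
* acceptor channel (552 nm excitation): $g_a\,\rho_a$.

Destroying a fraction $c$ of the acceptors rescales every transfer pathway's
rate by $1-c$; the expected donor dequenching is
$100\,(\bar E - \bar E')/(1-\bar E)$, which at complete bleach reduces to the
classical $100\,\bar E/(1-\bar E)$. Rate rescaling is a mean-field choice —
it treats a partially bleached acceptor population as a uniformly dimmer
sink rather than as a binomial mixture of intact and destroyed acceptors —
and it is what the renderer and the closed-form expectations both use, so
estimator checks compare like with like.

## What the generator emulates — and what it does not

`simulation_config()` describes one field of transiently transformed
epidermal-like tissue:

* **Geometry**: a Voronoi tessellation of `n_cells` convex cells with a
  2–4 px periphery band, where the tagged protein concentrates. Nuclear
  spots are available behind `nucleus = TRUE` but off by default.
* **Expression**: log-normal across cells (`expression_level = 15` molecules
  per periphery pixel, `expression_cv = 0.3`), emulating the broad
  cell-to-cell variability of transient transformation at a dim laser/gain
  setting.
* **Noise**: Poisson shot noise on the expected intensity (treated as a
  count; detector gain folded into the `g` factors) followed by Gaussian
  read noise (`noise_read_sd = 2` DN), clipped at zero. The zero clip
  mirrors non-negative detector output and is the reason background means
  sit slightly above zero — the "background interference" every
  intensity-ratio practitioner knows.
* **Condition defaults**: dimer fractions 0.85 (wild type, dark), 0.15
  (wild type, UV-B), 0.95 (constitutive dimer, UV-independent), and a 0.05
  residual for the constitutive monomer, modelling weak transient
  monomer–monomer contact. `E_intra = 0.15` and `E_inter = 0.30` are free
  parameters of plausible magnitude — no measured values exist for this
  construct pair — chosen once to reproduce the qualitative condition
  ordering, and exposed in `fret_params()`. UV-B is assumed not to change `E_intra`
  (no conformational rearrangement of the termini); pass a different
  `E_intra` for the +UV states to explore that hypothesis.
* **Photobleaching protocol**: five pre-bleach scans, an instantaneous
  in-region acceptor bleach of completeness 0.95 (a 50 s full-power
  acceptor-line bleach is strong but rarely total), five post-bleach scans,
  and a disjoint unbleached control region.

Not modelled: point-spread-function blur, 3-D sectioning, chromatic shifts,
stage drift, donor photobleaching during scans (available as the
`donor_fade` parameter, default 0), and fluorescence-lifetime effects.
Passing recovery tests on these synthetic fields therefore validates the
estimators' logic and noise behaviour, not their robustness to optical
artifacts absent from the model.

## The two estimators

**Sensitized-emission ratio.** Twenty 16×16 px regions per image are drawn
uniformly among positions whose donor mean exceeds a threshold (default:
the image mean), with ≤ 50 % pairwise overlap. Each region's ratio is
`mean(FRET channel) / mean(donor channel)`; ratios aggregate region → image
mean → experiment mean, and the standard error is taken across experiments
(the replication unit), never across pooled regions. The default protocol is
10 images × 20 regions × 5 experiments. The per-region-then-average
aggregation is one of two defensible readings of "mean fluorescence
intensity ratio"; the pooled alternative is available via `pooled = TRUE`.
Background subtraction is deliberately off by default, matching common
practice; on noiseless fields the estimator equals the closed form to
machine precision, while under the default noise model the clipped noise
floor inflates ratios slightly — a real artifact the model reproduces
rather than hides.

**Acceptor-photobleaching percent increase.** The cell periphery inside the
bleached region is traced automatically: Otsu threshold (with backoff to
half and quarter cuts for dim, partially framed cells), largest connected
object, hole fill, outline extraction, arc-length resampling to ~100 ordered
points, and snapping of each point to the local intensity ridge — the
placement a human operator uses. Tracing runs on the 3×3-smoothed
time-average of *all* scans: using the pre-scans alone would select positive
pre-noise fluctuations and bias the statistic downward by about a full
percentage point, whereas the pre+post average makes the selection symmetric
(validated against the closed form; residual bias is a few percent relative,
worst at the lowest efficiencies). Intensity at each point is the 3×3
neighbourhood mean sampled from the raw scans; `I_pre` and `I_pb` average
the five pre- and five post-scans, and the statistic is
$100\,(I_{Pb}-I_{Pre})/I_{Pre}$, reported alongside the same statistic on
the unbleached control region. If a control window frames too little
periphery to trace (a cell at the field edge; roughly 1 % of seeded
replicates), the control statistic falls back to the mask average with a
warning.

## Inference

Experiment-level responses enter a fixed-effects two-way ANOVA
(`value ~ genotype * uv`; sequential sums of squares for balanced designs,
Type II via `car::Anova` otherwise). Post-hoc pairwise comparisons use
pooled-MSE t statistics with Šídák adjustment $1-(1-p)^m$; the default
family is the three within-genotype ±UV pairs plus the three −UV
between-genotype pairs ($m = 6$), the contrasts such studies annotate.
Summaries report mean ± SE across experiments with stars on significant ±UV
contrasts at 0.05 and a compact letter display (greedy insertion over the
all-pairs adjusted-p matrix) at 0.01 — the two thresholds this kind of
figure uses for the ratio and photobleach panels respectively. The ANOVA
treats experiment means as replicates; the nested region/image structure is
deliberately not modelled as random effects.

## Numerical and design choices

* Coordinates are R-native: 1-based, `matrix[row, col]`, row = y.
* In-memory images are continuous; `write_acquisition()` /
  `write_bleach_series()` quantize to 16-bit DN (saturation clipping is
  warned about) and the readers return those integers exactly, so disk
  round-trips are bit-faithful to the quantized object.
* Channel-to-TIFF-page mapping travels in a YAML sidecar and is authoritative
  over page order; ground-truth efficiency/label maps ride along as a
  32-bit float companion TIFF.
* All randomness flows from explicit integer seeds; chained per-acquisition
  seeds are derived with exact double arithmetic kept below $2^{31}$.
* Degenerate inputs fail loudly: flat or structureless tracing targets,
  empty design cells, single-replicate cells, non-positive donor means,
  saturated (efficiency-1) donors.

## Validation strategy and problem sizes

The test suite validates each layer against something it cannot share code
with: the pathway combination against a kinetic Monte-Carlo simulation of
competing exponential clocks (9×9 efficiency grid, $10^5$ trials per point,
agreement within 1 %); the ANOVA against brute-force partition formulas
(equality to $10^{-9}$); the estimators against the closed-form model on
noiseless fields (≤ 0.1 % relative) and across an efficiency sweep
$\bar E \in \{0.05, 0.1, 0.2, 0.3, 0.4\}$ with default noise (perfect rank
recovery; photobleach means within ±15 % of the closed form over 20 seeded
replicates). The full default study grid — 2 constructs × 3 genotypes × ±UV
× 5 experiments × 10 images × 20 regions, plus 6 photobleach replicates per
condition — reproduces the expected pattern: a significant UV-induced
decrease for the wild type only, constitutive dimer ≈ dark wild type,
co-expression values below dual-tag values everywhere, and no detectable
dequenching for the co-expressed constitutive monomer. Null calibration
(type-I error of the headline ±UV comparison ≤ 8 % at α = 0.05 over 500
simulated studies) runs the full render → quantify → test chain at reduced
sizes (64×64 px fields, 1 image per experiment) chosen to keep the suite
fast while preserving the pipeline under test.

## A worked example

```{r example, eval = FALSE}
library(fretquant)

params <- fret_params()                      # E_intra 0.15, E_inter 0.30
dark <- population_state("NcCg", "WT", uv = FALSE)

# closed-form expectations
mix <- species_mixture(dark, params)
expected_sensitized_ratio(mix, params)       # ~0.60
expected_bleach_increase(mix, params, 0.95)  # ~48 %

# one synthetic acquisition and both readouts
acq <- render_acquisition(simulation_config(dark, params, seed = 42))
ratio <- sensitized_emission_ratio(
  select_random_regions(acq, n_regions = 20, seed = 7))
glance(ratio)

series <- render_bleach_series(simulation_config(dark, params, seed = 42))
bleach <- bleach_percent_increase(series)
glance(bleach)
autoplot(bleach)                             # pre/post periphery profiles

# a full in-memory study with inference
study <- run_study(seed = 1)
study$summaries$NcCg_ratio
autoplot(study$summaries$NcCg_ratio)
```

## Known limitations

* The 2-D, PSF-free rendering means segmentation and tracing are easier than
  on real confocal sections; tracing thresholds may need overriding
  (`threshold`, `min_area`) on real data.
* `E_intra`/`E_inter` defaults are plausible magnitudes, not measurements;
  all quantitative outputs of the synthetic study inherit them.
* The rate-rescaling partial-bleach model and the equal-brightness
  donor-weighting are mean-field simplifications.
* The sensitized-emission readout is not bleed-through-corrected (matching
  the protocol it implements); `beta_bleed`/`alpha_direct` let you study the
  size of the resulting false-positive floor, and the photobleaching readout
  is the artifact-robust cross-check.
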