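# fretquant

Quantify Förster resonance energy transfer (FRET) between a GFP donor and an
mCherry acceptor fused to a homodimerizing photoreceptor, and validate the
whole analysis chain on physics-based synthetic confocal images.

Plant UV-B photoreceptors such as UVR8 exist as homodimers that dissociate
into monomers under UV-B. With an acceptor at the N-terminus and a donor at
the C-terminus of each molecule, a dimer's donor can transfer energy through
two pathways — intramolecularly (efficiency `E_intra`) and across the dimer
interface (`E_inter`) — while a monomer keeps only the intramolecular
pathway; co-expressing donor-only-tagged and acceptor-only-tagged protein
1:1 instead yields a pure dimerization reporter, since only mixed dimers can
transfer. `fretquant` implements the forward model of these signals and the
two classical confocal readouts:

* **Sensitized-emission ratio** — the mean acceptor-band / donor-band
  intensity ratio under donor excitation over 20 randomly sampled regions
  per image, aggregated region → image → experiment, including the
  bleed-through (`beta_bleed`) and direct-excitation (`alpha_direct`)
  false-positive artifacts. With donor-weighted mean efficiency `Ē`,
  per-pixel expectations are `I_donor ∝ g_d (1 − Ē)` and
  `I_FRET ∝ g_a Ē + β I_donor + α g_a ρ_acceptor`.
* **Acceptor-photobleaching percent increase** — after five pre-bleach
  scans, an acceptor bleach, and five post-bleach scans, donor dequenching
  along ~100 traced cell-periphery points: `100 (I_Pb − I_Pre) / I_Pre`,
  which at complete bleach equals `100 Ē/(1 − Ē)`; an unbleached control
  region is reported alongside.

A seeded synthetic generator renders multi-channel epidermal-like fields
(Voronoi cells, periphery-band expression, log-normal cell variability,
Poisson + read noise) from any configured molecular state, so both
estimators can be checked by parameter recovery. Experiment-level inference
(two-way ANOVA genotype × UV with Šídák post-hoc comparisons, mean ± SE
summaries with stars/letters) completes the pipeline.

## A worked example

```r
library(fretquant)

params <- fret_params()                          # E_intra 0.15, E_inter 0.30
dark   <- population_state("NcCg", "WT", uv = FALSE)  # dimer-rich state

# closed-form expectations for this state
mix <- species_mixture(dark, params)
expected_sensitized_ratio(mix, params)
#> [1] 0.6023197
expected_bleach_increase(mix, params, bleach_completeness = 0.95)
#> [1] 48.19004

# render one field and run the ratio readout
acq   <- render_acquisition(simulation_config(dark, params, seed = 42))
ratio <- sensitized_emission_ratio(
  select_random_regions(acq, n_regions = 20, seed = 7))
glance(ratio)
#> # A tibble: 1 × 5
#>   mean_ratio    se n_experiments n_images n_regions
#>        <dbl> <dbl>         <int>    <int>     <int>
#> 1      0.659    NA             1        1        20

# render a photobleaching series and run the dequenching readout
series <- render_bleach_series(simulation_config(dark, params, seed = 42))
bleach_percent_increase(series)
#> <bleach_result> +46.6% donor increase (control -0.235%), 100 periphery-point samples
```

The measured ratio (0.659) sits a little above the closed form (0.602)
because the clipped read-noise floor inflates region means — the background
artifact real intensity ratios suffer from; the photobleach estimate
(46.6 %) recovers the expected 48.2 % dequenching, and the unbleached
control stays at zero.

A full study — both constructs, three genotypes (wild type, constitutive
monomer, constitutive dimer), ±UV, 5 experiments × 10 images × 20 regions
plus photobleach replicates, with ANOVA/post-hoc summaries — is one call:

```r
study <- run_study(seed = 1)
study$summaries$NcCg_ratio       # mean ± SE per condition, stars + letters
autoplot(study$summaries$NcCg_ratio)
```

Results follow broom conventions (`tidy()`, `glance()`) and every result
type has an `autoplot()` method. A thin command-line front end over the same
functions lives at `inst/cli/fretquant-cli.R`
(`simulate` / `quantify` / `stats` / `report` / `run-all`).

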