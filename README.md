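# abdecomp

Decomposition of the in vivo amyloid-PET signal into fibrillar and
nonfibrillar beta-amyloid plaque source components.

Amyloid-PET tracers were derived from thioflavin-T, which stains only
the dense, beta-sheet-rich (fibrillar) core of amyloid plaques — yet
mouse models whose plaques are mostly diffuse (nonfibrillar) still show
a clear PET signal. For anyone using amyloid PET as a preclinical
readout (or interpreting therapy-induced changes in plaque
composition), the question is how much signal each plaque compartment
produces. `abdecomp` answers it with a cross-modal regression pipeline
for two-genotype mouse studies:

1. **z-scoring** — PET SUV ratios are standardized against wild-type
   controls measured with the same reference region:
   `z = (SUVR − mean_WT) / sd_WT`.
2. **Pairing** — longitudinal PET observations are combined with
   cross-sectional immunohistochemistry (IHC) mice in all age- and
   genotype-matched combinations; nonfibrillar coverage is always
   derived as `total − fibrillar` percent area.
3. **Nested regression ladder** —
   `z ~ F`, `z ~ N`, `z ~ F + N`, `z ~ F + N + h`, `z ~ F + N + h + age`,
   where `F`/`N` are percent area covered by fibrillar/nonfibrillar
   amyloid and `h` is the heterogeneity covariate (an observation's
   deviation from its genotype-by-age group mean). Percentile bootstrap
   CIs (1000 case resamples) per coefficient.
4. **Coefficient synthesis** — the fibrillar and nonfibrillar
   coefficients of the two most complete models are averaged; their
   quotient is the fold ratio of tracer signal per percent coverage,
   with a plausible range from opposite CI edges.
5. **Decomposition & validation** — per-mouse contribution shares
   `share_N = β_N·N / (β_F·F + β_N·N)`, prediction of independent
   cohorts' PET z-scores from IHC alone (full vs fibrillar-only), and a
   group-level regression-line gap index. A built-in scenario models
   microglial (Trem2-like) dysfunction as reduced plaque fibrillarity
   at unchanged total coverage.

A seeded synthetic-cohort generator with known ground truth emulates
the two-genotype study design (compact-plaque `model_A`, diffuse-plaque
`model_B`, 3/6/12 months, longitudinal PET with partial enrollment,
cross-sectional IHC) so the entire pipeline is testable without animal
data. See `vignettes/decomposition-methods.Rmd` for the model,
assumptions, and design choices.

## Worked example

Synthesize the headline coefficients from a published-style per-model
coefficient table (shipped as `inst/extdata/table1_coefficients.csv`):

```r
library(abdecomp)
tab <- read.csv(system.file("extdata", "table1_coefficients.csv",
                            package = "abdecomp"))
summarize_coefficient_table(tab)
#> Signal per 1% area covered: fibrillar 3.17 z, nonfibrillar 0.20 z
#> Fibrillar-to-nonfibrillar fold ratio: 16-fold (range 11- to 26-fold)
```

One percent fibrillar coverage drives ~16× more PET signal than one
percent nonfibrillar coverage (plausibly 11–26×). Run the pipeline on a
synthetic study and fit the ladder:

```r
cfg <- default_config(seed = 1)
ihc   <- generate_ihc(cfg$sim)
scans <- generate_pet(cfg$sim)
pet_z <- compute_z(scans$pet, scans$wt)
pairs <- build_pairs(pet_z, ihc)
nrow(pairs)
#> [1] 296
ladder_table(fit_ladder(pairs))
#>                                            model    r2 adjusted_r2 b_fibrillar b_nonfibrillar         p
#> 1                                      fibrillar 0.762       0.761       3.215                 1.35e-93
#> 2                                   nonfibrillar 0.547       0.545                      0.940  1.87e-52
#> 3                       fibrillar x nonfibrillar 0.852       0.851       2.462          0.461 3.60e-122
#> 4       fibrillar x nonfibrillar x heterogeneity 0.869       0.867       2.462          0.461 2.31e-128
#> 5 fibrillar x nonfibrillar x heterogeneity x age 0.893       0.891       2.509          0.092 1.05e-139
```

Neither compartment alone explains the signal; both together, plus
heterogeneity and age, approach full explanation — the nested-R²
progression the decomposition relies on. Despite the ~16-fold weaker
per-percent signal, the diffuse model's abundant nonfibrillar amyloid
dominates its net PET signal:

```r
cohort_shares(ihc, c(b_fib = 3.17, b_nonfib = 0.20))
#>   genotype nonfibrillar_share_mean nonfibrillar_share_sd  n
#> 1  model_A                   0.130                0.0624 11
#> 2  model_B                   0.672                0.1871 11
```

i.e. nonfibrillar plaque produces ~67% ± 19% of the modelled signal in
the diffuse model but only ~13% ± 6% in the compact model.

A full orchestrated run (`run_all(cfg, out_dir)`) writes the simulated
tables, the ladder (`table1.csv`), the coefficient synthesis
(`summary.json`), contribution shares (`shares.csv`), the
independent-cohort prediction-bias report (`bias.csv`), a run manifest,
and a plain-text report. A thin command-line front end with
`simulate` / `pair` / `fit` / `decompose` / `validate` / `run-all`
subcommands is installed at `inst/scripts/abdecomp.R`.

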