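# oxypulse

Simulation and single-cell analysis of the *E. coli* OxyR oxidative
stress regulon under hydrogen peroxide treatment.

H2O2 stress does two things at once to a bacterium: it oxidizes the
transcription factor OxyR, which rewires transcription of its regulon,
and it transiently stalls growth, which stops dilution and makes *every*
protein accumulate — a passive "induction" pulse that has nothing to do
with regulation.  Disentangling the two requires growth-corrected
statistics on single-cell traces.  `oxypulse` is aimed at quantitative
microbiologists working with mother-machine time-lapse data (or models
of it) and provides:

* **A mechanistic ODE model** of the OxyR redox switch: H2O2 influx,
  enzymatic scavenging by AhpCF (kcat 660 s⁻¹, Km 1.2 µM) and catalase
  KatG (490 000 s⁻¹, 5 900 µM), GrxA-mediated OxyR re-reduction,
  growth-rate coupling, signed Michaelis–Menten reporter regulation
  (`R_basal + K_ind · OxyR_ox/(OxyR_ox + K_D)`), plasmid copy-number
  dynamics, catalase knockouts, and a 1-D trench extension with
  geometric H2O2 attenuation per shielding cell.
* **A seeded synthetic data generator** producing BACMMAN-style track
  tables (one row per cell per frame: trench, barrier count, lineage,
  length, area, per-channel fluorescence), driven either by the model or
  by planted phenomenological templates with known ground truth.
* **Trace statistics**: elongation rate, expression rate, promoter
  activity `(1/A)·d(I·A)/dt`, population peak (90th percentile,
  12–90 min) and steady state (mean, ≥150 min) levels, single-cell peak
  timing, gene-to-gene CV, frontier-normalised spatial profiles, and
  detrended temporal cross-correlations.
* **A classifier** that assigns each gene one of five regulation
  categories from windowed Mann–Whitney tests on promoter activity
  (peak 9–60 min and steady 120–180 min vs. the untreated baseline,
  α = 0.05) and splits sustained upregulated genes into *pulsatile*
  vs. *gradually responding* at a peak/steady ratio of 2.12, via
  OLS regression of peak on steady level across doses.

## Worked example

Simulate a 100 µM step treatment and watch the growth arrest and the
intracellular H2O2 spike:

```r
library(oxypulse)
p <- oxy_params()
genes <- list(constitutive_gene(p),
              gene_spec("PkatG_like", R_basal = 0.5, K_ind = 5.4, K_D = 0.18))
traj <- simulate_regulon(p, protocol_step(100), genes,
                         t_start = -60, t_end = 180)
min(traj$g_t) / p$g_max        # 0.044  -> growth collapses to 4.4% of g_max
max(traj$H2O2_cell)            # 2.8e-3 uM intracellular spike at t = 3 min
```

Generate a planted 31-gene synthetic regulon (11 sustained up — 7
pulsatile, 4 gradual — 8 sustained down, 7 transient down, 2 transient
up, 3 unregulated), classify it from growth-corrected promoter
activity, and inspect a pulsatile gene:

```r
lay <- channel_layout(n_trenches = 200, cells_per_trench = 1)
ds  <- generate_tracks("planted", lay,
                       templates = default_regulon_templates(),
                       noise = noise_model(seed = 1))
classify_regulon(ds, alpha = 0.05)
#> <regulon_report> 31 genes at alpha = 0.05
#>   sustained_up    11
#>   transient_up    2
#>   sustained_down  8
#>   transient_down  7
#>   none            3

population_peak(ds, "katG", normalize = TRUE)    # 6.04 x basal
population_steady(ds, "katG", normalize = TRUE)  # 2.05 x basal  (ratio 2.95)
```

The counts match the planted ground truth; the measured peak/steady
ratio of the planted pulsatile gene katG recovers its class ratio of ~3.
Because the per-gene tests run at α = 0.05 without multiple-testing
correction, occasional seeds miscall one of the truly null window tests
— see the methods vignette (`vignettes/oxypulse-methods.Rmd`) for the
statistics of exact-count recovery.

Config-driven runs (`generate → metrics → classify`, with manifest,
logs and byte-reproducible outputs) go through `run_pipeline()`:

```r
cfg <- system.file("extdata", "demo_planted.yaml", package = "oxypulse")
validate_config(cfg)     # empty violation table
run_pipeline(cfg, out_dir = "demo_run")
```

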