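# mqpi: multiparametric QPI drug-response analysis

Label-free drug-response profiling of single cells by quantitative phase
imaging (QPI), for groups running differential phase contrast (DPC)
timelapse assays on cell lines, organoid-derived cells, or primary tumor
samples. Because the phase shift through a cell is proportional to its
dry mass, a phase movie yields the mass trajectory of every cell; this
package turns those trajectories into drug-response parameters that a
single end-point viability number cannot provide:

* **EC50 and depth of response (DoR)** from Hill fits of mean specific
  growth rate (SGR) versus dose:
  `SGR(C) = Emax + (E0 - Emax) / (1 + (C/EC50)^HS)`,
  `DoR = (E0 - Emax)/E0` (1 = complete growth arrest, >1 = net mass
  loss);
* **Time of response (ToR)**: the time at which the Hellinger distance
  between treated and control single-cell SGR distributions, fitted with
  a saturating exponential, crosses a threshold calibrated from two
  on-plate control groups;
* **Subpopulation structure**: a sequentially initialized two-Gaussian
  mixture of the SGR distribution per 12 h window, tracking the
  non-responsive fraction of a heterogeneous population over time;
* **Mass filtering** that rescues dose-response analysis of contaminated
  direct-from-thaw samples by thresholding the bimodal initial-mass
  distribution at its antimode.

The chain starts wherever your data do: raw four-image half-circle DPC
intensity frames (Tikhonov-regularized phase retrieval, beta = 1e-3),
phase TIFFs (Sobel/morphology segmentation, dry mass via the specific
refractive increment 1.8e-4 m^3/kg, optimal-assignment tracking), or
ready-made single-cell mass tracks (CSV). A seeded synthetic-data
generator produces all three levels with ground truth, so the entire
pipeline is validated without any microscope data.

## Worked example

Simulate a plate (two vehicle control groups plus a six-point dose
curve), run the pipeline, and read off the drug-response parameters:

```r
library(mqpi)

plate <- read_plate_map(system.file("extdata", "example_plate.yaml",
                                    package = "mqpi"))
drug  <- drug_effect_spec(e0 = 0.02, emax = -0.012, ec50 = 0.3, hs = 1.2,
                          response_delay_tau = 6)       # ground truth
pop   <- population_spec(n_cells = 60, sgr_control = 0.02, sgr_sd = 0.004,
                         noise_sd_mass = 2, growth_model = "linear",
                         seed = 2024)
tracks <- simulate_experiment(pop, drug, plate)

res <- run_pipeline(run_config(seed = 2024, run_mixture = FALSE),
                    tracks, plate = plate)
res
#> mQPI pipeline result
#>   69600 observations -> 480 tracks (0 skipped as short)
#>   drugA: EC50 = 0.2724, DoR = 1.39
#>   ToR rows: 6 (4 responded)
#>   config: 740cbf794536a3f18e216088ec4f9dc4 seed: 2024

res$dose_response$drugA$fit
#> Hill dose-response fit
#>   E0   = 0.01971 1/h
#>   Emax = -0.007715 1/h
#>   EC50 = 0.2724
#>   HS   = 1.35
#>   DoR  = 1.39
#>   RMSE = 0.000331, R2 = 0.999, n = 7 doses
```

The fitted EC50 (0.27) recovers the generator's 0.3 within sampling
error; DoR = 1.39 says the high-dose asymptote is net mass *loss* (the
true value is (0.02+0.012)/0.02 = 1.6). The ToR table shows the two
lowest doses never separating from control (reported non-responsive, no
number invented) and response arriving faster as dose increases:

```r
res$tor[, c("dose", "h_inf", "tor", "responded")]
#>     dose      h_inf       tor responded
#> 1 0.0100 0.06807405        NA     FALSE
#> 2 0.0316 0.08486316        NA     FALSE
#> 3 0.1000 0.26402210 2.4056839      TRUE
#> 4 0.3160 0.66509395 1.1909205      TRUE
#> 5 1.0000 0.92225714 0.8174131      TRUE
#> 6 3.1600 0.94533941 0.7941516      TRUE
```

Lower-level entry points (`dpc_reconstruct()`, `detect_cells()`,
`build_tracks()`, `compute_sgr_table()`, `fit_hill()`,
`time_of_response()`, `fit_mixture_sequence()`, ...) expose each stage
separately; see the methods vignette (`vignettes/mqpi-methods.Rmd`) for
the models, parameter meanings, and design choices.

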