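# pkrscan

Stochastic models and single-molecule analysis of kinase scanning on
double-stranded RNA.

## The problem

The innate-immune kinase PKR is activated by dsRNA, but not by binding
alone: a single bound molecule cannot autophosphorylate, so two molecules
must meet on the same duplex and phosphorylate each other in trans.
Single-molecule FRET shows that bound PKR scans the duplex by 1D diffusion,
which is how those encounters happen — and which makes activation depend on
dsRNA length and concentration. The dsRNA-binding protein PACT co-occupies
the same duplexes, restricts PKR's scanning range and shortens its
residence time, suppressing activation *without* sequestering the RNA. The
dominant endogenous PKR ligands are inverted-repeat Alu elements (IR-Alus),
detected genomically as oppositely oriented repeat pairs that fold into
long intramolecular duplexes.

`pkrscan` packages the quantitative machinery around these observations for
anyone who wants to simulate, fit, or re-analyze this class of data:

* **smFRET simulation** (`sim_config`, `simulate_trajectory`,
  `simulate_with_obstacle`, `render_intensities`) — ground-truthed traces of
  binding, reflected Brownian scanning, and obstacle exclusion/eviction at
  33 ms camera resolution.
* **Trace analysis** (`compute_fret`, `segment_events`,
  `autocorrelate_events`, `fit_sliding_time`, `residence_stats`,
  `gated_fret_histogram`) — event segmentation with a 2 s abortive-event
  cutoff, pooled FRET autocorrelation
  (mean-subtracted, variance-normalized, pair-count weighted) with
  single-exponential sliding-time fits, Welch residence-time comparisons,
  and high-FRET-gated histograms.
* **Gel-shift quantification** (`bound_fraction`, `fit_hill`,
  `simulate_gel`) — the multi-band bound fraction
  `sum(I(n) n) / (sum(I(n)) N)` for a duplex with N = 8 sites, and Hill
  fitting `f(c) = c^h / (Kd^h + c^h)`.
* **Activation model** (`kinetic_params`, `simulate_system`,
  `activation_heatmap`) — a kinetic Monte Carlo lattice model in which
  kinases bind with a 15 bp footprint, scan, collide, and
  trans-autophosphorylate, and obstacles restrict and evict them; endpoint
  phospho fractions over length × dose × obstacle grids.
* **IR genomics** (`find_ir_pairs`, `synth_genome`, `normalize_coverage`,
  `subtract_tracks`, `call_peaks`, `quantify_peaks`, `annotate_near_ir`,
  `editing_cpm`) — Smith–Waterman inverted-repeat pairing (>80% identity,
  ≤1.5 kb gap), per-million coverage normalization, track subtraction, peak
  AuC and log2FC enrichment filtering, <300 bp near-IR classification, and
  editing CPM, exercised on synthetic genomes with planted truth.

See the methods vignette (`vignettes/scanning-models.Rmd`) for the models,
their assumptions, and every numerical choice.

## Worked example

Simulate eight molecules scanning a 112 bp duplex for ~17 minutes of total
observation, analyze the traces, and compare the fitted sliding time with
the diffusion-in-a-box prediction:

```r
library(pkrscan)

cfg <- sim_config(duplex_length = 112, n_frames = 30000, rng_seed = 1,
                  diffusion_coeff = 1000, k_on = 0.01, protein_conc = 50,
                  k_off = 0.05)
fp  <- fret_params_effective(112)
sim <- simulate_traces(cfg, fp, n_molecules = 8)
res <- analyze_traces(sim$traces, fp, on_threshold = 0.1, max_lag = 2)

nrow(res$events)                      # 392 binding events (366 non-abortive)
res$autocorrelation$sliding_time      # 0.734 s (SE 0.004)
mean(res$residence_s)                 # 19.4 s mean residence
(112 - 15)^2 / (pi^2 * 1000)          # 0.953 s box relaxation time
```

The fitted 0.73 s tracks the 0.95 s relaxation time `L_eff^2 / (pi^2 D)` of
reflected diffusion (the downward bias comes from FRET's nonlinearity in
position, see the vignette); across 42/59/112 bp duplexes the fitted
sliding times order strictly with length. Fitting a noisy simulated
gel-shift titration recovers the binding constant:

```r
lanes <- c(simulate_gel(357.5, h = 1, noise_sd = 0.02, seed = 1),
           simulate_gel(357.5, h = 1, noise_sd = 0.02, seed = 2),
           simulate_gel(357.5, h = 1, noise_sd = 0.02, seed = 3))
binding_curve(lanes)$fit              # Kd = 357.2 nM (SE 0.5), h = 0.998
```

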