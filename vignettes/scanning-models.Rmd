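---
title: "Models and methods: kinase scanning on dsRNA and its restriction by a co-occupying inhibitor"
author: "pkrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: kinase scanning on dsRNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkrscan)
```

# The biological system

PKR is an innate-immune kinase that is activated by double-stranded RNA. A
single PKR molecule cannot autophosphorylate: activation requires two
molecules to meet and phosphorylate each other in trans, and dsRNA serves as
the scaffold that brings them together. Single-molecule FRET experiments
show that PKR does not sit still on the duplex — it scans, diffusing in one
dimension along the RNA — and that this scanning is what lets two bound
molecules find each other. The dsRNA-binding protein PACT co-occupies the
same duplexes, restricts PKR's scanning range, and shortens its residence
time, suppressing activation without having to coat the RNA or block PKR
binding. On the genomics side, the dominant endogenous PKR ligands are
inverted-repeat Alu elements (IR-Alus): pairs of oppositely oriented Alu
copies in one transcript that fold back into long intramolecular duplexes.

`pkrscan` implements the quantitative machinery around these observations
as testable, reusable code: a ground-truthed smFRET trace simulator and the
matching analysis pipeline; the multi-band gel-shift bound-fraction formula
with Hill fitting; a stochastic scanning-collision model of activation; and
the inverted-repeat / coverage-enrichment arithmetic, exercised on synthetic
genomes. Everything stochastic is seeded and reproducible.

# The smFRET simulator

`simulate_trajectory()` propagates one molecule on one surface-immobilized
duplex. Binding from solution is a Poisson process with rate
`k_on * protein_conc`; dissociation has constant rate `k_off`; while bound,
the position (a continuous coordinate in bp, not an integer lattice)
performs Brownian motion with diffusion coefficient `D` on the accessible
interval `[0, L - footprint]`, with reflecting boundaries. Continuous
positions are used because the analytic results the tests rely on —
`MSD = 2 D t` at short times, and the diffusion-in-a-box relaxation time
`tau1 = L_eff^2 / (pi^2 D)` — hold exactly for reflected Brownian motion.

Integration uses `substeps_per_frame` Euler substeps per 33 ms camera frame
(default 10), so that a diffusion step (`sqrt(2 D dt)` ≈ 2.6 bp at
`D = 1000 bp^2/s`) stays much smaller than the duplex and discretization
does not distort the autocorrelation. Each frame records the state at the
frame's last substep (an unbiased sample of the stationary law) and the
average position over the frame's bound substeps — the simulator's explicit
camera-blur model. Per-frame FRET is computed at that substep-averaged
position, not as a time-average of FRET; the difference matters only
through the nonlinearity of the FRET curve and is documented so tests can
account for it.

Key defaults are the conditions of the single-molecule experiments this
emulates: 33 ms frames, 50 nM protein, a 15 bp kinase footprint, and duplex
lengths of 42/59/112 bp. The diffusion coefficient defaults to
1000 bp^2/s, which puts the box relaxation times (0.07–0.95 s across those
lengths) in the regime where sliding times are resolvable at 33 ms frames.
`k_on = 0.002 /nM/s` and `k_off = 0.1–0.2 /s` reproduce the qualitative
experimental picture of infrequent binding (one or two events per ~30–50 s
observation window) with multi-second residence.

## FRET geometry: physical versus effective

`position_to_fret()` maps position to efficiency through a rigid-rod
geometry: `r = dye_offset + position * helical_rise` and
`E = 1 / (1 + (r / R0)^6)`. The defaults of `fret_model_params()` are the
physical constants for a Cy3/Cy5 pair on an A-form duplex (R0 = 5.4 nm,
rise 0.28 nm/bp, 1.5 nm offset). With these constants, E is sensitive only
within ~25 bp of the labeled end of a long duplex and saturates to 0
beyond — whereas measured scanning traces span E ≈ 0.2–0.8 across a 112 bp
duplex, because the real assay geometry (surface tether, flexible dye
linkers, helix dynamics) compresses the effective distance range.

Rather than model that geometry, `fret_params_effective()` solves for an
effective offset and rise such that E runs from `e_near` (0.92) at the
labeled end to `e_far` (0.15) at the far end of the accessible interval,
i.e. an approximately linear position-to-FRET readout matching the
observed dynamic range. The comparison analyses in this package (length
ordering of sliding times, obstacle restriction) use the effective
geometry; the physical defaults remain available and all constants are
config-exposed. With the effective geometry, unbound frames read E = 0
after corrections, so the analysis pipelines segment events at a low
threshold (0.1) instead of the paper-style 0.6 that suits an end-proximal
binding geometry; both are parameters of `segment_events()`.

## The obstacle (PACT) model

How PACT microscopically restricts PKR is not established — static
roadblock, co-moving obstacle, and transient complex formation are all
consistent readings of the single-molecule data. `simulate_with_obstacle()`
implements one of them: `n_pact` obstacle particles (default 2, plausible
for 50 nM PACT on a 112 bp duplex with a 20 bp obstacle footprint) with
their own binding, diffusion and dissociation parameters; hard-core
exclusion between all footprints (attempted moves reflect off neighbors);
and, on each *new* contact (footprint gap ≤ 1 bp), eviction of the kinase
with probability `eviction_prob_on_contact`. Applying eviction per
collision rather than per frame-in-contact keeps the parameter's meaning
independent of the integration step. The obstacle defaults (slow diffusion
30 bp^2/s, stable binding, eviction probability 0.15) realize the
restriction phenotype — narrower gated FRET histograms, shorter sliding
times, shorter residence — while leaving enough long events to analyze;
they are a modeling choice, not a fit.

# Trace analysis

`compute_fret()` applies standard ratiometric corrections (background
subtraction and donor leakage) and clamps E to [0, 1]; frames below an
intensity floor are masked. `segment_events()` finds maximal runs of
E above the On threshold; events shorter than 2 s are classified abortive
and excluded from autocorrelation pooling — transient encounters carry no
usable scanning signal. `anticorrelation_score()` quantifies the
donor/acceptor anticorrelation of an event (Pearson correlation of the
frame-to-frame changes); exclusion on this score is available but off by
default, since the experimental analysis uses anticorrelation descriptively
rather than as a stated filter.

The autocorrelation of FRET within an event is printed in the experimental
methods as a convolution-style integral of E with itself. Taken literally,
that expression has no decay to fit; the only reading under which "fitted
with a single exponential decay" makes sense is the standard
mean-subtracted, variance-normalized autocovariance, and that is what
`autocorrelate_events()` computes: per event, the biased (1/n) estimator
(lower variance at the short lags used for fitting), with per-event mean
subtraction (removes event-to-event offsets before pooling), normalized so
G(0) = 1, then pooled across events weighted by the number of contributing
frame pairs. Events shorter than the lag window contribute only the lags
they support. `fit_sliding_time()` fits `A * exp(-lag/tau) + C` by
Levenberg–Marquardt least squares; by default C is fixed at 0 and the fit
window runs from lag 0 to the first lag where G < 0.05, both configurable
because the experimental fit's window and offset convention are not
reported. A failed fit or non-positive tau sets a failure flag rather than
silently falling back.

For reflected-diffusion traces the position autocovariance is dominated
(98% of variance) by the slowest box mode, so the fitted tau tracks
`tau1 = L_eff^2 / (pi^2 D)`; FRET's residual nonlinearity in position
biases the fitted value downward by up to ~15–25%, which is why the
parameter-recovery test uses a 25% tolerance while the length *ordering*
(42 < 59 < 112 bp) is required strictly.

`residence_stats()` compares residence ("on") times between conditions
with a Welch two-sample t-test by default. The experimental comparison used
a paired test; a pairing structure is not recoverable from independent
simulated events, so pairing is supported only through an explicit pairing
argument. `gated_fret_histogram()` implements the high-FRET gating used to
compare scanning ranges: only traces containing at least one On-frame with
E > 0.8 contribute, and the histogram then pools *all* On-frames of
qualifying traces (per-frame counting; per-event counting is the other
possible reading of the experimental figure). Gating is per trace, which is
why the obstacle comparisons simulate many short (~50 s) observation
windows rather than few long ones — with long multi-event traces every
trace eventually qualifies and the gate loses its selectivity.

# The gel-shift quantifier

A duplex with N binding sites (N = 8 for 112 bp) runs as N+1 bands; band n
is the complex with n proteins bound. The bound fraction of a lane is the
intensity-weighted mean occupancy divided by N:

$$\mathrm{bound\ fraction} = \frac{\sum_{n=0}^{N} I(n)\,n}{\sum_{n=0}^{N} I(n)\,N}$$

Band intensities are not molar-corrected for complex size: phosphorimaging
of end-labeled RNA measures the RNA, which is constant per band.
`fit_hill()` fits `f(c) = c^h / (Kd^h + c^h)` with both Kd and h free by
default. The "8 binding sites" enter through the occupancy weighting above,
not by fixing h = 8 — a Hill coefficient of 8 for independently binding
dsRNA-binding domains would be physically implausible — but `fix_h` allows
the other convention. `simulate_gel()` inverts the model for testing: per
lane the per-site occupancy is p(c) and band n gets the Binomial(N, p) mass,
so the noiseless bound fraction equals p(c) identically (the binomial-mean
identity), making generator and estimator mutually checking. The default
concentration ladder is the 12-lane titration (0 and 3.9–4000 nM in
two-fold steps) and the reference regime for recovery tests uses
Kd = 357.5 nM — the affinity scale of the protein this emulates.

# The scanning-collision activation model

`simulate_system()` is a fixed-time-step kinetic Monte Carlo over particles
on duplexes. Exact event-driven simulation (Gillespie) is not applicable
because hard-core diffusion on a continuous coordinate has no finite
reaction set; instead per-step event probabilities are kept small and the
simulator refuses to run if any reaches 0.1. Per step: free molecules bind
(rate `k_on * [duplex bp]` — the on-rate is per nM of duplex *base pairs*,
so longer duplexes are proportionally bigger targets and a matched mass
dose gives matched binding flux), landing uniformly on an unoccupied
footprint-sized site of a random duplex; bound molecules diffuse with
reflection at ends and neighbors, and dissociate; on each new kinase-kinase
contact both partners are phosphorylated with `phospho_prob_per_contact`
(mutual phosphorylation is chosen since the data do not resolve one-way vs
mutual; trans-only — a lone kinase never autophosphorylates, and no
dephosphorylation or activation threshold beyond a single hit is modeled);
each new kinase-obstacle contact evicts the kinase with
`eviction_prob_on_contact`. Phosphorylated kinase keeps binding and
scanning. Free-pool depletion is implicit in particle tracking, which is
what produces the dispersal effect at excess dsRNA.

System size is set by `n_pkr` (default 400 in the analyses); duplex and
obstacle counts follow from the concentration ratios at 100 nM kinase, the
standard assay concentration. The default kinetic set (k_on 1e-4 /nM_bp/s,
k_off 0.3 /s, D 1000 bp^2/s, phospho probability 0.05, 30 s horizon at
dt = 2 ms) is a regime-demonstration choice: it reproduces the qualitative
phenotypes — activation increasing with length at matched mass, biphasic
dose response, no activation for 21 bp duplexes or lone molecules, and an
inhibition-without-sequestration regime in which transient obstacles
(k_off 3 /s, eviction probability 1) occupy under 10% of duplex length yet
halve activation — and is not presented as fitted to any gel
quantification. The length preference requires residence times longer than
the scanning encounter time (k_off below ~0.5 /s at D = 1000 bp^2/s);
faster exchange reverses the ordering because short duplexes convert
co-occupancy into collisions instantly. The model-level heatmaps produced
by `activation_heatmap()` are grid summaries of this simulator; only their
orderings and shapes are meaningful, never absolute cell values.

# Inverted repeats and coverage arithmetic

`find_ir_pairs()` pairs same-family repeat annotations on one chromosome
with opposite strands and a gap of at most 1.5 kb, aligning the upstream
sequence against the reverse complement of the downstream one with exact
affine-gap local (Smith–Waterman) alignment at blastn-style scores
(match +2, mismatch −3, gap open 5, gap extend 2). The seeding heuristic of
blastn (word size 11) is deliberately *not* reproduced — an exact algorithm
substitutes for a heuristic one, which can only find equal-or-better
alignments. "Over 80% identity of the whole sequences" is ambiguous between
identity over alignment columns and over repeat length; the default
requires identity > 80% over alignment columns *and* aligned coverage ≥ 80%
of the shorter repeat, with both thresholds exposed. At 25% random
divergence the expected identity (~75%) fails the gate; at 10% (~90%) it
passes — the synthetic-genome tests pin both sides.

Coverage tracks are 0-based half-open interval lists (the BED convention
used throughout). `normalize_coverage()` rescales to per-million non-rRNA
reads; `subtract_tracks()` does breakpoint-exact interval arithmetic
treating uncovered regions as zero; `call_peaks()` is a deliberately simple
threshold-merge-filter stand-in for bedGraph peak callers, clearly
parameterized and not claimed equivalent to them; `quantify_peaks()`
computes the AuC (sum of value × overlap width) and
`log2((AuC_fclip + pseudo)/(AuC_input + pseudo))` with a pseudo-AuC floor
of 1 normalized unit to avoid division by zero (distribution-based
shrinkage is out of scope). The enrichment filter is the criteria pair
log2FC ≥ 1 with control log2FC ≤ 0. `annotate_near_ir()` classifies peaks
as IR-Alu (overlapping a pair member), near IR-Alu (within <300 bp of a
member, or flanked between the two members), or other. `editing_cpm()` is
mismatch counts per million mapped reads; the strand convention (A→G on
plus-strand features, T→C on minus) is applied upstream of this function
by whatever counts the mismatches.

`synth_genome()` plants inverted pairs at controlled divergence and gap in
a random background, plus same-strand decoys and over-window pairs, with a
truth table; 3 kb spacers keep unintended neighbors outside any window.
What it does not emulate: real Alu sequence structure (diagnostic
subfamilies, A-tails), indel divergence (substitutions only), transcript
context, or read-level noise — so perfect recall on synthetic genomes
bounds, but does not establish, performance on real annotation.

# Reproducibility and problem sizes

Every simulation consumes exactly one seed recorded in its config;
`derive_seed()` fans a single run seed out to modules, and
`run_pipeline()` writes a manifest with parameter values and MD5 hashes of
every output so a run can be re-verified bit-exactly. The shipped analyses
use problem sizes chosen to give stable statistics at interactive runtimes:
~300 binding events per sliding-time fit (8 molecules × 1000 s at 33 ms),
150–400 observation windows per obstacle comparison (>200 events per arm),
400 kinase molecules × 30 s per activation cell with 3 replicates, and
20-pair synthetic genomes. All scale linearly with their size parameters.

# Known limitations

* Photophysics beyond Gaussian read noise and donor leakage (blinking,
  bleaching, gamma correction, PIFE) is not modeled.
* No hidden-Markov state inference; segmentation is thresholding.
* The obstacle model is one mechanistic reading; it does not distinguish
  roadblocking from transient complex formation.
* The activation model is single-hit, trans-only, with no substrate
  phosphorylation step and no RNA-independent activation pathway at high
  protein concentration.
* Peak calling is a labeled stand-in, not a reimplementation of any
  published caller; differential statistics on peak AuCs are out of scope.
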