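---
title: "Methods: a hippocampal microcircuit model of gamma-band entrainment and its screening layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a hippocampal microcircuit model of gamma-band entrainment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Schizophrenic patients show a selective deficit in gamma-band steady-state
evoked potentials: when driven with auditory click trains, their cortical
response at 40 Hz is reduced (clinical MEG work puts the reduction around
26 %), while responses at 20 and 30 Hz are essentially normal. `hippogamma`
implements a tissue-level hippocampal microcircuit in which candidate
cellular-level abnormalities — NMDA receptor hypofunction, dendritic spine
loss, and GABA-system dysregulation — can be dialled in individually and in
combination, and scores how schizophrenia-like the resulting oscillatory
phenotype is. On top of the lesioned ("schizophrenic") model it runs
virtual-medication trials, scoring each candidate mechanism combination by
how fully it restores control behaviour.

## The circuit model

Four populations: 160 pyramidal cells and three interneuron classes — 30
basket cells (perisomatic inhibition), 30 chandelier cells (inhibition at
the pyramidal axon initial segment, the alpha2 GABA_A site), and 20
calretinin-positive cells, which project exclusively onto other
interneurons (a disinhibitory modulator). Cells are trees of cylindrical
compartments with six Traub-lineage voltage/calcium-gated conductances
(Na, Ca, K-DR, K-A, K-AHP, K-C) distributed along the somato-dendritic
axis, plus a per-compartment calcium pool with first-order decay
(tau = 13.3 ms) that gates the K-AHP and K-C channels. Two morphology
scales are bundled:

* `"full"`: 64-compartment pyramidal cells and 46-compartment
  interneurons, matching the compartment counts of the cited lineage;
* `"reduced"` (default): 8 / 5 compartments. All sweeps and tests use this
  desk scale so that a full trial integrates in seconds on one CPU.

The supplementary parameter tables of the source study are not publicly
archived, so every density, time constant and probability in
`inst/params/defaults.yaml` is tagged `[published]`, `[traub-default]` or
`[assumed]`. `[assumed]` values were chosen once from standard hippocampal
modelling practice and then tuned — as the original work also reports
tuning — until the control network entrains cleanly at 20, 30 and 40 Hz;
they were not revisited afterwards. Two tuning notes worth recording: the
somatic Na/K-DR densities were raised (60 / 25 mS/cm²) until the reduced
pyramidal cell fired tonically without depolarisation block, and the
calcium-pool coupling was reduced until subthreshold calcium no longer
saturated the slow K-AHP gate (whose recovery time constant of ~1 s
otherwise silences the cell after two clicks).

Synapses are peak-normalised dual exponentials,
`g(t) = w g_max N (e^{-t/tau2} - e^{-t/tau1})`, so `g_max` is literally the
peak conductance — this makes every "% change in g_max" lesion or drug
unambiguous. Defaults: AMPA 0.5/3 ms (3 ms is the stated control decay
constant), NMDA 5/100 ms with the Jahr–Stevens magnesium block at 1 mM,
GABA_A 0.5/7 ms with reversal −75 mV. Connectivity is Bernoulli per
ordered cell pair from a probability table; excitatory contacts carry
paired AMPA+NMDA synapses, and pyramidal→pyramidal dendritic contacts form
the spine registry eligible for pruning.

## Drive and simulated EEG

Each click of the 20/30/40 Hz train is a near-synchronous AMPA volley
(≤ 1 ms uniform jitter) onto the mid-apical compartment of every pyramidal
cell (fraction configurable). The simulated EEG is the population sum of
absolute synaptic currents into pyramidal apical-dendrite compartments —
the standard field-proxy choice; a mean-somatic-potential proxy can be
swapped in via config because the original study's exact EEG computation
is in an unavailable supplement. Spectra are Welch estimates (Hann window,
500 ms segments, 50 % overlap, 200 ms transient discarded), giving 2 Hz
resolution; band power integrates the density over ±2 Hz.

## Illness and wellness metrics

With baseline (control) and test on-drive band powers `P_f`:

* **illness**: 0 if the 20 or 30 Hz response deviates from baseline by
  more than ±7.5 %; otherwise, with `d = (P40_base − P40_test)/P40_base`,
  `score = max(0, 1 − |d − 0.26| / 0.26)`. A model scoring 1 reproduces
  the clinical pattern exactly: selective 26 % gamma reduction.
* **wellness**: 0 if the treated 20 or 30 Hz response deviates from
  control by more than ±10 %; otherwise decreasing linearly from 1 in the
  relative 40 Hz deviation.

Only the endpoints of these scores are published (1 at the target, 0 on
tolerance failure, "decreased" in between); the linear symmetric falloff
with scale 0.26 is this package's choice — the simplest monotone form
satisfying the published description — and both shape and scale are
configurable. The tolerance gate makes the illness score discontinuous at
the tolerance boundary; this is faithful to the published rule.

## Lesions, drugs and sweeps

The lesion grid is NMDA g_max reduction (0–45 %, step 5) × spine removal
(0–60 %, step 5) × 7 GABA "ordered pairs", i.e. 10 × 13 × 7 = 910 points.
Spine removal deletes an exact (hypergeometric) count of registry
contacts, both AMPA and NMDA components together, for reproducibility.
Each GABA pair removes a fraction of interneuron projections (tone) and
scales surviving GABA_A weights up (compensatory receptor upregulation).
The published pair list is stated as a uniform diagonal from (0, 0) to
(−45 %, +60 %), yet the published secondary lesion point uses the pair
(−37.5, +30), which lies on no uniform diagonal; the default here is the
uniform diagonal and the pair table is an explicit config argument, so the
secondary point's pair can be supplied directly. The separate 7 × 7 GABA
decomposition treats tone and weight as independent axes (49 trials).

The virtual-medication grid crosses five graded mechanisms — AMPA g_max
(+0–80 %), alpha2 GABA_A g_max at the initial segment (+0–60 %), NMDA
g_max (+0–80 %, with a +4.7 % excitatory-weight LTP side effect per 20 %
step), the AMPA decay constant (1/3/5 ms), and calretinin projection
weight (+0–60 %) — 5 × 5 × 5 × 3 × 4 = 1500 combinations including the
all-control point. Negative controls scale Na channel densities
(phenytoin), Ca channel densities (nifedipine), or AMPA g_max and tau2
jointly (ampakine). The published ampakine scan reports 30 iterations from
6 g_max levels × 5 tau2 levels while also describing a 0–60 % g_max range
in 10 % steps and a 0–100 % tau2 range in 20 % steps — ranges and level
counts that cannot all hold simultaneously; the default here keeps the
step sizes and level counts starting from 0 (g_max 0–50 % by 10, tau2
0–80 % by 20), and both axes are configurable.

Every grid point is seeded by hashing the master seed with the point's
coordinates, so any subset of a sweep reproduces the full run
point-for-point, and per-point failures are recorded without aborting the
sweep. Cluster detection on sweep results takes the points above a score
threshold (0.65 by default) and finds connected components of the grid
graph whose edges join points one level apart on exactly one axis.

## Cohorts and statistics

A simulated subject is a fresh connectivity realization (same probability
table, new seed) run through all three drives. The group analysis is the
published design: a mixed ANOVA with Group between subjects and Frequency
(20/30/40 Hz) repeated, Greenhouse–Geisser corrected (epsilon from the
eigenvalues of the double-centred pooled within-group covariance);
hierarchical regressions test whether Group predicts 40 Hz power after
controlling for 20/30 Hz power (and vice versa). Drug scores are
decomposed by a factorial ANOVA over the five mechanisms with terms up to
third order (5 main + 10 two-way + 10 three-way effects, each with one
degree of freedom because doses enter as graded covariates). Because
zero-score (failed) trials are excluded by default — the published
analysis covers only the scored medications — the design is unbalanced
and Type-II sums of squares are used.

## Numerical choices

* Exponential-Euler integration per compartment, dt = 0.025 ms, with
  neighbour voltages frozen within a step; gate kinetics tabulated on a
  0.05 mV grid. Convergence is verified by dt-halving (< 1 mV RMS on
  subthreshold traces) and by spike-count agreement against a 10× finer
  step. Pointwise voltage RMS across dt is only meaningful below
  threshold: suprathreshold traces accumulate sub-millisecond spike-time
  shifts that dominate any pointwise norm, which is why the convergence
  invariant is split into a subthreshold RMS check and a spike-count
  check.
* Spike detection: upward somatic crossing of 0 mV with a 2 ms lockout.
* Synaptic events are aggregated per (postsynaptic compartment, kinetic
  class) into two exponential state variables, which superposes events
  exactly and keeps the cost independent of synapse count.
* Cells are initialised at their true resting fixed point (an input-free
  relaxation, since the resting K conductances sit a few mV below the
  leak reversal).

## What the fixtures show — and what they do not

The surrogate-EEG generator (sinusoids plus white Gaussian noise) has
analytically known band powers and validates the whole analysis layer
(Welch spectra, band extraction, cycle averaging, metrics) independently
of the simulator. The synthetic sweep generator plants truncated score
bumps on a grid and validates cluster detection against a union-find
oracle. Passing these tests certifies the measurement pipeline, not the
biology: surrogates have no 1/f background, no cycle-skipping dynamics
and no parameter sensitivity, so claims about how lesions shift band
powers rest solely on the simulation layer.

## Problem sizes used by the test-suite

Unit and acceptance tests run the reduced morphology throughout: the
full-composition network (240 cells) for composition, determinism and the
20-seed entrainment property at 700 ms per trial (500 ms analysed), and a
24/6/6/4-cell network for sweep bookkeeping (a 3 × 3 × 3 subsampled lesion
grid) and cohort generation. These sizes are the package's desk-scale
preset; full 910-point and 1500-point sweeps at 1200 ms per trial are run
through the same engine via `run_experiment()` when more time is
available.

## Known limitations

* The published headline outcomes (the primary lesion cluster at
  NMDA −30 % / spine −30 % with a ~24–26 % selective gamma deficit, the
  97/1500 scored drugs, specific ANOVA F values) depended on the
  unavailable supplementary parameter set and supercomputer-scale runs;
  with substituted parameters at desk scale the package reproduces the
  machinery and its bookkeeping exactly, but not those specific numbers.
* Connection probabilities, channel densities and synaptic conductances
  are documented substitutes; conclusions about specific lesion
  sensitivities should be drawn only after re-tuning against data.
* No short-term plasticity, receptor desensitisation, GABA_B, gap
  junctions, or distance-dependent delays; temperature is implicit in the
  rate constants.
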