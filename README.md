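# hippogamma

A tissue-level hippocampal microcircuit simulator for studying the
gamma-band (40 Hz) steady-state entrainment deficit of schizophrenia, with
two screening layers on top: graded/combinatorial **lesion sweeps** scored
by a scalar *illness metric*, and **virtual-medication trials** scored by a
*wellness metric*.

## Who this is for

Computational neuroscientists and psychiatric-modelling researchers who
want a compact, fully scriptable version of the "lesion the circuit, drive
it with click trains, read out the FFT band powers" workflow: four cell
populations (160 pyramidal, 30 basket, 30 chandelier, 20
calretinin-positive cells), multicompartment Hodgkin–Huxley neurons with
the Traub-lineage channel set (Na, Ca, K-DR, K-A, K-AHP, K-C), kinetic
AMPA/NMDA/GABA_A synapses, probabilistic connectivity, and a simulated
EEG analysed by Welch spectra.

## The core quantities

For a drive frequency $f \in \{20, 30, 40\}$ Hz the model reports the
on-drive band power $P_f$ (density integrated over $f \pm 2$ Hz). With
baseline powers $P^{base}$ and test powers $P^{test}$:

**Illness metric** (how schizophrenia-like a lesioned model is):

$$
\text{score} =
\begin{cases}
0 & \left|P^{test}_{20}/P^{base}_{20}-1\right| > 0.075
    \text{ or } \left|P^{test}_{30}/P^{base}_{30}-1\right| > 0.075\\[4pt]
\max\!\left(0,\; 1 - \dfrac{|d - 0.26|}{0.26}\right) & \text{otherwise},
\quad d = \dfrac{P^{base}_{40}-P^{test}_{40}}{P^{base}_{40}}
\end{cases}
$$

i.e. a selective 26 % gamma reduction — the clinically calibrated target —
scores 1. The **wellness metric** mirrors it for drug trials: 1 when a
treated schizophrenic model exactly replicates control behaviour, 0 when
its 20/30 Hz responses leave a ±10 % tolerance.

Lesions are declarative transforms on a network: NMDA $g_{max}$ reduction
(0–45 %, step 5), dendritic spine pruning (0–60 %, step 5, exact-count
removal of excitatory contacts), and 7 GABA ordered pairs (tone reduction,
postsynaptic weight increase) — a 10 × 13 × 7 = 910-point grid. Virtual
medications vary five mechanisms (AMPA $g_{max}$, alpha2 GABA_A $g_{max}$
at the pyramidal initial segment, NMDA $g_{max}$ with its +4.7 %-per-20 %
LTP weight coupling, AMPA decay constant $\tau_2 \in \{1,3,5\}$ ms,
calretinin projection weight) over a 5 × 5 × 5 × 3 × 4 = 1500-point grid.

## Worked example

```r
library(hippogamma)

net <- build_network(seed = 1)          # 240 cells, reduced morphology
net
#> <hg_network> 240 cells (pyramidal 160, basket 30, chandelier 30,
#>   calretinin 20), 1680 compartments, 16254 synapses (seed 1)

trial <- run_ssep_trial(net, drive_spec(40), seed = 1)
spec  <- power_spectrum(trial$trace)
signif(band_powers(spec), 4)
#>        20        30        40
#> 5.392e-07 2.018e-07 3.765e-03

# the dominant band is the drive frequency: the control network entrains
names(which.max(band_powers(spec)))
#> "40"

# primary-point lesion: NMDA -30 %, spine density -30 %, no GABA deficit
les   <- lesion_spec(nmda_reduction = 0.30, spine_reduction = 0.30)
schiz <- apply_lesion(net, les, seed = 7)

base <- compute_baseline(net, master_seed = 1)
grid <- lesion_grid(nmda = c(0, 0.30), spine = c(0, 0.30), gaba_pair = 0)
sw   <- run_sweep(net, grid, base, metric = "illness", master_seed = 1)
head(sw[, c("nmda", "spine", "gaba_pair", "drive", "p40", "score")])
```

`band_powers()` returns the 20/30/40 Hz band powers of the simulated EEG
(arbitrary units²; only ratios matter to the metrics). The sweep emits one
row per grid point per drive with the full power triplet and the point's
illness score; `find_clusters(sw)` then returns connected high-score
regions of the grid with their peak points.

Experiment configs (YAML) drive the same machinery end to end, e.g. the
bundled smoke experiment:

```r
run_experiment(system.file("configs", "smoke.yaml", package = "hippogamma"),
               out_dir = "results/smoke")
```

A thin CLI wraps this: `Rscript inst/cli/hippogamma.R run <config>`, plus
`sweep {lesions|gaba|drugs}`, `scan {phenytoin|nifedipine|ampakine}`,
`cohort` and `clusters` subcommands.

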