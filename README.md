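# kopmeta

Quantifying how a single TMS pulse perturbs the brain's coordination
dynamics — and a mechanistic "digital twin" that explains why.

## The problem

Single-pulse transcranial magnetic stimulation (TMS) phase-resets the
stimulated cortical patch. Dynamically, a forced phase alignment pushes a
flexibly switching large-scale network into a transiently simple
coordinated state. That should appear in EEG as a drop in **metastability**
— the tendency to move in and out of synchrony states — followed by a
recovery whose duration indexes how long processing is perturbed.
`kopmeta` is for researchers analyzing TMS-EEG (or simulating whole-brain
oscillator models) who want that measurement chain end to end.

The core statistic is the Kuramoto order parameter over channel phases
θ\_j(t),

    r(t) e^{iψ(t)} = (1/N) Σ_j e^{iθ_j(t)},

with metastability operationalized as the standard deviation of r(t) in a
sliding window (50 ms on EEG). A second, independent measure labels each
sample with an EEG microstate (TAAHC clustering, Krzanowski–Lai model
selection, backfitting) and tracks the windowed Lempel–Ziv (LZ76)
complexity of the label sequence. Pre/post-pulse differences are tested
with exact one-tailed Wilcoxon signed-rank statistics. The digital twin is
a 90-node delayed Kuramoto network on a structural connectome,

    dθ_i/dt = ω_i + (K/N) Σ_j c_ij sin(θ_j(t − τ_ij) − θ_i) + d ζ(t),

with node frequencies assigned from anatomical strength (hubs slowest),
conduction delays τ\_ij = d\_ij / v, and a TMS pulse modeled as a phase
reset to π/2 that reaches remote nodes after their conduction delay.
A synthetic-data module generates EEG cohorts and connectomes with all of
this structure planted, so the whole pipeline is testable offline.

## Worked example

```r
library(kopmeta)

# a small synthetic TMS cohort: 4 subjects, 12 epochs, pulse at 500 ms
co <- generate_tms_epochs(cohort_spec(n_subjects = 4, n_epochs = 12,
                                      seed = 7))

# channel groups from the evoked potential
g <- group_channels(evoked_response(co$subjects[[1]]))
print(g$gfp_peak_ms)
#> [1] 521

# alpha-band KOP metastability on the planted cluster's channels
traces <- lapply(co$subjects, function(s) {
  ph <- extract_phase(s, c(8, 12))
  kt <- kop(ph, channels = co$planted[[1]]$cluster_channels)
  average_over(sliding_metastability(kt, window_ms = 50))
})
pm <- prepost_means(traces[[1]])
round(c(pre = pm$pre, post = pm$post), 4)
#>    pre   post
#> 0.0419 0.0320
```

The pre/post numbers are the mean windowed standard deviation of the
order parameter in the 250 ms before and after the pulse: the planted
phase reset synchronizes the cluster, so its synchrony fluctuates *less*
after the pulse (metastability drops), while the cluster's mean KOP rises
(0.52 → 0.66 on the same subject). With a full-size cohort,
`prepost_table()` + `run_stats_battery()` turn per-subject pairs into the
one-tailed Wilcoxon table (T, p, Holm-corrected p per band × effect).

Digital twin, pulse-aligned and seed-averaged:

```r
conn <- generate_connectome(connectome_spec(seed = 1))   # 90 nodes
p <- twin_params(duration_ms = 5000, dt = 0.2, store_every = 5, seed = 6)
ex <- run_experiment(conn, p, f_max_list = c(5, 15, 25, 35), n_seeds = 10)
sapply(ex, function(e) c(pre_kop = mean(e$per_seed$pre_kop),
                         post_kop = mean(e$per_seed$post_kop),
                         dip_ms = e$dip_ms))
#>                 5       15       25       35
#> pre_kop    0.5880   0.3080   0.1842   0.1205
#> post_kop   0.8239   0.7230   0.5212   0.3476
#> dip_ms  1034.0000 487.0000 680.0000 419.0000
```

Subgroup coherence jumps after the pulse at every maximum frequency
(10/10 seeds, Wilcoxon p = 0.001), and the seed-averaged metastability
trace dips below its baseline a few hundred ms later (`dip_ms`,
`dip_depth`) before recovering — the mechanistic account of the
empirical effect. See the methods vignette for why windows *adjacent*
to the pulse see the reset ramp instead of the dip.

## Command line

```sh
Rscript -e 'kopmeta::run_cli()' make-synthetic --kind tms --seed 1 --out-dir cohort/
Rscript -e 'kopmeta::run_cli()' analyze-kop --input cohort/tms_sub-01.h5 --band alpha --out-dir out/
Rscript -e 'kopmeta::run_cli()' simulate-twin --seed 1 --out-dir twin/
```

Formats: BrainVision (.vhdr/.vmrk/.eeg) and EDF import, an HDF5 canonical
container, CSV/TSV traces with JSON sidecars, YAML configs.

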