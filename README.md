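# replifork

Quantification of replication-fork stalling and restart kinetics from
live-cell fluorescence movies.

When nucleotide depletion (hydroxyurea) stalls replication forks, the
sliding clamp PCNA leaves replication foci within minutes while the
ssDNA-binding complex RPA gradually accumulates on the single-stranded
DNA exposed by continued unwinding; drug washout reverses both.
`replifork` is for cell biologists who image tagged PCNA/RPA1 (or similar
focus-forming replisome components) at 30 s resolution and want absolute,
per-fork numbers out of those movies.

Because foci are crowded and irregular, the package does not integrate
focal intensity. It measures the **freely diffusing pool** in foci-free
nuclear regions and exploits conservation of the total nuclear pool.
With `D_t` the background-corrected diffuse intensity and `T_ref` its
mean over a reference window in which the whole pool is free,

    E_t  = T_ref − D_t              (bound intensity)
    F_t  = E_t / T_ref              (bound fraction of the nuclear pool)
    nE_t = E_t / max(⟨E_t⟩₅)        (max-normalized bound intensity)
    G_t  = F_t · N / n_forks        (complexes per fork)
    H_t  = 30 nt · G_t              (ssDNA per fork, RPA channels)

with proteome copy numbers `N` (defaults: HeLa — 865,300 PCNA
homotrimers, 926,424 RPA heterotrimers) and ~4000 active forks.
Stalling/restart trajectories are fitted as single exponentials
(half-time `ln 2 / k`); FRAP recovery is normalized through the
bleached/unbleached-focus ratio chain and decomposed into fast
(diffusing), slow (bound-exchange) and immobile fractions; single tracked
foci are measured through 7×7 kymograms as an independent cross-check of
the diffuse-pool method.

A synthetic-movie generator with fully known ground truth (piecewise
exponential bound-fraction schedules, Gaussian foci, Poisson + read
noise, drift, photobleaching, FRAP bleach events) makes the entire
pipeline testable without microscopy data.

## Worked example

Simulate one cell under the standard conditions (15 min baseline, 1 h
HU, 30 s frames, focus SNR ≈ 10), quantify it end to end, and convert to
per-fork numbers:

```r
library(replifork)
sched <- kinetic_schedule(default_channels("HU"), t_treat = 15,
                          t_washout = NA, t_end = 75)
geo <- scene_geometry(dim = c(128, 128), n_foci = 14, seed = 8)
sim <- render_movie(sched, geo, optics_noise(seed = 9), frame_interval_s = 30)

res <- quantify_movie(sim$movie, roi_set_from_geometry(geo),
                      c(PCNA = "decay", RPA1 = "rise"))
res$fits$PCNA
res$fits$RPA1
```

```
fork_movie: 2 channel(s) [PCNA, RPA1], 151 frames of 128x128 px, 30 s interval
kinetic_fit (decay): t1/2 = 2.01 min, k = 0.344 /min, R2 = 0.929
kinetic_fit (rise): t1/2 = 24.6 min, k = 0.0282 /min, R2 = 0.988
bound PCNA before HU: 26.9% of the nuclear pool
bound RPA1 after 1 h HU: 34.5%
RPA complexes per fork: 80.0  ->  ssDNA per fork: 2400 nt
```

The fitted half-times (2.01 min PCNA dissolution, 24.6 min RPA
accumulation) recover this cell's ground truth (2.1 / 23.9 min) within
single-cell noise; the bound fractions convert to ~80 RPA complexes and
~2400 nt of exposed ssDNA per fork at the end of the treatment.

File-based workflows use the same machinery through `run_simulate()`,
`run_quantify()` and `run_frap()` driven by a YAML/JSON config (movies as
multi-page TIFF + JSON sidecar, traces as tidy CSV), or the thin CLI
wrapper in `inst/scripts/replifork.R`.

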