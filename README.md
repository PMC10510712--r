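# nanodwell

Single-particle residence-time analysis of nanoparticles at the cell
membrane, from two-channel fluorescence time-lapse movies.

When nanoparticles in the medium touch the outer membrane of a living
cell, each adsorption episode ends in one of two ways: the particle
desorbs back into the medium, or the cell internalizes it. Quantifying
*how long* particles reside on the membrane before either outcome — at
the single-event level, on time scales from ~1 s to minutes — requires a
chain of image-analysis steps: localizing diffraction-limited spots,
linking them into trajectories, deciding per frame whether each particle
is outside the cell, adsorbed to the membrane, or internalized, turning
those state timelines into residence events with proper right-censoring,
and fitting a characteristic time to the event-duration histogram.

`nanodwell` implements that chain, plus a synthetic movie generator with
exactly known kinetics so every stage can be validated against ground
truth.

## The model

Membrane residence is modelled as competing exponential risks. Episodes
arrive along the membrane as a Poisson process; each dwells for a time
`T ~ Exp(k_off + k_int)` and resolves to desorption with probability
`k_off / (k_off + k_int)`, otherwise to internalization. Event-duration
histograms are fitted with

```
N(t) = N0 * exp(-t / tau)
```

by nonlinear least squares on the bin counts, with the unbinned
maximum-likelihood estimate (the mean excess over the first occupied bin
edge) reported alongside.

Per-frame states come from line-intensity profiles perpendicular to the
membrane, sampled from outside the cell toward the interior. The
membrane position is the *first* peak of the membrane-stain channel along
the profile (interior peaks are vesicles); a particle is **adsorbed**
when its peak coincides with the membrane peak within one pixel, and
**internalized** only when it is displaced at least two pixels toward
the interior (240 nm at the 120 nm confocal pitch, 90 nm at the 45 nm
STED pitch) — a deliberately conservative rule, so that particles in
membrane invaginations that have not yet pinched off are not counted as
internalized.

Event timing follows the operational definitions: an internalization
time runs from the first adsorbed frame to the first internalized frame
(a single adsorbed frame suffices); a desorption time runs from the
first to the last adsorbed frame and requires at least two successive
adsorbed frames; episodes still adsorbed at the end of the recording are
censored and excluded from time statistics.

## Worked example

Simulate a fast-acquisition recording (1.25 s frames, 120 time points,
seconds-scale kinetics: `k_off = 0.5/s`, `k_int = 0.1/s`), run the full
pipeline, and inspect the result:

```r
library(nanodwell)

cfg <- run_config(mode = "confocal2d", seed = 7,
                  sim = simulation_config(mode = "confocal2d",
                                          n_frames = 120, seed = 7))
run <- run_pipeline(cfg)
print(run)
#> <pipeline_run> confocal2d seed 7
#>  $ episodes         : int 223
#>  $ detections       : int 1134
#>  $ track_points     : int 1134
#>  $ tracks           : int 144
#>  $ classified_points: int 1134
#>  $ events           : int 140
#>   tau desorption: 2.64 s
#>   tau internalization: 12 s

print(run$summary)
#> <residence_summary>
#>             type  n  mean_s     sem_s frac_within_cutoff
#>       desorption 49 2.52551 0.1945589                  1
#>  internalization 22 4.37500 0.4777942                  1
#>   internalized fraction of completed episodes: 0.162
```

223 adsorption episodes were simulated; 144 trajectories were recovered
and classified, yielding 49 valid desorption events and 22
internalizations, all shorter than the 60 s cutoff. The internalized
fraction of completed episodes, 0.162, estimates
`k_int / (k_off + k_int) = 1/6`. The fitted characteristic desorption
time at this event count still carries a sizeable standard error
(`2.64 ± 0.84 s` against a true `1/(k_off+k_int) = 1.67 s`); the
acceptance run below uses ~500 events, where it recovers the true value
within a few percent.

Ground truth lets you audit any stage, e.g. per-frame state accuracy:

```r
state_accuracy(run)$accuracy
```

A thin CLI over the same functions is installed at
`inst/scripts/nanodwell.R`
(`Rscript nanodwell.R simulate|run|detect|track|events|fit ...`).

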