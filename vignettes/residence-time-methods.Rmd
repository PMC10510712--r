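---
title: "Membrane residence-time analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane residence-time analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nanodwell` quantifies how long individual nanoparticles reside on the
outer membrane of a living cell before desorbing or being internalized.
This vignette explains the kinetic model, the image-analysis procedure,
every tunable parameter that matters, the synthetic-data generator that
anchors the test suite, and the design decisions taken where the
procedure was genuinely open.

## 1. The kinetic model

Membrane residence is a competing-risks process. Adsorption episodes
arrive along the membrane contour as a Poisson process with rate
$\lambda$ (events s$^{-1}$ per µm of membrane). Each episode dwells an
exponential time with total hazard $k_\mathrm{off}+k_\mathrm{int}$ and
ends in desorption with probability
$k_\mathrm{off}/(k_\mathrm{off}+k_\mathrm{int})$, otherwise in
internalization. Two consequences matter for the analysis:

* the distribution of completed dwell times is the same for both
  outcomes (outcome and duration are independent), so the internalized
  *fraction* of completed episodes estimates
  $k_\mathrm{int}/(k_\mathrm{off}+k_\mathrm{int})$ regardless of how
  durations are filtered, **provided** both outcomes are counted with
  the same observability rule (see §5);
* sampling at frame interval $\Delta t$ turns the exponential dwell into
  a geometric count of frame ticks with survival
  $q = e^{-\Delta t/\tau}$; by memorylessness the histogram of
  frame-quantized durations still decays with the *same* characteristic
  time $\tau$, so frame quantization does not bias the fit — if the
  histogram is binned correctly (§4).

## 2. From movie to states

1. **Detection** (`detect_particles`). The particle channel is median
   filtered (3×3), band-passed with a scale-matched
   Laplacian-of-Gaussian ($\sigma = d/2\sqrt2$ for expected spot
   diameter $d$), thresholded on the response (`min_quality`), pruned by
   greedy non-maximum suppression at $d/2$, and refined to subpixel
   positions by an intensity-weighted centroid in a window of $2d$ with
   the window-border median subtracted. Candidates whose window crosses
   the image border are dropped (their centroid would be biased).
   Optional background removal (`subtract_background`) subtracts a
   Gaussian-blurred copy (default radius 5 px), appropriate when leaked
   dye accumulates in the cytosol.
2. **Linking** (`link_tracks`). Frame-to-frame optimal assignment
   (Jonker–Volgenant) minimizing total squared displacement, with links
   capped at the maximum linking distance; unmatched detections start
   new tracks and an unmatched track terminates for good — no gap
   closing, so objects moving faster than the cap split into separate
   tracks. Caps default to twice the estimated object size: 0.8 / 1.4 /
   2.4 µm for 40 / 100 / 200 nm particles. The feasibility graph is
   decomposed into connected components first, so the assignment
   problems are tiny. In volumetric mode, detections of one time point
   closer than half the cap across z-planes are first merged into one
   object (intensity-weighted).
3. **Membrane geometry** (`extract_membrane_contour`). The membrane
   channel is smoothed, Otsu-thresholded; the largest connected
   component's filled footprint is the cell interior and its boundary,
   refined to the ridge crest along local normals, is the contour.
   Points are flagged *well defined* where the crest exceeds the image
   background by `contrast_mult` (default 5) robust SDs; only those
   anchor profiles.
4. **Profiles and classification** (`sample_normal_profile`,
   `classify_state`). A line through the contour point nearest the
   particle runs from outside the cell inward (half-length 3 µm, step =
   pitch/3). The membrane position is the **first** membrane-channel
   peak from the outside — interior peaks are vesicles and never move
   the membrane reference. A particle is *internalized* when its signed
   separation $d$ (positive into the cell) is at least the threshold
   (2 pixels: 240 nm confocal, 90 nm STED), *adsorbed* when $|d|$ is
   within the adsorption window (1 pixel), *free* when it is outside by
   more than the window. Separations between window and threshold — the
   "pit zone" of a forming invagination — are conservatively kept as
   adsorbed.
5. **Events** (`extract_events`). Maximal runs of adsorbed frames are
   episodes. Internalization is timed first-adsorbed → first-internalized
   (one adsorbed frame suffices); desorption first → last adsorbed and
   requires two successive adsorbed points (a single coincident frame
   cannot be told from a passer-by); runs reaching the final frame are
   censored and excluded from statistics.
6. **Fits** (`fit_exponential`). Unweighted nonlinear least squares of
   $N(t) = N_0 e^{-t/\tau}$ on histogram counts at bin centres, with the
   unbinned maximum-likelihood $\tau$ (mean excess over the first
   occupied bin edge) as a cross-check.

## 3. Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| pixel pitch | 120 (confocal), 45 (STED) | nm | 2 px = 240 nm / 90 nm thresholds |
| internalization threshold | 2 | px | conservative: guarantees ≥1.5 px ≈ 180 nm true depth |
| adsorption window | 1 | px | "coincident peaks" at pixel resolution |
| profile half-length / step | 3000 / pitch/3 | nm | spans membrane ± vesicles; ≥3 samples per PSF σ |
| peak prominence | 0.2 | of profile range | rejects shoulder ripples, keeps vesicle peaks |
| linking cap | 800/1400/2400 | nm | 2× estimated object size per particle size |
| frame interval | 15 (3D) / 1.25 (2D) / 1.5 (STED) | s | acquisition presets |
| fit bin width | frame interval | s | avoids aliasing the duration lattice (§4) |
| contrast multiple | 5 | robust SD | "well-defined membrane" gate |

## 4. Numerical choices

* **Peak refinement.** Three-point parabolic refinement on bilinearly
  interpolated profiles snaps to the pixel lattice, with errors up to
  ±0.4 px — enough to misclassify a particle 10 nm below the threshold.
  The membrane peak is therefore refined by a least-squares parabola in
  *log* intensity (exact for a Gaussian ridge) over a ±2 px window, and
  the particle's position along the line is the projection of its
  subpixel 2-d localization onto the profile axis, which is the best
  available estimate of the particle-channel peak. The raw profile peak
  is still located (its absence marks the profile invalid) and reported.
* **Histogram support.** Durations cannot be shorter than one frame, so
  the histogram's leading empty bins are not part of the decay and are
  trimmed before fitting; interior zero bins are kept with weight 1.
  Without trimming, the empty $[0,\Delta t)$ bin drags $\tau$ upward by
  a factor ~3 at seconds-scale kinetics.
* **Bin width.** Pipeline fits default to the frame interval. Event
  durations live on the lattice $k\Delta t$; binning a 1.25 s lattice
  into 1.5 s bins maps $k \mapsto \lfloor 5k/6 \rfloor$, so the count
  decay advances one geometric factor per 1.5 s instead of per 1.25 s
  and the fitted time stretches to $\tau' = \tau \cdot 1.5/1.25$ — a
  +20 % aliasing artifact. Matching the bin width
  to the acquisition interval (as the classic 16 s bins at 15 s frames
  and 1.5 s bins at ~1.5 s frames do) eliminates it.
* **Degenerate inputs.** Fewer than three occupied bins →
  "insufficient events"; blank membrane frames or frames whose ridge
  nowhere exceeds background → "no cell found"; tracks shorter than two
  frames carry no displacement information; empty detection lists pass
  through the tracker unchanged.
* **Ties and order.** Detections are processed by decreasing quality
  (non-maximum suppression, z-merging); the assignment step is
  order-independent by construction (tested by permuting detections
  within frames).

## 5. Event accounting and the internalized fraction

The two-point minimum applies to desorption only, while internalization
is valid from a single adsorbed frame. If single-frame desorptions were
simply discarded, the internalized fraction among surviving events would
be inflated from $k_\mathrm{int}/(k_\mathrm{off}+k_\mathrm{int})$ to
roughly $p/(p + (1-p)q)$ — ~0.30 instead of 1/6 at the fast-mode
defaults. `summarize_times` therefore counts `sub_minimum` episodes as
completed desorptions in the fraction's denominator (they contribute no
duration to any fit). Censored episodes are excluded everywhere.

A second accounting rule: an adsorbed run whose immediately preceding
frame is *internalized* does not open a new episode. Near the threshold
an internalized particle can flicker between labels; counting each
return as a fresh adsorption would double-count internalizations. A new
episode requires arrival from the medium (track start or a free frame),
which also preserves genuine re-adsorption after desorption.

## 6. The synthetic-data generator

`simulate_kinetics` + `render_movie` emulate a cell with a closed,
slowly deforming membrane (radial sinusoidal drift, default 10 nm/frame
amplitude, period 60 frames) in a 24 µm arena at three acquisition
presets (confocal 3D: 3 planes at 450 nm spacing — spanning the ~0.9 µm
imaged slab — every 15 s, 40 time points; confocal 2D: 1.25 s, 80
frames; STED: 45 nm pixels, 1.5 s). Adsorbed particles ride the membrane
with slow lateral diffusion (0.005 µm²/s); internalized particles are
transported inward at 200 nm/s with a 0.2 per-frame pause probability
and a rare exit hazard (0.002 s⁻¹); kinetic defaults are minute-scale
for the slow preset (k_off 0.055, k_int 0.008 s⁻¹) and seconds-scale for
the fast ones (k_off 0.5, k_int 0.1 s⁻¹), matching what each acquisition
can resolve. Rendering draws the membrane as a Gaussian-profile ridge
and particles as pixel-integrated Gaussian spots (PSF σ 130–160 nm
confocal, 30–60 nm STED; 5000 photons/particle/frame, 300 at the
membrane crest), then applies Poisson photon noise plus Gaussian read
noise (σ = 3 counts) and digitizes to 16-bit camera counts — which also
makes TIFF fixtures round-trip bit-exactly.

Arrivals are drawn as sequential Poisson-process increments with
per-episode marks interleaved, so extending a movie at the same seed
*extends* the episode list; the censoring-consistency property (censored
episodes complete, nothing else changes) is tested exactly. The
simulator's single RNG stream is seeded from the config; rendering uses
a derived stream (seed + 1) so kinetics are identical with or without
rendering.

**What it does not emulate** — and what passing tests therefore do not
show about real data: photobleaching and blinking; membrane topography
in z (the membrane is a vertical sheet across the thin slab);
agglomerates (objects are single particles); channel crosstalk; cytosol
autofluorescence (unless background subtraction is exercised
explicitly); and desorbed particles remain visible in reality until they
leave the focal volume, whereas the generator drops them immediately —
justified for a ~1 µm slab and free diffusion at ~2 µm²/s, where the
axial escape time is a fraction of a frame, but wrong for very slow
diffusers.

## 7. Open choices made here

* **z-plane spacing** is not dictated by the 0.9 µm slab alone; 3 planes
  at 450 nm were chosen so the planes tile the slab symmetrically.
* **Membrane deformation statistics** are unknown; a low-order radial
  sinusoid parameterized by nm-per-frame drift is the simplest motion
  with a controllable per-frame amplitude.
* **Membrane sampling for 2D runs.** Acquisitions that image the
  membrane only before and after the particle series are supported via
  `overlap_mask` (Otsu-binarized membranes, kept where they coincide
  within 1 px after dilation) and `membrane_sampling = "before_after"`;
  the default uses per-frame contours, since the simulator renders the
  membrane every frame.
* **Deep interior particles.** A tracked particle farther than the
  profile half-length from any membrane is classified by the cell
  footprint: internalized inside, free outside. Without this, a particle
  transported >3 µm inward would revert to "free".
* **Flicker smoothing** (bridging a single non-adsorbed frame inside a
  run) exists as an option (`bridge_flickers`) but defaults to off:
  repeated short interactions are reported as distinct events.

## 8. Problem sizes

The test suite validates stages on 12–16 µm arenas (100–130 px frames,
3–120 time points) and the end-to-end recovery on a 24 µm arena at 400
frames of 1.25 s (~750 simulated episodes, ~500 completed observable
ones), where the fitted desorption characteristic time and the
internalized fraction are checked against the configured hazards at the
tolerances stated in the tests. The acceptance script re-runs the same
computations from scratch under a caller-supplied seed.

## 9. Known limitations

* The classifier is 2-d: axial (z) displacement contributes only via
  the plane-merging step, not via the separation $d$.
* The conservative pit-zone rule systematically delays internalization
  calls by roughly the time to traverse the threshold depth (~1 frame at
  the default transport speed), inflating internalization times; the
  desorption statistics are unaffected.
* Censored episodes are discarded, not survival-corrected; with
  observation windows much longer than $\tau$ the bias is negligible,
  but slow kinetics recorded with short movies will underestimate long
  events.
* The exponential fit assumes a single dwell population;
  multi-exponential or heavy-tailed residence is out of scope.
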