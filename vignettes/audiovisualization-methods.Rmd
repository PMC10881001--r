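---
title: "Audiovisualizing spatiotemporal imaging data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Audiovisualizing spatiotemporal imaging data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonovis)
```

## The problem

Mesoscale and volumetric calcium imaging produce movies with thousands to
millions of voxels per frame. Activity in such data is highly structured —
a modest number of sources (cortical regions, dendritic segments) each
follow their own timecourse — but watching a raw grayscale movie makes it
hard to track several sources at once, and impossible to do so while also
watching the animal's behavior. sonovis addresses this by (a) compressing
the movie into a small set of spatial/temporal components, (b) painting
each component a distinct color in a remixed video, and (c) encoding the
component timecourses as sound, exploiting the ear's native ability to
segregate simultaneous streams by pitch, loudness and timbre.

## The linear model

All downstream steps assume the movie is approximately a nonnegative linear
mixture,

$$V(s, t) \;\approx\; \sum_{n} W(s, n)\, H(n, t),$$

with $V$ the movie (voxels × frames, fluorescence above a nonnegative
baseline), $H$ the basis timecourses and $W \ge 0$ the per-voxel weights.
The factorization route implemented here is the clustering route: voxel
timecourses are k-means clustered under correlation distance, cluster maps
are eroded into ROIs, ROI means give $H$, and $W$ is then fit per voxel by
non-negative least squares (NNLS). PCA or NMF could substitute for the
clustering step conceptually, but are deliberately out of scope; the
clustering route produces components with direct anatomical identity,
which is what the color and pitch assignments rely on.

### Correlation-distance k-means

Distance between a voxel trace and a centroid is $1 - r$ (Pearson). Traces
are z-scored once up front, which makes the distance scale- and
offset-invariant: a voxel whose signal is a positive multiple of another's
clusters with it regardless of local brightness. Implementation choices
that the method statement leaves open, fixed here as:

- **Initialization**: k-means++ under the same distance, **restricted to
  the upper variance quartile of usable voxels**. On movies that are mostly
  background, unrestricted seeding lands most seeds in noise voxels (all of
  which are roughly equidistant from everything) and Lloyd iteration then
  merges genuine sources; in our fixture benchmarks this produced a worse
  objective than the planted partition in roughly a quarter of seeds.
  Restricting the *seed pool* — the objective, assignment rule and centroid
  updates are untouched — removed every such failure while remaining fully
  deterministic given the seed.
- **Restarts**: 10, keeping the lowest total within-cluster distance.
- **Empty clusters** are re-seeded from the voxel farthest from its
  centroid, with a logged message.
- **Zero-variance voxels** are excluded (correlation undefined) and carry
  the background label 0.

### ROI erosion and extraction

Each cluster's binary mask is eroded with the face-connected cross
structuring element (1 iteration by default). Erosion serves two purposes:
it trims the mixed-signal boundary between adjacent sources, and it deletes
isolated stray voxels that joined a cluster by chance, so the ROI mean is
computed over the coherent core. A cluster eroded to nothing falls back to
its un-eroded mask with a warning rather than failing. $H$ is then the
plain ROI mean per frame.

### NNLS and reconstruction

$W(s,\cdot) = \arg\min_{w \ge 0} \lVert V(s,\cdot) - w H \rVert_2$ is
solved independently per voxel (Lawson–Hanson via `pracma::lsqnonneg`), so
results cannot depend on any processing order. The reconstruction
$V' = W H$ is compared to $V$ by per-frame mean residual and global RMS; on
synthetic data the residual RMS lands below the injected noise SD because
the noise was clipped at zero where the model is dark.

### Orderings

Components are ranked either by weight-weighted spatial centroid along a
chosen axis (anatomical ordering, e.g. front-to-back), or by the first
frame their timecourse crosses a threshold (so that, with an ascending
ladder, pitch rises over the recording). Never-crossing components rank
last, in index order; centroid ties break by index. Both orderings are
bijections by construction.

## Sonification

### Analog path

Each component's timecourse, minus its baseline and clipped at zero, is
linearly interpolated from frame rate to audio rate and multiplies a
zero-phase sinusoid at the component's assigned frequency; the tones are
summed and peak-normalized. Linear interpolation (rather than sample/hold)
avoids audible zipper artifacts. The scheme is linear before normalization:
rendering $H_1 + H_2$ equals the sum of separate renders, which the test
suite checks to 1e−9.

- **Baseline**: default is the per-component 10th percentile — a robust
  proxy for a quiescent period. A baseline that is too low saturates the
  stream; too high silences sub-threshold events. It is always overridable
  with an explicit quiescent window.
- **Headroom**: the final mix peaks at −1 dBFS (0.891).

### Digital path

An event is a maximal run of frames with $h > T$ lasting at least
`min_len` frames; its onset is the first frame time, the offset is
half-open (one frame past the last), and its raw strength is the peak of
$h$ within the run. Defaults:

- $T$ = quiescent mean + 2 SD (quiescent frames default to the
  sub-25th-percentile frames). A threshold set too low fuses several
  transients into one sustained note, so a conservative multiple is used.
- `min_len` = 2 frames, suppressing single-frame noise spikes.
- Strength scales linearly to MIDI velocity,
  $\mathrm{round}(127\,S/S_{\max})$, floored at 1 so weak events stay
  audible; the event at the global maximum encodes exactly 127. A
  logarithmic option exists for data with a wide dynamic range.

Events become Standard MIDI Files (format 1, one track per instrument,
fixed 120 bpm at 480 ticks per beat; seconds are the source of truth and
ticks are derived). Overlapping same-key events are merged with a warning,
since nested on/off pairs on one key are ambiguous in the MIDI protocol.
Audio is rendered by a built-in additive synthesizer so output is
deterministic and dependency-free: the **percussive** class has a 5 ms
attack and exponential decay (fast onset, slow decay — overlapping onsets
stay distinguishable), the **sustained** class an 80 ms attack, held
sustain, gentle vibrato, and a different harmonic recipe, so the two
classes are spectrally distinct. Pairing transient components with the
percussive class and slow components with the sustained class mirrors the
piano/violin split between neural and hemodynamic streams.

### Pitch ladders

Pitches cycle a chord's semitone intervals, adding an octave per cycle —
e.g. the minor-seventh ladder (0, 3, 7, 10 semitones) over 18 components
spans exactly five octave registers. Chord ladders rather than arbitrary
frequencies keep simultaneous tones consonant; all frequencies are 12-tone
equal temperament with A4 = 440 Hz. The octave naming convention is
**C3 = key 60** (middle C); note this differs from the also-common C4 = 60.

## Video

Colors are sampled evenly across a map computed by formula (`jet`, `hsv`)
so output is identical across environments, and assigned in component
order. Each frame is $W \cdot \mathrm{diag}(\max(H_{\cdot T}, 0)) \cdot C$,
clipped to $[0,1]$ **after** summation (a single final image, not per-
component clipping); negative activity contributes nothing and renders
black. Display gain is global: the 99th percentile of the pre-clip
intensity distribution maps to 1.0, a deterministic alternative to manual
display scaling. Volumetric components are shown as maximum intensity
projections (top/front/side). Panels compose on a letterboxed grid,
truncating to the shortest stream.

The muxed container is uncompressed RIFF/AVI (24-bit frames, PCM-16 audio,
interleaved, indexed) written natively — bit-exactness is guaranteed for
frames pre-encoding. When an `ffmpeg` binary is present on the PATH, an
H.264 MP4 is produced instead. Audio shorter/longer than the video by more
than one frame period is padded/truncated with a warning; within one frame
period it is adjusted silently.

## The synthetic generator

The fixture generator exists so every pipeline stage is testable with known
ground truth:

- **Spatial**: isotropic Gaussian blobs with unit peak, centers snapped to
  the voxel lattice on a jittered grid. Grid spacing prefers 3σ cells
  (essentially non-overlapping sources) and shrinks toward 2σ only when
  the requested count would not fit; over-capacity requests error.
- **Temporal**: Poisson-timed events (default 6 events/min per component —
  sparse spontaneous activity; at least one event is guaranteed whenever a
  positive rate is requested, so short fixtures never contain degenerate
  all-zero traces) shaped by the double-exponential kernel
  $(1 - e^{-t/\tau_r})\,e^{-t/\tau_d}$ with $\tau_r = 50$ ms,
  $\tau_d = 500$ ms — a GCaMP6f-like transient. The **slow** mode convolves
  the transient trace with a 2 s FWHM Gaussian and delays it 1 s,
  mimicking the hemodynamic response that low-pass filters and lags neural
  activity.
- **Noise**: additive Gaussian (default SD 0.1 against unit-peak events,
  SNR ≈ 10) clipped at zero, since all stages assume nonnegative signal.

What the generator does **not** emulate: optics (PSF blur, photobleaching),
motion artifacts, correlated/global noise, hemodynamic cross-talk into the
fluorescence channel. Passing the recovery tests therefore demonstrates
correctness of the unmixing machinery under the model's own assumptions,
not robustness to every artifact of real recordings.

## Problem sizes and numerical choices

The recovery benchmark uses 6 sources on a 64×64 field over 600 frames at
10 fps — large enough that clustering, erosion and the per-voxel NNLS are
all exercised at realistic aspect ratios, small enough to run comfortably
on a laptop core; the demonstration pipeline uses 32×32 × 240 frames.
Other numerical policies: event windows are half-open `[onset, offset)`;
all ties break by component index; envelope interpolation is linear;
sinusoid phases start at zero; TIFF output is peak-normalized to fit the
format's `[0,1]` domain (RDS round-trips absolute units losslessly);
z-scoring uses the sample SD; NNLS accepts the solver's default
tolerance, and an all-zero row of H is rejected with the offending row
named.

## Known limitations

- Correlation k-means assumes each voxel is dominated by one source;
  heavily overlapping sources belong to NMF-style methods instead.
- The z-score activity filter (threshold 4, >5% of frames) suits
  dark-background microscopy with many events; sparse widefield data can
  fail it entirely, in which case the pipeline logs the fact and proceeds
  unfiltered. Note that with sample z-scores at most ~6% of frames can
  mathematically exceed z = 4, so the 5% rule operates near its feasible
  ceiling.
- HDF5 input is not currently read; use multipage TIFF or RDS containers.
- The built-in synthesizer aims for clarity and determinism, not realistic
  instrument timbre; the SMF output can be taken into any DAW for
  higher-fidelity rendering.
- Stereo placement of components is not implemented; the mix is mono.
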