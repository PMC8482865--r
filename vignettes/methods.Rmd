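---
title: "Quantification methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vipquant)
```

`vipquant` implements the quantification procedures used to characterise
synaptic properties of cortical VIP interneuron subtypes: 3D colocalization
of presynaptic mGluR7 immunopuncta with labelled neurite processes, per-cell
multiplexed ISH quantification with a prior-matched calretinin (CR)
classifier, paired-pulse ratio (PPR) measurement of evoked synaptic
currents, and the group statistics that connect them. This vignette explains
each model, its assumptions, the tunable parameters, and the choices made
where the underlying procedures left the design open.

## 3D puncta-on-process colocalization

The measured statistic is a density: the number of punctum-scale connected
components of `puncta_mask AND process_mask`, divided by the physical
process volume in µm³. The pipeline is

1. **Histogram normalisation.** Both channels can be histogram-matched to a
   reference acquisition (`match_histogram`), a monotone quantile mapping
   that equalises intensity scales across sessions. The reference is an
   explicit input; analysing a stack against itself is the neutral choice
   and is what the batch runner does when no reference is given.
2. **Soma removal.** Cell bodies are found by soma-scale Gaussian blob
   enhancement (`soma_sigma_um`, default 1.5 µm — large enough to dim
   0.5 µm neurites while leaving ~10 µm somas bright), Otsu thresholding,
   and region-based active-contour refinement against the *raw* channel
   (the enhanced image locates somas but displaces their boundary outward
   by roughly the blur radius). Components smaller than `soma_floor_um3`
   (default 300 µm³, about half the volume of a 10 µm cell body) are not
   somas and are dropped. Soma voxels are then removed from the Otsu mask
   of the cell channel, leaving the neurite processes whose voxel count
   times the voxel volume normalises the count.
3. **Puncta segmentation.** Otsu thresholding of the (matched) puncta
   channel, followed by a minimum component size of `puncta_min_voxels`.
   The default is 4 voxels: at the default grid a terminal-scale punctum
   occupies over 30 voxels above threshold, while correlated noise
   excursions of 2–3 voxels are common at moderate SNR — and because the
   AND with the process mask can cut any component, a noise pair
   straddling the process boundary would otherwise survive as a spurious
   single-voxel colocalization. Four voxels sits far below any real
   punctum and far above what voxel noise produces.
4. **Counting.** Connected components of the AND mask under 26-neighbour
   connectivity (`connectivity`; 6 and 18 available). Two true puncta merged
   by the mask count once — the counting rule is defined on the mask, not
   on ground-truth objects.

Otsu's criterion assumes a bimodal intensity histogram. It fails in a
characteristic way on images whose foreground occupies well under ~2% of
voxels: the threshold then splits the *background* mode and the mask floods
with noise. The synthetic stacks therefore emulate what makes real
presynaptic immunostaining tractable — terminals are dense tissue-wide (the
generator's default 2500 off-process puncta in a 65,000 µm³ field, i.e.
most puncta are *not* on the labelled processes), which gives the puncta
channel the foreground mass that makes its histogram bimodal. This is also
scientifically the regime the AND-mask design targets: the whole point of
intersecting with the process mask is that the puncta channel alone is
unselective.

### Anisotropy

Stacks are anisotropic (confocal z-steps are coarser than the pixel size).
All physical parameters (sigmas, radii, separations, volumes) are specified
in micrometres and converted per axis, so kernels and structuring elements
are physically round on the voxel grid. The synthetic default grid is
0.5 × 0.25 × 0.25 µm over 128³ voxels — the same 2× z-anisotropy direction
as the source acquisitions but a wider field, chosen so that whole somas fit
in frame at desk scale.

## Synthetic colocalization stacks

`generate_coloc_stack` renders: persistent random-walk tubes of radius
`process_radius` (0.5 µm default, a dendrite-scale calibre); ellipsoidal
somas (semi-axes 4 × 5 × 5 µm, twice the process brightness, as somatic
cytosolic label accumulates); Gaussian puncta of sigma `puncta_radius`
(0.5 µm, synaptic-terminal scale). On-process puncta are Poisson-placed on
voxels inside the process mask and outside the soma mask — exactly the
definition the pipeline measures after soma removal, which is what makes
the generator's truth comparable to the measured statistic — and the
realised count is recorded, so parameter-recovery comparisons carry no
Poisson sampling error. All puncta keep a minimum centre separation of
5 × `puncta_radius`, which guarantees that thresholded puncta cannot touch
and the noise-free component count equals the placed count exactly.
Additive white noise has sigma = 1/`snr` with unit object amplitude;
negative intensities are clipped at zero, as in any offset-subtracted
acquisition.

What the generator does *not* emulate: a realistic PSF (objects are
rendered directly at their nominal size, not convolved), autofluorescence
texture, intensity falloff with depth, or chromatic misregistration.
Passing recovery tests therefore demonstrates the correctness of the
measurement logic under the stated geometry and noise, not robustness to
every optical artefact of real tissue.

## ISH per-cell quantification

Cell bodies are segmented from the cell-label channel by
difference-of-Gaussians enhancement (defaults 1 and 4 px, a band that
passes 3–6 px cell radii), Otsu thresholding, per-component active-contour
refinement, and an area filter (20–400 µm², generous bounds around
interneuron somata). Transcript channels are background-subtracted by
disk-opening (`background_disk_radius`, default 10 px — larger than any
cell, so cells survive with their amplitude while smooth background goes to
zero) and averaged over each cell's pixels.

Cells are assigned to the region/layer polygon containing their centroid;
a centroid on a shared boundary goes to the pia-proximal layer (first in
the ordered spec), and cells outside every polygon are `"unassigned"`.

### The prior-matched CR classifier

The classifier encodes one assumption: ~80% of VIP cells express CR. Given
per-cell CR means within one image, the threshold is their empirical
(1 − prior) quantile (linear interpolation between order statistics,
type-7), and cells strictly above it are CR⁺. With tied means this
classifies the closest attainable fraction from above, matching the
"approximately 80%" intent. No likelihood model is implied beyond the
quantile rule. The threshold is computed per image by default — intensity
scales are comparable within but not across sections — with a pooled mode
behind a flag. The achieved fraction obeys |fraction − prior| ≤ 1/n for
tie-free data, which is why a 500-cell population yields exactly 400 CR⁺
cells at the default prior.

The statistical unit for group comparisons defaults to the image (section):
per-image means enter a two-sided Mann–Whitney U test. Per-cell testing is
available but treats cells within a section as independent, which they are
not.

The synthetic ISH generator draws each cell's CR mean from a two-component
log-normal mixture (mixing weight `cr_pos_fraction` = 0.8; component means
40 and 120 a.u., separated far beyond the 12% between-cell coefficient of
variation) and its Elfn1 mean from a (genotype × CR class) table whose
default encodes a 2× knockout reduction — the effect size reported by
transcriptomic screening in this system. Cells render as uniform disks; the
measured per-cell mean therefore estimates the drawn mean directly, and
segmentation error enters only through boundary pixels.

## Paired-pulse ratio measurement

Each synthetic sweep is `amp1·g(t−t1) + amp2·g(t−t2)` plus white noise,
with `g` a unit-peak difference of exponentials (rise 0.5 ms, decay 6 ms —
fast AMPA-receptor-mediated kinetics) and stimuli 20 ms apart (50 Hz).
Twelve sweeps are averaged pointwise, matching the averaging protocol of
the recordings.

Amplitudes are measured from the averaged trace: baseline is the 50 ms
pre-stimulus mean; the first amplitude is the peak deviation within
1–15 ms after the stimulus. The window opens right at the end of the 1 ms
artifact blanking because fast glutamatergic transients (0.5 ms rise)
peak around 1.4 ms after the stimulus — a window that opened later would
read the decay, not the peak. Because the second response
rides on the decay of the first, the decay between the pulses (8–19 ms
after stimulus 1) is fit with a single exponential on the log scale and
extrapolated under the second window; the second amplitude is the peak
deviation from that extrapolation. This summation correction is exact for
mono-exponential decays; with the 0.5 ms rise constant, the rise term is
below 10⁻⁸ of the decay term in the fit window, so the noise-free
equal-amplitude case recovers PPR = 1 to better than 10⁻⁶. The correction
can be disabled (`correct_summation = FALSE`), since a plain
peak-from-baseline reading is also in common use; both modes are tested.
An amplitude below 3× the baseline noise SD raises a "no evoked response"
error rather than returning a meaningless ratio.

PPR = amp2/amp1 on positive magnitudes (inward currents are negative;
ratios are reported positive). Release probability is classed *low* for
facilitating pairs (PPR > 1), *high* for depressing pairs (PPR < 1), with
a configurable *moderate* band |PPR − 1| ≤ 0.1 making "PPR ∼ 1" concrete.
Recordings with access resistance above 40 or whole-cell capacitance below
4 pF fail QC, exactly as printed.

## Statistics

All tests are implemented from closed forms, with library routines used
only as independent cross-checks in the test suite:

- **Mann–Whitney U**: midranks for ties; exact p from the full permutation
  distribution of U (dynamic programming over rank-sum subsets) for
  tie-free samples with `n_a·n_b ≤ 400`; otherwise the normal
  approximation with tie and continuity correction. Two-sided exact p uses
  the doubled-tail convention `min(1, 2·min(P(U ≤ u), P(U ≥ u)))`.
- **t tests**: paired t on differences; Welch t with Welch–Satterthwaite
  degrees of freedom for unpaired comparisons (unequal variances assumed
  throughout, as in the source analyses). Zero-variance inputs with equal
  means return p = 1 by stated convention instead of NaN; zero variance
  with unequal means is an error.
- **One-way ANOVA** from the variance decomposition, with pairwise Welch t
  tests and Bonferroni-multiplied p values capped at 1.
- **Candidate filtering** of a differential-expression table keeps rows
  with |log2 ratio| ≥ 0.5 and p ≤ 0.01, inclusive on both bounds as
  printed. Whether the filtering p is raw or adjusted is selectable
  (`p_column`), since conventions differ between the screening filter and
  the formal differential-expression call.

## Numerical choices and degenerate inputs

- **Otsu** uses a 256-bin histogram over the channel's min–max range;
  foreground is *strictly greater than* the threshold; ties between cuts
  resolve to the lowest threshold. The result is invariant to monotone
  affine intensity rescaling up to binning granularity. A constant channel
  is an error, as is a constant histogram-matching reference.
- **Gaussian convolution** uses symmetric reflection at borders (no border
  darkening, hence no Otsu bias) and a kernel truncated at 3 sigma and
  renormalised, so the image mean is conserved.
- **Active contours** use a morphological scheme: interface voxels flip
  toward the closer of the inside/outside region means, then a
  majority-vote (binary median) pass approximates curvature flow
  (`ac_smoothing`, default 1; default budget 35 iterations). The front
  moves at most one voxel per update plus one per smoothing pass, so the
  output stays within a bounded dilation of the initialisation — which is
  also why refinement can run on a padded bounding box of the seed without
  changing the result materially. Without smoothing, an initialisation
  that exactly matches a sharp-edged object is an exact fixed point; with
  smoothing, a digitised disk is rounded by at most a boundary pixel
  (IoU > 0.99), the usual behaviour of median-regularised morphological
  flows.
- **Seeding**: every generator takes one integer seed that fans out to
  fixed per-stage substreams (geometry, placement, noise, population), so
  runs are bit-reproducible and stages stay independent. Generators save
  and restore the caller's RNG state.

## Problem sizes used in the checks

The self-checks run entirely on synthetic data at desk scale, chosen to
exercise each estimator's operating regime: colocalization recovery on a
3 × 3 grid of (on-process density 0.05/0.12/0.25 µm⁻³ × SNR 5/10/20) full
128³ stacks; the soma-exclusion property on ten 48 × 96 × 96 stacks at
SNR 20 with 30 puncta planted strictly inside somas; PPR recovery at
injected ratios 0.6–1.5 under 5 pA noise with 12 sweeps; CR classification
on a 500-cell population; and the knockout-effect recovery on 50
replicates of 18 control + 18 knockout rendered images with 8 cells each.
The Welch type-I rate is verified over 10,000 null simulations.

## Known limitations

- Global Otsu is the stated segmentation primitive; on images whose
  foreground falls well under ~2% of voxels its threshold collapses into
  the background mode. The size filter and the AND-mask intersection
  mitigate but cannot fully rescue that regime; the honest fix on such
  data is a local or percentile threshold, which is out of scope here.
- The summation correction assumes a mono-exponential inter-pulse decay;
  strongly bi-exponential or NMDA-dominated decays would bias the second
  amplitude.
- Region assignment consumes manually drawn polygons; no automatic layer
  segmentation from the nuclear channel is attempted.
- The classifier enforces the CR⁺ prior per image; images whose true CR⁺
  fraction deviates strongly from the prior will be mis-thresholded by
  construction — that is the stated assumption of the method, not a bug.
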