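---
title: "Locally ordered lattice reconstruction on membrane nanotubes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locally ordered lattice reconstruction on membrane nanotubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubelattice)
```

## The problem

Dynamin-family proteins such as Drp1 polymerize on lipid nanotubes into
lattices that are ordered only locally: rungs of stalk dimers wrap the tube,
adjacent rungs are bridged by GTPase (G) domain contacts, but the register
between distant patches of the lattice drifts, so classical helical
reconstruction -- which assumes one global symmetry -- averages incompatible
regions into mush.  The workflow implemented here isolates one locally
ordered surface patch per particle image and treats it as an independent
single particle:

1. estimate each tube's in-plane angle and across-tube shift, and measure
   its diameter from the membrane peaks;
2. build a featureless initial model (the *azimuthal average*) by
   backprojecting the particles at random azimuths and averaging along the
   tube axis;
3. subtract from each raw image the projection of the azimuthal average
   outside a soft spherical region of interest (ROI) on the tube surface,
   and re-center the image on the ROI -- the RASTR operation;
4. refine, reconstruct, classify, and quantify the resulting sub-particles;
5. extract sub-particles at a model-derived 3D coordinate (the
   membrane-contact site of the variable domain) and reconstruct it
   locally.

Because no public dataset accompanies the workflow, the package carries its
own forward model (`tube_lattice_spec()`, `build_lattice_volume()`,
`simulate_particles()`) that generates decorated-nanotube particles with
known ground truth, and every claim the test suite makes is a
parameter-recovery claim against that generator.

## Geometry conventions

All modules share one convention set (see `?rotation_matrix`):
intrinsic ZYZ Euler angles `R = Rz(psi) Ry(tilt) Rz(rot)` with degrees in
metadata; cubic volumes with the tube axis along z and the box center at
voxel `n/2 + 1`; shifts in pixels applied after projection.  A volume point
`p` appears in the projection at `(R p)_xy / pixel_size + shift`, and
`project_point()` and `rotate_project()` are tested to agree at sub-pixel
level.  Tilt 270 is the tilt-90 view with opposite polarity; the exact
identity is `R(rot, 270, psi) = diag(1, -1, -1) R(rot, 90, 180 - psi)`,
i.e. the projection is additionally mirrored in y.

Projections treat the volume as periodic along the tube axis.  Real boxed
filaments are windows cut from much longer tubes, so a finite simulation
box would otherwise show spurious tube ends in oblique views; wrapping in z
makes the simulated tube effectively infinite.  Interpolation is trilinear
everywhere, and reconstruction is weighted backprojection: the exact
adjoint of projection followed by a radial ramp in Fourier space that
compensates the 1/|f| sampling density of central sections.

## The forward model

A decorated tube is two concentric cylindrical Gaussian shells (the
membrane leaflets, radii 100/140 Å, cross-section sd 10 Å) plus Gaussian
blobs at lattice sites.  Each subunit carries a stalk blob (180 Å) and a
bottom-G blob (210 Å); in the stacked state additionally a top-G blob
(235 Å) and, at every second subunit, a membrane-contact rod spanning the
outer leaflet to the VD radius (150 Å).  Twelve subunits form a rung;
successive rungs twist by +12 degrees (right-handed).  Rung spacing is
50 Å (stacked) or 70 Å (relaxed).

Two choices deserve comment:

* **Local order.** Rung `k` sits at `z = k * spacing + e_k` with
  `e_k ~ N(0, spacing_jitter_sd)` (default 5 Å), and each subunit column
  `j` carries an extra axial offset from a Brownian-bridge random walk
  around the circumference (step sd `azimuthal_walk_sd`, default 10 Å, so
  columns half a circumference apart dephase by about half a rung period).
  Nearby columns stay in register; columns far apart in azimuth dephase.
  This is the property that makes a small ROI informative and a large one
  self-cancelling, and it is what the ROI-size scan reproduces
  qualitatively.
* **Protein contrast.** Protein blobs default to 2.5 times the membrane
  shell amplitude (`blob_amplitude`).  With equal amplitudes the membrane
  dominates the tube-region variance so strongly that, at the working
  SNR of 0.1, stacked and relaxed edge views become statistically
  indistinguishable -- contradicting the defining property of the edge
  view.  Published edge-view class averages show protein features at least
  as strong as the membrane, so the default reproduces that contrast.
  `blob_amplitude` is an ordinary spec field and can be set to any value.

Noise is additive white Gaussian applied after the CTF.  "SNR" always
means signal variance over the tube-occupied region (pixels within the
top-G radius plus three blob widths of the projected axis) divided by the
noise variance; the membrane dominates that signal variance, so SNR 0.1
corresponds to much weaker per-blob contrast.  The simulator does not
model membrane flattening differences between states, structured ice or
detector physics.

## Tube alignment and diameter

`estimate_psi_shift()` scans in-plane angles (coarse 4-degree pass, then
the 1-degree grid around the optimum with parabolic refinement) and scores
each angle by the variance of the across-tube profile; the shift is the
symmetric midpoint of the two outermost membrane peaks, and the score
(best/median variance ratio) separates tubes from blank images cleanly.
The 180-degree ambiguity is left unresolved, and the along-tube shift
component is unobservable by construction; every downstream step is
written to be invariant to both.

`measure_diameter()` reports the separation of the outermost symmetric
peak pair.  The projection of a shell of radius R with Gaussian
cross-section peaks slightly *inside* R (the Abel-projection tangent
singularity is pulled inward by the smearing; about 6.6 Å per side at
R = 140, sd 10).  When the shell width is known, `shell_sd` inverts this
bias numerically (`shell_peak_position()` / `shell_radius_from_peak()`),
which is what the lumen-diameter recovery uses.  Diameter binning follows
the 20-bin histogram scheme with ties resolved toward the lower bin.

## The azimuthal average

The initial model backprojects the aligned particles at assigned azimuths
and averages the volume along the tube axis.  Azimuths are assigned
stratified-uniform (a shuffled regular grid with sub-cell jitter):
independent uniform draws leave enough angular clumping at desk-scale
particle counts to move the average by over 1% RMS between seeds, while
the stratified assignment keeps it self-averaging below that.  After
z-averaging, the map is gently low-passed (12 Å) and explicitly
azimuthally symmetrized: the model is featureless by intent, and the
symmetrization removes the few-percent angular ripple that finite-angle
backprojection leaves.  The input is capped at 400 particles, which
changes the result by well under 1% RMS.

## RASTR

The ROI is a soft-edged sphere (cosine falloff, default 20 Å) centered on
the tube surface midway between the outer leaflet and the top-G layer
(187.5 Å) so that a 130-185 Å ROI covers the full protein depth of one
surface.  `subtract_outside_roi()` projects `azavg * (1 - mask)` at the
particle's orientation, CTF-matches it when the defocus is known, fits a
per-particle least-squares amplitude (which is exactly 1 on ideal input)
and subtracts.  Sub-particles are re-centered on the projected ROI center
by Fourier shift and re-booked with `rot = (rot + mask azimuth) mod 360`
and zero shifts.

In edge mode the mask azimuths alternate 90/270 in the viewing frame, and
because the azimuthal average is cylindrically symmetric only two
complement volumes ever need to be built; their projections at `psi = 0`
are reused for every particle by in-plane rotation and translation.  The
generic per-mask path remains available (`fast = FALSE`) and the two are
tested to agree.

## Stacked/relaxed quantification

Edge-view sub-particles are rotated tube-vertical and mirrored so the
membrane always sits on the -x side; the mirror decision is made from the
image itself (the membrane half of the profile is brighter), because the
psi ambiguity makes metadata-based mirroring impossible.

Quantification then works in the axial-frequency domain, which is
invariant to the unknown lattice phase.  For radial bands at the contact
rod/membrane, stalk, bottom-G and top-G positions, the cross-spectra
between band pairs are summed over a rung-frequency window, normalized by
the power of a signal-free reference band (the gap between the near top-G
stripe and the wrapped-in far silhouette).  Rungs in different radial
layers sit at the same axial positions, so true lattice layers are
coherent while noise cross-terms are zero-mean.  The top-G layer exists
only in the stacked state, and in an edge view nothing else reaches its
radial band, so the coherence of top-G with stalk and bottom-G is the
stacked marker.

Three numerical safeguards matter at SNR 0.1:

* CTF delocalization smears rung-frequency power across neighboring
  bands; features are computed on Wiener-corrected images
  (`ctf_wiener()`, constant 0.2) rather than merely phase-flipped ones.
* Each row is apodized along y to the ROI extent and its windowed-DC
  component is removed before the FFT; otherwise the strong smooth
  membrane stripes leak power into the rung window through window
  sidelobes.
* Features are *cross-fitted*: the upper y-half of each image drives the
  grouping, the lower y-half drives the class scores.  The two halves
  carry independent noise, so a class selected on noisy coherence is
  scored without selection bias.

Classes are balanced quantile groups along a monotone coherence axis
(total marker-window coherence minus the alternative-spacing window over
all band pairs).  K-means on these noisy low-dimensional features tends
to collapse into one giant mixed cluster, which ruins count-based
quantification; equal-count groups along a monotone axis cannot
degenerate, and their order is meaningful.  Each class's score is the
member *median* of the top-G coherence (lower-half features); because the
classes are ordered, the scores are monotone up to noise and are
stabilized by isotonic regression before thresholding.  The call
threshold is 3 noise units -- the member-median of an equal mixture of the
two states under the default conditions (relaxed members sit near 0,
stacked members near 7-12), so a class whose median crosses it is
majority-stacked.  The threshold was calibrated once on labeled
simulations at the default conditions and kept fixed.  Validation across
held-out seeds puts the accuracy of the recovered fraction at roughly
+/- 5 percentage points (one sd) at n = 400-1000, limited by the
per-sub-particle information available at SNR 0.1.  The reported fraction is the summed
membership of stacked classes, with a binomial confidence interval at the
number of parent particles.

What passing these tests shows -- and what it does not: the generator
draws both states from the same tube geometry and the same disorder
process, so recovery demonstrates that the subtraction, band geometry and
coherence scoring are self-consistent at realistic noise.  Real data add
off-axis tubes, curvature changes between states, non-white noise and
imperfect CTF estimation, none of which are modeled; the band geometry for
real data would have to come from the experimental radial profile.

## Refinement, FSC, lattice parameters

`projection_match()` is deterministic, low-pass-limited normalized
cross-correlation with FFT shift search and accept-if-better updates,
staged like the 20 Å/20% to 15 Å/50% to 10 Å/100% ladder; it makes no
likelihood claims.  `compute_fsc()` reports shell-wise Fourier
correlation with the 0.143 resolution convention.
`estimate_lattice_params()` grid-searches (rise, twist) by real-space
self-correlation restricted to the protein annulus and flags failure when
the best score does not double the score of the volume's cylindrical
average, which carries no lattice.

## Sub-particle reconstruction

`lattice_contact_points()` emits the nine tube-frame contact sites (the
central VD site and its neighbors one tetramer over in azimuth and one
rung over in z).  Offsets are pure geometry (`project_point`), azimuth
adjustments put each site on the reference azimuth, extraction is
sub-pixel by Fourier shift with an explicit boundary policy, and
reconstruction is plain backprojection without symmetry.  The chain is
validated by an impulse round-trip (an impulse at `p` reconstructs within
one voxel of the sub-box center) and by the contact-bridge contrast
between stacked and relaxed inputs.

## Problem sizes and determinism

The default test and acceptance problem sizes are desk-scale by design:
box 128 at 4 Å/voxel for full particles, 1000 particles for the
state-fraction recoveries, a few hundred elsewhere, smaller boxes (48-64)
for geometry and refinement unit tests.  Every stochastic step takes an
explicit seed.
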