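# tubelattice

Cryo-EM image processing for protein lattices that decorate lipid nanotubes
with only *local* order — the situation of dynamin-family fission proteins
such as Drp1 on GalCer membrane nanotubes, where classical helical
reconstruction fails because no single helical symmetry holds across the
tube.

The package implements, end to end and against its own synthetic forward
model, the locally-ordered reconstruction workflow:

* **Tube alignment** — per-particle in-plane angle and across-tube shift by
  profile-variance maximization; membrane diameter by peak detection with a
  principled correction for the Abel-projection peak bias; diameter
  histogram binning (20 bins, major-bin selection).
* **Azimuthal average** — backprojection at random azimuths followed by
  axial averaging gives a featureless, cylindrically symmetric initial
  model (leaflet shells preserved, protein smeared into an annulus).
* **RASTR** (reconstruction of average subtracted tubular regions) — a soft
  spherical region of interest (ROI) on the tube surface; the projection of
  the azimuthal average *outside* the ROI is CTF-matched, amplitude-fitted
  and subtracted from each raw image; the image is re-centered on the ROI
  and re-booked as an independent sub-particle with
  `rot <- (rot + mask azimuth) mod 360`.
* **Refinement and analysis** — constrained projection matching with a
  staged resolution/fraction ladder, Fourier shell correlation with the
  0.143 convention, and helical lattice (rise, twist) estimation by
  annulus-restricted self-correlation with a cylindrical-baseline
  significance flag.
* **Stacked/relaxed quantification** — edge-view (phi 90/270) sub-particles
  are classified by axial rung-frequency coherence between radial bands;
  the top-G layer exists only in the stacked state, so its coherence with
  the stalk/bottom-G layers calls each class, and summed class memberships
  give the stacked fraction with a binomial CI.
* **Sub-particle reconstruction** — offsets of model-derived 3D sites (the
  nine VD membrane-contact positions at the center of the stacked lattice)
  from pure geometry, sub-pixel extraction (box 128, nine per particle),
  azimuth-adjusted metadata and symmetry-free backprojection.

The synthetic generator (`tube_lattice_spec()`, `simulate_particles()`)
produces decorated nanotubes with a ~20 nm lumen, two lattice states
(stacked: top + bottom G-domain layers, 50 Å rungs, membrane-contact rods;
relaxed: bottom layer only, 70 Å rungs), local-only order via an azimuthal
height walk, CTF and white noise — with full ground truth for every
particle.

## Worked example

```r
library(tubelattice)

spec   <- tube_lattice_spec(stacked_fraction = 0.6)
optics <- optics_params()                      # 4 A/px, 300 kV

sim <- simulate_particles(spec, optics, n = 400, noise_sd = 0, seed = 7)
q   <- quantify_edge_states(sim$stack, sim$records, spec, optics,
                            k = 20, n_masks = 2, seed = 8)
q$fraction
round(q$ci95, 3)
print(q$classes)
```

This run prints

```
> q$fraction
[1] 0.6
> round(q$ci95, 3)
[1] 0.552 0.648
> print(q$classes)
class_average_set: 20 classes over 800 particles
  stacked classes: 12 (60.0% of particles)
```

i.e. from 400 particles whose realized stacked fraction was 0.59, the
edge-view RASTR + classification pipeline recovers 60.0% with a binomial
95% CI of about ±5 points; at the acceptance conditions (SNR 0.1,
n = 1000) the recovery is accurate to roughly ±5 percentage points.

Measuring the tube itself:

```r
bare <- simulate_particles(spec, optics, n = 1, noise_sd = 0, seed = 1,
                           decorated = FALSE)
img  <- bare$stack$data[, , 1]
est  <- estimate_psi_shift(img)
dfoc <- bare$records$defocus[1]
img  <- ctf_phase_flip(img, optics, dfoc)   # restore contrast polarity
measure_diameter(img, est$psi, 4, shell_sd = spec$membrane_sd,
                 transfer = function(f) abs(ctf_1d(f, optics, dfoc)))
#> [1] 279.8172   # outer-leaflet diameter, A (truth: 280)
```

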