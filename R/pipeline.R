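#' Edge-view stacked-state quantification pipeline
#'
#' The full workflow used to measure the stacked/relaxed equilibrium on a
#' raw particle stack: per-particle psi/shift alignment, random azimuth
#' assignment, azimuthal-average initial model, edge-mode RASTR sub-particle
#' creation, canonical alignment, 2D classification and per-class
#' stacked-state calling.
#'
#' @param stack raw particle [image_stack()].
#' @param records raw records (only `defocus` and `tl_` columns are used;
#'   alignment is re-estimated).
#' @param spec the [tube_lattice_spec()] providing the scoring band geometry.
#' @param optics an [optics_params()].
#' @param k number of 2D classes.
#' @param n_masks edge masks per particle (2 covers both silhouettes).
#' @param mask_radius ROI radius, Angstrom.
#' @param seed RNG seed for every stochastic step.
#' @return list as [quantify_stacked_fraction()] plus `records` (aligned),
#'   `azavg` and `sub` (the sub-particle set).
#' @export
quantify_edge_states <- function(stack, records, spec, optics, k = 20,
                                 n_masks = 2, mask_radius = 185, seed = 1) {
  records <- align_tube_stack(stack, records, optics = optics)
  keep <- which(is.finite(records$psi))
  if (!length(keep)) stop_tl("no aligned particles", "tl_invalid_argument")
  if (length(keep) < nrow(records)) {
    stack <- image_stack(stack$data[, , keep, drop = FALSE], stack$pixel_size)
    records <- records[keep, , drop = FALSE]
  }
  records <- assign_random_orientations(records, seed = seed + 1)
  azavg <- azimuthal_average(stack, records, assign = FALSE,
                             ctf_mode = "phase_flip", optics = optics)
  sub <- make_rastr_subparticles(stack, records, azavg, mask_radius,
                                 n_masks = n_masks, phi_mode = "edge",
                                 seed = seed + 2,
                                 center_radius = roi_center_radius(spec),
                                 optics = optics)
  q <- quantify_stacked_fraction(sub$stack, sub$records,
                                 stacked_band_geometry(spec), k = k,
                                 seed = seed + 3, optics = optics)
  c(q, list(records = records, azavg = azavg, sub = sub))
}
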