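#' 2D classification of aligned sub-particles
#'
#' Dimensionality reduction (PCA of masked, band-pass-filtered, optionally
#' phase-flipped and downsampled images) followed by k-group clustering:
#' k-means with deterministic quantile-bin initialization for pixel/spectrum
#' features, balanced quantile groups along the coherence axis for
#' `"coherence"` features.  Class averages are the plain means of the
#' member images.  Deterministic given `seed` and invariant to particle
#' order.
#'
#' @param stack an [image_stack()] of pre-aligned particles (psi resolved,
#'   ROI centered).
#' @param k number of classes.
#' @param n_iter maximum k-means iterations.
#' @param seed RNG seed.
#' @param records optional records supplying `defocus` for per-particle
#'   phase flipping before feature extraction.
#' @param optics an [optics_params()]; required for phase flipping.
#' @param bp_low,bp_high band-pass resolution limits, Angstrom.
#' @param features `"pixels"` (masked, downsampled pixel values),
#'   `"yspec"` (per-row power spectra along y: translation-invariant along
#'   the tube axis, so lattice phase is not a nuisance variable),
#'   `"bandpower"` (mean axial power per radial band and frequency window,
#'   see `band_defs`/`freq_windows`) or `"coherence"` (real cross-spectra
#'   between all pairs of radial bands per frequency window, normalized by
#'   the power of the last band, which should be signal-free: rungs in
#'   different radial layers sit at the same axial positions, so their
#'   cross-spectrum at the rung frequency is positive for true lattice
#'   layers while pure-noise cross-terms average to zero.  Used for
#'   stacked/relaxed quantification).
#' @param mask_frac circular feature mask radius as a fraction of the half
#'   box (pixel features).
#' @param downsample integer feature downsampling factor (pixel features).
#' @param band_range x interval (Angstrom, relative to the box center) whose
#'   rows enter the `"yspec"` features.
#' @param band_defs named list of x intervals (Angstrom) for `"bandpower"`.
#' @param freq_windows named list of axial frequency windows (1/Angstrom)
#'   for `"bandpower"`.
#' @param y_halfwidth half-width (Angstrom) of a raised-cosine apodization
#'   along y applied before `"bandpower"` spectra (match it to the ROI
#'   radius so out-of-ROI noise does not enter the window; `NULL` = none).
#' @param n_pc number of principal components retained.
#' @param align_y cyclically align members along y to their class running
#'   mean before averaging (restores axial periodicity in the averages when
#'   members differ by lattice phase).
#' @param align_rows row indices used for the `align_y` correlation
#'   (default: all rows).
#' @return object of class `class_average_set`: list with `averages`
#'   (n x n x k array), `assignment` (length-m integer), `counts`, `k`.
#' @export
classify_2d <- function(stack, k, n_iter = 30, seed = 1, records = NULL,
                        optics = NULL, bp_low = 300, bp_high = 20,
                        features = c("pixels", "yspec", "bandpower",
                                     "coherence"),
                        mask_frac = 0.9, downsample = 2,
                        band_range = c(-80, 80), band_defs = NULL,
                        freq_windows = NULL, y_halfwidth = NULL, n_pc = 40,
                        align_y = FALSE, align_rows = NULL) {
  features <- match.arg(features)
  m <- n_images(stack)
  if (k < 1) stop_tl("k must be >= 1", "tl_invalid_argument")
  if (k > m) stop_tl("k must not exceed the number of particles", "tl_invalid_argument")
  n <- dim(stack$data)[1]
  ps <- stack$pixel_size
  ax <- seq_len(n) - (n / 2 + 1)
  fmask <- sqrt(outer(ax^2, ax^2, "+")) <= mask_frac * n / 2
  band_rows <- which(ax * ps >= band_range[1] & ax * ps <= band_range[2])
  kmax_y <- min(n %/% 2, ceiling(n * ps / 25))   # keep periods down to ~25 A
  if (features %in% c("bandpower", "coherence") &&
      (is.null(band_defs) || is.null(freq_windows)))
    stop_tl("bandpower/coherence features need band_defs and freq_windows",
            "tl_invalid_argument")
  fy <- abs(fft_freq(n, ps))                     # axial frequency per FFT bin
  ywin <- if (is.null(y_halfwidth)) rep(1, n) else {
    d <- abs(ax) * ps
    w <- 0.5 * (1 + cos(pi * pmin(pmax((d - 0.7 * y_halfwidth) /
                                         (0.6 * y_halfwidth), 0), 1)))
    w
  }
  flip <- !is.null(optics) && !is.null(records$defocus) && !anyNA(records$defocus)
  filtered <- array(0, dim = dim(stack$data))
  featlist <- vector("list", m)
  for (i in seq_len(m)) {
    img <- get_image(stack, i)
    if (flip) {
      img <- if (features %in% c("bandpower", "coherence")) {
        # Wiener correction re-localizes CTF-delocalized signal, which
        # matters when nearby radial bands must be kept apart
        ctf_wiener(img, optics, records$defocus[i])
      } else ctf_phase_flip(img, optics, records$defocus[i])
    }
    filtered[, , i] <- img
    # band powers/coherences are measured on the unfiltered image: the
    # frequency windows do the filtering, and an extra band-pass would tilt
    # the noise spectrum
    if (!features %in% c("bandpower", "coherence"))
      img <- bandpass_filter(img, ps, low = bp_low, high = bp_high)
    featlist[[i]] <- if (features == "pixels") {
      as.vector(downsample_image(img * fmask, downsample))
    } else if (features == "yspec") {
      sp <- Mod(t(apply(img[band_rows, , drop = FALSE], 1, fft)))
      as.vector(sp[, seq_len(kmax_y + 1), drop = FALSE])
    } else if (features == "bandpower") {
      f <- numeric(0)
      wn2 <- sum(ywin^2)
      for (b in band_defs) {
        rws <- which(ax * ps >= b[1] & ax * ps <= b[2])
        pw <- rowMeans(vapply(rws, function(r) {
          v <- img[r, ] * ywin
          # remove the windowed-DC component: strong smooth stripes would
          # otherwise leak power into the rung windows via window sidelobes
          v <- v - ywin * (sum(v * ywin) / wn2)
          Mod(fft(v))^2
        }, numeric(n)))
        for (w in freq_windows)
          f <- c(f, mean(pw[fy >= w[1] & fy <= w[2]]))
      }
      f
    } else {
      # Cross-fitted coherences: features from the upper y-half drive the
      # clustering, features from the lower y-half drive the class scores.
      # The two halves carry independent noise, so a cluster selected on
      # (noisy) upper-half coherence is scored without selection bias.
      f <- numeric(0)
      for (half in list(ax >= 0, ax < 0)) {
        yw <- ywin * half
        wn2 <- sum(yw^2)
        sp <- lapply(band_defs, function(b) {
          rws <- which(ax * ps >= b[1] & ax * ps <= b[2])
          s <- 0
          for (r in rws) {
            v <- img[r, ] * yw
            v <- v - yw * (sum(v * yw) / wn2)
            s <- s + fft(v)
          }
          s / length(rws)
        })
        nb <- length(sp)
        wins <- lapply(freq_windows, function(w) which(fy >= w[1] & fy <= w[2]))
        nrm <- mean(Mod(sp[[nb]][unlist(wins)])^2)  # last band: noise ref
        for (b1 in seq_len(nb - 1)) for (b2 in seq_len(nb - 1)) {
          if (b2 <= b1) next
          cc <- sp[[b1]] * Conj(sp[[b2]])
          for (w in wins) f <- c(f, sum(Re(cc[w])) / (nrm + 1e-12))
        }
      }
      f
    }
  }
  feats <- do.call(rbind, featlist)
  band_powers <- NULL
  if (features == "bandpower") {
    band_powers <- feats
    colnames(band_powers) <- as.vector(outer(names(freq_windows),
                                             names(band_defs),
                                             function(w, b) paste(b, w, sep = ".")))
    feats <- log(feats + 1e-12)
  }
  coh_axis <- NULL
  if (features == "coherence") {
    bn <- names(band_defs)
    nms <- character(0)
    for (b1 in seq_along(bn)[-length(bn)]) for (b2 in seq_along(bn)[-length(bn)]) {
      if (b2 <= b1) next
      nms <- c(nms, paste(bn[b1], bn[b2], names(freq_windows), sep = "."))
    }
    half <- ncol(feats) / 2
    band_powers <- feats[, half + seq_len(half), drop = FALSE]  # lower half
    colnames(band_powers) <- nms
    feats <- feats[, seq_len(half), drop = FALSE]               # upper half
    # grouping axis: total coherence in the first (marker) frequency window
    # minus the second, over all band pairs -- increases with lattice
    # order at the marker spacing
    nw <- length(freq_windows)
    w1 <- seq(1, half, by = nw)
    coh_axis <- rowSums(feats[, w1, drop = FALSE]) -
      rowSums(feats[, w1 + 1, drop = FALSE])
  }
  feats <- sweep(feats, 2, colMeans(feats))
  csd <- apply(feats, 2, sd)
  feats <- sweep(feats, 2, pmax(csd, 1e-12 + max(csd) * 1e-6), "/")
  n_pc <- min(n_pc, m - 1, ncol(feats))
  scores <- if (m >= 2 && n_pc >= 1) {
    ev <- eigen(crossprod(feats) / m, symmetric = TRUE)
    feats %*% ev$vectors[, seq_len(n_pc), drop = FALSE]
  } else feats
  assignment <- if (k == 1) {
    rep(1L, m)
  } else if (features == "coherence") {
    # balanced quantile classes along the coherence axis: k-means on these
    # noisy low-dimensional features tends to collapse into one giant
    # mixed cluster, which ruins count-based quantification; equal-count
    # groups along a monotone axis cannot degenerate, and their order is
    # meaningful (class index increases with lattice order)
    grp <- integer(m)
    grp[order(coh_axis, method = "radix")] <- as.integer(cut(seq_len(m), k))
    grp
  } else {
    # k-means initialized at the centroids of PC1-quantile bins:
    # deterministic and invariant to particle order
    ord <- order(scores[, 1], method = "radix")
    grp <- as.integer(cut(seq_len(m), k))
    ctrs <- rowsum(scores[ord, , drop = FALSE], grp) /
      as.vector(table(grp))
    ctrs <- ctrs + 1e-9 * seq_len(k)    # break exact duplicates
    with_seed(seed, {
      kmeans(scores, centers = ctrs, iter.max = n_iter)$cluster
    })
  }
  averages <- array(0, dim = c(n, n, k))
  counts <- tabulate(assignment, nbins = k)
  for (cl in seq_len(k)) {
    idx <- which(assignment == cl)
    if (!length(idx)) next
    averages[, , cl] <- if (align_y) {
      class_mean_align_y(filtered[, , idx, drop = FALSE], rows = align_rows)
    } else {
      apply(filtered[, , idx, drop = FALSE], c(1, 2), mean)
    }
  }
  structure(list(averages = averages, assignment = assignment, counts = counts,
                 k = k, pixel_size = ps, band_powers = band_powers),
            class = "class_average_set")
}

# Average a set of images after cyclic y-alignment to the running mean.
# Alignment correlates the axial profiles of the given rows (defaults to
# all), so it can be restricted to the signal-bearing band.
class_mean_align_y <- function(arr, rows = NULL, n_pass = 3) {
  n <- dim(arr)[1]; m <- dim(arr)[3]
  if (m == 1) return(arr[, , 1])
  if (is.null(rows)) rows <- seq_len(n)
  shifts <- integer(m)
  avg <- apply(arr, c(1, 2), mean)
  for (pass in seq_len(n_pass)) {
    b <- colMeans(avg[rows, , drop = FALSE])
    fb <- fft(b - mean(b))
    for (i in seq_len(m)) {
      # cyclic cross-correlation of axial band profiles
      a <- colMeans(arr[rows, , i, drop = FALSE])
      cc <- Re(fft(Conj(fft(a - mean(a))) * fb, inverse = TRUE))
      shifts[i] <- which.max(cc) - 1
    }
    acc <- array(0, dim = c(n, n))
    for (i in seq_len(m)) {
      sh <- shifts[i] %% n
      idx <- ((seq_len(n) - 1 + sh) %% n) + 1
      acc <- acc + arr[, idx, i]
    }
    avg <- acc / m
  }
  avg
}

#' @export
print.class_average_set <- function(x, ...) {
  cat(sprintf("class_average_set: %d classes over %d particles\n",
              x$k, sum(x$counts)))
  if (!is.null(x$stacked_call))
    cat(sprintf("  stacked classes: %d (%.1f%% of particles)\n",
                sum(x$stacked_call), 100 * sum(x$counts[x$stacked_call]) / sum(x$counts)))
  invisible(x)
}

#' Radial band geometry for stacked-state scoring of edge views
#'
#' For an edge-view sub-particle (tube axis vertical, ROI on the silhouette
#' centered in the box, membrane on the -x side) each protein layer at tube
#' radius `r` appears as a vertical stripe at `x = r - center_radius`
#' (Angstrom, relative to the box center).  Returns the stripe positions of
#' the stalk and top-G layers plus the stripe half-width.
#'
#' @param spec a [tube_lattice_spec()].
#' @param center_radius ROI center radius, Angstrom (see
#'   [roi_center_radius()]).
#' @return list with `stalk_x`, `topG_x`, `halfwidth` (Angstrom).
#' @export
stacked_band_geometry <- function(spec, center_radius = roi_center_radius(spec)) {
  list(membrane_x = spec$leaflet_radii[2] - center_radius,
       stalk_x = spec$layer_radii[["stalk"]] - center_radius,
       bottomG_x = spec$layer_radii[["bottomG"]] - center_radius,
       topG_x = spec$layer_radii[["topG"]] - center_radius,
       halfwidth = spec$blob_sd,
       spacing_stacked = spec$rung_spacing_stacked,
       spacing_relaxed = spec$rung_spacing_relaxed)
}

#' Score a class average for the stacked-state feature
#'
#' The top G layer exists only in the stacked state, and in an edge view
#' nothing else reaches the top-G radial band (the relaxed tube's silhouette
#' ends at the bottom G layer).  The score is therefore the rung-periodic
#' axial signal amplitude in the top-G band normalized by the same amplitude
#' in the stalk band, both net of the noise floor measured outside the tube
#' silhouette; it is phase-invariant, so class averages need no axial
#' alignment.  A class is called stacked when the score exceeds `threshold`.
#'
#' @param class_average numeric matrix (edge view, tube vertical, ROI
#'   centered, membrane on the -x side).
#' @param geometry band definitions from [stacked_band_geometry()].
#' @param pixel_size Angstrom per pixel.
#' @param threshold stacked call threshold.
#' @return list with `score` and `is_stacked`.
#' @export
score_class_stacked <- function(class_average, geometry, pixel_size,
                                threshold = 0.2) {
  n <- nrow(class_average)
  c0 <- n / 2 + 1
  band_rows <- function(x_a, hw = geometry$halfwidth) {
    cols <- c0 + round((x_a + c(-1, 1) * hw) / pixel_size)
    if (cols[1] < 1 || cols[2] > n)
      stop_tl("scoring band outside the image", "tl_invalid_argument")
    seq(cols[1], cols[2])
  }
  fy <- abs(fft_freq(n, pixel_size))
  win <- fy >= 0.75 / geometry$spacing_stacked &
    fy <= 1.30 / geometry$spacing_stacked
  band_power <- function(rows) {
    pw <- rowMeans(vapply(rows, function(r) Mod(fft(class_average[r, ]))^2,
                          numeric(n)))
    mean(pw[win])
  }
  p_top <- band_power(band_rows(geometry$topG_x))
  p_stalk <- band_power(band_rows(geometry$stalk_x))
  # noise reference: the clean gap between the near top-G stripe and the
  # wrapped-in far silhouette
  p_noise <- band_power(band_rows(geometry$topG_x + 22, 9))
  den <- max(p_stalk - p_noise, 1e-12)
  score <- sqrt(max(p_top - p_noise, 0) / den)
  list(score = score, is_stacked = score > threshold)
}

#' Rotate edge-view sub-particles to the canonical frame
#'
#' Rotates each sub-image so the tube axis is vertical and mirrors it, when
#' needed, so the membrane always lies on the -x side of the ROI center.
#' Because psi carries a 180-degree ambiguity and the ROI may sit on either
#' silhouette, the mirror decision is made from the image itself: the
#' membrane half of the across-tube profile is the brighter one (images are
#' phase-flipped for the decision when optics are available).  Records get
#' `psi = 0` and `rot = 90`.
#'
#' @param stack sub-particle [image_stack()] from
#'   [make_rastr_subparticles()] in edge mode.
#' @param records matching sub-records.
#' @param optics an [optics_params()] for phase flipping during the mirror
#'   decision.
#' @return list with `stack` and `records` (`tl_mirrored` added).
#' @export
align_edge_subparticles <- function(stack, records, optics = NULL) {
  m <- n_images(stack)
  n <- dim(stack$data)[1]
  ps <- stack$pixel_size
  xs <- (seq_len(n) - (n / 2 + 1)) * ps
  inner <- xs >= -70 & xs <= -25        # membrane-to-stalk band, -x side
  outer <- xs >= 25 & xs <= 70
  out <- array(0, dim = dim(stack$data))
  mirrored <- logical(m)
  for (i in seq_len(m)) {
    img <- cpp_rotate_image(get_image(stack, i), 90 - records$psi[i])
    det <- if (!is.null(optics) && is.finite(records$defocus[i]))
      ctf_phase_flip(img, optics, records$defocus[i]) else img
    prof <- rowMeans(det)
    if (mean(prof[outer]) > mean(prof[inner])) {
      img <- img[c(1, n:2), ]
      mirrored[i] <- TRUE
    }
    out[, , i] <- img
  }
  records$psi <- 0
  records$rot <- 90
  records$tl_mirrored <- mirrored
  list(stack = image_stack(out, stack$pixel_size), records = records)
}

#' Quantify the stacked-state fraction from edge-view sub-particles
#'
#' Classifies canonical edge views into `k` classes, calls each class
#' stacked or relaxed by its top-G band score, and sums the member counts of
#' stacked classes.  The confidence interval is the normal approximation to
#' the binomial at the effective number of independent particles (parents,
#' not sub-particles).
#'
#' @param stack edge-mode sub-particle [image_stack()].
#' @param records matching sub-records.
#' @param geometry band definitions from [stacked_band_geometry()].
#' @param k number of classes.
#' @param seed RNG seed.
#' @param optics an [optics_params()] for phase flipping.
#' @param threshold stacked call threshold.
#' @param roi_halfwidth ROI extent along the tube axis, Angstrom (apodizes
#'   the spectral features; match to the RASTR mask radius).
#' @param ... passed to [classify_2d()].
#' @return list with `fraction`, `ci95` (length-2), `classes` (a
#'   `class_average_set` with `stacked_call` and `class_score` filled in)
#'   and `n` (sub-particle count).
#' @export
quantify_stacked_fraction <- function(stack, records, geometry, k = 20,
                                      seed = 1, optics = NULL,
                                      threshold = 3, roi_halfwidth = 200,
                                      ...) {
  al <- align_edge_subparticles(stack, records, optics = optics)
  g <- geometry
  band_defs <- list(
    rod = g$membrane_x + c(-11, 14),        # membrane + VD contact rods
    stalk = g$stalk_x + c(-13, 8),
    bottomG = g$bottomG_x + c(-14, 8),
    topG = g$topG_x + c(-12, 7),
    # clean gap between the near top-G stripe and the wrapped-in far
    # silhouette: the last band is the coherence noise reference
    gap = g$topG_x + c(13, 31))
  freq_windows <- list(
    rung_stacked = c(0.78, 1.27) / g$spacing_stacked,
    rung_relaxed = c(0.80, 1.10) / g$spacing_relaxed)
  cls <- classify_2d(al$stack, k = k, seed = seed, records = al$records,
                     optics = optics, features = "coherence",
                     band_defs = band_defs, freq_windows = freq_windows,
                     y_halfwidth = roi_halfwidth, ...)
  # Class score from member cross-band coherences: the top G layer exists
  # only in the stacked state, so its rung-frequency coherence with the
  # stalk and bottom-G layers is the stacked marker.  The units are
  # noise-referenced (gap band) and noise cross-terms are zero-mean, so a
  # relaxed member scores ~0 while a stacked member scores the top-G
  # coherence level.  The class score is the member MEDIAN, which is robust
  # to the heavy-tailed per-image normalization and follows the class
  # majority; a class is called stacked above `threshold` (noise units).
  bp <- cls$band_powers
  memb <- bp[, "stalk.topG.rung_stacked"] + bp[, "bottomG.topG.rung_stacked"]
  sc <- vapply(seq_len(k), function(cl) {
    idx <- which(cls$assignment == cl)
    if (!length(idx)) return(0)
    stats::median(memb[idx])
  }, numeric(1))
  # classes are ordered along the coherence axis, so the class scores are
  # monotone up to noise; isotonic smoothing stabilizes the call cutoff
  sc_iso <- if (k > 1) stats::isoreg(seq_len(k), sc)$yf else sc
  call <- sc_iso > threshold
  sc <- pmax(sc, 0)
  cls$class_score <- sc
  cls$stacked_call <- call
  frac <- sum(cls$counts[call]) / sum(cls$counts)
  n_eff <- if (!is.null(records$tl_parent)) length(unique(records$tl_parent))
           else n_images(stack)
  se <- sqrt(frac * (1 - frac) / n_eff)
  list(fraction = frac, ci95 = c(max(0, frac - 1.96 * se), min(1, frac + 1.96 * se)),
       classes = cls, n = n_images(stack))
}
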