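#' Constrained projection-matching refinement
#'
#' Classic deterministic projection matching: per stage, each (sampled)
#' particle's permitted Euler angles are grid-searched coordinate-wise
#' around their current values; candidates are scored by low-pass-limited
#' normalized cross-correlation against the reference projection with shift
#' optimization via FFT cross-correlation, and an update is accepted only if
#' it improves the score.  Later stages typically widen the particle
#' fraction and tighten the resolution limit (the 20 A/20% to 15 A/50% to
#' 10 A/100% ladder).
#'
#' @param stack an [image_stack()].
#' @param records particle records (angles, shifts).
#' @param reference a [density_volume()] on the same grid.
#' @param stages list of stages; each a list with `search` (half-range,
#'   degrees), `step` (degrees), `reslim` (low-pass limit, Angstrom),
#'   `frac` (particle fraction in (0, 1]), optional `angles` (subset of
#'   `c("rot", "tilt", "psi")`, default all) and `n_iter` (default 2).
#' @param max_shift shift search radius, pixels.
#' @return list with `records` (updated) and `scores` (per particle).
#' @export
projection_match <- function(stack, records, reference, stages,
                             max_shift = 6) {
  if (!length(stages)) stop_tl("stage list must be non-empty", "tl_invalid_argument")
  m <- n_images(stack)
  n <- dim(stack$data)[1]
  ps <- stack$pixel_size
  vol <- as.vector(reference$data)
  scores <- rep(-Inf, m)
  bandlimit <- function(img, filt) Re(fft(fft(img) * filt, inverse = TRUE)) / n^2
  score_one <- function(img_f, img_norm, e, lp) {
    proj <- cpp_project(vol, n, rotation_matrix(e), 0, 0)
    proj_bl <- bandlimit(proj, lp$filt)
    cc <- Re(fft(img_f * Conj(fft(proj_bl)), inverse = TRUE)) / n^2
    cc_w <- cc[lp$shift_ok]            # shifts within max_shift (FFT wrap layout)
    best <- which.max(cc_w)
    den <- img_norm * sqrt(sum(proj_bl^2))
    list(score = if (den > 0) cc_w[best] / den else -Inf,
         shift = lp$shifts[best, ])
  }
  for (stage in stages) {
    search <- stage$search; step <- stage$step
    reslim <- stage$reslim; frac <- stage$frac
    which_ang <- if (is.null(stage$angles)) c("rot", "tilt", "psi") else stage$angles
    n_iter <- if (is.null(stage$n_iter)) 2 else stage$n_iter
    idx <- seq_len(max(1, floor(frac * m)))
    fr <- freq_grid2d(n, ps)
    filt <- ifelse(fr <= 1 / reslim, 1, 0)
    filt[1, 1] <- 0                    # exclude DC so correlation is mean-free
    sx_g <- fft_freq(n) * n; sy_g <- fft_freq(n) * n
    grid <- expand.grid(dx = sx_g, dy = sy_g)
    shift_ok <- abs(grid$dx) <= max_shift & abs(grid$dy) <= max_shift
    lp <- list(filt = filt, shifts = as.matrix(grid[shift_ok, ]),
               shift_ok = shift_ok, apod = 1)
    for (iter in seq_len(n_iter)) {
      changed <- FALSE
      for (i in idx) {
        img <- bandlimit(get_image(stack, i), filt)
        img_f <- fft(img)
        img_norm <- sqrt(sum(img^2))
        cur <- c(rot = records$rot[i], tilt = records$tilt[i], psi = records$psi[i])
        base <- score_one(img_f, img_norm, euler(cur[1], cur[2], cur[3]), lp)
        best_score <- base$score; best <- cur; best_shift <- base$shift
        for (angname in which_ang) {
          cand <- best
          for (d in seq(-search, search, by = step)) {
            if (d == 0) next
            cand[angname] <- (cur[angname] + d) %% 360
            r <- score_one(img_f, img_norm, euler(cand[1], cand[2], cand[3]), lp)
            if (r$score > best_score) {
              best_score <- r$score; best <- cand; best_shift <- r$shift
              changed <- TRUE
            }
          }
          cur <- best
        }
        records$rot[i] <- best[1]; records$tilt[i] <- best[2]; records$psi[i] <- best[3]
        # cc displacement d means the image is the projection moved by +d
        records$sx[i] <- best_shift[1]
        records$sy[i] <- best_shift[2]
        scores[i] <- best_score
      }
      if (!changed) break
    }
  }
  list(records = records, scores = scores)
}

#' Fourier shell correlation of two volumes
#'
#' Shell-wise normalized cross-correlation of the Fourier coefficients;
#' shells with zero power get correlation 0.
#'
#' @param volA,volB [density_volume()]s on the same grid.
#' @return object of class `fsc_curve`: data frame with `freq` (1/Angstrom)
#'   and `fsc`, plus a `resolution_at(threshold)` convention via
#'   [fsc_resolution()].
#' @export
compute_fsc <- function(volA, volB) {
  if (!identical(dim(volA$data), dim(volB$data)))
    stop_tl("volumes must share the grid", "tl_invalid_argument")
  n <- dim(volA$data)[1]
  ps <- volA$pixel_size
  fa <- fft(volA$data); fb <- fft(volB$data)
  f <- fft_freq(n, ps)
  fr <- sqrt(outer(outer(f^2, f^2, "+"), f^2, "+"))
  shell <- round(fr * n * ps)            # integer shell index
  nshell <- n %/% 2
  keep <- shell >= 1 & shell <= nshell
  num <- Re(fa * Conj(fb))
  pa <- Mod(fa)^2; pb <- Mod(fb)^2
  s_num <- rowsum(num[keep], shell[keep])
  s_pa <- rowsum(pa[keep], shell[keep])
  s_pb <- rowsum(pb[keep], shell[keep])
  den <- sqrt(s_pa * s_pb)
  fsc <- ifelse(den > 0, s_num / den, 0)
  structure(data.frame(freq = as.numeric(rownames(s_num)) / (n * ps),
                       fsc = as.numeric(fsc)),
            class = c("fsc_curve", "data.frame"))
}

#' Resolution at an FSC threshold
#'
#' First crossing below `threshold`, linearly interpolated between shells;
#' returns the Nyquist resolution when the curve never crosses.
#'
#' @param fsc an `fsc_curve` from [compute_fsc()].
#' @param threshold FSC threshold (0.143 by convention).
#' @return resolution in Angstrom.
#' @export
fsc_resolution <- function(fsc, threshold = 0.143) {
  below <- which(fsc$fsc < threshold)
  if (!length(below)) return(1 / max(fsc$freq))
  i <- below[1]
  if (i == 1) return(1 / fsc$freq[1])
  f0 <- fsc$freq[i - 1]; f1 <- fsc$freq[i]
  y0 <- fsc$fsc[i - 1]; y1 <- fsc$fsc[i]
  1 / (f0 + (y0 - threshold) / (y0 - y1) * (f1 - f0))
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("fsc_curve: %d shells to %.3g 1/A; FSC0.143 resolution %.1f A\n",
              nrow(x), max(x$freq), fsc_resolution(x)))
  invisible(x)
}

# cylindrical (azimuthal) average of a volume, same grid
cylindrical_average <- function(volume) {
  n <- dim(volume$data)[1]
  ax <- seq_len(n) - (n / 2 + 1)
  ridx <- round(sqrt(outer(ax^2, ax^2, "+"))) + 1L
  out <- array(0, dim = dim(volume$data))
  tab <- tabulate(as.vector(ridx))
  for (iz in seq_len(n)) {
    sl <- volume$data[, , iz]
    s <- rowsum(as.vector(sl), as.vector(ridx))
    vals <- as.integer(rownames(s))
    prof <- numeric(max(vals))
    prof[vals] <- s / tab[vals]
    out[, , iz] <- prof[ridx]
  }
  density_volume(out, volume$pixel_size)
}

#' Estimate helical lattice parameters from a refined map
#'
#' Grid search over (rise, twist): the score is the real-space normalized
#' correlation, restricted to the protein annulus, between the volume's
#' lattice deviation and itself rotated by `twist` about the tube axis and
#' translated by `rise` along it; the argmax is refined parabolically.
#' The deviation is the volume minus its cylindrical average and minus the
#' axial mean of that difference, so that ring-like and axially invariant
#' structure (which correlates under any transform) does not contribute.
#' The search is flagged unsuccessful when the best score does not exceed
#' twice the best score of the volume's cylindrical average processed the
#' same way (which carries no lattice).
#'
#' @param volume a [density_volume()].
#' @param rise_range,twist_range search intervals (Angstrom, degrees).
#' @param rise_step,twist_step grid steps.
#' @param annulus radial interval of the protein lattice, Angstrom.
#' @return object of class `lattice_params`: list with `rise`, `twist`,
#'   `handedness`, `score`, `baseline`, `success`.
#' @export
estimate_lattice_params <- function(volume, rise_range = c(30, 80),
                                    twist_range = c(-30, 30),
                                    rise_step = 2, twist_step = 2,
                                    annulus = c(150, 250)) {
  if (diff(rise_range) < 0 || diff(twist_range) < 0 ||
      rise_range[1] <= 0)
    stop_tl("empty or invalid search range", "tl_invalid_argument")
  n <- dim(volume$data)[1]
  ps <- volume$pixel_size
  ax <- seq_len(n) - (n / 2 + 1)
  r <- sqrt(outer(ax^2, ax^2, "+")) * ps
  ring <- r >= annulus[1] & r <= annulus[2]
  zmax <- n / 2 - ceiling(max(rise_range) / ps) - 1
  zsel <- abs(ax) <= zmax
  sel <- array(ring, dim = dim(volume$data))
  sel[, , !zsel] <- FALSE
  deviation <- function(vol) {
    d <- vol$data - cylindrical_average(vol)$data
    zm <- apply(d, c(1, 2), mean)
    density_volume(d - array(zm, dim = dim(d)), vol$pixel_size)
  }
  score_grid <- function(vol) {
    vol <- deviation(vol)
    v <- as.vector(vol$data)
    a <- vol$data[sel]
    rises <- seq(rise_range[1], rise_range[2], by = rise_step)
    twists <- seq(twist_range[1], twist_range[2], by = twist_step)
    sc <- matrix(NA_real_, length(rises), length(twists))
    for (it in seq_along(twists)) {
      A <- rotation_matrix(euler(twists[it], 0, 0))
      for (ir in seq_along(rises)) {
        tv <- cpp_affine_volume(v, n, A, c(0, 0, rises[ir] / ps))
        b <- array(tv, dim = dim(vol$data))[sel]
        sc[ir, it] <- ncc(a, b)
      }
    }
    list(sc = sc, rises = rises, twists = twists)
  }
  g <- score_grid(volume)
  best <- which(g$sc == max(g$sc), arr.ind = TRUE)[1, ]
  refine1 <- function(vals, scores, i) {
    if (i == 1 || i == length(vals)) return(vals[i])
    den <- scores[i - 1] - 2 * scores[i] + scores[i + 1]
    if (den >= 0) return(vals[i])
    vals[i] + 0.5 * (scores[i - 1] - scores[i + 1]) / den * (vals[2] - vals[1])
  }
  rise <- refine1(g$rises, g$sc[, best[2]], best[1])
  twist <- refine1(g$twists, g$sc[best[1], ], best[2])
  base <- score_grid(cylindrical_average(volume))
  baseline <- max(base$sc)
  score <- max(g$sc)
  structure(list(rise = rise, twist = twist,
                 handedness = if (twist >= 0) "right" else "left",
                 score = score, baseline = baseline,
                 success = is.finite(score) && score > 2 * max(baseline, 0.05)),
            class = "lattice_params")
}

#' @export
print.lattice_params <- function(x, ...) {
  cat(sprintf("lattice_params: rise %.1f A, twist %+.1f deg (%s-handed), score %.3f (baseline %.3f, %s)\n",
              x$rise, x$twist, x$handedness, x$score, x$baseline,
              if (x$success) "significant" else "no significant lattice"))
  invisible(x)
}
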