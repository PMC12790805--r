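#' Read and write MRC maps and stacks (mode 2, little-endian)
#'
#' Minimal MRC2014 support: 32-bit float data, pixel size carried in the
#' cell dimensions.  Volumes are written with `ispg = 1`, image stacks with
#' `ispg = 0` (`nz` = number of images).
#'
#' @param x a [density_volume()] or [image_stack()].
#' @param path file path.
#' @return `write_mrc` returns `path` invisibly; `read_mrc` returns a
#'   [density_volume()] or [image_stack()] depending on the header.
#' @export
write_mrc <- function(x, path) {
  is_vol <- inherits(x, "density_volume")
  if (!is_vol && !inherits(x, "image_stack"))
    stop_tl("x must be a density_volume or image_stack", "tl_invalid_argument")
  d <- dim(x$data)
  ps <- x$pixel_size
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wi(d)                                   # nx ny nz
  wi(2)                                   # mode 2 = float32
  wi(c(0, 0, 0))                          # nxstart
  wi(d)                                   # mx my mz
  wf(d * ps)                              # cella
  wf(c(90, 90, 90))                       # cellb
  wi(c(1, 2, 3))                          # mapc mapr maps
  v <- x$data
  wf(c(min(v), max(v), mean(v)))          # dmin dmax dmean
  wi(if (is_vol) 1 else 0)                # ispg
  wi(0)                                   # nsymbt
  wi(rep(0, 25))                          # extra
  wf(c(0, 0, 0))                          # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(sd(v))                               # rms
  wi(0)                                   # nlabl
  wi(rep(0, 200))                         # labels
  writeBin(as.numeric(v), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_mrc
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(k) readBin(con, "integer", k, size = 4, endian = "little")
  rf <- function(k) readBin(con, "numeric", k, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop_tl("only MRC mode 2 is supported", "tl_io_error")
  ri(3)
  mxyz <- ri(3)
  cella <- rf(3)
  seek(con, 4 * 22)
  ispg <- ri(1)
  nsymbt <- ri(1)
  ps <- if (mxyz[1] > 0) cella[1] / mxyz[1] else 1
  seek(con, 1024 + nsymbt)
  v <- rf(prod(d))
  arr <- array(v, dim = d)
  if (ispg >= 1 && d[1] == d[2] && d[2] == d[3]) density_volume(arr, ps)
  else image_stack(arr, ps)
}

#' Read and write STAR metadata tables
#'
#' Supports a single `data_` block with a `loop_` of `_column` names, the
#' dialect used by RELION particle tables.  Numeric columns are written with
#' full precision.
#'
#' @param df data frame.
#' @param path file path.
#' @param block block name (written as `data_<block>`).
#' @return `write_star` returns `path` invisibly; `read_star` a data frame.
#' @export
write_star <- function(df, path, block = "particles") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", paste0("data_", block), "", "loop_"), con)
  writeLines(sprintf("_%s #%d", names(df), seq_along(df)), con)
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.10g", col) else as.character(col)
  })
  writeLines(do.call(paste, cols), con)
  invisible(path)
}

#' @rdname write_star
#' @export
read_star <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  loop <- which(lines == "loop_")
  if (length(loop) == 0) stop_tl("no loop_ block in STAR file", "tl_io_error")
  i <- loop[1] + 1
  cols <- character()
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    cols <- c(cols, sub("^_", "", sub("\\s+#\\d+$", "", lines[i])))
    i <- i + 1
  }
  rows <- lines[i:length(lines)]
  rows <- rows[nzchar(rows) & !startsWith(rows, "data_")]
  if (length(rows) == 0) stop_tl("empty STAR table", "tl_io_error")
  mat <- do.call(rbind, strsplit(rows, "\\s+"))
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- cols
  for (j in seq_along(df)) {
    num <- suppressWarnings(as.numeric(df[[j]]))
    if (!anyNA(num)) df[[j]] <- num
  }
  df
}

#' Convert particle records to and from RELION-style STAR columns
#'
#' Internal record columns are `rot, tilt, psi` (degrees), `sx, sy` (pixels),
#' `defocus` (Angstrom) and `image` (index in the companion stack); STAR
#' columns are `rlnAngleRot/Tilt/Psi`, `rlnOriginX/YAngst` (Angstrom),
#' `rlnDefocusU` and `rlnImageName`.  Ground-truth and bookkeeping columns
#' prefixed `tl_` pass through unchanged.
#'
#' @param records internal records data frame.
#' @param pixel_size Angstrom per pixel (shift conversion).
#' @param image_file stack file name used to form `rlnImageName`.
#' @return data frame in the other representation.
#' @export
records_to_star <- function(records, pixel_size, image_file = "particles.mrcs") {
  out <- data.frame(
    rlnImageName = sprintf("%06d@%s", seq_len(nrow(records)), image_file),
    rlnAngleRot = records$rot, rlnAngleTilt = records$tilt,
    rlnAnglePsi = records$psi,
    rlnOriginXAngst = records$sx * pixel_size,
    rlnOriginYAngst = records$sy * pixel_size,
    stringsAsFactors = FALSE)
  if (!is.null(records$defocus)) out$rlnDefocusU <- records$defocus
  for (nm in grep("^tl_", names(records), value = TRUE)) out[[nm]] <- records[[nm]]
  out
}

#' @rdname records_to_star
#' @param star data frame with RELION-style columns.
#' @export
star_to_records <- function(star, pixel_size) {
  out <- data.frame(
    rot = star$rlnAngleRot, tilt = star$rlnAngleTilt, psi = star$rlnAnglePsi,
    sx = star$rlnOriginXAngst / pixel_size,
    sy = star$rlnOriginYAngst / pixel_size)
  if (!is.null(star$rlnDefocusU)) out$defocus <- star$rlnDefocusU
  if (!is.null(star$rlnImageName))
    out$image <- as.integer(sub("@.*$", "", star$rlnImageName))
  for (nm in grep("^tl_", names(star), value = TRUE)) out[[nm]] <- star[[nm]]
  out
}
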