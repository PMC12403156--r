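# Movie file formats: multi-frame 16-bit TIFF and the PMA container used
# by single-molecule acquisition software (a 4-byte header of width and
# height as little-endian uint16, then raw 8-bit frames, row-major).

#' Write a movie as multi-frame 16-bit TIFF
#'
#' Counts are clamped to `[0, 65535]` and rounded.
#'
#' @param movie An `"sm_movie"`.
#' @param file Output path.
#' @export
write_tiff_movie <- function(movie, file) {
  stopifnot(inherits(movie, "sm_movie"))
  imgs <- lapply(seq_len(movie$n_frames), function(t) {
    m <- pmin(pmax(round(movie$frames[, , t]), 0), 65535)
    m / 65535
  })
  tiff::writeTIFF(imgs, file, bits.per.sample = 16)
  invisible(file)
}

#' Read a multi-frame TIFF movie
#'
#' @param file TIFF path.
#' @param dt Frame interval to attach, s.
#' @return An `"sm_movie"` (counts on the 16-bit scale).
#' @export
read_tiff_movie <- function(file, dt = 0.1) {
  imgs <- tiff::readTIFF(file, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  h <- nrow(imgs[[1]]); w <- ncol(imgs[[1]])
  frames <- array(0, dim = c(h, w, length(imgs)))
  for (t in seq_along(imgs)) frames[, , t] <- round(imgs[[t]] * 65535)
  sm_movie(frames, dt = dt)
}

#' Write a movie in PMA format
#'
#' 8-bit container: two little-endian 16-bit unsigned integers (width,
#' height) followed by the frames as raw bytes, row-major. Counts are
#' clamped to `[0, 255]`; rescale before writing if the movie uses a
#' larger dynamic range.
#'
#' @param movie An `"sm_movie"`.
#' @param file Output path.
#' @param scale Multiplier applied to counts before clamping (default 1).
#' @export
write_pma <- function(movie, file, scale = 1) {
  stopifnot(inherits(movie, "sm_movie"))
  con <- file(file, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(movie$width, movie$height)), con, size = 2,
           endian = "little")
  for (t in seq_len(movie$n_frames)) {
    m <- pmin(pmax(round(movie$frames[, , t] * scale), 0), 255)
    writeBin(as.raw(as.vector(t(m))), con)   # row-major: x fastest
  }
  invisible(file)
}

#' Read a PMA movie
#'
#' @param file PMA path.
#' @param dt Frame interval to attach, s.
#' @return An `"sm_movie"`.
#' @export
read_pma <- function(file, dt = 0.1) {
  con <- file(file, "rb")
  on.exit(close(con))
  wh <- readBin(con, integer(), n = 2, size = 2, signed = FALSE,
                endian = "little")
  w <- wh[1]; h <- wh[2]
  bytes <- readBin(con, raw(), n = file.size(file) - 4L)
  n_frames <- length(bytes) %/% (w * h)
  stopifnot(n_frames >= 1, length(bytes) == n_frames * w * h)
  frames <- array(0, dim = c(h, w, n_frames))
  v <- as.integer(bytes)
  for (t in seq_len(n_frames)) {
    off <- (t - 1L) * w * h
    frames[, , t] <- matrix(v[(off + 1L):(off + w * h)], nrow = h,
                            byrow = TRUE)
  }
  sm_movie(frames, dt = dt)
}
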