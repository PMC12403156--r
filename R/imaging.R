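# Dual-channel TIRF movie simulation and movie-to-trace extraction:
# Gaussian-PSF rendering, spot detection, channel pairing and aperture
# photometry. Pixel coordinates are 0-based, x rightward, y downward; the
# donor channel is the left half of the field and the acceptor channel the
# right half (a pure x translation by width/2).

#' Construct a movie object
#'
#' @param frames 3D array `[y, x, t]` of pixel intensities (counts).
#' @param dt Frame interval, s.
#' @return An `"sm_movie"` with `frames`, `width`, `height`, `n_frames`,
#'   `dt`.
#' @export
sm_movie <- function(frames, dt = 0.1) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[2] %% 2 == 0)
  structure(list(frames = frames, width = dim(frames)[2],
                 height = dim(frames)[1], n_frames = dim(frames)[3],
                 dt = dt),
            class = "sm_movie")
}

#' @export
print.sm_movie <- function(x, ...) {
  cat(sprintf("<sm_movie> %d x %d px (two %d-px channels), %d frames @ %.3g s\n",
              x$width, x$height, x$width %/% 2, x$n_frames, x$dt))
  invisible(x)
}

#' Render a cohort as a dual-channel movie
#'
#' Each molecule is a 2D Gaussian spot whose integrated intensity per
#' frame equals its trace value in the matching channel: the donor spot at
#' the molecule position in the left channel, the acceptor spot at the
#' same position translated by `width/2`. Additive Gaussian read noise on
#' top of a constant offset; no Poisson component.
#'
#' @param x An `"sm_cohort"` or list of `"sm_trace"`.
#' @param positions Optional n x 2 matrix of 0-based donor-channel `(x, y)`
#'   positions; drawn uniformly with `min_separation` enforced when `NULL`.
#' @param width,height Field size in pixels (`width` must be even).
#' @param psf_sigma_px PSF Gaussian s.d. in pixels (default 1.1).
#' @param bg_offset Camera offset per pixel, counts.
#' @param read_noise Read noise s.d. per pixel, counts.
#' @param min_separation Minimum spot separation in either channel, px.
#' @param margin Keep-out border inside each channel, px.
#' @param seed Integer seed (positions and noise).
#' @param n_frames,dt Frame count and interval, needed only for an empty
#'   cohort (a blank movie of pure background).
#' @return An `"sm_movie"` with attribute `"positions"` (the ground-truth
#'   donor-channel positions).
#' @export
render_movie <- function(x, positions = NULL, width = 128, height = 64,
                         psf_sigma_px = 1.1, bg_offset = 10, read_noise = 2,
                         min_separation = 6, margin = 6, seed = NULL,
                         n_frames = NULL, dt = 0.1) {
  traces <- if (length(x) == 0) list() else as_trace_list(x)
  n <- length(traces)
  if (n == 0) {
    stopifnot(!is.null(n_frames))
    return(with_local_seed(seed, {
      frames <- array(bg_offset, dim = c(height, width, n_frames))
      if (read_noise > 0)
        frames <- frames + array(rnorm(length(frames), 0, read_noise),
                                 dim = dim(frames))
      mv <- sm_movie(frames, dt = dt)
      attr(mv, "positions") <- matrix(numeric(0), 0, 2)
      mv
    }))
  }
  n_frames <- length(traces[[1]]$i_d)
  stopifnot(width %% 2 == 0)
  cw <- width %/% 2
  with_local_seed(seed, {
    if (is.null(positions)) {
      positions <- matrix(NA_real_, n, 2)
      placed <- 0
      tries <- 0
      while (placed < n) {
        cand <- c(runif(1, margin, cw - 1 - margin),
                  runif(1, margin, height - 1 - margin))
        ok <- placed == 0 ||
          all(sqrt(colSums((t(positions[seq_len(placed), , drop = FALSE]) -
                              cand)^2)) >= min_separation)
        if (ok) { placed <- placed + 1; positions[placed, ] <- cand }
        tries <- tries + 1
        if (tries > 1000 * n) stop("could not place spots with the requested separation")
      }
    } else {
      positions <- as.matrix(positions)
      stopifnot(nrow(positions) == n, ncol(positions) == 2)
      if (any(positions[, 1] < 0 | positions[, 1] > cw - 1 |
              positions[, 2] < 0 | positions[, 2] > height - 1))
        stop("positions outside the donor channel bounds")
      if (n > 1 && min_separation > 0) {
        dmat <- as.matrix(dist(positions))
        if (min(dmat[upper.tri(dmat)]) < min_separation)
          stop("positions violate the minimum separation")
      }
    }
    frames <- array(0, dim = c(height, width, n_frames))
    r <- ceiling(4 * psf_sigma_px)
    for (m in seq_len(n)) {
      for (ch in 1:2) {
        x0 <- positions[m, 1] + (ch - 1) * cw
        y0 <- positions[m, 2]
        xs <- max(0, floor(x0) - r):min(width - 1, floor(x0) + r)
        ys <- max(0, floor(y0) - r):min(height - 1, floor(y0) + r)
        kx <- exp(-(xs - x0)^2 / (2 * psf_sigma_px^2))
        ky <- exp(-(ys - y0)^2 / (2 * psf_sigma_px^2))
        kern <- (ky %o% kx) / (2 * pi * psf_sigma_px^2)
        intens <- if (ch == 1) traces[[m]]$i_d else traces[[m]]$i_a
        frames[ys + 1, xs + 1, ] <- frames[ys + 1, xs + 1, ] +
          kern %o% intens
      }
    }
    frames <- frames + bg_offset
    if (read_noise > 0)
      frames <- frames + array(rnorm(length(frames), 0, read_noise),
                               dim = dim(frames))
    mv <- sm_movie(frames, dt = traces[[1]]$dt)
    attr(mv, "positions") <- positions
    mv
  })
}

# Separable Gaussian smoothing with edge replication.
gauss_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad <- function(m, r) {
    m <- rbind(matrix(rep(m[1, ], r), r, byrow = TRUE), m,
               matrix(rep(m[nrow(m), ], r), r, byrow = TRUE))
    cbind(matrix(rep(m[, 1], r), ncol = r), m,
          matrix(rep(m[, ncol(m)], r), ncol = r))
  }
  p <- pad(img, r)
  out <- matrix(0, nrow(img), ncol(img))
  for (dy in -r:r) for (dx in -r:r) {
    w <- k[dy + r + 1] * k[dx + r + 1]
    out <- out + w * p[(1 + r + dy):(nrow(img) + r + dy),
                       (1 + r + dx):(ncol(img) + r + dx)]
  }
  out
}

#' Detect spots on the averaged image
#'
#' Averages the first `k` frames, smooths with a Gaussian, and keeps local
#' maxima exceeding `background + threshold_sd * noise` (background and
#' noise estimated as the image median and MAD). Detections within
#' `merge_px` of a brighter one are merged; positions are refined to
#' sub-pixel precision by an intensity-weighted centroid over a 5x5
#' neighbourhood of the average image. Detection count is monotone
#' non-increasing in `threshold_sd`.
#'
#' @param movie An `"sm_movie"`.
#' @param k Number of leading frames to average (default 10).
#' @param threshold_sd Detection threshold in noise s.d. (default 5).
#' @param smooth_sigma Smoothing Gaussian s.d., px (default 1).
#' @param merge_px Merge radius, px (default 2).
#' @return Data frame of 0-based centroids `x`, `y` and peak `intensity`
#'   (possibly empty).
#' @export
detect_spots <- function(movie, k = 10, threshold_sd = 5, smooth_sigma = 1,
                         merge_px = 2) {
  stopifnot(inherits(movie, "sm_movie"), k >= 1)
  k <- min(k, movie$n_frames)
  avg <- apply(movie$frames[, , seq_len(k), drop = FALSE], c(1, 2), mean)
  sm <- gauss_smooth(avg, smooth_sigma)
  bg <- median(sm)
  noise <- max(mad(sm), 1e-9)
  thr <- bg + threshold_sd * noise
  h <- nrow(sm); w <- ncol(sm)
  cand <- which(sm > thr, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    yy <- cand[i, 1]; xx <- cand[i, 2]
    ys <- max(1, yy - 1):min(h, yy + 1)
    xs <- max(1, xx - 1):min(w, xx + 1)
    keep[i] <- sm[yy, xx] >= max(sm[ys, xs])
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0)
    return(data.frame(x = numeric(0), y = numeric(0),
                      intensity = numeric(0)))
  inten <- sm[cand]
  o <- order(inten, decreasing = TRUE)
  cand <- cand[o, , drop = FALSE]
  inten <- inten[o]
  taken <- rep(FALSE, nrow(cand))
  out <- list()
  for (i in seq_len(nrow(cand))) {
    if (taken[i]) next
    d <- sqrt((cand[, 1] - cand[i, 1])^2 + (cand[, 2] - cand[i, 2])^2)
    taken[d <= merge_px] <- TRUE
    # sub-pixel centroid over a 5x5 box of the background-subtracted average
    ys <- max(1, cand[i, 1] - 2):min(h, cand[i, 1] + 2)
    xs <- max(1, cand[i, 2] - 2):min(w, cand[i, 2] + 2)
    wbox <- pmax(avg[ys, xs, drop = FALSE] - bg, 0)
    if (sum(wbox) == 0) wbox[] <- 1
    cy <- sum(row(wbox) * wbox) / sum(wbox)
    cx <- sum(col(wbox) * wbox) / sum(wbox)
    out[[length(out) + 1L]] <- data.frame(
      x = xs[1] - 1 + (cx - 1), y = ys[1] - 1 + (cy - 1),
      intensity = inten[i])
  }
  do.call(rbind, out)
}

#' Split detections into donor- and acceptor-channel spots
#'
#' @param spots Data frame from [detect_spots()].
#' @param width Full field width, px.
#' @return List with `donor` and `acceptor` data frames; acceptor `x` is
#'   kept in full-field coordinates.
#' @export
split_channels <- function(spots, width) {
  cw <- width / 2
  list(donor = spots[spots$x < cw, , drop = FALSE],
       acceptor = spots[spots$x >= cw, , drop = FALSE])
}

#' Pair donor and acceptor spots across channels
#'
#' Greedy nearest-neighbour matching of donor positions translated by the
#' inter-channel offset against acceptor detections, accepting pairs
#' within `tol_px`. Unpaired spots on either side (e.g. an acceptor
#' bleached before the movie, leaving a donor-only spot) are reported in
#' the `"unpaired"` attribute.
#'
#' @param donor,acceptor Spot tables ([split_channels()]).
#' @param offset Inter-channel translation `(dx, dy)`; default
#'   `c(width/2, 0)`.
#' @param tol_px Pairing tolerance, px (default 2).
#' @param width Full field width (used for the default offset).
#' @return Data frame of `"spot_pair"` rows: `donor_x`, `donor_y`,
#'   `acceptor_x`, `acceptor_y`, `distance`.
#' @export
pair_channels <- function(donor, acceptor, offset = NULL, tol_px = 2,
                          width = NULL) {
  if (is.null(offset)) {
    stopifnot(!is.null(width))
    offset <- c(width / 2, 0)
  }
  nd <- nrow(donor); na <- nrow(acceptor)
  pairs <- list()
  used_d <- rep(FALSE, nd); used_a <- rep(FALSE, na)
  if (nd > 0 && na > 0) {
    dm <- outer(donor$x + offset[1], acceptor$x, "-")^2 +
      outer(donor$y + offset[2], acceptor$y, "-")^2
    dm <- sqrt(dm)
    repeat {
      dm2 <- dm
      dm2[used_d, ] <- Inf; dm2[, used_a] <- Inf
      i <- which(dm2 == min(dm2), arr.ind = TRUE)[1, ]
      if (!is.finite(dm2[i[1], i[2]]) || dm2[i[1], i[2]] > tol_px) break
      used_d[i[1]] <- TRUE; used_a[i[2]] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(
        donor_x = donor$x[i[1]], donor_y = donor$y[i[1]],
        acceptor_x = acceptor$x[i[2]], acceptor_y = acceptor$y[i[2]],
        distance = dm[i[1], i[2]])
      if (all(used_d) || all(used_a)) break
    }
  }
  out <- if (length(pairs)) do.call(rbind, pairs)
  else data.frame(donor_x = numeric(0), donor_y = numeric(0),
                  acceptor_x = numeric(0), acceptor_y = numeric(0),
                  distance = numeric(0))
  attr(out, "unpaired") <- list(donor = donor[!used_d, , drop = FALSE],
                                acceptor = acceptor[!used_a, , drop = FALSE])
  out
}

# Aperture mask sum helper: pixels with centre within radius of (x0, y0).
aperture_idx <- function(x0, y0, radius, width, height) {
  xs <- floor(x0 - radius):ceiling(x0 + radius)
  ys <- floor(y0 - radius):ceiling(y0 + radius)
  g <- expand.grid(x = xs, y = ys)
  g <- g[(g$x - x0)^2 + (g$y - y0)^2 <= radius^2, ]
  list(idx = g, clipped = any(g$x < 0 | g$x >= width |
                                g$y < 0 | g$y >= height))
}

#' Extract intensity traces by aperture photometry
#'
#' For each paired molecule and each frame, the channel intensity is the
#' sum over a circular aperture minus the local background (median of a
#' surrounding annulus, scaled to the aperture area). Pairs whose aperture
#' or annulus clips the image edge are excluded and reported; pairs with
#' another detection closer than `2 * aperture + 1` px are flagged
#' `contaminated`.
#'
#' @param movie An `"sm_movie"`.
#' @param pairs Pair table from [pair_channels()].
#' @param aperture Aperture radius, px (default 2).
#' @param annulus Background annulus radii `c(inner, outer)`, px (default
#'   `c(4, 6)`).
#' @return List of `"sm_trace"` (background already subtracted, `bg = 0`);
#'   attributes `"excluded"` (edge-clipped pair rows) and `"contaminated"`
#'   (logical per returned trace).
#' @export
extract_traces <- function(movie, pairs, aperture = 2, annulus = c(4, 6)) {
  stopifnot(inherits(movie, "sm_movie"), annulus[1] > aperture,
            annulus[2] > annulus[1])
  n_frames <- movie$n_frames
  traces <- list()
  contaminated <- logical(0)
  excluded <- integer(0)
  flat <- matrix(movie$frames, nrow = movie$height * movie$width,
                 ncol = n_frames)
  pix_sum <- function(g) {
    lin <- (g$x) * movie$height + g$y + 1L
    if (length(lin) == 1L) flat[lin, ] else colSums(flat[lin, , drop = FALSE])
  }
  pix_med <- function(g) {
    lin <- (g$x) * movie$height + g$y + 1L
    apply(flat[lin, , drop = FALSE], 2, median)
  }
  for (i in seq_len(nrow(pairs))) {
    centers <- list(d = c(pairs$donor_x[i], pairs$donor_y[i]),
                    a = c(pairs$acceptor_x[i], pairs$acceptor_y[i]))
    ok <- TRUE
    vals <- list()
    for (ch in names(centers)) {
      ap <- aperture_idx(centers[[ch]][1], centers[[ch]][2], aperture,
                         movie$width, movie$height)
      an_out <- aperture_idx(centers[[ch]][1], centers[[ch]][2], annulus[2],
                             movie$width, movie$height)
      if (ap$clipped || an_out$clipped) { ok <- FALSE; break }
      rr <- (an_out$idx$x - centers[[ch]][1])^2 +
        (an_out$idx$y - centers[[ch]][2])^2
      ann <- an_out$idx[rr >= annulus[1]^2, ]
      vals[[ch]] <- pix_sum(ap$idx) - nrow(ap$idx) * pix_med(ann)
    }
    if (!ok) { excluded <- c(excluded, i); next }
    dmin <- Inf
    if (nrow(pairs) > 1) {
      others <- setdiff(seq_len(nrow(pairs)), i)
      dmin <- min(sqrt((pairs$donor_x[others] - pairs$donor_x[i])^2 +
                         (pairs$donor_y[others] - pairs$donor_y[i])^2))
    }
    contaminated <- c(contaminated, dmin < 2 * aperture + 1)
    traces[[length(traces) + 1L]] <- structure(
      list(molecule_id = sprintf("spot%03d", i), dt = movie$dt,
           i_d = vals$d, i_a = vals$a,
           red_laser_start = n_frames,
           bg = 0, noise_sd = NA_real_, i_total = NA_real_, truth = NULL),
      class = "sm_trace")
  }
  attr(traces, "excluded") <- excluded
  attr(traces, "contaminated") <- contaminated
  traces
}
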