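# Transition density plots: histogram of (initial, final) FRET at each
# observed transition, 2D-Gaussian peak location, and a reversibility
# score.

#' Build a transition density plot
#'
#' For every within-segment Viterbi transition, the initial and final FRET
#' coordinates are the mean *raw* E over the dwell preceding and following
#' the transition (not the fitted state means), so that TDP peak positions
#' are an independent check on the HMM state means. Transitions are
#' accumulated on a fixed `[0,1] x [0,1]` grid.
#'
#' @param viterbi Integer state path (1 = low, 2 = high).
#' @param e Raw FRET series aligned with `viterbi`.
#' @param boundaries 0-based stitch-seam indices; no transition is counted
#'   across a seam.
#' @param bin Bin width of the square grid (default 0.02, resolving the
#'   smallest state separation of 0.2 used by the sensor panel).
#' @return A `"fret_tdp"`: `grid` (count matrix, rows = initial E bins,
#'   columns = final E bins), `transitions` (data frame `e_initial`,
#'   `e_final`), `bin`, `breaks`, `mids`. An empty TDP (no transitions) is
#'   valid.
#' @export
build_tdp <- function(viterbi, e, boundaries = integer(0), bin = 0.02) {
  stopifnot(length(viterbi) == length(e), bin > 0)
  n <- length(viterbi)
  starts <- c(0L, as.integer(boundaries))
  ends <- c(as.integer(boundaries), n)
  ei <- numeric(0); ef <- numeric(0)
  for (s in seq_along(starts)) {
    idx <- (starts[s] + 1L):ends[s]
    seg <- viterbi[idx]
    eseg <- e[idx]
    r <- rle(seg)
    if (length(r$lengths) < 2L) next
    stops <- cumsum(r$lengths)
    dwell_mean <- vapply(seq_along(r$lengths), function(j) {
      mean(eseg[(c(0L, stops)[j] + 1L):stops[j]], na.rm = TRUE)
    }, numeric(1))
    ei <- c(ei, dwell_mean[-length(dwell_mean)])
    ef <- c(ef, dwell_mean[-1L])
  }
  breaks <- seq(0, 1, by = bin)
  nb <- length(breaks) - 1L
  grid <- matrix(0L, nb, nb)
  if (length(ei)) {
    bi <- pmin(pmax(findInterval(ei, breaks, rightmost.closed = TRUE), 1L), nb)
    bf <- pmin(pmax(findInterval(ef, breaks, rightmost.closed = TRUE), 1L), nb)
    for (t in seq_along(bi)) grid[bi[t], bf[t]] <- grid[bi[t], bf[t]] + 1L
  }
  structure(list(grid = grid,
                 transitions = data.frame(e_initial = ei, e_final = ef),
                 bin = bin, breaks = breaks,
                 mids = breaks[-1] - bin / 2),
            class = "fret_tdp")
}

#' @export
print.fret_tdp <- function(x, ...) {
  cat(sprintf("<fret_tdp> %d transitions on a %dx%d grid (bin %.2g)\n",
              nrow(x$transitions), nrow(x$grid), ncol(x$grid), x$bin))
  invisible(x)
}

#' @export
plot.fret_tdp <- function(x, ...) {
  image(x$mids, x$mids, x$grid, col = hcl.colors(64, "inferno"),
        xlab = "initial FRET", ylab = "final FRET", ...)
  abline(0, 1, col = "white", lty = 2)
  invisible(x)
}

#' Locate TDP peaks by 2D Gaussian fitting
#'
#' Fits `n_peaks` isotropic 2D Gaussians (plus a flat offset) to the TDP
#' grid by least squares, seeded at the largest well-separated local
#' maxima, and returns sub-bin peak coordinates. If the nonlinear fit
#' fails, the argmax bin centers are returned with `flagged = TRUE`.
#'
#' @param tdp A `"fret_tdp"` with at least 10 transitions.
#' @param n_peaks Number of peaks (default 2: the forward and reverse
#'   transition clusters of a two-state system).
#' @return Data frame: `e_initial`, `e_final`, `amplitude`, `width`
#'   (shared Gaussian s.d. per peak), `flagged`.
#' @export
locate_peaks <- function(tdp, n_peaks = 2L) {
  stopifnot(inherits(tdp, "fret_tdp"))
  if (nrow(tdp$transitions) < 10)
    stop("need at least 10 transitions to locate peaks")
  g <- tdp$grid
  mids <- tdp$mids
  # seeds: greedy largest local maxima, suppressing a 5x5 neighbourhood
  gg <- g
  seeds <- matrix(NA_real_, n_peaks, 3)
  for (p in seq_len(n_peaks)) {
    i <- which(gg == max(gg), arr.ind = TRUE)[1, ]
    seeds[p, ] <- c(mids[i[1]], mids[i[2]], g[i[1], i[2]])
    ri <- pmax(i[1] - 2, 1):pmin(i[1] + 2, nrow(gg))
    ci <- pmax(i[2] - 2, 1):pmin(i[2] + 2, ncol(gg))
    gg[ri, ci] <- -Inf
  }
  xy <- expand.grid(x = mids, y = mids)
  z <- as.vector(g)
  model <- function(par) {
    pred <- rep(0, length(z))
    for (p in seq_len(n_peaks)) {
      a <- par[4 * p - 3]; mx <- par[4 * p - 2]
      my <- par[4 * p - 1]; s <- abs(par[4 * p]) + 1e-4
      pred <- pred + a * exp(-((xy$x - mx)^2 + (xy$y - my)^2) / (2 * s^2))
    }
    pred
  }
  par0 <- as.vector(t(cbind(seeds[, 3], seeds[, 1], seeds[, 2],
                            rep(1.5 * tdp$bin, n_peaks))))
  fit <- try(optim(par0, function(p) sum((z - model(p))^2),
                   method = "BFGS", control = list(maxit = 500)),
             silent = TRUE)
  if (inherits(fit, "try-error") || !all(is.finite(fit$par))) {
    return(data.frame(e_initial = seeds[, 1], e_final = seeds[, 2],
                      amplitude = seeds[, 3], width = NA_real_,
                      flagged = TRUE))
  }
  par <- fit$par
  out <- data.frame(
    e_initial = par[seq(2, by = 4, length.out = n_peaks)],
    e_final = par[seq(3, by = 4, length.out = n_peaks)],
    amplitude = par[seq(1, by = 4, length.out = n_peaks)],
    width = abs(par[seq(4, by = 4, length.out = n_peaks)]) + 1e-4,
    flagged = FALSE)
  # a vanishing second component indicates a single-cluster TDP
  out$flagged <- out$flagged | out$amplitude < 0.02 * max(out$amplitude)
  out$e_initial <- pmin(pmax(out$e_initial, 0), 1)
  out$e_final <- pmin(pmax(out$e_final, 0), 1)
  out
}

#' Reversibility (symmetry) score of a TDP
#'
#' A reversible two-state system populates the upper (low to high) and
#' lower (high to low) triangles equally:
#' `score = 1 - |n_up - n_down| / n_total`. For alternating two-state
#' paths the per-trace count imbalance is at most 1, so the aggregate
#' score approaches 1.
#'
#' @param tdp A nonempty `"fret_tdp"`.
#' @return Scalar in `[0, 1]`.
#' @export
symmetry_score <- function(tdp) {
  stopifnot(inherits(tdp, "fret_tdp"))
  tr <- tdp$transitions
  if (nrow(tr) == 0) stop("empty TDP has no symmetry score")
  up <- sum(tr$e_final > tr$e_initial)
  down <- sum(tr$e_final < tr$e_initial)
  1 - abs(up - down) / nrow(tr)
}
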