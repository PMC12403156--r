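# Two-state Gaussian-emission hidden Markov model for stitched FRET
# series: truncate-and-stitch, Baum-Welch fit, Viterbi decoding, dwell
# extraction and rate estimation.

#' Truncate FRET traces to a fixed window and stitch them
#'
#' Takes the first `window_frames` defined in-window frames of each
#' qualifying FRET trace (the pre-bleach, pre-red-laser analysis window)
#' and concatenates them into one series for a global HMM fit. Seam
#' positions are recorded so that no transition or dwell is ever counted
#' across two molecules. Traces with fewer defined in-window frames than
#' `window_frames` are dropped and reported.
#'
#' @param fret_traces List of `"fret_trace"` objects ([compute_fret()]).
#' @param window_frames Window length in frames (default 200, i.e. 20 s at
#'   100 ms frames).
#' @return A `"stitched_series"`: list with `e` (concatenated FRET values),
#'   `seglen` (frames per retained trace), `boundaries` (0-based seam
#'   indices into `e`), `trace_ids`, `dropped` (ids of dropped traces) and
#'   `dt`.
#' @export
truncate_and_stitch <- function(fret_traces, window_frames = 200L) {
  stopifnot(is.list(fret_traces), window_frames >= 1)
  kept <- list(); ids <- character(0); dropped <- character(0)
  dt <- NA_real_
  for (f in fret_traces) {
    stopifnot(inherits(f, "fret_trace"))
    dt <- f$dt
    v <- window_values(f)
    if (length(v) >= window_frames) {
      kept[[length(kept) + 1L]] <- v[seq_len(window_frames)]
      ids <- c(ids, f$molecule_id)
    } else dropped <- c(dropped, f$molecule_id)
  }
  if (length(kept) == 0) stop("zero traces qualify for the stitch window")
  seglen <- rep(as.integer(window_frames), length(kept))
  structure(list(e = unlist(kept, use.names = FALSE), seglen = seglen,
                 boundaries = if (length(kept) > 1)
                   cumsum(seglen)[-length(seglen)] else integer(0),
                 trace_ids = ids, dropped = dropped, dt = dt),
            class = "stitched_series")
}

#' @export
print.stitched_series <- function(x, ...) {
  cat(sprintf("<stitched_series> %d traces x %d frames = %d frames (%d dropped)\n",
              length(x$seglen), x$seglen[1], length(x$e), length(x$dropped)))
  invisible(x)
}

as_segmented <- function(series) {
  if (inherits(series, "stitched_series"))
    list(e = series$e, seglen = series$seglen, dt = series$dt)
  else if (is.numeric(series))
    list(e = as.numeric(series), seglen = length(series), dt = NA_real_)
  else stop("series must be numeric or a stitched_series")
}

#' Fit a two-state Gaussian hidden Markov model
#'
#' Baum-Welch (EM) fit of a two-state HMM with Gaussian emissions to a
#' FRET series, typically the output of [truncate_and_stitch()]. Each
#' stitched segment is treated as an independent sequence, so transition
#' statistics never cross a stitch seam. States are labelled so that
#' `mu["high"] > mu["low"]` (state 1 = high FRET, state 2 = low FRET in
#' the junction-conformer convention). Initialization: state means at the
#' 25th/75th percentiles of E, emission s.d. at half the interquartile
#' range (floored at 1e-3), self-transition probability 0.95. The
#' log-likelihood is non-decreasing over EM iterations; convergence when
#' its increase falls below `tol`.
#'
#' @param series Numeric FRET vector or `"stitched_series"`.
#' @param init Optional list with `mu` (length 2), `sigma`, `A` (2x2
#'   row-stochastic), `pi` to override the defaults.
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Log-likelihood convergence tolerance (default 1e-6).
#' @param min_len Minimum series length (default 100 frames; per-trace
#'   classification uses 50).
#' @return An `"hj_hmm"` model object; see [coef.hj_hmm()],
#'   [predict.hj_hmm()], [logLik.hj_hmm()], [plot.hj_hmm()].
#' @examples
#' e <- rep(c(0.2, 0.6), each = 10, times = 10) + rnorm(400, 0, 0.05)
#' fit <- fit_hmm2(e)
#' coef(fit)
#' @export
fit_hmm2 <- function(series, init = NULL, max_iter = 500L, tol = 1e-6,
                     min_len = 100L) {
  seg <- as_segmented(series)
  e <- seg$e
  stopifnot(all(is.finite(e)))
  if (length(e) < min_len)
    stop(sprintf("series too short for an HMM fit (%d < %d frames)",
                 length(e), min_len))
  q <- quantile(e, c(0.25, 0.75), names = FALSE)
  mu <- init$mu %||% c(q[1], q[2])
  if (diff(mu) < 1e-6) mu <- mu + c(-5e-4, 5e-4)
  sigma <- init$sigma %||% rep(max((q[2] - q[1]) / 2, 1e-3), 2)
  A <- init$A %||% matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE)
  p0 <- init$pi %||% c(0.5, 0.5)
  loglik_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    es <- hmm2_estep_cpp(e, as.integer(seg$seglen), mu, sigma, A, p0)
    ll <- es$loglik
    if (!is.finite(ll))
      stop(sprintf("non-finite likelihood at iteration %d (mu = %.4g/%.4g, sigma = %.4g/%.4g)",
                   iter, mu[1], mu[2], sigma[1], sigma[2]))
    loglik_trace <- c(loglik_trace, ll)
    if (ll - ll_old < tol && iter > 1L) { converged <- TRUE; break }
    if (iter >= max_iter) break
    ll_old <- ll
    occupied <- es$Ng > 1e-8              # a state may die on degenerate data
    mu[occupied] <- (es$Sx / es$Ng)[occupied]
    sigma[occupied] <- pmax(sqrt(pmax(es$Sxx / es$Ng - mu^2, 0)),
                            1e-3)[occupied]
    A <- es$Xi / rowSums(es$Xi)
    A[!is.finite(A)] <- 0.5                 # state never visited
    p0 <- es$Pi / es$nseg
    p0 <- p0 / sum(p0)
  }
  if (mu[1] > mu[2]) {                      # relabel: index 1 = low FRET
    mu <- rev(mu); sigma <- rev(sigma); p0 <- rev(p0)
    A <- A[2:1, 2:1]
  }
  names(mu) <- names(sigma) <- names(p0) <- c("low", "high")
  dimnames(A) <- list(from = c("low", "high"), to = c("low", "high"))
  structure(list(mu = mu, sigma = sigma, A = A, pi = p0,
                 loglik = loglik_trace[length(loglik_trace)],
                 loglik_trace = loglik_trace, n_iter = iter,
                 converged = converged, e = e,
                 seglen = as.integer(seg$seglen),
                 boundaries = if (length(seg$seglen) > 1)
                   cumsum(seg$seglen)[-length(seg$seglen)] else integer(0),
                 dt = seg$dt),
            class = "hj_hmm")
}

#' @export
print.hj_hmm <- function(x, ...) {
  cat(sprintf("Two-state Gaussian HMM (%s, %d EM iterations)\n",
              if (x$converged) "converged" else "not converged", x$n_iter))
  cat(sprintf("  FRET states: low %.3f (sd %.3f), high %.3f (sd %.3f)\n",
              x$mu[1], x$sigma[1], x$mu[2], x$sigma[2]))
  cat(sprintf("  per-frame transition prob: low->high %.4f, high->low %.4f\n",
              x$A[1, 2], x$A[2, 1]))
  cat(sprintf("  log-likelihood: %.2f over %d frames (%d segments)\n",
              x$loglik, length(x$e), length(x$seglen)))
  invisible(x)
}

#' @export
coef.hj_hmm <- function(object, ...) {
  c(mu_low = unname(object$mu[1]), mu_high = unname(object$mu[2]),
    sigma_low = unname(object$sigma[1]), sigma_high = unname(object$sigma[2]),
    a_low_high = unname(object$A[1, 2]), a_high_low = unname(object$A[2, 1]))
}

#' @export
logLik.hj_hmm <- function(object, ...) {
  structure(object$loglik, df = 7L, nobs = length(object$e),
            class = "logLik")
}

#' Viterbi decoding of a fitted two-state HMM
#'
#' Most probable state path under the fitted parameters; ties are broken
#' toward the previous state (hysteresis), so a tie never creates a
#' spurious transition.
#'
#' @param object An `"hj_hmm"` fit.
#' @param newdata Optional numeric series or `"stitched_series"` to decode;
#'   defaults to the training series.
#' @param ... Unused.
#' @return Integer vector of states per frame: 1 = low FRET, 2 = high FRET.
#' @export
predict.hj_hmm <- function(object, newdata = NULL, ...) {
  seg <- if (is.null(newdata))
    list(e = object$e, seglen = object$seglen)
  else as_segmented(newdata)
  hmm2_viterbi_cpp(seg$e, as.integer(seg$seglen), object$mu, object$sigma,
                   object$A, object$pi)
}

#' @rdname predict.hj_hmm
#' @param fit An `"hj_hmm"` fit.
#' @param series Series to decode (defaults to the training series).
#' @export
viterbi_path <- function(fit, series = NULL) predict(fit, newdata = series)

#' @export
residuals.hj_hmm <- function(object, ...) {
  object$e - object$mu[predict(object)]
}

#' @export
summary.hj_hmm <- function(object, ...) {
  v <- predict(object)
  out <- list(fit = object,
              occupancy = c(low = mean(v == 1), high = mean(v == 2)),
              n_transitions = sum(diff(v) != 0) -
                sum(v[object$boundaries] != v[object$boundaries + 1L]))
  class(out) <- "summary.hj_hmm"
  out
}

#' @export
print.summary.hj_hmm <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  Viterbi occupancy: low %.1f%%, high %.1f%%; %d within-segment transitions\n",
              100 * x$occupancy[1], 100 * x$occupancy[2], x$n_transitions))
  invisible(x)
}

#' @export
plot.hj_hmm <- function(x, segment = 1L, ...) {
  i0 <- if (segment > 1) sum(x$seglen[seq_len(segment - 1L)]) else 0L
  idx <- i0 + seq_len(x$seglen[segment])
  t <- (seq_along(idx) - 1) * (if (is.finite(x$dt)) x$dt else 1)
  plot(t, x$e[idx], type = "l", col = "grey40",
       xlab = if (is.finite(x$dt)) "time (s)" else "frame",
       ylab = "FRET efficiency", ylim = range(c(x$e[idx], 0, 1)), ...)
  lines(t, x$mu[predict(x)[idx]], col = "darkgreen", lwd = 2)
  abline(h = x$mu, lty = 3, col = "steelblue")
  invisible(x)
}

#' @export
simulate.hj_hmm <- function(object, nsim = 1, seed = NULL, n_frames = 500, ...) {
  with_local_seed(seed, {
    replicate(nsim, simplify = FALSE, {
      s <- integer(n_frames)
      s[1] <- sample(1:2, 1, prob = object$pi)
      for (t in 2:n_frames)
        s[t] <- sample(1:2, 1, prob = object$A[s[t - 1], ])
      rnorm(n_frames, object$mu[s], object$sigma[s])
    })
  })
}

#' Extract dwell times from a Viterbi path
#'
#' Run-length encodes the state path within each stitched segment. A dwell
#' is censored when it touches a segment start (left-censored: its true
#' beginning was not observed) or a segment end / stitch seam
#' (right-censored: its exit was not observed).
#'
#' @param viterbi Integer state path (1 = low, 2 = high) from
#'   [viterbi_path()].
#' @param boundaries 0-based seam indices (from the fit or
#'   [truncate_and_stitch()]); `integer(0)` for a single trace.
#' @param dt Frame interval, s.
#' @return A `"dwell_set"` data frame: `state` (`"low"`/`"high"`),
#'   `duration` (s, a positive multiple of `dt`), `segment`,
#'   `censored_left`, `censored_right`, `censored`.
#' @export
extract_dwells <- function(viterbi, boundaries = integer(0), dt = 0.1) {
  stopifnot(all(viterbi %in% 1:2), dt > 0)
  n <- length(viterbi)
  starts <- c(0L, as.integer(boundaries))
  ends <- c(as.integer(boundaries), n)
  out <- vector("list", length(starts))
  for (s in seq_along(starts)) {
    seg <- viterbi[(starts[s] + 1L):ends[s]]
    r <- rle(seg)
    k <- length(r$lengths)
    out[[s]] <- data.frame(
      state = c("low", "high")[r$values],
      duration = r$lengths * dt,
      segment = s,
      censored_left = seq_len(k) == 1L,
      censored_right = seq_len(k) == k,
      stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, out)
  d$censored <- d$censored_left | d$censored_right
  structure(d, class = c("dwell_set", "data.frame"), dt = dt)
}

#' Estimate transition rates and the equilibrium constant
#'
#' Two estimators over the Viterbi dwells. The default (`"mle"`) is the
#' censored-exponential maximum-likelihood estimator: for each state,
#' `k_out = (number of observed exits) / (total time spent in the state)`,
#' which uses every frame of every dwell and is unbiased under window
#' truncation (essential when a mean dwell is comparable to the 20 s
#' stitch window, as for HJ1's high state). The `"dwell"` estimator is the
#' reciprocal mean of fully uncensored dwells; the two agree when dwells
#' are short relative to the window. Uncertainties are bootstrap standard
#' deviations over dwells (seeded). `Keq = k_lh / k_hl` exactly.
#'
#' @param dwells A `"dwell_set"` from [extract_dwells()].
#' @param method `"mle"` (default) or `"dwell"`.
#' @param n_boot Bootstrap resamples for the rate s.d. (default 1000).
#' @param seed Optional integer seed for the bootstrap.
#' @return A `"rate_estimate"`: `k_lh`, `k_hl` (1/s), `sd_lh`, `sd_hl`,
#'   `n_transitions` (observed state changes), `keq`, `method`.
#' @export
estimate_rates <- function(dwells, method = c("mle", "dwell"),
                           n_boot = 1000L, seed = NULL) {
  stopifnot(inherits(dwells, "dwell_set"))
  method <- match.arg(method)
  rate_of <- function(d) {
    k <- c(low = NA_real_, high = NA_real_)
    for (st in c("low", "high")) {
      sub <- d[d$state == st, , drop = FALSE]
      if (method == "mle") {
        exits <- sum(!sub$censored_right)
        k[st] <- exits / sum(sub$duration)
      } else {
        unc <- sub$duration[!sub$censored]
        k[st] <- 1 / mean(unc)
      }
    }
    k
  }
  # precondition: enough observed events per state
  for (st in c("low", "high")) {
    sub <- dwells[dwells$state == st, , drop = FALSE]
    n_ev <- if (method == "mle") sum(!sub$censored_right)
            else sum(!sub$censored)
    if (n_ev < 5)
      stop(sprintf("too few %s dwell events for rate estimation (%d < 5) in the %s state",
                   if (method == "mle") "observed-exit" else "uncensored",
                   n_ev, st))
  }
  k <- rate_of(dwells)
  boot <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      rate_of(dwells[sample.int(nrow(dwells), replace = TRUE), , drop = FALSE])
    }, numeric(2))
  })
  sds <- apply(boot, 1, sd, na.rm = TRUE)
  structure(list(k_lh = unname(k["low"]), k_hl = unname(k["high"]),
                 sd_lh = unname(sds[1]), sd_hl = unname(sds[2]),
                 n_transitions = sum(!dwells$censored_right),
                 keq = unname(k["low"] / k["high"]),
                 method = method),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("Transition rates (", x$method, " estimator)\n", sep = "")
  cat(sprintf("  k(2->1, low->high)  = %.3g +/- %.2g /s\n", x$k_lh, x$sd_lh))
  cat(sprintf("  k(1->2, high->low)  = %.3g +/- %.2g /s\n", x$k_hl, x$sd_hl))
  cat(sprintf("  transitions (N) = %d;  Keq = k21/k12 = %.3g\n",
              x$n_transitions, x$keq))
  invisible(x)
}

#' @export
coef.rate_estimate <- function(object, ...) {
  c(k_lh = object$k_lh, k_hl = object$k_hl, keq = object$keq)
}

#' Cross-check rates from the per-frame transition matrix
#'
#' Diagnostic alternative to [estimate_rates()]: converts the fitted
#' per-frame transition probabilities to continuous rates via
#' `k = -log(1 - a_ij) / dt`.
#'
#' @param fit An `"hj_hmm"`.
#' @param dt Frame interval, s (defaults to the fit's recorded `dt`).
#' @return Named vector `c(k_lh, k_hl)` in 1/s.
#' @export
rates_from_matrix <- function(fit, dt = fit$dt) {
  stopifnot(inherits(fit, "hj_hmm"), is.finite(dt), dt > 0)
  c(k_lh = -log(1 - fit$A[1, 2]) / dt,
    k_hl = -log(1 - fit$A[2, 1]) / dt)
}
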