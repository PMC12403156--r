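# FRET efficiency, molecule QC (acceptor verification, photobleach
# detection) and the dynamic/static digital classification.

#' Compute the FRET-efficiency trace of a molecule
#'
#' FRET efficiency per frame is `E = IA / (IA + ID)` after background
#' subtraction. Frames whose background-subtracted total is not positive
#' are undefined (`NA`) and excluded from downstream statistics rather than
#' imputed; E is never clamped to `[0, 1]`. The analysis window is the
#' half-open, 0-based frame interval from 0 to the earliest of detected
#' donor bleach, detected acceptor bleach and the red-laser segment; the
#' acceptor is verified from the red-laser segment when one exists.
#'
#' @param trace An `"sm_trace"`.
#' @param bg Per-channel background in counts; defaults to the trace's own
#'   metadata (0 for photometry traces whose background was annulus
#'   subtracted).
#' @param noise_sd Channel noise s.d. used by QC thresholds; estimated
#'   robustly from the trace when not recorded.
#' @return A `"fret_trace"`: `molecule_id`, `dt`, `e` (with `NA` where
#'   undefined), `window = c(start, stop)` (0-based, half-open),
#'   `acceptor_confirmed`, `donor_bleach_frame`, `acceptor_bleach_frame`
#'   (0-based or `NA`), and `qc_ok`.
#' @examples
#' tr <- emit_trace(NULL, hj_sensor_panel()$HJ4, emission_spec(noise_sd = 0),
#'                  n_frames = 200, red_laser_start = 150,
#'                  e_fixed = 0.6, seed = 1)
#' f <- compute_fret(tr)
#' mean(window_values(f))
#' @export
compute_fret <- function(trace, bg = NULL, noise_sd = NULL) {
  stopifnot(inherits(trace, "sm_trace"), length(trace$i_d) > 0)
  bg <- bg %||% trace$bg %||% 0
  noise_sd <- noise_sd %||% trace$noise_sd
  if (is.null(noise_sd) || is.na(noise_sd))
    noise_sd <- mad(diff(trace$i_d), na.rm = TRUE) / sqrt(2)
  id <- trace$i_d - bg
  ia <- trace$i_a - bg
  tot <- id + ia
  e <- ifelse(tot > 0, ia / tot, NA_real_)
  bl <- detect_bleach(trace, bg = bg, noise_sd = noise_sd)
  n <- length(e)
  stop_f <- min(bl$donor_bleach_frame %||% NA_integer_,
                bl$acceptor_bleach_frame %||% NA_integer_,
                trace$red_laser_start, n, na.rm = TRUE)
  acc_ok <- confirm_acceptor(trace, bg = bg, noise_sd = noise_sd)
  # signal QC: a genuine pre-bleach window carries the full FRET-pair
  # emission, so its median background-subtracted total must clear the
  # noise floor; windows left over from an undetected early bleach do not.
  sig_ok <- stop_f >= 1 &&
    median(tot[seq_len(stop_f)]) > 5 * sqrt(2) * noise_sd
  qc_ok <- (isTRUE(acc_ok) || is.na(acc_ok)) && sig_ok &&
    any(is.finite(e[seq_len(stop_f)]))
  structure(list(molecule_id = trace$molecule_id, dt = trace$dt, e = e,
                 window = c(0L, as.integer(stop_f)),
                 acceptor_confirmed = acc_ok,
                 donor_bleach_frame = bl$donor_bleach_frame,
                 acceptor_bleach_frame = bl$acceptor_bleach_frame,
                 qc_ok = qc_ok),
            class = "fret_trace")
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf("<fret_trace %s> %d frames, window [%d, %d), acceptor %s\n",
              x$molecule_id, length(x$e), x$window[1], x$window[2],
              if (isTRUE(x$acceptor_confirmed)) "confirmed" else "not confirmed"))
  invisible(x)
}

#' In-window FRET values of a fret_trace
#'
#' @param f A `"fret_trace"`.
#' @param drop_na Drop undefined frames (default `TRUE`).
#' @return Numeric vector of E over the analysis window.
#' @export
window_values <- function(f, drop_na = TRUE) {
  stopifnot(inherits(f, "fret_trace"))
  v <- f$e[(f$window[1] + 1L):f$window[2]]
  if (drop_na) v[is.finite(v)] else v
}

#' Verify the acceptor dye from the red-laser segment
#'
#' Toward the end of acquisition the acceptor is excited directly with a
#' red laser to confirm an active FRET pair. A molecule passes when its
#' mean acceptor intensity over that segment strictly exceeds
#' `background + 3 * noise_sd`.
#'
#' @inheritParams compute_fret
#' @return `TRUE`/`FALSE`, or `NA` when the trace has no red-laser segment.
#' @export
confirm_acceptor <- function(trace, bg = NULL, noise_sd = NULL) {
  stopifnot(inherits(trace, "sm_trace"))
  bg <- bg %||% trace$bg %||% 0
  noise_sd <- noise_sd %||% trace$noise_sd
  if (is.null(noise_sd) || is.na(noise_sd))
    noise_sd <- mad(diff(trace$i_a), na.rm = TRUE) / sqrt(2)
  n <- length(trace$i_a)
  if (trace$red_laser_start >= n) return(NA)
  seg <- trace$i_a[(trace$red_laser_start + 1L):n]
  mean(seg) > bg + 3 * noise_sd
}

# Best two-segment mean-shift split of y: maximizes n1*n2/n * (m1-m2)^2.
# Returns the 0-based index of the first frame after the shift, the drop
# amplitude (m1 - m2) and the post-split mean, or NULL for n < 2*minlen.
best_mean_shift <- function(y, minlen = 5L) {
  n <- length(y)
  if (n < 2L * minlen) return(NULL)
  cs <- cumsum(y)
  k <- minlen:(n - minlen)               # split after k-th frame (1-based)
  m1 <- cs[k] / k
  m2 <- (cs[n] - cs[k]) / (n - k)
  stat <- k * (n - k) / n * (m1 - m2)^2
  i <- which.max(stat)
  list(frame = k[i], drop = m1[i] - m2[i], post_mean = m2[i])
}

#' Locate donor and acceptor photobleach frames
#'
#' Photobleaching shows as a step drop: in total intensity `ID + IA` for
#' the donor, and in `IA` for the acceptor. Each changepoint is the best
#' two-segment mean-shift split, accepted only when the drop exceeds
#' `5 * noise_sd`; the acceptor changepoint must additionally land near
#' background (post-split mean below `bg + 3 * noise_sd`), which prevents
#' FRET switching in a dynamic trace from masquerading as a bleach. The
#' search stops at the red-laser segment. Returned frame indices are
#' 0-based ("first dark frame"); an absent drop returns `NA`.
#'
#' @inheritParams compute_fret
#' @return List with `donor_bleach_frame` and `acceptor_bleach_frame`.
#' @export
detect_bleach <- function(trace, bg = NULL, noise_sd = NULL) {
  stopifnot(inherits(trace, "sm_trace"))
  bg <- bg %||% trace$bg %||% 0
  noise_sd <- noise_sd %||% trace$noise_sd
  n_all <- length(trace$i_d)
  n <- min(trace$red_laser_start, n_all)
  if (is.null(noise_sd) || is.na(noise_sd))
    noise_sd <- mad(diff((trace$i_d + trace$i_a)[seq_len(n)])) / sqrt(2)
  noise_sd <- max(noise_sd, 1e-12)
  donor <- NA_integer_
  acceptor <- NA_integer_
  if (n >= 10L) {
    tot <- (trace$i_d + trace$i_a)[seq_len(n)]
    sh <- best_mean_shift(tot)
    if (!is.null(sh) && sh$drop > 5 * sqrt(2) * noise_sd)
      donor <- as.integer(sh$frame)
    n_a <- if (is.na(donor)) n else donor
    if (n_a >= 10L) {
      sh_a <- best_mean_shift(trace$i_a[seq_len(n_a)])
      if (!is.null(sh_a) && sh_a$drop > 5 * noise_sd &&
          sh_a$post_mean < bg + 3 * noise_sd)
        acceptor <- as.integer(sh_a$frame)
    }
  }
  list(donor_bleach_frame = donor, acceptor_bleach_frame = acceptor)
}

#' Classify a molecule as dynamic or static
#'
#' A dynamic (target-bound) molecule shows continuous anticorrelated
#' switching of the two channels between two FRET states. The call is
#' dynamic iff (i) the Pearson correlation of donor vs acceptor intensity
#' over the analysis window is at most `r_max`, and (ii) a two-state HMM
#' fit of the windowed E trace finds at least `min_transitions` transitions
#' with state separation at least `dE_min`. A molecule failing QC (no
#' verified acceptor, or a window shorter than `min_window`) is rejected.
#'
#' @param trace An `"sm_trace"`.
#' @param fret Optional precomputed [compute_fret()] result for `trace`.
#' @param r_max Anticorrelation threshold (default -0.1; calibrated on
#'   synthetic cohorts so that junctions switching faster than the frame
#'   rate, whose anticorrelation is attenuated by frame integration, are
#'   still caught while static molecules stay below the 2% false-call
#'   budget).
#' @param dE_min Minimum FRET separation of the fitted states (default
#'   0.15).
#' @param min_transitions Minimum number of Viterbi transitions (default 2).
#' @param min_window Minimum analysis-window length in frames (default 50).
#' @return A one-row data frame (`"dynamic_call"`): `molecule_id`, `call`
#'   (`"dynamic"`, `"static"` or `"rejected"`), `r` (anticorrelation) and
#'   `evidence` (qualifying transition count).
#' @export
classify_dynamic <- function(trace, fret = NULL, r_max = -0.1, dE_min = 0.15,
                             min_transitions = 2L, min_window = 50L) {
  stopifnot(inherits(trace, "sm_trace"))
  f <- fret %||% compute_fret(trace)
  reject <- function(r = NA_real_) data.frame(
    molecule_id = trace$molecule_id, call = "rejected", r = r,
    evidence = NA_integer_, stringsAsFactors = FALSE)
  if (!isTRUE(f$qc_ok)) return(reject())
  win <- f$window
  if (win[2] - win[1] < min_window) return(reject())
  idx <- (win[1] + 1L):win[2]
  ok <- is.finite(f$e[idx])
  if (sum(ok) < min_window) return(reject())
  r <- suppressWarnings(cor(trace$i_d[idx][ok], trace$i_a[idx][ok]))
  if (!is.finite(r)) r <- 0
  evidence <- 0L
  if (r <= r_max) {
    e <- f$e[idx][ok]
    # wide-quantile init: brief excursions of fast switchers occupy only
    # the tails of the E histogram
    fit <- try(fit_hmm2(e, init = list(mu = unname(quantile(e, c(0.05, 0.95)))),
                        min_len = min_window), silent = TRUE)
    if (!inherits(fit, "try-error") &&
        (fit$mu[2] - fit$mu[1]) >= dE_min) {
      v <- predict(fit)
      evidence <- sum(diff(v) != 0)
    }
  }
  call <- if (r <= r_max && evidence >= min_transitions) "dynamic" else "static"
  data.frame(molecule_id = trace$molecule_id, call = call, r = r,
             evidence = evidence, stringsAsFactors = FALSE)
}

#' Classify every molecule of a cohort
#'
#' @param x An `"sm_cohort"` or list of `"sm_trace"`.
#' @param ... Passed to [classify_dynamic()].
#' @return A data frame of dynamic calls, one row per molecule.
#' @export
classify_cohort <- function(x, ...) {
  traces <- as_trace_list(x)
  do.call(rbind, lapply(traces, classify_dynamic, ...))
}

#' Percentage of dynamic molecules (digital count)
#'
#' `% dynamic = 100 * n_dynamic / n_total`, where the total counts dynamic
#' plus static molecules; rejected molecules enter neither numerator nor
#' denominator.
#'
#' @param calls Data frame of calls from [classify_cohort()] (or a
#'   character vector of calls).
#' @return Percentage in `[0, 100]`.
#' @export
percent_dynamic <- function(calls) {
  cl <- if (is.data.frame(calls)) calls$call else calls
  cl <- cl[cl != "rejected"]
  if (length(cl) == 0) stop("no analyzable molecules (all rejected)")
  100 * sum(cl == "dynamic") / length(cl)
}
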