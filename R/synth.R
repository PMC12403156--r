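#' Simulate a continuous-time two-state conformer path
#'
#' Draws an exact continuous-time Markov path over the low- and high-FRET
#' conformers: exponential dwells at the given rates, alternating states,
#' with the initial state drawn from the stationary distribution
#' `P(high) = k_lh / (k_lh + k_hl)`. If one rate is zero the other state is
#' absorbing; both rates zero is a degenerate dynamic molecule and is an
#' error.
#'
#' @param kinetics An [hj_kinetics()] object.
#' @param duration_s Path duration in seconds (> 0).
#' @param seed Optional integer seed; the same seed gives an identical path.
#' @return A `"state_path"` data frame with columns `state`
#'   (`"low"`/`"high"`) and `duration` (s). Durations sum to `duration_s`;
#'   states alternate.
#' @examples
#' p <- simulate_state_path(hj_kinetics(0.7, 0.8), 20, seed = 1)
#' tapply(p$duration, p$state, sum)
#' @export
simulate_state_path <- function(kinetics, duration_s, seed = NULL) {
  stopifnot(inherits(kinetics, "hj_kinetics"), duration_s > 0)
  k_lh <- kinetics$k_lh
  k_hl <- kinetics$k_hl
  if (k_lh == 0 && k_hl == 0)
    stop("degenerate kinetics: both rates are zero for a dynamic molecule")
  with_local_seed(seed, {
    p_high <- k_lh / (k_lh + k_hl)
    state <- if (runif(1) < p_high) "high" else "low"
    states <- character(0)
    durs <- numeric(0)
    t_total <- 0
    while (t_total < duration_s) {
      rate_out <- if (state == "high") k_hl else k_lh
      d <- if (rate_out > 0) rexp(1, rate_out) else Inf
      d <- min(d, duration_s - t_total)
      states <- c(states, state)
      durs <- c(durs, d)
      t_total <- t_total + d
      state <- if (state == "high") "low" else "high"
    }
    structure(data.frame(state = states, duration = durs,
                         stringsAsFactors = FALSE),
              class = c("state_path", "data.frame"),
              duration_s = duration_s)
  })
}

# Cumulative time spent in the high state up to each time in `t` (vectorized).
path_high_time <- function(path, t) {
  tb <- c(0, cumsum(path$duration))
  is_high <- path$state == "high"
  cumhigh <- c(0, cumsum(ifelse(is_high, path$duration, 0)))
  t <- pmin(pmax(t, 0), tb[length(tb)])
  i <- findInterval(t, tb, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(path))
  cumhigh[i] + ifelse(is_high[i], t - tb[i], 0)
}

#' Render a donor/acceptor intensity trace from a state path
#'
#' Emits a camera-level trace at fixed frame interval `dt`. Each frame's
#' FRET level is the occupancy-weighted mixture of the two state means
#' (fractional occupancy of the high state within the frame), which avoids
#' aliasing artifacts for kinetics fast relative to the frame time. Donor
#' and acceptor photobleach times are drawn exponentially; after donor
#' (Cy3) bleach both channels fall to background, after acceptor (Cy5)
#' bleach all emission appears in the donor channel. From frame
#' `red_laser_start` onward the acceptor is excited directly (intensity
#' independent of FRET) while it remains unbleached, emulating the
#' end-of-movie red-laser verification segment.
#'
#' @param path A `"state_path"`, or `NULL` for a static molecule (then
#'   `e_fixed` must be given).
#' @param sensor An [hj_sensor()] providing the state FRET means.
#' @param em An [emission_spec()].
#' @param n_frames Number of frames (>= 1).
#' @param dt Frame interval in seconds (default 0.1, i.e. 100 ms frames).
#' @param red_laser_start 0-based frame index at which direct acceptor
#'   excitation begins (default 1000); use `n_frames` to disable.
#' @param e_fixed Constant FRET level for a static molecule (e.g. the
#'   sensor's `e_static`); overrides `path`.
#' @param molecule_id Identifier stored in the trace.
#' @param seed Optional integer seed.
#' @return An `"sm_trace"`: list with `molecule_id`, `dt`, `i_d`, `i_a`,
#'   `red_laser_start`, emission metadata (`bg`, `noise_sd`, `i_total`) and
#'   a `truth` list (generating sensor, path, frame FRET, bleach frames).
#' @export
emit_trace <- function(path, sensor, em = emission_spec(), n_frames,
                       dt = 0.1, red_laser_start = 1000, e_fixed = NULL,
                       molecule_id = "mol1", seed = NULL) {
  stopifnot(n_frames >= 1, dt > 0, red_laser_start >= 0)
  red_laser_start <- min(red_laser_start, n_frames)   # may fall past the end
  with_local_seed(seed, {
    if (is.null(e_fixed)) {
      stopifnot(inherits(path, "state_path"))
      stopifnot(attr(path, "duration_s") >= n_frames * dt - 1e-9)
      edges <- (0:n_frames) * dt
      occ <- diff(path_high_time(path, edges)) / dt
      e_frame <- occ * sensor$e_high + (1 - occ) * sensor$e_low
    } else {
      stopifnot(e_fixed >= 0, e_fixed <= 1)
      e_frame <- rep(e_fixed, n_frames)
    }
    tb_d <- if (is.finite(em$t_bleach_mean)) rexp(1, 1 / em$t_bleach_mean) else Inf
    tb_a <- if (is.finite(em$t_bleach_cy5_mean)) rexp(1, 1 / em$t_bleach_cy5_mean) else Inf
    donor_bleach <- if (tb_d < n_frames * dt) floor(tb_d / dt) else NA_integer_
    acc_bleach <- if (tb_a < n_frames * dt) floor(tb_a / dt) else NA_integer_

    f <- 0:(n_frames - 1)                       # 0-based frame index
    d_alive <- is.na(donor_bleach) | f < donor_bleach
    a_alive <- is.na(acc_bleach) | f < acc_bleach
    red_on <- f >= red_laser_start

    sig_a <- ifelse(red_on, em$i_total * a_alive,
                    em$i_total * e_frame * (d_alive & a_alive))
    sig_d <- ifelse(red_on, 0,
                    ifelse(d_alive,
                           em$i_total * ifelse(a_alive, 1 - e_frame, 1), 0))
    i_a <- em$bg + sig_a + rnorm(n_frames, 0, em$noise_sd)
    i_d <- em$bg + sig_d + rnorm(n_frames, 0, em$noise_sd)

    structure(list(molecule_id = molecule_id, dt = dt,
                   i_d = i_d, i_a = i_a,
                   red_laser_start = as.integer(red_laser_start),
                   bg = em$bg, noise_sd = em$noise_sd, i_total = em$i_total,
                   truth = list(sensor = sensor$name,
                                dynamic = is.null(e_fixed),
                                e_frame = e_frame,
                                path = if (is.null(e_fixed)) path else NULL,
                                donor_bleach_frame = donor_bleach,
                                acceptor_bleach_frame = acc_bleach)),
              class = "sm_trace")
  })
}

#' @export
print.sm_trace <- function(x, ...) {
  cat(sprintf("<sm_trace %s> %d frames @ %.3g s, red laser from frame %d\n",
              x$molecule_id, length(x$i_d), x$dt, x$red_laser_start))
  invisible(x)
}

#' Simulate a cohort of single molecules
#'
#' Each molecule is assigned to a sensor by the mixing weights and to the
#' dynamic (target-bound, switching) or static (incomplete junction) class
#' by the per-sensor dynamic fraction. Static molecules emit at the
#' sensor's `e_static`; dynamic ones follow a fresh Markov path at the
#' sensor's rates. A ground-truth table is returned alongside the traces.
#'
#' @param sensors List of [hj_sensor()] objects (e.g. [hj_sensor_panel()]).
#' @param n_molecules Number of molecules to simulate.
#' @param weights Sensor mixing weights, non-negative, summing to 1.
#'   Default: equimolar.
#' @param fraction_dynamic Scalar or per-sensor vector of the probability
#'   that a molecule of that sensor is dynamic, in `[0, 1]`.
#' @param em An [emission_spec()].
#' @param n_frames,dt,red_laser_start Frame geometry, as in [emit_trace()].
#' @param seed Optional integer seed (cohort is bit-reproducible).
#' @return An `"sm_cohort"`: list with `traces` (list of `"sm_trace"`) and
#'   `truth` (data frame: molecule_id, sensor, dynamic, bleach frames).
#' @examples
#' co <- simulate_cohort(hj_sensor_panel(), n_molecules = 8,
#'                       fraction_dynamic = 0.5, n_frames = 300, seed = 1)
#' table(co$truth$sensor, co$truth$dynamic)
#' @export
simulate_cohort <- function(sensors, n_molecules,
                            weights = rep(1 / length(sensors), length(sensors)),
                            fraction_dynamic = 1, em = emission_spec(),
                            n_frames = 1500, dt = 0.1,
                            red_laser_start = 1000, seed = NULL) {
  if (length(sensors) == 0) stop("empty sensor list")
  stopifnot(all(weights >= 0), abs(sum(weights) - 1) < 1e-9,
            all(fraction_dynamic >= 0), all(fraction_dynamic <= 1))
  if (length(fraction_dynamic) == 1L)
    fraction_dynamic <- rep(fraction_dynamic, length(sensors))
  stopifnot(length(fraction_dynamic) == length(sensors),
            length(weights) == length(sensors))
  with_local_seed(seed, {
    idx <- sample.int(length(sensors), n_molecules, replace = TRUE,
                      prob = weights)
    traces <- vector("list", n_molecules)
    truth <- vector("list", n_molecules)
    for (m in seq_len(n_molecules)) {
      sn <- sensors[[idx[m]]]
      dyn <- runif(1) < fraction_dynamic[idx[m]]
      id <- sprintf("mol%04d", m)
      if (dyn) {
        p <- simulate_state_path(sn$kinetics, n_frames * dt)
        tr <- emit_trace(p, sn, em, n_frames, dt, red_laser_start,
                         molecule_id = id)
      } else {
        tr <- emit_trace(NULL, sn, em, n_frames, dt, red_laser_start,
                         e_fixed = sn$e_static, molecule_id = id)
      }
      traces[[m]] <- tr
      truth[[m]] <- data.frame(
        molecule_id = id, sensor = sn$name, dynamic = dyn,
        donor_bleach_frame = tr$truth$donor_bleach_frame %||% NA_integer_,
        acceptor_bleach_frame = tr$truth$acceptor_bleach_frame %||% NA_integer_,
        stringsAsFactors = FALSE)
    }
    structure(list(traces = traces, truth = do.call(rbind, truth)),
              class = "sm_cohort")
  })
}

#' @export
print.sm_cohort <- function(x, ...) {
  cat(sprintf("<sm_cohort> %d molecules (%d dynamic) across sensors: %s\n",
              nrow(x$truth), sum(x$truth$dynamic),
              paste(unique(x$truth$sensor), collapse = ", ")))
  invisible(x)
}

#' Simulate a digital-counting dose-response experiment
#'
#' Simulates one cohort per target concentration for a single sensor. The
#' probability that a molecule is dynamic (target-bound) follows a Hill
#' binding curve `f(c) = f_max * c^h / (c^h + c50^h)`; each molecule's
#' status is an independent Bernoulli draw, which is what makes the
#' counting "digital" and gives rise to limit-of-detection behaviour at
#' small molecule numbers. A concentration of exactly 0 is treated as the
#' blank (fraction 0).
#'
#' @param sensor An [hj_sensor()].
#' @param concentrations Molar concentrations (>= 0; include 0 for a blank).
#' @param binding List with `f_max` (0 < f_max <= 1), `c50` (molar) and
#'   `h` (Hill coefficient).
#' @param n_per_conc Molecules per concentration (the study used ~100).
#' @param em,n_frames,dt,red_laser_start As in [simulate_cohort()].
#' @param seed Optional integer seed.
#' @return A `"dose_sim"`: list with `concentration`, `fraction_dynamic`
#'   (the generating fractions) and `cohorts` (one `"sm_cohort"` each).
#' @export
simulate_dose_response <- function(sensor, concentrations,
                                   binding = list(f_max = 0.8, c50 = 1e-9, h = 1),
                                   n_per_conc = 100, em = emission_spec(),
                                   n_frames = 1500, dt = 0.1,
                                   red_laser_start = 1000, seed = NULL) {
  stopifnot(all(concentrations >= 0), binding$f_max > 0, binding$f_max <= 1,
            binding$c50 > 0, binding$h > 0)
  frac <- hill_fraction(concentrations, binding$f_max, binding$c50, binding$h)
  with_local_seed(seed, {
    cohorts <- lapply(seq_along(concentrations), function(i) {
      simulate_cohort(list(sensor), n_molecules = n_per_conc, weights = 1,
                      fraction_dynamic = frac[i], em = em,
                      n_frames = n_frames, dt = dt,
                      red_laser_start = red_laser_start)
    })
    structure(list(concentration = concentrations, fraction_dynamic = frac,
                   cohorts = cohorts, sensor = sensor$name),
              class = "dose_sim")
  })
}

# Hill/Langmuir bound fraction; c = 0 maps to exactly 0.
hill_fraction <- function(c, f_max, c50, h) {
  ifelse(c > 0, f_max * c^h / (c^h + c50^h), 0)
}
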