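# Shared fixtures, built in code at test time.

# Noise-free camera model without photobleaching or background.
em_clean <- function(i_total = 1000, bg = 0)
  emission_spec(i_total = i_total, noise_sd = 0, bg = bg,
                t_bleach_mean = Inf, t_bleach_cy5_mean = Inf)

# Realistic camera model without photobleaching.
em_nobleach <- function()
  emission_spec(t_bleach_mean = Inf, t_bleach_cy5_mean = Inf)

# Bare intensity trace with explicit channels (no simulation).
make_trace <- function(i_d, i_a, dt = 0.1, red_laser_start = length(i_d),
                       bg = 0, noise_sd = NA_real_, id = "t1") {
  structure(list(molecule_id = id, dt = dt, i_d = i_d, i_a = i_a,
                 red_laser_start = as.integer(red_laser_start),
                 bg = bg, noise_sd = noise_sd, i_total = NA_real_,
                 truth = NULL),
            class = "sm_trace")
}

# Bare FRET trace with a given window (0-based, half-open).
make_fret_trace <- function(e, window = c(0L, length(e)), dt = 0.1,
                            id = "f1") {
  structure(list(molecule_id = id, dt = dt, e = e,
                 window = as.integer(window), acceptor_confirmed = NA,
                 donor_bleach_frame = NA_integer_,
                 acceptor_bleach_frame = NA_integer_, qc_ok = TRUE),
            class = "fret_trace")
}

# Deterministic state path from explicit (state, duration) runs.
make_path <- function(states, durations) {
  structure(data.frame(state = states, duration = durations,
                       stringsAsFactors = FALSE),
            class = c("state_path", "data.frame"),
            duration_s = sum(durations))
}
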