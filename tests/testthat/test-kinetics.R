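# Two-state HMM: stitching, Baum-Welch, Viterbi, dwells, rates.

test_that("truncate-and-stitch keeps fixed windows and records seams", {
  fts <- list(make_fret_trace(runif(500), id = "a"),
              make_fret_trace(runif(250), id = "b"),
              make_fret_trace(runif(150), id = "c"))
  st <- truncate_and_stitch(fts, 200)
  expect_length(st$e, 400)
  expect_equal(st$boundaries, 200)
  expect_equal(st$trace_ids, c("a", "b"))
  expect_equal(st$dropped, "c")
  expect_equal(st$e[1:200], fts[[1]]$e[1:200])
  # a single qualifying trace has no seams
  st1 <- truncate_and_stitch(fts[1], 200)
  expect_equal(st1$boundaries, integer(0))
  expect_error(truncate_and_stitch(fts[3], 200), "zero traces")
})

test_that("forward likelihood matches exhaustive enumeration", {
  mu <- c(0.25, 0.62); sigma <- c(0.05, 0.08)
  A <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  pi0 <- c(0.35, 0.65)
  set.seed(20)
  for (T in c(1, 3, 5, 8)) {
    e <- runif(T)
    es <- hjfret:::hmm2_estep_cpp(e, T, mu, sigma, A, pi0)
    expect_equal(es$loglik, log(brute_likelihood(e, mu, sigma, A, pi0)),
                 tolerance = 1e-10)
  }
})

test_that("Viterbi matches the exhaustively enumerated best path", {
  mu <- c(0.2, 0.6); sigma <- c(0.06, 0.06)
  A <- matrix(c(0.85, 0.15, 0.25, 0.75), 2, 2, byrow = TRUE)
  pi0 <- c(0.5, 0.5)
  set.seed(21)
  for (rep in 1:5) {
    e <- runif(8)
    v <- hjfret:::hmm2_viterbi_cpp(e, 8L, mu, sigma, A, pi0)
    expect_equal(v, brute_viterbi(e, mu, sigma, A, pi0)$path,
                 ignore_attr = TRUE)
  }
})

test_that("EM log-likelihood is monotone and noiseless series recover exactly", {
  e <- rep(c(0.2, 0.2, 0.2, 0.4, 0.4), times = 40)
  fit <- fit_hmm2(e)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_equal(unname(fit$mu), c(0.2, 0.4), tolerance = 1e-6)
  expect_equal(unname(fit$sigma), c(1e-3, 1e-3))    # floored
  expect_gt(fit$mu[2], fit$mu[1])                   # labelling invariant
  expect_equal(rowSums(fit$A), c(low = 1, high = 1), tolerance = 1e-9)
  # model-object surface
  expect_s3_class(logLik(fit), "logLik")
  expect_named(coef(fit), c("mu_low", "mu_high", "sigma_low", "sigma_high",
                            "a_low_high", "a_high_low"))
  expect_length(residuals(fit), length(e))
  expect_lt(max(abs(residuals(fit))), 1e-9)
})

test_that("EM recovers parameters of a noisy stitched simulation", {
  s <- hj_sensor_panel()$HJ2
  res <- characterize_sensor(s, n_traces = 80, n_frames = 900,
                             red_laser_start = 800, seed = 22)
  expect_true(res$fit$converged)
  expect_equal(unname(res$fit$mu), c(0.2, 0.6), tolerance = 0.1)
  expect_lt(abs(res$fit$mu[1] - 0.2), 0.02)
  expect_lt(abs(res$fit$mu[2] - 0.6), 0.02)
  # rates within 20% of the generating values
  expect_lt(abs(res$rates$k_lh - 0.7) / 0.7, 0.2)
  expect_lt(abs(res$rates$k_hl - 0.8) / 0.8, 0.2)
  # transition-matrix diagnostic agrees with the dwell-based estimate
  km <- rates_from_matrix(res$fit, 0.1)
  expect_lt(abs(km["k_lh"] - res$rates$k_lh) / res$rates$k_lh, 0.25)
  expect_lt(abs(km["k_hl"] - res$rates$k_hl) / res$rates$k_hl, 0.25)
})

test_that("Viterbi decoding is stable and catches large excursions", {
  e0 <- rep(0.2, 200)
  fit <- fit_hmm2(e0, init = list(mu = c(0.2, 0.6), sigma = c(0.05, 0.05)))
  v <- predict(fit, newdata = e0)
  expect_true(all(v == 1))
  # a one-frame 5-sigma excursion becomes a one-frame dwell
  e1 <- rep(0.2, 101); e1[51] <- 0.6
  v1 <- hjfret:::hmm2_viterbi_cpp(e1, length(e1), c(0.2, 0.6), c(0.05, 0.05),
                                  matrix(c(0.95, 0.05, 0.05, 0.95), 2,
                                         byrow = TRUE, nrow = 2),
                                  c(0.5, 0.5))
  expect_equal(sum(v1 == 2), 1L)
  expect_equal(which(v1 == 2), 51L)
})

test_that("dwell extraction run-length encodes with boundary censoring", {
  # path L L L H H L L, no seams
  v <- c(1, 1, 1, 2, 2, 1, 1)
  d <- extract_dwells(v, integer(0), dt = 1)
  expect_equal(d$state, c("low", "high", "low"))
  expect_equal(d$duration, c(3, 2, 2))
  expect_equal(d$censored, c(TRUE, FALSE, TRUE))
  # a seam inside a high run splits it and censors both halves
  v2 <- c(1, 2, 2, 2, 2, 1)                       # seam after index 3
  d2 <- extract_dwells(v2, boundaries = 3L, dt = 1)
  expect_equal(d2$state, c("low", "high", "high", "low"))
  expect_equal(d2$duration, c(1, 2, 2, 1))
  expect_true(all(d2$censored))
  # an all-low path is one fully censored dwell
  d3 <- extract_dwells(rep(1, 10), integer(0), dt = 0.1)
  expect_equal(nrow(d3), 1L)
  expect_true(d3$censored)
  expect_equal(d3$duration, 1)
})

test_that("rate estimators invert dwell means and respect Keq identity", {
  # synthetic dwell set: low dwells of exactly 2 s, high of exactly 0.5 s
  d <- structure(data.frame(
    state = rep(c("low", "high"), 12),
    duration = rep(c(2, 0.5), 12),
    segment = 1L,
    censored_left = rep(FALSE, 24),
    censored_right = rep(FALSE, 24)),
    class = c("dwell_set", "data.frame"), dt = 0.1)
  d$censored <- d$censored_left | d$censored_right
  r_dwell <- estimate_rates(d, method = "dwell", n_boot = 50, seed = 1)
  expect_equal(r_dwell$k_lh, 0.5)
  expect_equal(r_dwell$k_hl, 2)
  expect_equal(r_dwell$keq, r_dwell$k_lh / r_dwell$k_hl)
  # with nothing censored the MLE coincides with the dwell-mean estimator
  r_mle <- estimate_rates(d, method = "mle", n_boot = 50, seed = 1)
  expect_equal(r_mle$k_lh, r_dwell$k_lh)
  expect_equal(r_mle$k_hl, r_dwell$k_hl)
  expect_equal(r_mle$n_transitions, 24L)
  # deficient state named in the error
  d_low <- d[d$state == "low", ]
  class(d_low) <- class(d); attr(d_low, "dt") <- 0.1
  expect_error(estimate_rates(d_low), "high")
})

test_that("symmetric kinetics give Keq near one", {
  s <- hj_sensor("sym", 0.2, 0.6, 0.3, hj_kinetics(0.5, 0.5))
  res <- characterize_sensor(s, n_traces = 60, n_frames = 700,
                             red_laser_start = 600, seed = 23)
  expect_lt(abs(res$rates$keq - 1), 0.15)
})

test_that("rates faster than the frame rate are underestimated (known bias)", {
  s <- hj_sensor("fast", 0.3, 0.7, 0.4, hj_kinetics(6, 6))
  res <- characterize_sensor(s, n_traces = 40, n_frames = 600,
                             red_laser_start = 500, seed = 24)
  expect_lt(res$rates$k_lh, 6)
  expect_lt(res$rates$k_hl, 6)
})

test_that("the stitched fit never counts transitions across seams", {
  # two segments with opposite constant states: a naive fit would see one
  # giant transition at the seam
  e <- c(rnorm(200, 0.2, 0.02), rnorm(200, 0.6, 0.02))
  st <- structure(list(e = e, seglen = c(200L, 200L), boundaries = 200L,
                       trace_ids = c("a", "b"), dropped = character(0),
                       dt = 0.1), class = "stitched_series")
  fit <- fit_hmm2(st, init = list(mu = c(0.2, 0.6)))
  v <- predict(fit)
  d <- extract_dwells(v, fit$boundaries, dt = 0.1)
  r <- try(estimate_rates(d), silent = TRUE)
  expect_s3_class(r, "try-error")        # zero observed exits in each state
  expect_equal(summary(fit)$n_transitions, 0L)
})
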