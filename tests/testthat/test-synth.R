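# Synthetic trace generator: Markov paths, emission model, cohorts.

test_that("state paths have the analytic stationary occupancy", {
  p <- simulate_state_path(hj_kinetics(0.25, 0.06), 1e5, seed = 4)
  frac_high <- sum(p$duration[p$state == "high"]) / 1e5
  expect_equal(frac_high, 0.25 / 0.31, tolerance = 0.012)
  # states alternate and durations are positive, summing to the duration
  expect_true(all(p$duration > 0))
  expect_true(all(p$state[-1] != p$state[-nrow(p)]))
  expect_equal(sum(p$duration), 1e5)
})

test_that("a zero rate makes the opposite state absorbing", {
  # k_hl = 0: stationary P(high) = 1, so the path starts high and stays
  p <- simulate_state_path(hj_kinetics(0.25, 0), 50, seed = 1)
  expect_equal(nrow(p), 1L)
  expect_equal(p$state, "high")
  expect_equal(p$duration, 50)
  expect_error(simulate_state_path(hj_kinetics(0, 0), 10),
               "degenerate")
})

test_that("dwell times are exponential with the right mean", {
  p <- simulate_state_path(hj_kinetics(1, 1), 1e4, seed = 8)
  inner <- p[-c(1, nrow(p)), ]            # drop boundary-truncated dwells
  expect_gt(nrow(inner), 5000)
  expect_equal(mean(inner$duration[inner$state == "low"]), 1, tolerance = 0.05)
  expect_equal(mean(inner$duration[inner$state == "high"]), 1, tolerance = 0.05)
  ks <- stats::ks.test(inner$duration[inner$state == "low"], "pexp", 1)
  expect_gt(ks$p.value, 0.01)
})

test_that("identical seeds give bit-identical traces and cohorts", {
  s <- hj_sensor_panel()$HJ2
  p <- simulate_state_path(s$kinetics, 30, seed = 5)
  p2 <- simulate_state_path(s$kinetics, 30, seed = 5)
  expect_identical(p, p2)
  t1 <- emit_trace(p, s, emission_spec(), 300, seed = 6)
  t2 <- emit_trace(p, s, emission_spec(), 300, seed = 6)
  expect_identical(t1, t2)
  c1 <- simulate_cohort(hj_sensor_panel(), 10, n_frames = 100, seed = 7)
  c2 <- simulate_cohort(hj_sensor_panel(), 10, n_frames = 100, seed = 7)
  expect_identical(c1, c2)
})

test_that("noiseless emission conserves the total intensity", {
  s <- hj_sensor_panel()$HJ1
  p <- simulate_state_path(s$kinetics, 30, seed = 2)
  em <- emission_spec(i_total = 1000, noise_sd = 0, bg = 100,
                      t_bleach_mean = Inf, t_bleach_cy5_mean = Inf)
  tr <- emit_trace(p, s, em, 300, red_laser_start = 300, seed = 3)
  expect_equal(tr$i_d + tr$i_a, rep(2 * 100 + 1000, 300))
})

test_that("a noiseless static high-FRET molecule splits channels exactly", {
  s <- hj_sensor("X", 0.2, 0.6, 0.6, hj_kinetics(1, 1))
  tr <- emit_trace(NULL, s, em_clean(), 100, red_laser_start = 100,
                   e_fixed = 0.6, seed = 1)
  expect_equal(tr$i_a, rep(600, 100))
  expect_equal(tr$i_d, rep(400, 100))
})

test_that("recomputed E of a noisy two-state trace clusters at the state means", {
  s <- hj_sensor_panel()$HJ1                     # 0.2 <-> 0.4
  slow <- hj_sensor("slow", s$e_low, s$e_high, s$e_static,
                    hj_kinetics(0.2, 0.2))
  p <- simulate_state_path(slow$kinetics, 200, seed = 10)
  tr <- emit_trace(p, slow, em_nobleach(), 2000, red_laser_start = 2000,
                   seed = 11)
  e <- (tr$i_a - 100) / (tr$i_a + tr$i_d - 200)
  km <- kmeans(e, centers = c(0.25, 0.35))
  expect_equal(sort(km$centers[, 1]), c(0.2, 0.4), tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("cohort assignment partitions molecules as specified", {
  co <- simulate_cohort(hj_sensor_panel(), 400, fraction_dynamic = 1,
                        n_frames = 10, seed = 13)
  counts <- table(co$truth$sensor)
  expect_equal(sum(counts), 400)
  expect_true(all(abs(counts - 100) < 3 * sqrt(400 * 0.25 * 0.75)))
  expect_true(all(co$truth$dynamic))
  # omission design: HJ1 fraction zero leaves its molecules static
  co2 <- simulate_cohort(hj_sensor_panel(), 200,
                         fraction_dynamic = c(0, 1, 1, 1), n_frames = 10,
                         seed = 14)
  expect_equal(sum(co2$truth$dynamic[co2$truth$sensor == "HJ1"]), 0)
  expect_true(all(co2$truth$dynamic[co2$truth$sensor != "HJ1"]))
  # all-static single-sensor cohort emits at e_static
  co3 <- simulate_cohort(hj_sensor_panel()["HJ1"], 5, weights = 1,
                         fraction_dynamic = 0, em = em_clean(),
                         n_frames = 20, red_laser_start = 20, seed = 15)
  e <- with(co3$traces[[1]], i_a / (i_a + i_d))
  expect_equal(e, rep(0.2, 20))
  expect_error(simulate_cohort(list(), 10), "empty")
})

test_that("dose-response fractions follow the Hill binding model", {
  s <- hj_sensor_panel()$HJ4
  ds <- simulate_dose_response(s, c(0, 1e-15, 1e-9, 1e-3),
                               binding = list(f_max = 0.8, c50 = 1e-9, h = 1),
                               n_per_conc = 50, n_frames = 10, seed = 16)
  expect_equal(ds$fraction_dynamic[1], 0)            # blank
  expect_equal(ds$fraction_dynamic[3], 0.4)          # half-saturation
  expect_equal(ds$fraction_dynamic[4], 0.8, tolerance = 1e-5)  # saturation
  # truth dynamic counts are Bernoulli draws at those fractions
  n_dyn <- vapply(ds$cohorts, function(co) sum(co$truth$dynamic), integer(1))
  expect_equal(n_dyn[1], 0L)
  expect_lt(abs(n_dyn[3] - 20), 3 * sqrt(50 * 0.4 * 0.6) + 1)
  # far below c50 at small n, detections are rare or absent
  ds2 <- simulate_dose_response(s, 5e-14,
                                binding = list(f_max = 0.8, c50 = 1e-9, h = 1),
                                n_per_conc = 100, n_frames = 10, seed = 17)
  expect_lt(sum(ds2$cohorts[[1]]$truth$dynamic), 4)
})

test_that("photobleaching darkens the right channels", {
  s <- hj_sensor_panel()$HJ4
  em <- emission_spec(noise_sd = 0, bg = 100, t_bleach_mean = 2,
                      t_bleach_cy5_mean = 1e9)
  # force an early donor bleach by trying seeds until one lands mid-trace
  tr <- emit_trace(NULL, s, em, 100, red_laser_start = 100, e_fixed = 0.6,
                   seed = 21)
  bf <- tr$truth$donor_bleach_frame
  expect_false(is.na(bf))
  expect_true(all(tr$i_d[(bf + 1):100] == 100))
  expect_true(all(tr$i_a[(bf + 1):100] == 100))
  # acceptor-first bleach routes everything into the donor channel
  em2 <- emission_spec(noise_sd = 0, bg = 100, t_bleach_mean = 1e9,
                       t_bleach_cy5_mean = 2)
  tr2 <- emit_trace(NULL, s, em2, 100, red_laser_start = 100, e_fixed = 0.6,
                    seed = 22)
  bf2 <- tr2$truth$acceptor_bleach_frame
  expect_false(is.na(bf2))
  expect_true(all(tr2$i_a[(bf2 + 1):100] == 100))
  expect_true(all(tr2$i_d[(bf2 + 1):100] == 1100))
})

test_that("the red-laser segment boosts the acceptor while Cy5 lives", {
  s <- hj_sensor_panel()$HJ1
  tr <- emit_trace(NULL, s, em_clean(i_total = 800), 100,
                   red_laser_start = 60, e_fixed = 0.2, seed = 23)
  expect_true(all(tr$i_a[61:100] == 800))
  expect_true(all(tr$i_d[61:100] == 0))
  expect_true(all(tr$i_a[1:60] == 160))
})

test_that("trace tables round-trip through the delimited format", {
  co <- simulate_cohort(hj_sensor_panel(), 4, n_frames = 50,
                        red_laser_start = 40, seed = 30)
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  write_traces(co, f)
  back <- read_traces(f)
  expect_length(back, 4)
  expect_equal(back[[1]]$i_d, round(co$traces[[1]]$i_d, 3))
  expect_equal(back[[2]]$dt, 0.1)
  expect_equal(back[[3]]$red_laser_start, 40L)
  expect_equal(back[[4]]$bg, 100)
})
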