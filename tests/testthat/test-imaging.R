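# Movie rendering, spot detection, channel pairing, photometry, movie I/O.

# small noiseless dynamic cohort with distinct intensities, so extracted
# traces can be matched to their generators by correlation
imaging_cohort <- function(n = 6, n_frames = 30, seed = 60) {
  s <- hj_sensor("IMG", 0.2, 0.8, 0.4, hj_kinetics(2, 2))
  lapply(seq_len(n), function(m) {
    p <- simulate_state_path(s$kinetics, n_frames * 0.1, seed = seed + m)
    emit_trace(p, s, em_clean(i_total = 600 + 80 * m), n_frames,
               red_laser_start = n_frames,
               molecule_id = sprintf("gt%02d", m), seed = seed + m)
  })
}

test_that("a rendered spot conserves its integrated flux", {
  tr <- imaging_cohort(1)
  mv <- render_movie(tr, positions = cbind(20, 20), width = 96, height = 48,
                     bg_offset = 0, read_noise = 0, seed = 1)
  # 7x7 box around the donor spot holds the trace value to within 1%
  box <- mv$frames[(20 - 3):(20 + 3) + 1, (20 - 3):(20 + 3) + 1, 1]
  expect_equal(sum(box), tr[[1]]$i_d[1], tolerance = 0.01)
  boxa <- mv$frames[(20 - 3):(20 + 3) + 1, (20 + 48 - 3):(20 + 48 + 3) + 1, 1]
  expect_equal(sum(boxa), tr[[1]]$i_a[1], tolerance = 0.01)
})

test_that("a blank movie is background only and yields no detections", {
  mv <- render_movie(list(), width = 64, height = 32, bg_offset = 10,
                     read_noise = 2, seed = 2, n_frames = 12)
  expect_equal(mean(mv$frames), 10, tolerance = 0.05)
  expect_lt(sd(mv$frames), 3)
  expect_equal(nrow(detect_spots(mv)), 0)
})

test_that("detection finds rendered spots to sub-pixel accuracy", {
  n <- 12
  tr <- imaging_cohort(n)
  mv <- render_movie(tr, width = 128, height = 64, seed = 3)
  pos <- attr(mv, "positions")
  spots <- detect_spots(mv, k = 10, threshold_sd = 5)
  ch <- split_channels(spots, mv$width)
  expect_equal(nrow(ch$donor), n)
  expect_equal(nrow(ch$acceptor), n)
  for (i in seq_len(n)) {
    d <- sqrt((ch$donor$x - pos[i, 1])^2 + (ch$donor$y - pos[i, 2])^2)
    expect_lt(min(d), 0.5)
  }
})

test_that("detection count is monotone non-increasing in the threshold", {
  tr <- imaging_cohort(8)
  mv <- render_movie(tr, width = 128, height = 64, seed = 4)
  counts <- vapply(c(3, 5, 8, 15, 50),
                   function(th) nrow(detect_spots(mv, threshold_sd = th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("spots closer than the merge radius collapse to one detection", {
  tr <- imaging_cohort(2)
  mv <- render_movie(tr, positions = rbind(c(20, 20), c(21, 20)),
                     width = 96, height = 48, min_separation = 0, seed = 5)
  spots <- split_channels(detect_spots(mv), mv$width)
  expect_equal(nrow(spots$donor), 1)
})

test_that("channel pairing is greedy nearest-neighbour with a tolerance", {
  donor <- data.frame(x = c(10, 30, 50), y = c(10, 20, 30))
  acceptor <- data.frame(x = c(10, 30, 50) + 64, y = c(10, 20, 30))
  p <- pair_channels(donor, acceptor, offset = c(64, 0))
  expect_equal(nrow(p), 3)
  expect_equal(p$distance, rep(0, 3))
  # an acceptor-only spot stays unpaired
  extra <- rbind(acceptor, data.frame(x = 100, y = 40))
  p2 <- pair_channels(donor, extra, offset = c(64, 0))
  expect_equal(nrow(p2), 3)
  expect_equal(nrow(attr(p2, "unpaired")$acceptor), 1)
  # a 1 px global misregistration still pairs, at distance ~1
  shifted <- transform(acceptor, x = x + 1)
  p3 <- pair_channels(donor, shifted, offset = c(64, 0), tol_px = 2)
  expect_equal(nrow(p3), 3)
  expect_equal(p3$distance, rep(1, 3), tolerance = 1e-9)
  # beyond tolerance nothing pairs
  far <- transform(acceptor, x = x + 5)
  expect_equal(nrow(pair_channels(donor, far, offset = c(64, 0))), 0)
})

test_that("photometry round-trips rendered traces and ignores background", {
  n <- 10
  tr <- imaging_cohort(n, n_frames = 40)
  mv <- render_movie(tr, width = 128, height = 64, read_noise = 0.5,
                     seed = 6)
  pos <- attr(mv, "positions")
  spots <- split_channels(detect_spots(mv), mv$width)
  pairs <- pair_channels(spots$donor, spots$acceptor, width = mv$width)
  expect_equal(nrow(pairs), n)
  out <- extract_traces(mv, pairs)
  expect_length(out, n)
  # match each extracted trace to its generator by position
  for (j in seq_along(out)) {
    i <- which.min((pos[, 1] - pairs$donor_x[j])^2 +
                     (pos[, 2] - pairs$donor_y[j])^2)
    expect_gt(cor(out[[j]]$i_d, tr[[i]]$i_d), 0.99)
    expect_gt(cor(out[[j]]$i_a, tr[[i]]$i_a), 0.99)
    # the finite aperture clips the same PSF fraction from both channels,
    # so the recovered FRET ratio is unbiased
    scale_d <- median(out[[j]]$i_d) / median(tr[[i]]$i_d)
    scale_a <- median(out[[j]]$i_a) / median(tr[[i]]$i_a)
    expect_gt(scale_d, 0.7)
    expect_equal(scale_d, scale_a, tolerance = 0.05)
  }
  # a uniform +50-count pedestal changes nothing (annulus subtraction)
  mv2 <- mv
  mv2$frames <- mv2$frames + 50
  out2 <- extract_traces(mv2, pairs)
  expect_equal(out2[[1]]$i_d, out[[1]]$i_d, tolerance = 1e-6)
})

test_that("overlapping molecules are flagged as contaminated", {
  tr <- imaging_cohort(2, n_frames = 10)
  mv <- render_movie(tr, positions = rbind(c(20, 20), c(23, 20)),
                     width = 96, height = 48, min_separation = 0, seed = 7)
  pairs <- data.frame(donor_x = c(20, 23), donor_y = c(20, 20),
                      acceptor_x = c(68, 71), acceptor_y = c(20, 20),
                      distance = 0)
  out <- extract_traces(mv, pairs)
  expect_equal(attr(out, "contaminated"), c(TRUE, TRUE))
  # edge-clipped apertures are excluded, not returned
  pairs_edge <- data.frame(donor_x = 2, donor_y = 2, acceptor_x = 50,
                           acceptor_y = 2, distance = 0)
  out2 <- extract_traces(mv, pairs_edge)
  expect_length(out2, 0)
  expect_equal(attr(out2, "excluded"), 1L)
})

test_that("movies round-trip through TIFF and PMA containers", {
  tr <- imaging_cohort(3, n_frames = 5)
  mv <- render_movie(tr, width = 64, height = 32, seed = 8)
  tf <- tempfile(fileext = ".tif")
  pf <- tempfile(fileext = ".pma")
  on.exit(unlink(c(tf, pf)))
  write_tiff_movie(mv, tf)
  back <- read_tiff_movie(tf, dt = mv$dt)
  expect_equal(dim(back$frames), dim(mv$frames))
  expect_equal(back$frames, round(pmax(mv$frames, 0)), tolerance = 1e-6)
  # PMA stores 8-bit; rescale into range first
  sc <- 255 / max(mv$frames)
  write_pma(mv, pf, scale = sc)
  backp <- read_pma(pf, dt = mv$dt)
  expect_equal(dim(backp$frames), dim(mv$frames))
  expect_equal(backp$frames, round(pmax(mv$frames * sc, 0)),
               tolerance = 1e-6)
  # header carries the geometry
  expect_equal(backp$width, 64)
  expect_equal(backp$height, 32)
})
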