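test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(dt_s = 0), "dt_s")
  expect_error(sim_config(bleach_fraction = 1), "bleach_fraction")
  expect_error(sim_config(ca_coupled_fraction = 1.2), "ca_coupled_fraction")
  expect_error(sim_config(pause_mean_s = 2, dt_s = 5), "pause_mean_s")
  expect_error(sim_config(pause_rate_per_min = -1), "non-negative")
  expect_error(sim_config(mean_speed_um_min = NaN), "non-finite")
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_cells = 5, duration_s = 200, seed = 42)
  a <- simulate_calcium(simulate_tracks(cfg))
  b <- simulate_calcium(simulate_tracks(cfg))
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_tracks(sim_config(n_cells = 5, duration_s = 200, seed = 43))
  expect_false(identical(a$tracks[[1]]$pos_um, c2$tracks[[1]]$pos_um))
})

test_that("no pauses means no arrest; infinite persistence means straight", {
  cfg <- sim_config(n_cells = 8, duration_s = 300, pause_rate_per_min = 0, seed = 5)
  sim <- simulate_tracks(cfg)
  for (tr in sim$tracks) {
    expect_true(all(instantaneous_velocities(tr) > 2))
    expect_equal(arrest_coefficient(tr), 0)
  }
  expect_equal(nrow(sim$truth$pauses), 0)
  cfg2 <- sim_config(n_cells = 3, duration_s = 300, pause_rate_per_min = 0,
                     persistence_s = Inf, speed_cv = 0, seed = 6)
  d <- directionality_ratio_curve(simulate_tracks(cfg2)$tracks, fit = FALSE)
  expect_equal(d$curve$ratio, rep(1, nrow(d$curve)), tolerance = 1e-9)
})

test_that("ensemble arrest matches the two-state occupancy closed form", {
  cfg <- sim_config(n_cells = 500, duration_s = 600, dt_s = 5,
                    mean_speed_um_min = 11, pause_rate_per_min = 0.5,
                    pause_mean_s = 30, seed = 7)
  sim <- simulate_tracks(cfg)
  ac <- mean(vapply(sim$tracks, arrest_coefficient, numeric(1)))
  occ <- with(list(r = 0.5 / 60, m = 30), r * m / (1 + r * m))
  expect_lt(abs(ac - occ) / occ, 0.20)
  # brute-force state-sequence count agrees with the velocity-threshold route
  occ_states <- mean(unlist(sim$truth$states) == "pause")
  expect_equal(ac, occ_states, tolerance = 0.02)
})

test_that("ground-truth pauses are non-overlapping and consistent with states", {
  cfg <- sim_config(n_cells = 30, duration_s = 400, pause_rate_per_min = 1, seed = 8)
  sim <- simulate_tracks(cfg)
  pz <- sim$truth$pauses
  for (cid in unique(pz$cell_id)) {
    p <- pz[pz$cell_id == cid, ]
    p <- p[order(p$start_s), ]
    expect_true(all(p$end_s > p$start_s))
    if (nrow(p) > 1) expect_true(all(p$start_s[-1] >= p$end_s[-nrow(p)]))
    expect_equal(sum(p$duration_s),
                 sum(sim$truth$states[[cid]] == "pause") * cfg$dt_s)
  }
})

test_that("mean track speed matches speed times go-occupancy at n = 300", {
  cfg <- sim_config(n_cells = 300, duration_s = 600, dt_s = 5, seed = 9)
  sim <- simulate_tracks(cfg)
  means <- vapply(sim$tracks, function(tr) mean(instantaneous_velocities(tr)),
                  numeric(1))
  occ <- with(list(r = cfg$pause_rate_per_min / 60, m = cfg$pause_mean_s),
              r * m / (1 + r * m))
  expected <- cfg$mean_speed_um_min * (1 - occ)
  sem <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - expected), 2 * sem + 0.5 * occ)  # pause jitter adds < 0.5*occ
})

test_that("calcium traces obey the bleach closed form", {
  # bleach 25%, zero noise, no transients: raw ratio drifts x1/0.75 at end,
  # corrected ratio flat to 1e-6
  cfg <- sim_config(n_cells = 3, duration_s = 400, pause_rate_per_min = 0,
                    sparkle_rate_per_cell_min = 0, transient_amplitude = 0,
                    bleach_fraction = 0.25, trace_noise_cv = 0, seed = 10)
  sim <- simulate_calcium(simulate_tracks(cfg))
  tr <- sim$tracks[[1]]
  raw_ratio <- tr$green / tr$red
  expect_equal(raw_ratio[length(raw_ratio)] / raw_ratio[1], 1 / 0.75,
               tolerance = 1e-9)
  rt <- ratio_trace(tr$t_s, tr$green, tr$red)
  expect_lt(diff(range(rt$ratio)) / mean(rt$ratio), 1e-6)
  expect_equal(rt$norm_ratio, rep(1, length(tr$t_s)), tolerance = 1e-6)
})

test_that("zero-amplitude, zero-bleach, zero-noise gives a flat unit ratio", {
  cfg <- sim_config(n_cells = 2, duration_s = 300, pause_rate_per_min = 0,
                    sparkle_rate_per_cell_min = 0, transient_amplitude = 0,
                    bleach_fraction = 0, trace_noise_cv = 0, seed = 11)
  sim <- simulate_calcium(simulate_tracks(cfg))
  for (tr in sim$tracks) {
    rt <- ratio_trace(tr$t_s, tr$green, tr$red)
    expect_equal(rt$norm_ratio, rep(1, length(tr$t_s)), tolerance = 1e-9)
  }
})

test_that("coupled transient peaks lead the pause velocity minimum by ca_lead_s", {
  cfg <- sim_config(n_cells = 40, duration_s = 600, pause_rate_per_min = 0.6,
                    ca_coupled_fraction = 1, ca_lead_s = 5,
                    sparkle_rate_per_cell_min = 0, trace_noise_cv = 0, seed = 12)
  sim <- simulate_calcium(simulate_tracks(cfg))
  ev <- sim$truth$events
  expect_gt(nrow(ev), 10)
  for (j in seq_len(nrow(ev))) {
    tr <- sim$tracks[[which(vapply(sim$tracks, `[[`, character(1), "cell_id") ==
                            ev$cell_id[j])]]
    v <- instantaneous_velocities(tr)
    step_t <- tr$t_s[-length(tr$t_s)]
    pz <- sim$truth$pauses
    pz <- pz[pz$cell_id == ev$cell_id[j] & pz$start_s == ev$pause_start_s[j], ]
    sel <- step_t >= pz$start_s & step_t < pz$end_s
    t_min <- step_t[sel][which.min(v[sel])]
    expect_lte(abs(ev$peak_s[j] - (t_min - 5)), cfg$dt_s)
    # by construction exactly at the onset
    expect_equal(ev$peak_s[j], t_min - 5)
  }
  # every coupled event maps to exactly one pause
  cw <- ev[ev$class == "cell_wide", ]
  expect_false(any(duplicated(cw[, c("cell_id", "pause_start_s")])))
})

test_that("true peak normalized ratio equals 1 + transient_amplitude", {
  cfg <- sim_config(n_cells = 6, duration_s = 600, pause_rate_per_min = 0.4,
                    ca_coupled_fraction = 1, transient_amplitude = 0.5,
                    sparkle_rate_per_cell_min = 0, bleach_fraction = 0.25,
                    trace_noise_cv = 0, seed = 13)
  sim <- simulate_calcium(simulate_tracks(cfg))
  for (tr in sim$tracks) {
    has_early_event <- any(sim$truth$events$cell_id == tr$cell_id &
                           sim$truth$events$onset_s < 5 * cfg$dt_s)
    if (has_early_event) next  # R0 contaminated by an event at track start
    rt <- ratio_trace(tr$t_s, tr$green, tr$red)
    if (any(sim$truth$events$cell_id == tr$cell_id)) {
      expect_equal(max(rt$norm_ratio), 1.5, tolerance = 1e-6)
    }
  }
})

test_that("rendered stacks honour geometry, filters and monotonic intensity", {
  # no events, no autofluorescence, no noise: green never exceeds baseline
  r0 <- render_image_stack(size_px = c(60, 60), duration_s = 10, noise = FALSE,
                           seed = 1)
  expect_lte(max(r0$stack$green), 100)
  expect_equal(r0$stack$pixel_um, 0.65)
  expect_equal(r0$stack$dt_s, 0.5)
  # one 2 um^2 / 2 s event at 0.5 um/px: above-half-max support ~8 px x 4 frames
  ev <- data.frame(x_um = 15, y_um = 15, t_start_s = 4, duration_s = 2,
                   area_um2 = 2, amplitude = 100)
  r1 <- render_image_stack(events = ev, pixel_um = 0.5, dt_s = 0.5,
                           size_px = c(60, 60), duration_s = 10,
                           noise = FALSE, seed = 1)
  supra <- which(r1$stack$green > 100 + 50, arr.ind = TRUE)
  expect_equal(length(unique(supra[, 3])), 4)  # 4 frames
  per_frame <- table(supra[, 3])
  expect_true(all(per_frame >= 6 & per_frame <= 10))  # ~8 px
  expect_gt(sum(per_frame), 10)  # passes the >10 voxel filter
  # integrated green intensity increases monotonically with amplitude
  tot <- vapply(c(50, 100, 200), function(a) {
    ev$amplitude <- a
    r <- render_image_stack(events = ev, pixel_um = 0.5, dt_s = 0.5,
                            size_px = c(60, 60), duration_s = 10,
                            noise = FALSE, seed = 1)
    sum(as.numeric(r$stack$green))
  }, numeric(1))
  expect_true(all(diff(tot) > 0))
  # out-of-field or out-of-recording events are rejected
  expect_error(render_image_stack(events = transform(ev, x_um = 500),
                                  size_px = c(60, 60), duration_s = 10),
               "outside the field")
  expect_error(render_image_stack(events = transform(ev, t_start_s = 50),
                                  size_px = c(60, 60), duration_s = 10),
               "outside the recording")
  expect_error(render_image_stack(size_px = c(10, 10), duration_s = 5),
               "footprint")
})

test_that("rendering is deterministic and tracks paint the red channel", {
  cfg <- sim_config(n_cells = 3, dim = 2, duration_s = 20, dt_s = 0.5,
                    pause_rate_per_min = 0, seed = 14)
  sim <- simulate_tracks(cfg)
  a <- render_image_stack(tracks = sim$tracks, size_px = c(200, 200),
                          duration_s = 20, dt_s = 0.5, seed = 3)
  b <- render_image_stack(tracks = sim$tracks, size_px = c(200, 200),
                          duration_s = 20, dt_s = 0.5, seed = 3)
  expect_identical(a$stack$green, b$stack$green)
  expect_identical(a$stack$red, b$stack$red)
  expect_gt(max(a$stack$red), 300)  # cell footprints present
})
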