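# Detection fixtures are built in code: integer stacks with seeded blobs.

test_that("autofluorescence masking finds exactly the stationary blob", {
  n <- 40; nt <- 30
  frames <- replicate(nt, matrix(100L, n, n), simplify = FALSE)
  stk <- stack_from_frames(frames)
  expect_equal(sum(mask_autofluorescence(stk)$mask), 0)  # nothing to mask
  # constant bright 5x5 blob in every frame
  for (k in seq_len(nt)) frames[[k]][10:14, 20:24] <- 500L
  stk2 <- stack_from_frames(frames)
  m <- mask_autofluorescence(stk2)
  expect_equal(sum(m$mask), 25)
  expect_true(all(which(m$mask, arr.ind = TRUE)[, 1] %in% 10:14))
  expect_true(all(which(m$mask, arr.ind = TRUE)[, 2] %in% 20:24))
  expect_true(all(m$stack$green[10:14, 20:24, ] == 100L))
  # a transient present in few frames is never masked
  frames3 <- replicate(nt, matrix(100L, n, n), simplify = FALSE)
  for (k in 5:8) frames3[[k]][30:32, 5:7] <- 800L
  m3 <- mask_autofluorescence(stack_from_frames(frames3))
  expect_equal(sum(m3$mask), 0)
  expect_error(mask_autofluorescence(stack_from_frames(frames3[1:10])),
               "20 frames")
})

test_that("detection applies the voxel and duration filters", {
  n <- 40; nt <- 40
  blank <- stack_from_frames(replicate(nt, matrix(100L, n, n), simplify = FALSE))
  expect_equal(nrow(detect_transients(blank, threshold = 150)), 0)
  mk <- function(rows, cols, frames_on) {
    fr <- replicate(nt, matrix(100L, n, n), simplify = FALSE)
    for (k in frames_on) fr[[k]][rows, cols] <- 300L
    stack_from_frames(fr, pixel_um = 1, dt_s = 0.5)
  }
  # 3x3 px x 5 frames at dt 0.5: 45 voxels, 2.5 s -> exactly one event
  ev <- detect_transients(mk(10:12, 10:12, 11:15), threshold = 150)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_voxels, 45)
  expect_equal(ev$duration_s, 2.5)
  expect_equal(ev$onset_s, 5)
  # 1-frame blob (0.5 s) fails the 2 s minimum duration
  expect_equal(nrow(detect_transients(mk(10:12, 10:12, 11), threshold = 150)), 0)
  # 2x1 px x 4 frames = 8 voxels fails the >10 voxel filter despite 2 s
  expect_equal(nrow(detect_transients(mk(10:11, 10, 11:14), threshold = 150)), 0)
  # 3x1 px x 4 frames = 12 voxels and 2.0 s passes both (inclusive extent)
  ev2 <- detect_transients(mk(10:12, 10, 11:14), threshold = 150)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$duration_s, 2.0)
  # exactly 10 voxels is rejected (strictly greater than 10 required)
  fr <- replicate(nt, matrix(100L, n, n), simplify = FALSE)
  for (k in 11:15) fr[[k]][20:21, 20] <- 300L  # 2 voxels x 5 frames
  expect_equal(nrow(detect_transients(stack_from_frames(fr, dt_s = 0.5),
                                      threshold = 150)), 0)
  expect_warning(detect_transients(blank, threshold = 50), "background")
})

test_that("26-connectivity joins diagonal spatiotemporal neighbours", {
  n <- 20; nt <- 20
  fr <- replicate(nt, matrix(0L, n, n), simplify = FALSE)
  # a staircase: each frame shifts the 2x2 blob one pixel diagonally
  for (k in 5:12) fr[[k]][(k):(k + 1), (k):(k + 1)] <- 200L
  ev <- detect_transients(stack_from_frames(fr, dt_s = 1), threshold = 100,
                          min_duration_s = 2)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_voxels, 8 * 4)
})

test_that("ellipsoid metrics recover a uniform disc and symmetry", {
  for (r_px in c(3, 5, 8)) {
    img <- raster_disc(40, 20, 20, r_px)
    comp <- which(img > 0, arr.ind = TRUE)
    cm <- data.frame(x = comp[, 2] - 1, y = comp[, 1] - 1, t = 0L,
                     intensity = 100)
    m <- ellipsoid_metrics(cm, pixel_um = 1, dt_s = 0.5)
    expect_equal(m$area_um2, pi * r_px^2, tolerance = 0.10)
    expect_equal(m$x_diameter_um, m$y_diameter_um, tolerance = 0.02)
    expect_equal(m$centroid_x_um, 20, tolerance = 0.01)
    expect_equal(m$duration_s, 0.5)  # single-frame component lasts one dt
  }
  # degenerate single voxel floors diameters at one voxel
  m1 <- ellipsoid_metrics(data.frame(x = 3, y = 4, t = 2, intensity = 10),
                          pixel_um = 0.65, dt_s = 0.5)
  expect_equal(m1$x_diameter_um, 0.65)
  expect_equal(m1$area_um2, pi * 0.325^2)
})

test_that("classification splits sparkles from cell-wide at the area threshold", {
  expect_equal(classify_event(2), "sparkle")
  expect_equal(classify_event(50), "cell_wide")
  expect_equal(classify_event(20), "cell_wide")  # boundary inclusive
  # raising the threshold never converts sparkle -> cell_wide
  for (a in c(1, 5, 19, 25, 60)) {
    k1 <- classify_event(a, 20); k2 <- classify_event(a, 30)
    expect_false(k1 == "sparkle" && k2 == "cell_wide")
  }
})

test_that("event statistics normalize by green SD and count classes", {
  es0 <- event_statistics(detect_transients(
    stack_from_frames(replicate(25, matrix(100L, 20, 20), simplify = FALSE)),
    threshold = 200))
  expect_equal(es0$n_events, 0)
  expect_equal(sum(es0$counts_by_class), 0)
  n <- 40; nt <- 40
  fr <- replicate(nt, matrix(100L, n, n), simplify = FALSE)
  for (k in 11:15) fr[[k]][10:12, 10:12] <- 300L
  stk <- stack_from_frames(fr, dt_s = 0.5)
  ev <- detect_transients(stk, threshold = 150)
  es <- event_statistics(ev)
  expect_equal(es$n_events, 1)
  # doubling the gain leaves the SD-normalized intensity unchanged
  stk2 <- image_stack(stk$green * 2L, stk$red, stk$pixel_um, stk$dt_s)
  ev2 <- detect_transients(stk2, threshold = 300)
  expect_equal(ev2$integrated_norm_intensity, ev$integrated_norm_intensity,
               tolerance = 1e-9)
  expect_equal(2 * ev$integrated_intensity, ev2$integrated_intensity)
})

test_that("event count is invariant to adding masked autofluorescent bodies", {
  ev <- data.frame(x_um = c(20, 60, 40), y_um = c(30, 60, 80),
                   t_start_s = c(5, 15, 25), duration_s = 2,
                   area_um2 = 2, amplitude = 100)
  base <- render_image_stack(events = ev, pixel_um = 0.5, dt_s = 0.5,
                             size_px = c(200, 200), duration_s = 40,
                             n_autofluorescent = 0, seed = 31)
  with_af <- render_image_stack(events = ev, pixel_um = 0.5, dt_s = 0.5,
                                size_px = c(200, 200), duration_s = 40,
                                n_autofluorescent = 6, seed = 31)
  n_base <- nrow(detect_transients(mask_autofluorescence(base$stack)$stack))
  n_af <- nrow(detect_transients(mask_autofluorescence(with_af$stack)$stack))
  expect_equal(n_base, 3)
  expect_equal(n_af, n_base)
})

test_that("no returned event violates the filters on noisy rendered data", {
  ev <- data.frame(x_um = c(25, 75), y_um = c(25, 75), t_start_s = c(5, 12),
                   duration_s = c(2, 6), area_um2 = c(2, 40), amplitude = 100)
  r <- render_image_stack(events = ev, pixel_um = 0.5, dt_s = 0.5,
                          size_px = c(220, 220), duration_s = 30, seed = 32)
  det <- detect_transients(mask_autofluorescence(r$stack)$stack)
  expect_true(all(det$n_voxels > 10))
  expect_true(all(det$duration_s >= 2))
  expect_equal(sort(det$klass), c("cell_wide", "sparkle"))
})
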