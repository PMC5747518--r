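test_that("instantaneous velocities convert displacements to um/min", {
  # 1 um in 12 s = 5 um/min
  tr <- track_from_points(rbind(c(0, 0, 0), c(1, 0, 0)), dt_s = 12)
  expect_equal(instantaneous_velocities(tr), 5.0)
  # 3-4-5 triangle: 5 um in 30 s = 10 um/min
  tr2 <- track_from_points(rbind(c(0, 0), c(3, 4)), dt_s = 30)
  expect_equal(instantaneous_velocities(tr2), 10.0)
  # stationary
  tr3 <- track_from_points(matrix(2, 5, 2), dt_s = 10)
  expect_equal(instantaneous_velocities(tr3), rep(0, 4))
  # 3D uses all dimensions
  tr4 <- track_from_points(rbind(c(0, 0, 0), c(1, 2, 2)), dt_s = 30)
  expect_equal(instantaneous_velocities(tr4), 6.0)
})

test_that("arrest coefficient counts strictly sub-threshold steps", {
  v <- c(1, 3, 1, 5, 9, 1, 8, 8, 8, 8)
  expect_equal(arrest_coefficient(track_from_speeds(v)), 0.3)
  expect_equal(arrest_coefficient(track_from_speeds(rep(0, 6))), 1.0)
  expect_equal(arrest_coefficient(track_from_speeds(rep(12, 6))), 0.0)
  # boundary: exactly 2 um/min is not arrested (strict <)
  expect_equal(arrest_coefficient(track_from_speeds(c(2, 2, 5, 5))), 0.0)
  expect_error(arrest_coefficient(track_from_speeds(v), threshold_um_min = 0),
               "positive")
})

test_that("arrest coefficient is non-decreasing in the threshold", {
  set.seed(11)
  for (rep in 1:5) {
    tr <- track_from_speeds(runif(50, 0, 15))
    ac <- vapply(c(0.5, 1, 2, 4, 8, 16), function(th)
      arrest_coefficient(tr, th), numeric(1))
    expect_true(all(diff(ac) >= 0))
  }
})

test_that("pause segments are maximal sub-threshold runs times dt", {
  expect_equal(pause_segments(track_from_speeds(c(5, 8, 7))), numeric(0))
  expect_equal(pause_segments(track_from_speeds(c(1, 1, 1), dt_s = 20)), 60)
  expect_equal(pause_segments(track_from_speeds(c(5, 1, 5, 1, 1, 5), dt_s = 10)),
               c(10, 20))
})

test_that("total pause time equals arrest coefficient times step time", {
  set.seed(12)
  for (rep in 1:10) {
    dt <- sample(c(5, 10, 20), 1)
    tr <- track_from_speeds(runif(80, 0, 6), dt_s = dt)
    expect_equal(sum(pause_segments(tr)),
                 arrest_coefficient(tr) * 80 * dt)
  }
})

test_that("coefficient of variation is the percent SD/mean and scale free", {
  expect_equal(coefficient_of_variation(track_from_speeds(c(5, 15))),
               100 * sqrt(50) / 10)  # 70.71%
  expect_equal(coefficient_of_variation(track_from_speeds(rep(7, 9))), 0)
  set.seed(13)
  v <- runif(30, 1, 20)
  for (k in c(0.1, 3)) {
    expect_equal(coefficient_of_variation(track_from_speeds(k * v)),
                 coefficient_of_variation(track_from_speeds(v)))
  }
  expect_error(coefficient_of_variation(track_from_speeds(rep(0, 5))),
               "undefined")
})

test_that("turn angles follow the dot-product geometry", {
  fwd <- track_from_points(rbind(c(0, 0), c(1, 0), c(2, 0)))
  expect_equal(turn_angles(fwd), 0)
  rev <- track_from_points(rbind(c(0, 0), c(1, 0), c(0, 0)))
  expect_equal(turn_angles(rev), 180)
  right <- track_from_points(rbind(c(0, 0), c(1, 0), c(1, 1)))
  expect_equal(turn_angles(right), 90)
  # sub-threshold steps are skipped and the angle spans the gap
  jitter <- track_from_points(rbind(c(0, 0), c(1, 0), c(1.1, 0), c(1.1, 1)))
  expect_equal(turn_angles(jitter, min_step_um = 0.5), 90)
})

test_that("directionality ratio is 1 for straight and 0 at a return", {
  straight <- track_from_points(cbind(0:10, 0))
  d <- directionality_ratio_curve(track_set(list(straight)), fit = FALSE)
  expect_equal(d$curve$ratio, rep(1, 10))
  back <- track_from_points(rbind(c(0, 0), c(5, 0), c(0, 0)))
  d2 <- directionality_ratio_curve(track_set(list(back)), fit = FALSE)
  expect_equal(d2$curve$ratio, c(1, 0))
  expect_true(all(d$curve$ratio > 0 & d$curve$ratio <= 1))
})

test_that("MSD matches the brute-force double loop exactly", {
  set.seed(14)
  trs <- lapply(1:5, function(i) {
    track_from_points(matrix(rnorm(20 * 3, sd = 4), 20, 3), cell_id = i)
  })
  m <- msd_curve(track_set(trs))
  oracle <- rowMeans(vapply(trs, function(tr) brute_msd(tr$pos_um),
                            numeric(19)))
  expect_equal(m$curve$msd_um2, oracle, tolerance = 1e-12)
})

test_that("ballistic MSD is (v tau)^2 with log-log slope 2", {
  v <- 9  # um/min
  tr <- track_from_speeds(rep(v, 40), dt_s = 15)
  m <- msd_curve(track_set(list(tr)))
  expect_equal(m$curve$msd_um2, (v * m$curve$lag_min)^2, tolerance = 1e-10)
  slope <- stats::coef(stats::lm(log(msd_um2) ~ log(lag_min), m$curve))[[2]]
  expect_equal(slope, 2, tolerance = 0.01)
  # stationary tracks have MSD identically 0
  still <- track_from_points(matrix(1, 20, 2))
  expect_equal(msd_curve(track_set(list(still)))$curve$msd_um2, rep(0, 19))
})

test_that("mixed frame intervals are rejected for MSD", {
  a <- track_from_speeds(rep(5, 10), dt_s = 10)
  b <- track_from_speeds(rep(5, 10), dt_s = 20)
  expect_error(msd_curve(track_set(list(a, b))), "frame interval")
})

test_that("velocity histogram fractions sum to 1 and fraction_below is strict", {
  mk <- function(v) track_from_speeds(rep(v, 10))
  ts <- track_set(lapply(c(5, 6, 8, 9), mk))
  h <- velocity_histogram(ts)
  expect_equal(sum(h$fraction), 1)
  expect_equal(h$fraction_below, 0.5)
  ts2 <- track_set(lapply(rep(12, 4), mk))
  expect_equal(velocity_histogram(ts2)$fraction_below, 0)
  # boundary: exactly 7 um/min is not below 7
  ts3 <- track_set(lapply(c(7, 7, 3), mk))
  expect_equal(velocity_histogram(ts3)$fraction_below, 1 / 3)
})

test_that("statistics are invariant under rigid rotation and translation", {
  set.seed(15)
  pts <- matrix(rnorm(30, sd = 5), 15, 2)
  th <- 0.7
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts2 <- pts %*% Rm + matrix(c(100, -40), 15, 2, byrow = TRUE)
  a <- track_from_points(pts); b <- track_from_points(pts2)
  expect_equal(instantaneous_velocities(a), instantaneous_velocities(b))
  expect_equal(turn_angles(a), turn_angles(b))
  expect_equal(arrest_coefficient(a), arrest_coefficient(b))
  expect_equal(msd_curve(track_set(list(a)))$curve$msd_um2,
               msd_curve(track_set(list(b)))$curve$msd_um2)
  expect_equal(directionality_ratio_curve(track_set(list(a)), fit = FALSE)$curve$ratio,
               directionality_ratio_curve(track_set(list(b)), fit = FALSE)$curve$ratio)
})

test_that("motility summary keeps min <= mean <= max and bounded arrest", {
  set.seed(16)
  for (rep in 1:5) {
    tr <- track_from_speeds(runif(40, 0, 20))
    s <- motility_summary(tr)
    expect_lte(s$min_inst_velocity_um_min, s$mean_velocity_um_min)
    expect_lte(s$mean_velocity_um_min, s$max_inst_velocity_um_min)
    expect_gte(s$arrest_coefficient, 0)
    expect_lte(s$arrest_coefficient, 1)
    expect_gte(s$cov_percent, 0)
  }
})
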