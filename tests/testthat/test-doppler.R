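test_that("volumetric flow is velocity times lumen area", {
  time <- seq(0, 1, by = 0.01)
  w <- velocity_waveform(time, rep(10, length(time)), S = 0.30, "artery")
  fl <- volumetric_flow(w)
  expect_equal(unique(fl$flow_cm3_s), 3.0)
  wz <- velocity_waveform(time, rep(0, length(time)), S = 0.38, "vein")
  expect_true(all(volumetric_flow(wz)$flow_cm3_s == 0))
  expect_error(velocity_waveform(c(0, 0.2, 0.1), c(1, 1, 1), 0.3), "increasing")
  expect_error(velocity_waveform(c(0, 0.1, 0.3), c(1, 1, 1), 0.3), "uniform")
  expect_error(velocity_waveform(time, rep(-1, length(time)), 0.3, "artery"),
               "non-negative")
})

test_that("half-sine systolic pulse integrates to its closed-form volume", {
  # peak 40 cm/s over 0.3 s through 0.30 cm^2: cycle volume (2/pi)*40*0.3*0.30
  time <- seq(0, 1, by = 1 / 500)
  v <- half_sine_velocity(time, peak = 40, Ts = 0.3)
  w <- velocity_waveform(time, v, S = 0.30, "artery")
  fl <- volumetric_flow(w)
  expect_equal(max(fl$flow_cm3_s), 12, tolerance = 1e-4)
  vol <- pracma::trapz(fl$time_s, fl$flow_cm3_s)
  expect_equal(vol, 2 / pi * 40 * 0.3 * 0.30, tolerance = 1e-3)
})

test_that("blood volume change integrates the arterio-venous difference", {
  time <- seq(0, 1, by = 1 / 500)
  v <- half_sine_velocity(time, peak = 40, Ts = 0.3)
  art <- volumetric_flow(velocity_waveform(time, v, S = 0.30, "artery"))
  # balanced flows: Q identically zero
  vein_same <- art
  attr(vein_same, "role") <- "vein"
  Q0 <- blood_volume_change(art, vein_same)
  expect_true(all(Q0$Q_cm3 == 0))
  # constant venous outflow returning the cycle volume: Q(T) = 0 and the
  # peak sits where the flow curves cross
  vol <- 2 / pi * 40 * 0.3 * 0.30
  vein <- volumetric_flow(velocity_waveform(time, rep(vol / 0.30, length(time)),
                                            S = 0.30, "vein"))
  Q <- blood_volume_change(art, vein)
  expect_equal(Q$Q_cm3[1], 0)
  # Q(T) returns to zero up to trapezoid-rule error on the half-sine
  expect_equal(Q$Q_cm3[length(time)], 0, tolerance = 5e-4)
  crossings <- which(diff(sign(art$flow_cm3_s - vein$flow_cm3_s)) != 0)
  expect_true(abs(which.max(Q$Q_cm3) - crossings[length(crossings)]) <= 1)
  # zero outflow: Q is the running integral (a ramp for constant inflow)
  artc <- volumetric_flow(velocity_waveform(time, rep(5, length(time)),
                                            S = 0.30, "artery"))
  veinz <- volumetric_flow(velocity_waveform(time, rep(0, length(time)),
                                             S = 0.38, "vein"))
  Qr <- blood_volume_change(artc, veinz)
  expect_equal(Qr$Q_cm3, 1.5 * time, tolerance = 1e-9)
})

test_that("cycle volume converges at second order in the time step", {
  exact <- 2 / pi * 40 * 0.35 * 0.30
  qT <- function(rate) {
    time <- seq(0, 1, by = 1 / rate)
    art <- volumetric_flow(velocity_waveform(
      time, half_sine_velocity(time, 40, 0.35), S = 0.30, "artery"))
    veinz <- volumetric_flow(velocity_waveform(time, rep(0, length(time)),
                                               S = 0.38, "vein"))
    Q <- blood_volume_change(art, veinz)
    Q$Q_cm3[length(time)]
  }
  e1 <- abs(qT(100) - exact)
  e2 <- abs(qT(200) - exact)
  e3 <- abs(qT(400) - exact)
  expect_equal(e1 / e2, 4, tolerance = 0.15)
  expect_equal(e2 / e3, 4, tolerance = 0.15)
})

test_that("alignment resamples both series onto the acquisition grid", {
  t1 <- seq(0, 1, by = 1 / 100)
  t2 <- seq(0, 1, by = 1 / 250)
  x <- data.frame(t = t1, v = sin(2 * pi * t1))
  y <- data.frame(t = t2, v = cos(2 * pi * t2))
  al <- align_and_resample(x, y, rate = 500)
  expect_equal(length(al$time), 501)
  expect_equal(length(al$x), length(al$y))
  # identical grids pass through unchanged values
  al2 <- align_and_resample(x, x, rate = 100)
  expect_equal(al2$x, x$v, tolerance = 1e-12)
  expect_error(align_and_resample(x, data.frame(t = t1 + 5, v = t1)),
               "overlap")
})

test_that("correlation behaves for exact, inverted and noisy relations", {
  time <- seq(0, 1, by = 1 / 500)
  v <- half_sine_velocity(time, 40, 0.35, floor = 5)
  art <- volumetric_flow(velocity_waveform(time, v, S = 0.30, "artery"))
  veinc <- volumetric_flow(velocity_waveform(
    time, rep(mean(v) * 0.30 / 0.38, length(time)), S = 0.38, "vein"))
  Q <- blood_volume_change(art, veinc)
  dz1 <- data.frame(time_s = Q$time_s, dz = 3 * Q$Q_cm3)
  expect_equal(pearson_correlation(Q, dz1), 1.0)
  dzneg <- data.frame(time_s = Q$time_s, dz = -Q$Q_cm3)
  expect_equal(pearson_correlation(Q, dzneg), -1.0)
  dz0 <- data.frame(time_s = Q$time_s, dz = rep(1, nrow(Q)))
  expect_error(pearson_correlation(Q, dz0), "variance")
  # affine invariance
  dz2 <- data.frame(time_s = Q$time_s, dz = 5 - 2 * dz1$dz)
  expect_equal(abs(pearson_correlation(Q, dz2)), 1.0)
})

test_that("noise at 20% of signal sd attenuates r to about 0.98", {
  # attenuation 1 / sqrt(1 + 0.2^2) = 0.981 at n = 500
  time <- seq(0, 1, length.out = 500)
  Q <- structure(data.frame(time_s = time,
                            Q_cm3 = 2 * pmin(time, 1 - time)),
                 class = c("blood_volume_curve", "data.frame"))
  dz <- synth_impedance_from_volume(Q, gain = 1,
                                    noise_sd = 0.2 * stats::sd(Q$Q_cm3),
                                    seed = 7)
  r <- pearson_correlation(Q, dz)
  expect_gt(r, 0.96)
  expect_lt(r, 0.995)
})
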