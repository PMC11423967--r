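test_that("butterworth_lowpass has unit DC gain and the analytic rolloff", {
  rate <- 90
  const <- uniform_series(rep(3.7, 900), rate)
  out <- butterworth_lowpass(const, cutoff = 10, order = 2)
  expect_equal(out$values, const$values, tolerance = 1e-9)
  zero <- uniform_series(numeric(900), rate)
  expect_equal(butterworth_lowpass(zero, 10)$values, numeric(900))
  # 30 Hz sine through a 10 Hz order-2 filter, applied forward-backward:
  # expected amplitude |H(30)|^2 with |H(f)| = 1/sqrt(1 + (f/fc)^(2n))
  tt <- (0:(20 * rate - 1)) / rate
  s <- uniform_series(sin(2 * pi * 30 * tt), rate)
  y <- butterworth_lowpass(s, 10, 2)$values
  interior <- seq(5 * rate, 15 * rate)
  got_amp <- sqrt(2 * mean(y[interior]^2))
  expect_equal(got_amp, (1 / sqrt(1 + (30 / 10)^4))^2, tolerance = 0.05)
  expect_error(butterworth_lowpass(s, 45), "Nyquist")
  expect_error(butterworth_lowpass(s, 50), "Nyquist")
})

test_that("heavy oversmoothing is idempotent within 1% RMS", {
  set.seed(5)
  rate <- 90
  s <- uniform_series(cumsum(rnorm(1800)), rate)
  once <- butterworth_lowpass(s, 1, 2)
  twice <- butterworth_lowpass(once, 20, 2)   # passband limit
  rel <- sqrt(mean((twice$values - once$values)^2)) /
    sqrt(mean(once$values^2))
  expect_lt(rel, 0.01)
})

test_that("speed recovers static, linear and circular motion", {
  rate <- 90
  static <- marker_trajectory("m", matrix(2, 30, 3), rate)
  expect_equal(speed(static)$values, numeric(30))
  tt <- (0:899) / rate
  lin <- marker_trajectory("m", cbind(2 * tt, 0 * tt, 0 * tt), rate)
  v <- speed(lin)$values
  expect_equal(v[2:899], rep(2, 898), tolerance = 1e-6)
  # circle r = 1 at angular rate 2*pi/3: tangential speed r*omega
  om <- 2 * pi / 3
  circ <- marker_trajectory("m", cbind(cos(om * tt), sin(om * tt), 0 * tt),
                            rate)
  vc <- speed(circ)$values[10:890]
  expect_equal(vc, rep(om, length(vc)), tolerance = om * 1e-3)
  expect_error(speed(marker_trajectory("m", matrix(0, 2, 3), rate)),
               "3 frames")
})

test_that("speed matches an independent finite-difference oracle", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 50
    pos <- matrix(rnorm(n * 3), n, 3)
    tr <- marker_trajectory("m", pos, 90)
    got <- speed(tr)$values
    # oracle: literal differences
    want <- numeric(n)
    for (i in 2:(n - 1))
      want[i] <- sqrt(sum(((pos[i + 1, ] - pos[i - 1, ]) * 45)^2))
    want[1] <- sqrt(sum(((pos[2, ] - pos[1, ]) * 90)^2))
    want[n] <- sqrt(sum(((pos[n, ] - pos[n - 1, ]) * 90)^2))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("sum_wrist_speeds is an elementwise sum with checks", {
  a <- uniform_series(c(1, 2, 3), 90, label = "head_speed")
  b <- uniform_series(c(4, 5, 6), 90, label = "head_speed")
  z <- uniform_series(c(0, 0, 0), 90, label = "head_speed")
  expect_equal(sum_wrist_speeds(z, b)$values, b$values)
  expect_equal(sum_wrist_speeds(a, a)$values, 2 * a$values)
  expect_identical(sum_wrist_speeds(a, b)$label, "wrist_speed")
  expect_error(sum_wrist_speeds(a, uniform_series(1:2, 90)), "length")
  expect_error(sum_wrist_speeds(a, uniform_series(1:3, 45)), "rate")
})

test_that("amplitude_envelope demodulates pure and AM tones", {
  rate <- 8000
  tt <- (0:(rate - 1)) / rate
  silence <- uniform_series(numeric(rate), rate)
  expect_equal(amplitude_envelope(silence)$values,
               numeric(length(amplitude_envelope(silence)$values)))
  tone <- uniform_series(sin(2 * pi * 220 * tt), rate)
  env <- amplitude_envelope(tone, smooth_cutoff = 12, target_rate = 90)
  expect_identical(env$label, "voice_env")
  expect_equal(env$rate, 90)
  interior <- 20:70
  expect_equal(env$values[interior], rep(1, length(interior)),
               tolerance = 0.02)
  # AM at 3 Hz, depth 0.5: envelope must track the modulator
  modu <- 1 + 0.5 * sin(2 * pi * 3 * tt)
  am <- uniform_series(modu * sin(2 * pi * 220 * tt), rate)
  env2 <- amplitude_envelope(am, 12, 90)
  want <- 1 + 0.5 * sin(2 * pi * 3 * (seq_along(env2$values) - 1) / 90)
  int2 <- 10:80
  expect_gt(stats::cor(env2$values[int2], want[int2]), 0.99)
  expect_error(amplitude_envelope(tone, smooth_cutoff = 5000), "rate")
  expect_error(amplitude_envelope(tone, target_rate = 9000), "target_rate")
})

test_that("resample preserves duration and waveform", {
  rate <- 1000
  tt <- (0:(10 * rate - 1)) / rate
  s <- uniform_series(sin(2 * pi * 1 * tt), rate)
  expect_identical(resample(s, 1000), s)
  r <- resample(s, 90)
  expect_equal(r$rate, 90)
  expect_lt(abs(duration(r) - duration(s)), 1 / 90 + 1e-9)
  want <- sin(2 * pi * (seq_along(r$values) - 1) / 90)
  expect_gt(stats::cor(r$values, want), 0.999)
})

test_that("build_dyad_recording yields six aligned non-negative series", {
  set.seed(21)
  rate <- 90
  n <- 10 * rate
  tt <- (0:(n - 1)) / rate
  mk_traj <- function() marker_trajectory(
    "m", cbind(cumsum(rnorm(n, sd = 0.01)), cumsum(rnorm(n, sd = 0.01)),
               cumsum(rnorm(n, sd = 0.01))), rate)
  mk_part <- function(short = 0) {
    na <- 8000 * (10 - short)
    list(head = mk_traj(), wrist_left = mk_traj(), wrist_right = mk_traj(),
         audio = uniform_series(sin(2 * pi * 220 * (0:(na - 1)) / 8000),
                                8000))
  }
  rec <- build_dyad_recording("s1", mk_part(), mk_part())
  expect_s3_class(rec, "dyad_recording")
  expect_equal(rec$rate, 90)
  for (p in c("A", "B")) for (m in c("head", "wrist", "voice")) {
    s <- get_series(rec, p, m)
    expect_true(all(is.finite(s$values)))
    expect_true(all(s$values >= 0))
    expect_equal(length(s$values), rec$n)
  }
  # one participant's audio 1 s shorter: everything trimmed to 9 s
  rec2 <- build_dyad_recording("s2", mk_part(), mk_part(short = 1))
  expect_equal(rec2$n / rec2$rate, 9, tolerance = 2 / 90)
  # missing wrist joint propagates as an error
  bad <- mk_part(); bad$wrist_left <- NULL
  expect_error(build_dyad_recording("s3", bad, mk_part()))
})
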