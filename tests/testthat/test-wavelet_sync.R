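# Wavelet tests run on a reduced grid (fewer voices, narrower period range)
# to stay fast; the mathematical identities do not depend on grid density.

wv_rate <- 90
wv_grid <- scale_grid(0.25, 16, 8)
wv_tt <- function(n) (0:(n - 1)) / wv_rate

test_that("scale_grid is geometric and validated", {
  g <- scale_grid(0.125, 32, 16)
  ratios <- g$periods[-1] / g$periods[-length(g$periods)]
  expect_lt(max(abs(ratios - 2^(1 / 16))), 1e-12)
  expect_gte(min(g$periods), 0.125)
  expect_lte(max(g$periods), 32 * (1 + 1e-12))
  expect_error(scale_grid(2, 1), "min_period")
})

test_that("default_bands returns the 23 contiguous conversational bands", {
  b <- default_bands()
  expect_equal(nrow(b), 23)
  expect_equal(c(b$lo_s[1], b$hi_s[1]), c(0.125, 0.25))
  expect_equal(c(b$lo_s[23], b$hi_s[23]), c(28, 30))
  expect_equal(b$lo_s[-1], b$hi_s[-23])   # contiguous over (0.125, 30]
})

test_that("cwt_morlet is linear, kills constants, and checks lengths", {
  set.seed(41)
  n <- 60 * wv_rate
  x <- uniform_series(rnorm(n), wv_rate)
  const <- uniform_series(rep(2.5, n), wv_rate)
  wc <- cwt_morlet(const, wv_grid)
  expect_lt(max(Mod(wc$coeffs)), 1e-9)
  w1 <- cwt_morlet(x, wv_grid)
  a <- 3.7
  w2 <- cwt_morlet(uniform_series(a * x$values, wv_rate), wv_grid)
  expect_equal(w2$coeffs, a * w1$coeffs, tolerance = 1e-10)
  expect_error(cwt_morlet(uniform_series(rnorm(200), wv_rate), wv_grid),
               "too short")
  expect_error(cwt_morlet(x, wv_grid, omega0 = 3), "omega0")
})

test_that("CWT power of a 2 s periodic signal peaks at 0.5 Hz", {
  n <- 120 * wv_rate
  s <- uniform_series(sin(2 * pi * wv_tt(n) / 2), wv_rate)
  w <- cwt_morlet(s, wv_grid)
  pow <- Mod(w$coeffs)^2
  valid <- outer(w$coi, w$periods, `>`)
  pow[!valid] <- NA
  prof <- colMeans(pow, na.rm = TRUE)
  expect_equal(w$periods[which.max(prof)],
               w$periods[which.min(abs(w$periods - 2))])
})

test_that("cross_wavelet of a signal with itself and its negation", {
  set.seed(43)
  n <- 60 * wv_rate
  a <- cwt_morlet(uniform_series(rnorm(n), wv_rate), wv_grid)
  xs <- cross_wavelet(a, a)
  expect_lt(max(abs(Im(xs$cross))), 1e-12 * max(Mod(xs$cross)))
  expect_equal(Re(xs$cross), Mod(a$coeffs)^2, tolerance = 1e-12)
  neg <- a; neg$coeffs <- -a$coeffs
  xn <- cross_wavelet(a, neg)
  ang <- Arg(xn$cross[Mod(xn$cross) > 1e-6])
  expect_true(all(abs(abs(ang) - pi) < 1e-9))
  b <- cwt_morlet(uniform_series(rnorm(2048), wv_rate),
                  scale_grid(0.25, 8, 8))
  expect_error(cross_wavelet(a, b), "share")
})

test_that("coherence identities: self, affine copy, bounds, symmetry", {
  set.seed(44)
  n <- 60 * wv_rate
  s <- uniform_series(cumsum(rnorm(n)), wv_rate)
  wa <- cwt_morlet(s, wv_grid)
  coh <- wavelet_coherence(wa, wa)
  valid <- outer(coh$coi, coh$periods, `>`)
  expect_equal(coh$values[valid], rep(1, sum(valid)), tolerance = 1e-9)
  # affine rescaling is invisible after mean removal
  wb <- cwt_morlet(uniform_series(3 * s$values + 5, wv_rate), wv_grid)
  cohb <- wavelet_coherence(wa, wb)
  expect_equal(cohb$values[valid], rep(1, sum(valid)), tolerance = 1e-9)
  # bounds and exchange symmetry on independent signals
  wo <- cwt_morlet(uniform_series(cumsum(rnorm(n)), wv_rate), wv_grid)
  c1 <- wavelet_coherence(wa, wo)
  c2 <- wavelet_coherence(wo, wa)
  expect_true(all(c1$values >= 0 & c1$values <= 1, na.rm = TRUE))
  expect_equal(c1$values, c2$values, tolerance = 1e-9)
})

test_that("relative phase: identity, inversion, lag sign and antisymmetry", {
  n <- 120 * wv_rate
  base <- sin(2 * pi * wv_tt(n) / 4)
  wa <- cwt_morlet(uniform_series(base, wv_rate), wv_grid)
  ph_self <- relative_phase(wa, wa)
  j <- which.min(abs(ph_self$periods - 4))
  valid <- outer(ph_self$coi, ph_self$periods, `>`)
  expect_lt(max(abs(ph_self$values[valid])), 0.5)
  # sign-inverted copy: +-180
  wn <- cwt_morlet(uniform_series(-base, wv_rate), wv_grid)
  ph_anti <- relative_phase(wa, wn)
  expect_equal(mean(abs(ph_anti$values[valid[, j], j])), 180,
               tolerance = 0.5)
  # quarter-period delay of the second series: first leads by +90
  del <- sin(2 * pi * (wv_tt(n) - 1) / 4)
  wd <- cwt_morlet(uniform_series(del, wv_rate), wv_grid)
  ph <- relative_phase(wa, wd)
  expect_equal(mean(ph$values[valid[, j], j]), 90, tolerance = 2)
  ph_swap <- relative_phase(wd, wa)
  expect_equal(ph_swap$values[valid], -ph$values[valid], tolerance = 1e-6)
})

test_that("imposed narrowband lags are recovered within 5 degrees", {
  # band-limited coupling at 2-4 s with lags across the circle; average
  # recovery error checked over multiple seeds per lag
  lags <- c(-135, -90, -45, 0, 45, 90, 135, 180)
  n <- 60 * wv_rate
  grid <- scale_grid(1, 8, 8)
  bands <- timescale_bands(2, 4)
  for (lag in lags) {
    errs <- vapply(1:5, function(sd) {
      set.seed(1000 + sd)
      drv <- pink_noise(n, wv_rate)
      comp <- dyadsync:::coupled_component(drv, wv_rate, 2, 4, lag)
      tgt <- 0.9 * comp + sqrt(1 - 0.81) * pink_noise(n, wv_rate)
      wa <- cwt_morlet(uniform_series(tgt, wv_rate), grid)
      wb <- cwt_morlet(uniform_series(drv, wv_rate), grid)
      m <- xwt_maps(wa, wb)
      bs <- band_average(m$coherence, m$phase, bands)
      wrap_deg(bs$circ_mean_phase_deg - lag)
    }, numeric(1))
    cm <- circular_mean(errs)
    expect_lt(abs(cm$mean_deg), 5)
  }
})

test_that("band_average equals the literal-loop recount oracle", {
  set.seed(46)
  n <- 40 * wv_rate
  g <- scale_grid(0.5, 8, 6)
  wa <- cwt_morlet(uniform_series(cumsum(rnorm(n)), wv_rate), g)
  wb <- cwt_morlet(uniform_series(cumsum(rnorm(n)), wv_rate), g)
  m <- xwt_maps(wa, wb)
  bands <- timescale_bands(c(0.5, 1, 2, 4), c(1, 2, 4, 8))
  for (use_coi in c(TRUE, FALSE)) {
    got <- band_average(m$coherence, m$phase, bands, use_coi = use_coi)
    want <- oracle_band_average(m$coherence, m$phase, bands,
                                use_coi = use_coi)
    expect_equal(got$mean_coherence, want$mean_coherence)
    expect_equal(got$circ_mean_phase_deg, want$circ_mean_phase_deg,
                 tolerance = 1e-9)
    expect_equal(got$n_valid_bins, want$n_valid_bins)
  }
  # constant maps: every band (1, 0)
  cohc <- m$coherence; cohc$values[] <- 1
  phc <- m$phase; phc$values[] <- 0
  flat <- band_average(cohc, phc, bands)
  expect_true(all(flat$mean_coherence == 1))
  expect_true(all(flat$circ_mean_phase_deg == 0))
  # band with no grid support is missing, not zero
  far <- band_average(m$coherence, m$phase, timescale_bands(20, 30))
  expect_true(is.na(far$mean_coherence))
  expect_equal(far$n_valid_bins, 0L)
})

test_that("noise coherence sits on a stable chance floor matching shuffles", {
  # mean out-of-COI coherence of independent noise pairs is well inside
  # (0, 0.5) and indistinguishable from the segment-shuffle null
  set.seed(47)
  g <- scale_grid(0.5, 4, 6)
  bands <- timescale_bands(1, 4)
  n <- 45 * wv_rate
  floor_vals <- c(); shuf_vals <- c()
  for (k in 1:12) {
    a <- uniform_series(pink_noise(n, wv_rate), wv_rate)
    b <- uniform_series(pink_noise(n, wv_rate), wv_rate)
    wa <- cwt_morlet(a, g)
    m <- xwt_maps(wa, cwt_morlet(b, g))
    floor_vals <- c(floor_vals,
                    band_average(m$coherence, m$phase, bands)$mean_coherence)
    sh <- segment_shuffle(b, 0.2, rng_seed = 7000 + k)
    ms <- xwt_maps(wa, cwt_morlet(sh, g))
    shuf_vals <- c(shuf_vals,
                   band_average(ms$coherence, ms$phase,
                                bands)$mean_coherence)
  }
  expect_gt(mean(floor_vals), 0.02)
  expect_lt(mean(floor_vals), 0.5)
  expect_lt(abs(mean(floor_vals) - mean(shuf_vals)), 0.02)
})
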