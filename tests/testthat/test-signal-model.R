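test_that("parameter objects enforce their invariants", {
  expect_error(single_pool_tissue(100, 200), "T2 > T1")
  expect_error(single_pool_tissue(100, -1), "positive")
  expect_error(two_pool_tissue(1000, 100, 0.8), "mf")
  expect_error(seq_params(flip_angle_deg = 0), "flip_angle")
  expect_error(seq_params(flip_angle_deg = 120), "flip_angle")
  expect_error(seq_params(te_ms = 10, tr_ms = 4), "te_ms")
  sq <- seq_params(30, tr_ms = 4, tinv_ms = 3001)
  expect_identical(sq$n_readouts, 750L) # maximal readouts fitting in T_inv
})

test_that("zero proton density and vanishing flip angle give zero signal", {
  sq <- default_seq()
  z <- simulate_single_pool(single_pool_tissue(1000, 100, pd = 0), sq)
  expect_true(all(z$values == 0))
  tiny <- simulate_single_pool(single_pool_tissue(1000, 100),
                               seq_params(1e-3, tr_ms = 4, tinv_ms = 3000))
  expect_lt(max(tiny$values), 1e-4)
  z2 <- simulate_two_pool(two_pool_tissue(1000, 100, 0.1, pd = 0), sq)
  expect_true(all(z2$values == 0))
})

test_that("late echoes match the closed-form bSSFP steady state within 1%", {
  sq <- seq_params(30, tr_ms = 4, tinv_ms = 12000)
  for (t1 in c(700, 1000, 1400)) for (t2 in c(100, 150, 220)) {
    tis <- single_pool_tissue(t1, t2)
    curve <- simulate_single_pool(tis, sq)
    cf <- bssfp_steady_state(tis, 30)
    expect_lt(abs(curve$values[length(curve)] - cf) / cf, 0.01,
              label = sprintf("T1=%d T2=%d closed-form mismatch", t1, t2))
  }
})

test_that("fitted transient rate recovers T1* within 1%", {
  sq <- seq_params(30, tr_ms = 4, tinv_ms = 12000)
  for (t1 in c(700, 1000, 1400)) for (t2 in c(100, 150, 220)) {
    tis <- single_pool_tissue(t1, t2)
    t1s <- apparent_relaxation(tis, sq)
    fitted <- fit_transient_rate(simulate_single_pool(tis, sq),
                                 t_max_ms = 2 * t1s)
    expect_lt(abs(fitted - t1s) / t1s, 0.01,
              label = sprintf("T1=%d T2=%d transient mismatch", t1, t2))
  }
})

test_that("apparent relaxation limits are exact", {
  tis <- single_pool_tissue(1000, 100)
  expect_equal(apparent_relaxation(tis, seq_params(90, tr_ms = 4)),
               1 / (cos(pi / 4)^2 / 1000 + sin(pi / 4)^2 / 100))
  expect_equal(apparent_relaxation(tis, seq_params(1e-6, tr_ms = 4)), 1000,
               tolerance = 1e-6)
  expect_equal(apparent_relaxation(tis, seq_params(30, tr_ms = 4)), 623.87,
               tolerance = 1e-4)
})

test_that("non-convergence within the cycle budget is signalled", {
  sq <- seq_params(30, tr_ms = 4, tinv_ms = 1000, n_cycles_max = 2)
  expect_error(simulate_single_pool(single_pool_tissue(4000, 1800), sq),
               "not reached")
  expect_error(simulate_two_pool(two_pool_tissue(4000, 1800, 0.01), sq),
               "not reached")
})

test_that("frame averaging follows the window arithmetic", {
  sq <- default_seq()
  train <- simulate_single_pool(single_pool_tissue(850, 70), sq)
  fr <- frame_average(train, 20, 3000)
  expect_length(fr$values, 20)
  # T_inv = 3 s over 20 frames gives a 150 ms temporal footprint per TI
  expect_equal(unique(diff(fr$ti_ms)), 150)
  expect_equal(fr$ti_ms[1], 75)

  const <- signal_curve(seq(10, 3000, by = 10), rep(2.5, 300))
  expect_equal(frame_average(const, 20, 3000)$values, rep(2.5, 20))

  # linear ramp: each window mean equals the ramp at the mean echo time
  ti <- seq(5, 2995, by = 5)
  ramp <- signal_curve(ti, 0.001 * ti)
  fr2 <- frame_average(ramp, 20, 3000)
  w <- 3000 / 20
  expected <- vapply(seq_len(20), function(k)
    mean(0.001 * ti[ti > (k - 1) * w & ti <= k * w]), numeric(1))
  expect_equal(fr2$values, expected, tolerance = 1e-12)

  expect_error(frame_average(const, 400, 3000), "exceed")
})

test_that("frame of minimum signal is non-decreasing in T1", {
  sq <- default_seq()
  mins <- vapply(seq(600, 3000, by = 300), function(t1) {
    fr <- frame_average(simulate_single_pool(single_pool_tissue(t1, 90), sq),
                        20, 3000)
    which.min(fr$values)
  }, numeric(1))
  expect_true(all(diff(mins) >= 0))
})

test_that("two-pool model reduces to the single-pool model for mf=0, k=0", {
  sq <- default_seq()
  for (p in list(c(850, 70), c(1400, 90), c(3000, 250))) {
    a <- simulate_single_pool(single_pool_tissue(p[1], p[2]), sq)
    b <- simulate_two_pool(two_pool_tissue(p[1], p[2], 0,
                                           k_exchange_per_s = 0), sq)
    expect_lt(max(abs(a$values - b$values)) / max(a$values), 1e-6)
  }
})

test_that("magnetization transfer removes signal monotonically and separably", {
  sq <- default_seq()
  late <- vapply(seq(0, 0.3, by = 0.05), function(m) {
    cv <- simulate_two_pool(two_pool_tissue(1000, 100, m), sq)
    mean(utils::tail(cv$values, 50))
  }, numeric(1))
  expect_true(all(diff(late) <= 1e-12))

  norm_frames <- function(m) {
    f <- frame_average(simulate_two_pool(two_pool_tissue(1000, 100, m), sq),
                       20, 3000)$values
    f / sqrt(sum(f^2))
  }
  ip <- sum(norm_frames(0.05) * norm_frames(0.15))
  expect_lt(ip, 1 - 1e-4) # distinct mf leaves a usable shape difference
})

test_that("super-Lorentzian lineshape has the expected scale and ordering", {
  g10 <- super_lorentzian_g0(10)
  g20 <- super_lorentzian_g0(20)
  expect_gt(g10, 1e-6)
  expect_lt(g10, 1e-4)
  expect_gt(g20, g10) # G(0) grows with the bound-pool T2
})

test_that("curves can round-trip through config and CSV interfaces", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "sequence:",
    "  flip_angle_deg: 30",
    "  tr_ms: 4",
    "  tinv_ms: 3000",
    "tissues:",
    "  WM: {t1_ms: 850, t2_ms: 70}",
    "  WMmt: {t1f_ms: 850, t2f_ms: 70, mf: 0.1}"), cfg)
  p <- read_params_config(cfg)
  expect_s3_class(p$seq, "seq_params")
  expect_s3_class(p$tissues$WM, "single_pool_tissue")
  expect_s3_class(p$tissues$WMmt, "two_pool_tissue")

  curve <- simulate_single_pool(p$tissues$WM, p$seq)
  out <- tempfile(fileext = ".csv")
  write_curve_csv(curve, out)
  back <- utils::read.csv(out)
  expect_equal(back$value, curve$values)
  expect_equal(back$ti_ms, curve$ti_ms)
})
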