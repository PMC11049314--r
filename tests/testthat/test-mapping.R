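test_that("degenerate grids build valid dictionaries", {
  sq <- default_seq()
  d1 <- build_dictionary(param_grid(1000, 100, 0.1), sq)
  expect_identical(nrow(d1$atoms), 1L)
  expect_equal(sum(d1$atoms^2), 1, tolerance = 1e-12)

  # infeasible points (T2 > T1) are excluded
  d2 <- build_dictionary(param_grid(c(150, 1000), c(100, 400), 0), sq)
  expect_identical(nrow(d2$atoms), 3L)
  expect_false(any(d2$params[, "t2"] > d2$params[, "t1"]))
})

test_that("an MF-free dictionary equals normalized single-pool curves", {
  sq <- default_seq()
  d <- build_dictionary(param_grid(c(850, 1400), c(70, 90), 0), sq,
                        constants = two_pool_constants(k_exchange_per_s = 0))
  for (i in seq_len(nrow(d$atoms))) {
    f <- frame_average(simulate_single_pool(
      single_pool_tissue(d$params[i, "t1"], d$params[i, "t2"]), sq),
      sq$n_frames, sq$tinv_ms)$values
    expect_equal(d$atoms[i, ], f / sqrt(sum(f^2)), tolerance = 1e-9)
  }
})

test_that("atoms self-match exactly with quality one, at any scale", {
  dict <- small_dictionary()
  set.seed(21)
  for (i in sample(nrow(dict$atoms), 40)) {
    m <- match_curve(dict$atoms[i, ], dict)
    expect_identical(unname(m[c("t1_ms", "t2_ms", "mf")]),
                     unname(dict$params[i, ]))
    expect_equal(unname(m["quality"]), 1, tolerance = 1e-12)
    m2 <- match_curve(5.1 * dict$atoms[i, ], dict)
    expect_identical(m2[1:3], m[1:3])
  }
  expect_lte(max(abs(dict$atoms %*% t(dict$atoms))), 1 + 1e-9)
})

test_that("chunked matching equals a direct nearest-neighbor search", {
  dict <- small_dictionary()
  set.seed(22)
  sub <- dict
  keep <- sort(sample(nrow(dict$atoms), 500))
  sub$atoms <- dict$atoms[keep, , drop = FALSE]
  sub$params <- dict$params[keep, , drop = FALSE]
  y <- matrix(rnorm(20 * 50), 50, 20)
  y <- abs(y) / sqrt(rowSums(y^2))
  m <- iirbssfp:::match_matrix(y, sub, chunk = 64L)
  sim <- y %*% t(sub$atoms)
  expect_identical(m$index, max.col(sim, ties.method = "first"))
  expect_equal(m$quality, pmin(apply(sim, 1, max), 1), tolerance = 1e-12)
})

test_that("zero-norm curves return the background sentinel", {
  dict <- small_dictionary()
  m <- match_curve(rep(0, 20), dict)
  expect_identical(unname(m), c(0, 0, 0, 0))
})

test_that("noiseless volumes synthesized from atoms are recovered exactly", {
  dict <- small_dictionary()
  set.seed(23)
  idx <- sample(nrow(dict$atoms), 27)
  vol <- array(0, c(3, 3, 3, 20))
  vol[] <- aperm(array(t(dict$atoms[idx, ]), c(20, 3, 3, 3)), c(2, 3, 4, 1))
  series <- ti_series(vol, c(2, 2, 2), dict$ti_ms)
  mask <- array(TRUE, c(3, 3, 3))
  maps <- map_volume(series, mask, dict)
  expect_equal(as.vector(maps$t1_map_ms), unname(dict$params[idx, "t1"]))
  expect_equal(as.vector(maps$t2_map_ms), unname(dict$params[idx, "t2"]))
  expect_equal(as.vector(maps$mf_map), unname(dict$params[idx, "mf"]))
  expect_equal(as.vector(maps$match_quality), rep(1, 27), tolerance = 1e-9)

  mask[1, 1, 1] <- FALSE
  maps2 <- map_volume(series, mask, dict)
  expect_identical(maps2$t1_map_ms[1, 1, 1], 0)
  expect_error(map_volume(series, array(TRUE, c(4, 4, 4)), dict), "mask")
})

test_that("class-median T1 preserves the true tissue ordering under noise", {
  sq <- default_seq()
  dict <- small_dictionary()
  tissues <- list(WM = c(848, 28.5, 0.10), GM = c(912.4, 83.1, 0.053),
                  CSF = c(2990.4, 218.1, 0.01))
  curves <- lapply(tissues, function(p)
    frame_average(simulate_two_pool(two_pool_tissue(p[1], p[2], p[3]), sq),
                  20, 3000)$values)
  peak <- max(unlist(curves))
  set.seed(24)
  med <- vapply(curves, function(cv) {
    n <- 200
    noisy <- sqrt(sweep(matrix(rnorm(20 * n, sd = peak / 50), n), 2, cv,
                        "+")^2 +
                    matrix(rnorm(20 * n, sd = peak / 50), n)^2)
    nrm <- sqrt(rowSums(noisy^2))
    best <- iirbssfp:::match_matrix(noisy / nrm, dict)$index
    stats::median(dict$params[best, "t1"])
  }, numeric(1))
  expect_true(med["WM"] < med["GM"] && med["GM"] < med["CSF"])
})

test_that("dictionaries persist with full provenance", {
  dict <- build_dictionary(param_grid(c(850, 1400), c(70, 90),
                                      c(0, 0.1)), default_seq())
  dir <- file.path(tempdir(), "dict-rt")
  save_dictionary(dict, dir)
  back <- load_dictionary(dir)
  expect_equal(back$atoms, dict$atoms, tolerance = 1e-12)
  expect_equal(unname(back$params), unname(dict$params))
  expect_equal(back$seq$flip_angle_deg, dict$seq$flip_angle_deg)
  expect_equal(back$constants$k_exchange_per_s,
               dict$constants$k_exchange_per_s)
})
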