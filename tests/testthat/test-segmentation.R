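test_that("voxel normalization is scale invariant and guards zero norms", {
  bl <- block_series(list(c(850, 70), c(1400, 90), c(4000, 1800)))
  n1 <- normalize_voxels(bl$series)
  scaled <- bl$series
  scaled$volume <- scaled$volume * 7.3
  n2 <- normalize_voxels(scaled)
  expect_equal(n1$volume, n2$volume, tolerance = 1e-12)

  vol <- bl$series$volume
  vol[1, 1, 1, ] <- 0
  n3 <- normalize_voxels(ti_series(vol, c(2, 2, 2), bl$series$ti_ms))
  expect_false(any(is.nan(n3$volume)))
  expect_true(attr(n3, "background")[1, 1, 1])
})

test_that("a multiplicative bias field cancels under normalization", {
  ph0 <- build_phantom(phantom_spec(shape = c(32, 32, 32), snr = Inf,
                                    bias_order = 0, seed = 5))
  ph2 <- build_phantom(phantom_spec(shape = c(32, 32, 32), snr = Inf,
                                    bias_order = 3, bias_amp = 0.3, seed = 5))
  n0 <- normalize_voxels(ph0$series)$volume
  n2 <- normalize_voxels(ph2$series)$volume
  expect_lt(max(abs(n0 - n2)), 1e-6)
})

test_that("background mask matches the support on noiseless data", {
  ph <- noiseless_phantom()
  m <- background_mask(ph$series)
  expect_identical(m, ph$truth$labels$labels > 0)
  # degenerate threshold keeps every voxel with any signal
  m0 <- background_mask(ph$series, threshold_frac = 0)
  expect_identical(m0, apply(ph$series$volume, 1:3, max) > 0)
})

test_that("background mask keeps the head and rejects air under noise", {
  ph <- tumor_phantom()
  m <- background_mask(ph$series)
  head <- ph$truth$labels$labels > 0
  expect_gte(mean(m[head]), 0.99)
  expect_lte(mean(m[!head]), 0.01)
  expect_error(background_mask(ti_series(array(0, c(4, 4, 4, 3)), c(1, 1, 1),
                                         1:3) , 0.5), "empty mask")
})

test_that("spherical k-means recovers orthonormal prototypes exactly", {
  proto <- diag(3)
  x <- proto[rep(1:3, each = 5), ]
  cs <- spherical_kmeans(x, 3, seed = 0)
  expect_setequal(split(seq_len(15), cs$cluster) |> lengths(), 5)
  # each center must equal one prototype
  best <- apply(cs$centers %*% t(proto), 1, max)
  expect_equal(best, rep(1, 3), tolerance = 1e-12)
})

test_that("spherical k-means objective is non-decreasing within a run", {
  set.seed(11)
  x <- matrix(rnorm(600), 60, 10)
  x <- x / sqrt(rowSums(x^2))
  cs <- spherical_kmeans(x, 4, seed = 3, n_start = 1)
  expect_true(all(diff(cs$objective_trace) >= -1e-9))
  expect_error(spherical_kmeans(x[1:3, ], 4), "at least k")
})

test_that("noiseless three-tissue clustering reproduces the ground truth", {
  bl <- block_series(list(c(850, 70), c(1400, 90), c(4000, 1800)),
                     noise_sd = 1e-4)
  nser <- normalize_voxels(bl$series)
  x <- matrix(nser$volume, ncol = dim(nser$volume)[4])
  cs <- spherical_kmeans(x, 3, seed = 0)
  lab <- array(cs$cluster, dim(bl$labels))
  for (k in 1:3)
    expect_equal(dice(lab == k, bl$labels == k), 1,
                 label = sprintf("tissue %d not recovered", k))
  # sorted cluster order equals tissue order by T1 (WM earliest minimum)
  expect_true(all(diff(cs$min_time_index) >= 0))
})

test_that("brain extraction removes the skull shell", {
  ph <- tumor_phantom()
  seg <- tumor_segmentation()
  truth <- ph$truth$labels$labels
  brain_true <- array(truth %in% 1:7, dim(truth))
  expect_gte(dice(seg$mask, brain_true), 0.95)
  skull <- truth == 8L
  expect_lt(mean(seg$mask[skull]), 0.05)
})

test_that("brain extraction keeps the head when there is no skull", {
  tt <- phantom_tissues()
  tt$pd[tt$name == "skull"] <- 0 # no skull signal at all
  ph <- build_phantom(phantom_spec(shape = c(48, 48, 48), seed = 2,
                                   tissues = tt))
  mask <- brain_extract(ph$series, seed = 0)
  brain_true <- array(ph$truth$labels$labels %in% 1:7,
                      dim(ph$truth$labels$labels))
  expect_gte(sum(mask & brain_true) / sum(brain_true), 0.99)
})

test_that("sequential clustering yields ten sorted segments and labels", {
  seg <- tumor_segmentation()$labels
  segments <- attr(seg, "segments")
  expect_setequal(setdiff(unique(as.vector(segments)), 0L), 1:10)
  expect_identical(seg$class_names[1:7],
                   c("WM", "GM", "CSF", "T2L-1", "T2L-2", "CEL", "NEC"))
  centers <- attr(seg, "centers")
  expect_equal(rowSums(centers^2), rep(1, 10), tolerance = 1e-9)
})

test_that("lesion compartments are recovered on the tumor phantom", {
  ph <- tumor_phantom()
  seg <- tumor_segmentation()$labels
  truth <- ph$truth$labels$labels
  expect_gte(dice(seg$labels == 6L, truth == 6L), 0.80) # CEL
  t2l_seg <- array(seg$labels %in% 4:5, dim(truth))
  t2l_true <- array(truth %in% 4:5, dim(truth))
  expect_gte(dice(t2l_seg, t2l_true), 0.80)
  expect_gte(dice(seg$labels == 7L, truth == 7L), 0.80) # enclosed necrosis
})

test_that("segmentation is deterministic and per-voxel scale invariant", {
  ph <- tumor_phantom()
  seg <- tumor_segmentation()
  s2 <- hierarchical_segment(ph$series, mask = seg$mask, seed = 0, nec = TRUE)
  expect_identical(seg$labels$labels, s2$labels)

  set.seed(7)
  gains <- array(exp(runif(prod(dim(ph$series$volume)[1:3]), -0.7, 0.7)),
                 dim(ph$series$volume)[1:3])
  biased <- ph$series
  biased$volume <- biased$volume * as.vector(gains)
  s3 <- hierarchical_segment(biased, mask = seg$mask, seed = 0, nec = TRUE)
  expect_identical(seg$labels$labels, s3$labels)
})

test_that("lesion classes stay empty on a lesion-free phantom", {
  ph <- build_phantom(phantom_spec(seed = 4, lesion = FALSE))
  seg <- hierarchical_segment(ph$series, seed = 0)
  v <- lesion_volumes(seg)
  expect_lt(sum(v[c("T2L-1", "T2L-2", "CEL", "NEC")]),
            0.005 * sum(v))
})

test_that("volumes convert counts to mL", {
  lab <- array(0L, c(20, 20, 20))
  lab[1:10, 1:10, 1:10] <- 1L
  lv <- structure(list(labels = lab, class_names = c("WM", "GM"),
                       voxel_size_mm = c(1, 1, 1)), class = "label_volume")
  expect_equal(unname(lesion_volumes(lv)), c(1, 0))

  # 10 mm radius sphere at 1 mm voxels: 4.19 mL within voxelization error
  sph <- array(0L, c(32, 32, 32))
  sph[iirbssfp:::ellipsoid_mask(c(32, 32, 32), c(16.5, 16.5, 16.5),
                                c(10, 10, 10))] <- 1L
  lv2 <- structure(list(labels = sph, class_names = "S",
                        voxel_size_mm = c(1, 1, 1)), class = "label_volume")
  expect_equal(unname(lesion_volumes(lv2)), 4 / 3 * pi, tolerance = 0.03)
})
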