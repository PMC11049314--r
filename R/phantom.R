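#' Default tissue parameters of the digital brain-tumor phantom
#'
#' One two-compartment parameter set per phantom structure. The per-class
#' values (free-pool T1/T2 in ms, macromolecular fraction) anchor the phantom
#' to in-vivo IIR-bSSFP whole-brain measurements: CSF 2990.4/218.1/1.0%, WM
#' 848.0/28.5/10.0%, GM 912.4/83.1/5.3%, T2L-1 749.5/62.2/7.8%, T2L-2
#' 883.8/94.1/3.4%, CEL 1300.7/115.8/2.6%, NEC 2696.6/190.7/2.2%. Cortical
#' grey matter is modeled as four concentric ribbon layers whose parameters
#' straddle the GM class mean, emulating the partial-volume continuum from
#' the white-matter boundary to the CSF surface that the staged clustering
#' resolves into layers on real brains; all four carry the GM class label.
#' The skull shell is a short-T2, low-proton-density structure.
#'
#' @return A data frame with columns `name`, `class` (label code 1-8),
#'   `t1f`, `t2f`, `mf`, `pd`.
#' @export
phantom_tissues <- function() {
  data.frame(
    name = c("WM", "GM-L1", "GM-L2", "GM-L3", "GM-L4", "CSF",
             "T2L-1", "T2L-2", "CEL", "NEC", "skull"),
    class = c(1L, 2L, 2L, 2L, 2L, 3L, 4L, 5L, 6L, 7L, 8L),
    t1f = c(848, 630, 980, 1340, 1900, 2990.4, 749.5, 883.8, 1300.7, 2696.6, 400),
    t2f = c(28.5, 54, 75, 100, 150, 218.1, 62.2, 94.1, 115.8, 190.7, 20),
    mf = c(0.100, 0.072, 0.055, 0.042, 0.028, 0.010, 0.078, 0.034, 0.026,
           0.022, 0.20),
    pd = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0.3))
}

#' Specification of a synthetic brain-tumor phantom
#'
#' Nested-ellipsoid head geometry (skull shell, outer CSF film, four-layer
#' cortical ribbon, white-matter interior, ventricles) plus an optional
#' lesion complex of concentric spheres (necrotic core, contrast-enhancing
#' rim, inner and outer T2-lesion shells) placed in the white matter. Signal
#' curves are corrupted by Rician noise (magnitude of complex Gaussian) and
#' an optional smooth multiplicative polynomial bias field.
#'
#' @param shape Volume dimensions in voxels (length 3; >= 32 recommended).
#' @param voxel_size_mm Isotropic voxel size (mm).
#' @param snr Ratio of peak clean tissue signal to the Gaussian noise
#'   standard deviation; `Inf` for noiseless.
#' @param bias_order Polynomial order of the multiplicative bias field
#'   (0 = no bias, field identically 1).
#' @param bias_amp Maximum log-amplitude of the bias field.
#' @param lesion Include the lesion complex.
#' @param lesion_center_vox Lesion-complex center offset from the volume
#'   center, in 64-matrix voxel units (scaled with `shape`).
#' @param lesion_radii_vox Radii of the nested lesion spheres (outer T2L,
#'   inner T2L, enhancing rim, necrotic core), same units.
#' @param seed Seed for noise and bias (geometry and labels are
#'   deterministic and independent of it).
#' @param seq A [seq_params()] describing the acquisition.
#' @param tissues Tissue table as from [phantom_tissues()].
#' @param constants Bound-pool constants, see [two_pool_constants()].
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), voxel_size_mm = 2, snr = 50,
                         bias_order = 2, bias_amp = 0.2, lesion = TRUE,
                         lesion_center_vox = c(8, 4, 0),
                         lesion_radii_vox = c(10, 7.5, 5.5, 3),
                         seed = 0, seq = seq_params(),
                         tissues = phantom_tissues(),
                         constants = two_pool_constants()) {
  stopifnot(length(shape) == 3, all(shape >= 24), snr > 0,
            length(lesion_center_vox) == 3, length(lesion_radii_vox) == 4,
            all(diff(lesion_radii_vox) < 0))
  structure(list(shape = as.integer(shape), voxel_size_mm = voxel_size_mm,
                 snr = snr, bias_order = as.integer(bias_order),
                 bias_amp = bias_amp, lesion = isTRUE(lesion),
                 lesion_center_vox = lesion_center_vox,
                 lesion_radii_vox = lesion_radii_vox,
                 seed = as.integer(seed), seq = seq, tissues = tissues,
                 constants = constants),
            class = "phantom_spec")
}

# ellipsoid mask helper on normalized coordinates
ellipsoid_mask <- function(shape, center, radii) {
  cx <- (seq_len(shape[1]) - center[1]) / radii[1]
  cy <- (seq_len(shape[2]) - center[2]) / radii[2]
  cz <- (seq_len(shape[3]) - center[3]) / radii[3]
  r2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
  r2 <= 1
}

# build the per-voxel tissue index (row into spec$tissues; 0 = air)
phantom_geometry <- function(spec) {
  sh <- spec$shape
  ctr <- (sh + 1) / 2
  sc <- sh / 64  # radii scale with the matrix so smaller demos stay valid
  head_r <- c(26, 30, 24) * sc
  shells <- list(
    head = ellipsoid_mask(sh, ctr, head_r),
    inner_skull = ellipsoid_mask(sh, ctr, head_r - 2 * sc),
    inner_csf = ellipsoid_mask(sh, ctr, head_r - 3 * sc),
    gm1 = ellipsoid_mask(sh, ctr, head_r - 4 * sc),
    gm2 = ellipsoid_mask(sh, ctr, head_r - 5 * sc),
    gm3 = ellipsoid_mask(sh, ctr, head_r - 6 * sc),
    wm = ellipsoid_mask(sh, ctr, head_r - 7 * sc))
  tis <- array(0L, sh)
  row_of <- function(nm) which(spec$tissues$name == nm)
  tis[shells$head] <- row_of("skull")
  tis[shells$inner_skull] <- row_of("CSF")
  tis[shells$inner_csf] <- row_of("GM-L4")
  tis[shells$gm1] <- row_of("GM-L3")
  tis[shells$gm2] <- row_of("GM-L2")
  tis[shells$gm3] <- row_of("GM-L1")
  tis[shells$wm] <- row_of("WM")
  # ventricles: two CSF ellipsoids inside the white matter
  for (sgn in c(-1, 1)) {
    vent <- ellipsoid_mask(sh, ctr + c(sgn * 5, -10, 0) * sc, c(2, 3.5, 2) * sc)
    if (any(tis[vent] == 0L | tis[vent] == row_of("skull")))
      stop("overlapping geometry: ventricle CSF leaves the brain interior")
    tis[vent] <- row_of("CSF")
  }
  if (spec$lesion) {
    # patient-scale lesion complex: ~19 mL outer T2L shell, ~9 mL inner T2L
    # shell, ~5 mL enhancing rim, ~1 mL necrotic core (at 64^3, 2 mm voxels)
    lc <- ctr + spec$lesion_center_vox * sc
    r <- spec$lesion_radii_vox
    outer_t2l <- ellipsoid_mask(sh, lc, rep(r[1], 3) * sc)
    if (!all(tis[outer_t2l] == row_of("WM"))) {
      hit <- unique(tis[outer_t2l])
      hit <- setdiff(hit, row_of("WM"))
      nm <- ifelse(hit == 0L, "air", spec$tissues$name[hit])
      stop("overlapping geometry: lesion complex extends beyond WM into ",
           paste(nm, collapse = "/"))
    }
    tis[outer_t2l] <- row_of("T2L-1")
    tis[ellipsoid_mask(sh, lc, rep(r[2], 3) * sc)] <- row_of("T2L-2")
    tis[ellipsoid_mask(sh, lc, rep(r[3], 3) * sc)] <- row_of("CEL")
    tis[ellipsoid_mask(sh, lc, rep(r[4], 3) * sc)] <- row_of("NEC")
  }
  tis
}

#' Build a synthetic 4D TI series with ground truth
#'
#' Simulates each tissue's two-compartment frame-averaged signal evolution,
#' paints it into the phantom geometry, adds complex Gaussian noise of
#' standard deviation `peak / snr` to the real and imaginary channels before
#' taking the magnitude (Rician noise), and applies the multiplicative bias
#' field. Deterministic given `spec$seed`; labels and geometry do not depend
#' on the seed.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom` list: `series` (a [ti_series()]), `truth` (list with
#'   `labels` label_volume, `t1`, `t2`, `mf` ground-truth arrays, `clean` 4D
#'   array, `tissue_index`, `sigma`, `peak`), and `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  tis <- phantom_geometry(spec)
  sq <- spec$seq
  tt <- spec$tissues
  curves <- matrix(0, nrow(tt) + 1L, sq$n_frames) # row 1 = air
  for (i in seq_len(nrow(tt))) {
    tissue <- two_pool_tissue(tt$t1f[i], tt$t2f[i], tt$mf[i],
                              t1b_ms = spec$constants$t1b_ms,
                              t2b_us = spec$constants$t2b_us,
                              k_exchange_per_s = spec$constants$k_exchange_per_s,
                              pd = tt$pd[i])
    curves[i + 1L, ] <- frame_average(simulate_two_pool(tissue, sq),
                                      sq$n_frames, sq$tinv_ms)$values
  }
  nvox <- prod(spec$shape)
  clean <- curves[as.vector(tis) + 1L, , drop = FALSE]
  peak <- max(clean)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  sigma <- if (is.finite(spec$snr)) peak / spec$snr else 0
  noisy <- if (sigma > 0) {
    sqrt((clean + stats::rnorm(length(clean), sd = sigma))^2 +
           stats::rnorm(length(clean), sd = sigma)^2)
  } else clean
  bias <- phantom_bias_field(spec)
  noisy <- noisy * as.vector(bias)

  d4 <- c(spec$shape, sq$n_frames)
  w <- sq$tinv_ms / sq$n_frames
  series <- ti_series(array(noisy, d4), rep(spec$voxel_size_mm, 3),
                      (seq_len(sq$n_frames) - 0.5) * w)
  labels <- structure(list(
    labels = array(c(0L, tt$class)[as.vector(tis) + 1L], spec$shape),
    class_names = c("WM", "GM", "CSF", "T2L-1", "T2L-2", "CEL", "NEC", "skull"),
    voxel_size_mm = rep(spec$voxel_size_mm, 3)), class = "label_volume")
  truth_map <- function(col) {
    v <- c(0, tt[[col]])[as.vector(tis) + 1L]
    array(v, spec$shape)
  }
  list(series = series,
       truth = list(labels = labels, t1 = truth_map("t1f"),
                    t2 = truth_map("t2f"), mf = truth_map("mf"),
                    clean = array(clean, d4), tissue_index = tis,
                    bias = bias, sigma = sigma, peak = peak),
       spec = spec)
}

# smooth positive multiplicative bias field exp(P(x,y,z)) with random
# polynomial P of the given order, scaled to max |P| = bias_amp
phantom_bias_field <- function(spec) {
  sh <- spec$shape
  if (spec$bias_order == 0L) return(array(1, sh))
  u <- lapply(sh, function(n) seq(-1, 1, length.out = n))
  p <- array(0, sh)
  for (dx in 0:spec$bias_order) for (dy in 0:spec$bias_order)
    for (dz in 0:spec$bias_order) {
      deg <- dx + dy + dz
      if (deg < 1 || deg > spec$bias_order) next
      coef <- stats::runif(1, -1, 1)
      p <- p + coef * outer(outer(u[[1]]^dx, u[[2]]^dy, `*`), u[[3]]^dz, `*`)
    }
  m <- max(abs(p))
  if (m == 0) return(array(1, sh))
  exp(p / m * spec$bias_amp)
}

#' Write a phantom fixture to disk
#'
#' Writes the 4D series, the label volume, the ground-truth parameter maps
#' and the clean signal as double-precision NIfTI plus the generating
#' specification as JSON, so the fixture round-trips losslessly and can be
#' regenerated from its spec.
#'
#' @param phantom A phantom from [build_phantom()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_fixture <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- phantom$series$voxel_size_mm
  wr <- function(x, name) RNifti::writeNifti(
    RNifti::asNifti(x, pixdim = c(vs, 1)[seq_len(length(dim(x)))]),
    file.path(dir, name), datatype = "double")
  wr(phantom$series$volume, "series.nii.gz")
  wr(phantom$truth$clean, "clean.nii.gz")
  wr(phantom$truth$t1, "t1.nii.gz")
  wr(phantom$truth$t2, "t2.nii.gz")
  wr(phantom$truth$mf, "mf.nii.gz")
  lab <- phantom$truth$labels$labels
  storage.mode(lab) <- "integer"
  wr(lab, "labels.nii.gz")
  sp <- phantom$spec
  meta <- list(shape = sp$shape, voxel_size_mm = sp$voxel_size_mm,
               snr = if (is.finite(sp$snr)) sp$snr else "Inf",
               bias_order = sp$bias_order,
               bias_amp = sp$bias_amp, lesion = sp$lesion,
               lesion_center_vox = sp$lesion_center_vox,
               lesion_radii_vox = sp$lesion_radii_vox, seed = sp$seed,
               seq = unclass(sp$seq), tissues = sp$tissues,
               constants = sp$constants, ti_ms = phantom$series$ti_ms,
               class_names = phantom$truth$labels$class_names)
  jsonlite::write_json(meta, file.path(dir, "spec.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a phantom fixture written by [write_fixture()]
#'
#' @param dir Fixture directory.
#' @return A list with `series`, `truth` (labels and parameter maps) and the
#'   parsed `spec` (a `phantom_spec` that regenerates the phantom).
#' @export
read_fixture <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "spec.json"), simplifyVector = TRUE)
  rd <- function(name) {
    a <- RNifti::readNifti(file.path(dir, name))
    array(as.numeric(a), dim(a))
  }
  vol <- rd("series.nii.gz")
  series <- ti_series(vol, rep(meta$voxel_size_mm, 3), meta$ti_ms)
  labels <- structure(list(labels = array(as.integer(rd("labels.nii.gz")),
                                          dim(vol)[1:3]),
                           class_names = meta$class_names,
                           voxel_size_mm = rep(meta$voxel_size_mm, 3)),
                      class = "label_volume")
  spec <- phantom_spec(
    shape = meta$shape, voxel_size_mm = meta$voxel_size_mm,
    snr = as.numeric(meta$snr), bias_order = meta$bias_order,
    bias_amp = meta$bias_amp,
    lesion = meta$lesion, lesion_center_vox = meta$lesion_center_vox,
    lesion_radii_vox = meta$lesion_radii_vox, seed = meta$seed,
    seq = do.call(seq_params, meta$seq[setdiff(names(meta$seq), "n_readouts")]),
    tissues = meta$tissues, constants = meta$constants)
  list(series = series,
       truth = list(labels = labels, t1 = rd("t1.nii.gz"),
                    t2 = rd("t2.nii.gz"), mf = rd("mf.nii.gz"),
                    clean = rd("clean.nii.gz")),
       spec = spec)
}
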