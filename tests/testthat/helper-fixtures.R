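# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

default_seq <- function() seq_params(30, tr_ms = 4, tinv_ms = 3000)

tumor_phantom <- function(seed = 1) {
  cached(paste0("tumor", seed), build_phantom(phantom_spec(seed = seed)))
}

tumor_segmentation <- function(seed = 1) {
  cached(paste0("seg", seed), {
    ph <- tumor_phantom(seed)
    mask <- brain_extract(ph$series, seed = 0)
    list(mask = mask,
         labels = hierarchical_segment(ph$series, mask = mask, seed = 0,
                                       nec = TRUE))
  })
}

noiseless_phantom <- function() {
  cached("noiseless", build_phantom(
    phantom_spec(shape = c(32, 32, 32), snr = Inf, bias_order = 0)))
}

small_dictionary <- function() {
  cached("dict", build_dictionary(
    param_grid(geom_seq(100, 4000, 1.12), geom_seq(10, 400, 1.12),
               seq(0, 0.4, by = 0.02)),
    default_seq()))
}

# three-tissue block series: each third of the x axis holds one tissue curve
block_series <- function(tissues, n = 12, noise_sd = 0, seed = 99) {
  sq <- default_seq()
  curves <- lapply(tissues, function(p)
    frame_average(simulate_single_pool(single_pool_tissue(p[1], p[2]), sq),
                  sq$n_frames, sq$tinv_ms)$values)
  k <- length(curves)
  vol <- array(0, c(n * k, 4, 4, sq$n_frames))
  labs <- array(0L, c(n * k, 4, 4))
  for (i in seq_len(k)) {
    idx <- ((i - 1) * n + 1):(i * n)
    vol[idx, , , ] <- rep(curves[[i]], each = n * 16)
    labs[idx, , ] <- i
  }
  if (noise_sd > 0) {
    set.seed(seed)
    vol <- abs(vol + array(rnorm(length(vol), sd = noise_sd), dim(vol)))
  }
  list(series = ti_series(vol, c(2, 2, 2), (seq_len(sq$n_frames) - 0.5) * 150),
       labels = labs)
}
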