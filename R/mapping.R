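#' Parameter grid for dictionary construction
#'
#' Axes of the (T1, T2, MF) grid over which two-compartment signal evolutions
#' are simulated. T1 and T2 default to geometric progressions (constant
#' relative step) and MF to a linear grid.
#'
#' @param t1_values_ms,t2_values_ms Strictly increasing relaxation-time axes.
#' @param mf_values Strictly increasing macromolecular-fraction axis.
#' @return A `param_grid`.
#' @export
param_grid <- function(t1_values_ms = geom_seq(100, 4000, 1.03),
                       t2_values_ms = geom_seq(10, 400, 1.03),
                       mf_values = seq(0, 0.40, by = 0.01)) {
  for (v in list(t1_values_ms, t2_values_ms, mf_values))
    if (length(v) < 1 || any(diff(v) <= 0)) stop("axes must be strictly increasing")
  if (any(mf_values < 0) || any(mf_values > 0.5))
    stop("mf_values must lie in [0, 0.5]")
  structure(list(t1_values_ms = t1_values_ms, t2_values_ms = t2_values_ms,
                 mf_values = mf_values), class = "param_grid")
}

#' Geometric sequence covering a range
#'
#' @param from,to Range endpoints (positive).
#' @param ratio Relative step (e.g. 1.03 for ~3 percent steps).
#' @return Increasing numeric vector from `from` to `to`.
#' @export
geom_seq <- function(from, to, ratio = 1.03) {
  stopifnot(from > 0, to > from, ratio > 1)
  n <- ceiling(log(to / from) / log(ratio))
  exp(seq(log(from), log(to), length.out = n + 1))
}

#' Fixed two-compartment constants for dictionary simulation
#'
#' Exchange rate, bound-pool relaxation and total proton density held fixed
#' while (T1, T2, MF) vary over the grid.
#'
#' @param t1b_ms Bound-pool T1 (ms).
#' @param t2b_us Bound-pool T2 (microseconds).
#' @param k_exchange_per_s Fundamental exchange rate constant (1/s).
#' @param pd Proton density used in simulation (cancels after normalization).
#' @return A named list.
#' @export
two_pool_constants <- function(t1b_ms = 1000, t2b_us = 10,
                               k_exchange_per_s = 19, pd = 1) {
  list(t1b_ms = t1b_ms, t2b_us = t2b_us,
       k_exchange_per_s = k_exchange_per_s, pd = pd)
}

#' Build a dictionary of simulated IIR-bSSFP signal evolutions
#'
#' Simulates the two-compartment frame-averaged signal evolution at every
#' feasible grid point (T2 <= T1), normalizes each curve to unit L2 norm, and
#' stores the grid, sequence and constants as provenance. Grid points whose
#' simulation does not reach the periodic steady state are excluded with a
#' message.
#'
#' @param grid A [param_grid()].
#' @param seq A [seq_params()].
#' @param constants Fixed two-pool constants, see [two_pool_constants()].
#' @param verbose Print progress.
#' @return An `mrf_dictionary` with `atoms` (one unit-norm curve per row),
#'   `params` (matrix of t1, t2, mf per atom), `grid`, `seq`, `constants`.
#' @export
build_dictionary <- function(grid, seq, constants = two_pool_constants(),
                             verbose = FALSE) {
  stopifnot(inherits(grid, "param_grid"), inherits(seq, "seq_params"))
  pts <- expand.grid(t1 = grid$t1_values_ms, t2 = grid$t2_values_ms,
                     mf = grid$mf_values, KEEP.OUT.ATTRS = FALSE)
  pts <- pts[pts$t2 <= pts$t1, , drop = FALSE]
  pts <- pts[order(pts$t1, pts$t2, pts$mf), , drop = FALSE]
  if (!nrow(pts)) stop("no feasible grid points (need T2 <= T1)")
  if (verbose)
    message(sprintf("simulating %d dictionary atoms (%d frames)...",
                    nrow(pts), seq$n_frames))
  sat <- bound_saturation(seq$flip_angle_deg, seq$pulse_us, constants$t2b_us)
  w <- seq$tinv_ms / seq$n_frames
  t0 <- if (seq$catalyze) seq$tr_ms / 2 else 0
  ti <- t0 + (seq_len(seq$n_readouts) - 1) * seq$tr_ms + seq$te_ms
  frame_of_echo <- pmin(pmax(ceiling(ti / w), 1L), seq$n_frames)
  res <- .cpp_two_pool_batch(
    as.matrix(pts), constants$t1b_ms, constants$k_exchange_per_s,
    constants$pd, seq$flip_angle_deg, seq$tr_ms, seq$te_ms, seq$n_readouts,
    seq$n_frames, as.integer(frame_of_echo), sat$pulse, sat$catalyze,
    seq$catalyze, seq$invert_bound, seq$n_cycles_max, seq$convergence_tol)
  keep <- res$converged
  if (!all(keep))
    message(sprintf("excluded %d non-converged grid points", sum(!keep)))
  atoms <- res$atoms[keep, , drop = FALSE]
  nrm <- sqrt(rowSums(atoms^2))
  ok <- nrm > 0
  atoms <- atoms[ok, , drop = FALSE] / nrm[ok]
  structure(list(atoms = atoms,
                 params = as.matrix(pts[keep, , drop = FALSE][ok, , drop = FALSE]),
                 grid = grid, seq = seq, constants = constants,
                 ti_ms = (seq_len(seq$n_frames) - 0.5) * w),
            class = "mrf_dictionary")
}

#' @export
print.mrf_dictionary <- function(x, ...) {
  cat(sprintf(
    "mrf_dictionary: %d atoms x %d frames (T1 %g..%g, T2 %g..%g ms, MF %g..%g)\n",
    nrow(x$atoms), ncol(x$atoms),
    min(x$params[, "t1"]), max(x$params[, "t1"]),
    min(x$params[, "t2"]), max(x$params[, "t2"]),
    min(x$params[, "mf"]), max(x$params[, "mf"])))
  invisible(x)
}

# exact maximum-inner-product matching of unit-norm rows of y against the
# dictionary; doubly chunked (curves x atoms) so memory stays bounded.
# Atoms are ordered by (t1, t2, mf) ascending, and the strict > update keeps
# the first (smallest) on exact ties.
match_matrix <- function(y, dict, chunk = 8192L, row_chunk = 4096L) {
  n <- nrow(y)
  best <- rep(1L, n)
  bestv <- rep(-Inf, n)
  na <- nrow(dict$atoms)
  for (rs in seq(1L, n, by = row_chunk)) {
    re <- min(rs + row_chunk - 1L, n)
    yr <- y[rs:re, , drop = FALSE]
    nr <- re - rs + 1L
    for (s in seq(1L, na, by = chunk)) {
      e <- min(s + chunk - 1L, na)
      sim <- yr %*% t(dict$atoms[s:e, , drop = FALSE])
      mj <- max.col(sim, ties.method = "first")
      mv <- sim[cbind(seq_len(nr), mj)]
      upd <- mv > bestv[rs:re]
      if (any(upd)) {
        rows <- (rs:re)[upd]
        best[rows] <- mj[upd] + (s - 1L)
        bestv[rows] <- mv[upd]
      }
    }
  }
  list(index = best, quality = pmin(bestv, 1))
}

#' Match a signal curve against a dictionary
#'
#' Returns the grid parameters of the atom with maximal inner product with
#' the unit-normalized input curve (exact nearest neighbor in cosine
#' distance; ties break toward the smallest T1, then T2, then MF). A
#' zero-norm curve returns the background sentinel (all parameters 0,
#' quality 0).
#'
#' @param curve A [signal_curve()] with as many points as the dictionary has
#'   frames, or a bare numeric vector.
#' @param dict An `mrf_dictionary`.
#' @return Named numeric vector `t1_ms, t2_ms, mf, quality`.
#' @export
match_curve <- function(curve, dict) {
  stopifnot(inherits(dict, "mrf_dictionary"))
  v <- if (inherits(curve, "signal_curve")) curve$values else as.numeric(curve)
  if (length(v) != ncol(dict$atoms))
    stop("curve length must equal the dictionary frame count")
  nrm <- sqrt(sum(v^2))
  if (nrm == 0)
    return(c(t1_ms = 0, t2_ms = 0, mf = 0, quality = 0))
  m <- match_matrix(matrix(v / nrm, 1), dict)
  p <- dict$params[m$index, ]
  c(t1_ms = unname(p["t1"]), t2_ms = unname(p["t2"]), mf = unname(p["mf"]),
    quality = m$quality)
}

#' Voxel-wise parametric mapping by dictionary matching
#'
#' Normalizes every in-mask voxel curve and matches it against the
#' dictionary, producing T1, T2 and macromolecular-fraction maps plus a
#' cosine-similarity match-quality map. Deterministic given its inputs.
#'
#' @param series A [ti_series()].
#' @param mask Logical 3D array of voxels to map.
#' @param dict An `mrf_dictionary`.
#' @return A `parametric_maps` list: `t1_map_ms`, `t2_map_ms`, `mf_map`,
#'   `match_quality` (3D arrays; 0 outside the mask).
#' @export
map_volume <- function(series, mask, dict) {
  stopifnot(inherits(series, "ti_series"), inherits(dict, "mrf_dictionary"))
  d <- dim(series$volume)
  if (!identical(dim(mask), d[1:3])) stop("mask dimensions must match the series")
  if (d[4] != ncol(dict$atoms))
    stop("series frame count must equal the dictionary frame count")
  x <- series_matrix(series)[as.vector(mask), , drop = FALSE]
  nrm <- sqrt(rowSums(x^2))
  ok <- nrm > 0
  t1 <- t2 <- mf <- q <- numeric(nrow(x))
  if (any(ok)) {
    m <- match_matrix(x[ok, , drop = FALSE] / nrm[ok], dict)
    t1[ok] <- dict$params[m$index, "t1"]
    t2[ok] <- dict$params[m$index, "t2"]
    mf[ok] <- dict$params[m$index, "mf"]
    q[ok] <- m$quality
  }
  mk_map <- function(v) { a <- array(0, d[1:3]); a[mask] <- v; a }
  structure(list(t1_map_ms = mk_map(t1), t2_map_ms = mk_map(t2),
                 mf_map = mk_map(mf), match_quality = mk_map(q),
                 voxel_size_mm = series$voxel_size_mm),
            class = "parametric_maps")
}

#' Persist a dictionary as plain text with full provenance
#'
#' Writes `dictionary.json` (grid axes, sequence, constants) and
#' `atoms.csv.gz` (parameters and unit-norm curves) into a directory so that
#' maps are reproducible bit-for-bit.
#'
#' @param dict An `mrf_dictionary`.
#' @param dir Output directory (created if needed).
#' @export
save_dictionary <- function(dict, dir) {
  stopifnot(inherits(dict, "mrf_dictionary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(grid = unclass(dict$grid), seq = unclass(dict$seq),
               constants = dict$constants, ti_ms = dict$ti_ms,
               n_atoms = nrow(dict$atoms))
  jsonlite::write_json(meta, file.path(dir, "dictionary.json"),
                       auto_unbox = TRUE, digits = NA)
  tab <- cbind(as.data.frame(dict$params),
               as.data.frame(dict$atoms))
  names(tab) <- c("t1", "t2", "mf", paste0("f", seq_len(ncol(dict$atoms))))
  con <- gzfile(file.path(dir, "atoms.csv.gz"))
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(dir)
}

#' Load a dictionary written by [save_dictionary()]
#'
#' @param dir Directory containing `dictionary.json` and `atoms.csv.gz`.
#' @return An `mrf_dictionary`.
#' @export
load_dictionary <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "dictionary.json"),
                              simplifyVector = TRUE)
  tab <- utils::read.csv(gzfile(file.path(dir, "atoms.csv.gz")))
  atoms <- as.matrix(tab[, -(1:3)])
  dimnames(atoms) <- NULL
  params <- as.matrix(tab[, 1:3])
  colnames(params) <- c("t1", "t2", "mf")
  structure(list(
    atoms = atoms, params = params,
    grid = do.call(param_grid, meta$grid),
    seq = do.call(seq_params, meta$seq[setdiff(names(meta$seq), "n_readouts")]),
    constants = meta$constants[setdiff(names(meta$constants), "")],
    ti_ms = meta$ti_ms), class = "mrf_dictionary")
}
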