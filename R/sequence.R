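#' IIR-bSSFP sequence parameters
#'
#' Describes a balanced SSFP readout train repeated between nonselective
#' inversion pulses (incomplete inversion recovery). The inversion interval
#' `tinv_ms` is tiled with the maximal number of TR periods that fit,
#' `n_readouts = floor(tinv_ms / tr_ms)`, and the reconstructed image series
#' divides the train into `n_frames` equal inversion-time windows.
#'
#' @param flip_angle_deg Excitation flip angle in degrees, in (0, 90].
#' @param tr_ms Repetition time (ms).
#' @param te_ms Echo time (ms); defaults to `tr_ms / 2` (centered echo).
#' @param tinv_ms Interval between inversion pulses (ms).
#' @param n_frames Number of reconstructed inversion-time frames.
#' @param n_cycles_max Maximum number of inversion cycles simulated while
#'   waiting for the periodic steady state.
#' @param convergence_tol Relative cycle-to-cycle tolerance declaring the
#'   periodic steady state reached.
#' @param catalyze Apply an alpha/2 catalyzation pulse followed by a TR/2
#'   delay after each inversion (standard IR-bSSFP practice). Logical.
#' @param pulse_us Equivalent rectangular RF pulse duration in microseconds;
#'   only the bound-pool saturation in the two-compartment model depends on
#'   it (the free pool sees instantaneous rotations).
#' @param invert_bound Whether the inversion pulse also inverts the bound
#'   pool's longitudinal magnetization. The short bound-pool T2 (~10 us)
#'   destroys any coherent rotation, so the default leaves it untouched.
#' @return An object of class `seq_params`.
#' @examples
#' seq_params(flip_angle_deg = 30, tr_ms = 4, tinv_ms = 3000)
#' @export
seq_params <- function(flip_angle_deg = 30, tr_ms = 4, te_ms = tr_ms / 2,
                       tinv_ms = 3000, n_frames = 20, n_cycles_max = 80,
                       convergence_tol = 1e-6, catalyze = TRUE,
                       pulse_us = 600, invert_bound = FALSE) {
  stopifnot(is.numeric(flip_angle_deg), length(flip_angle_deg) == 1L)
  if (flip_angle_deg <= 0 || flip_angle_deg > 90)
    stop("flip_angle_deg must lie in (0, 90]")
  if (tr_ms <= 0 || tinv_ms <= 0) stop("tr_ms and tinv_ms must be positive")
  if (tr_ms * 1000 <= pulse_us)
    stop("tr_ms must exceed the RF pulse duration")
  if (te_ms < 0 || te_ms > tr_ms) stop("te_ms must lie in [0, tr_ms]")
  n_readouts <- as.integer(floor(tinv_ms / tr_ms))
  if (n_frames < 1 || n_frames > n_readouts)
    stop("n_frames must be between 1 and n_readouts = ", n_readouts)
  if (n_cycles_max < 2) stop("n_cycles_max must be >= 2")
  structure(list(
    flip_angle_deg = flip_angle_deg, tr_ms = tr_ms, te_ms = te_ms,
    tinv_ms = tinv_ms, n_readouts = n_readouts, n_frames = as.integer(n_frames),
    n_cycles_max = as.integer(n_cycles_max), convergence_tol = convergence_tol,
    catalyze = isTRUE(catalyze), pulse_us = pulse_us,
    invert_bound = isTRUE(invert_bound)
  ), class = "seq_params")
}

#' @export
print.seq_params <- function(x, ...) {
  cat(sprintf(
    "IIR-bSSFP sequence: FA %g deg, TR/TE %g/%g ms, T_inv %g ms (%d readouts, %d frames)\n",
    x$flip_angle_deg, x$tr_ms, x$te_ms, x$tinv_ms, x$n_readouts, x$n_frames))
  invisible(x)
}

#' Single-compartment tissue
#'
#' @param t1_ms Longitudinal relaxation time (ms).
#' @param t2_ms Transverse relaxation time (ms); must not exceed `t1_ms`.
#' @param pd Proton density (equilibrium magnetization M0), arbitrary
#'   non-negative scale.
#' @return An object of class `single_pool_tissue`.
#' @export
single_pool_tissue <- function(t1_ms, t2_ms, pd = 1) {
  stopifnot(is.numeric(t1_ms), is.numeric(t2_ms), is.numeric(pd))
  if (t2_ms <= 0) stop("t2_ms must be positive")
  if (t1_ms < t2_ms) stop("t1_ms must be >= t2_ms (T2 > T1 is unphysical)")
  if (pd < 0) stop("pd must be non-negative")
  structure(list(t1_ms = t1_ms, t2_ms = t2_ms, pd = pd),
            class = "single_pool_tissue")
}

#' Two-compartment (free water + macromolecular) tissue
#'
#' The macromolecular (bound) pool holds a fraction `mf` of the total proton
#' density, relaxes with `t1b_ms` / `t2b_us`, and exchanges longitudinal
#' magnetization with the free pool. `k_exchange_per_s` is the fundamental
#' exchange rate constant: the free-to-bound rate is `k * mf` and the
#' bound-to-free rate `k * (1 - mf)`, which preserves detailed balance.
#'
#' @param t1f_ms,t2f_ms Free-pool relaxation times (ms).
#' @param mf Macromolecular proton fraction in [0, 0.5].
#' @param t1b_ms Bound-pool T1 (ms).
#' @param t2b_us Bound-pool T2 in microseconds (~10 us; sets the RF
#'   absorption lineshape width).
#' @param k_exchange_per_s Fundamental exchange rate constant (1/s).
#' @param pd Total proton density.
#' @return An object of class `two_pool_tissue`.
#' @export
two_pool_tissue <- function(t1f_ms, t2f_ms, mf, t1b_ms = 1000, t2b_us = 10,
                            k_exchange_per_s = 19, pd = 1) {
  if (t2f_ms <= 0) stop("t2f_ms must be positive")
  if (t1f_ms < t2f_ms) stop("t1f_ms must be >= t2f_ms")
  if (mf < 0 || mf > 0.5) stop("mf must lie in [0, 0.5]")
  if (t1b_ms <= 0 || t2b_us <= 0) stop("bound-pool times must be positive")
  if (k_exchange_per_s < 0) stop("k_exchange_per_s must be non-negative")
  if (pd < 0) stop("pd must be non-negative")
  structure(list(t1f_ms = t1f_ms, t2f_ms = t2f_ms, mf = mf, t1b_ms = t1b_ms,
                 t2b_us = t2b_us, k_exchange_per_s = k_exchange_per_s, pd = pd),
            class = "two_pool_tissue")
}

#' Signal evolution curve
#'
#' A signal magnitude sampled at increasing inversion times.
#'
#' @param ti_ms Strictly increasing inversion times (ms).
#' @param values Signal magnitudes, same length as `ti_ms`.
#' @return An object of class `signal_curve`.
#' @export
signal_curve <- function(ti_ms, values) {
  stopifnot(length(ti_ms) == length(values))
  if (length(ti_ms) == 0) stop("empty curve")
  if (any(diff(ti_ms) <= 0)) stop("ti_ms must be strictly increasing")
  if (any(!is.finite(values)) || any(values < 0))
    stop("values must be finite and non-negative (magnitude convention)")
  structure(list(ti_ms = as.numeric(ti_ms), values = as.numeric(values)),
            class = "signal_curve")
}

#' @export
as.data.frame.signal_curve <- function(x, ...) {
  data.frame(ti_ms = x$ti_ms, value = x$values)
}

#' @export
length.signal_curve <- function(x) length(x$values)

#' @export
print.signal_curve <- function(x, ...) {
  cat(sprintf("signal_curve: %d points, TI %g..%g ms\n",
              length(x$values), min(x$ti_ms), max(x$ti_ms)))
  invisible(x)
}

#' Write a signal curve to CSV (columns `ti_ms,value`)
#'
#' @param curve A `signal_curve`.
#' @param path Output file path.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "signal_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Read sequence and tissue parameters from a YAML configuration file
#'
#' The file may contain a `sequence:` block (fields of [seq_params()]) and a
#' `tissues:` block naming tissues; a tissue with an `mf` field is built as a
#' [two_pool_tissue()], otherwise as a [single_pool_tissue()].
#'
#' @param path Path to a YAML file.
#' @return A list with elements `seq` and `tissues`.
#' @export
read_params_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  sq <- do.call(seq_params, cfg$sequence %||% list())
  tissues <- lapply(cfg$tissues %||% list(), function(t) {
    if (!is.null(t$mf)) do.call(two_pool_tissue, t)
    else do.call(single_pool_tissue, t)
  })
  list(seq = sq, tissues = tissues)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
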