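#' Representative brain tissue panel
#'
#' Named list of [single_pool_tissue()] objects for the five tissues used in
#' the scan-parameter optimization: white matter, grey matter, CSF, glioma
#' and edema, with literature relaxation times at 3 T.
#'
#' @param wm,gm,csf,glioma,edema `c(T1, T2)` pairs in ms.
#' @return A named list of tissues (class `tissue_panel`).
#' @export
default_tissue_panel <- function(wm = c(850, 70), gm = c(1400, 90),
                                 csf = c(4000, 1800), glioma = c(1700, 140),
                                 edema = c(1500, 110)) {
  tissue_panel(
    WM = single_pool_tissue(wm[1], wm[2]),
    GM = single_pool_tissue(gm[1], gm[2]),
    CSF = single_pool_tissue(csf[1], csf[2]),
    glioma = single_pool_tissue(glioma[1], glioma[2]),
    edema = single_pool_tissue(edema[1], edema[2]))
}

#' Assemble a named tissue panel
#'
#' @param ... Named [single_pool_tissue()] objects (at least two, unique
#'   names).
#' @return A `tissue_panel` list.
#' @export
tissue_panel <- function(...) {
  panel <- list(...)
  if (length(panel) < 2) stop("a tissue panel needs at least two tissues")
  nm <- names(panel)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("tissues must have unique names")
  if (!all(vapply(panel, inherits, logical(1), "single_pool_tissue")))
    stop("all panel entries must be single_pool_tissue objects")
  structure(panel, class = c("tissue_panel", "list"))
}

#' Sweep amplitude and inter-tissue contrast over flip angle and T_inv
#'
#' For every grid combination of flip angle and inversion interval the
#' frame-averaged signal evolutions of all panel tissues are simulated;
#' `amplitude` is the mean (over tissues and frames) signal magnitude, a
#' surrogate for SNR, and `distance` the mean pairwise Euclidean distance
#' between the tissue curves, a surrogate for inter-tissue contrast. Curves
#' are compared unnormalized on a fixed number of frames so different
#' inversion intervals yield comparable-length vectors.
#'
#' @param panel A [tissue_panel()].
#' @param fa_grid_deg Flip-angle grid (degrees).
#' @param tinv_grid_ms Inversion-interval grid (ms).
#' @param seq_template A [seq_params()] supplying TR, TE, frame count and
#'   convergence settings; its flip angle and T_inv are overridden by the
#'   grids.
#' @return An `opt_surface` with matrices `amplitude` and `distance` of shape
#'   `length(fa_grid_deg) x length(tinv_grid_ms)`.
#' @export
sweep_surfaces <- function(panel, fa_grid_deg = seq(10, 60, by = 2),
                           tinv_grid_ms = seq(1000, 5000, by = 250),
                           seq_template = seq_params()) {
  stopifnot(inherits(panel, "tissue_panel"), inherits(seq_template, "seq_params"))
  if (length(panel) < 2)
    stop("inter-tissue distance is undefined for fewer than two tissues")
  if (!length(fa_grid_deg) || !length(tinv_grid_ms)) stop("empty grid")
  nf <- seq_template$n_frames
  pairs <- utils::combn(length(panel), 2)
  amp <- dst <- matrix(NA_real_, length(fa_grid_deg), length(tinv_grid_ms),
                       dimnames = list(fa_grid_deg, tinv_grid_ms))
  for (it in seq_along(tinv_grid_ms)) {
    for (jf in seq_along(fa_grid_deg)) {
      sq <- seq_params(
        flip_angle_deg = fa_grid_deg[jf], tr_ms = seq_template$tr_ms,
        te_ms = seq_template$te_ms, tinv_ms = tinv_grid_ms[it],
        n_frames = nf, n_cycles_max = seq_template$n_cycles_max,
        convergence_tol = seq_template$convergence_tol,
        catalyze = seq_template$catalyze, pulse_us = seq_template$pulse_us)
      curves <- lapply(panel, function(t)
        frame_average(simulate_single_pool(t, sq), nf, sq$tinv_ms)$values)
      amp[jf, it] <- mean(vapply(curves, mean, numeric(1)))
      dst[jf, it] <- mean(apply(pairs, 2, function(ij)
        sqrt(sum((curves[[ij[1]]] - curves[[ij[2]]])^2))))
    }
  }
  structure(list(fa_grid_deg = fa_grid_deg, tinv_grid_ms = tinv_grid_ms,
                 amplitude = amp, distance = dst),
            class = "opt_surface")
}

#' Joint optimal flip angle over an inversion-interval window
#'
#' For each T_inv in the window, the flip angles maximizing amplitude and
#' maximizing inter-tissue distance are found and averaged; the result is the
#' mean of these per-T_inv averages.
#'
#' @param surface An `opt_surface` from [sweep_surfaces()].
#' @param tinv_lo_ms,tinv_hi_ms Window bounds (ms), inclusive.
#' @return Flip angle in degrees.
#' @export
optimal_fa <- function(surface, tinv_lo_ms = 2500, tinv_hi_ms = 4000) {
  stopifnot(inherits(surface, "opt_surface"))
  win <- surface$tinv_grid_ms >= tinv_lo_ms & surface$tinv_grid_ms <= tinv_hi_ms
  if (!any(win)) stop("window does not intersect the T_inv grid")
  fa_amp <- surface$fa_grid_deg[apply(surface$amplitude[, win, drop = FALSE],
                                      2, which.max)]
  fa_dst <- surface$fa_grid_deg[apply(surface$distance[, win, drop = FALSE],
                                      2, which.max)]
  mean((fa_amp + fa_dst) / 2)
}

#' @export
print.opt_surface <- function(x, ...) {
  cat(sprintf("opt_surface: %d flip angles x %d inversion intervals\n",
              length(x$fa_grid_deg), length(x$tinv_grid_ms)))
  invisible(x)
}

#' @export
as.data.frame.opt_surface <- function(x, ...) {
  data.frame(
    fa_deg = rep(x$fa_grid_deg, times = length(x$tinv_grid_ms)),
    tinv_ms = rep(x$tinv_grid_ms, each = length(x$fa_grid_deg)),
    amplitude = as.vector(x$amplitude),
    distance = as.vector(x$distance))
}
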