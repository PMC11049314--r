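#' Simulate the single-compartment IIR-bSSFP echo train
#'
#' Propagates the Bloch equations for a single water pool through repeated
#' inversion cycles of a balanced SSFP train (instantaneous, sign-alternating
#' excitations; on resonance) until the periodic steady state of the
#' incomplete inversion recovery is reached: magnetization is never reset to
#' M0 between cycles, so consecutive cycles converge geometrically to a limit
#' cycle. The echo magnitudes of the converged cycle are returned, one per TR.
#'
#' Because every event in a cycle is an affine map of the magnetization, the
#' cycle is composed into a single affine map which is iterated; the returned
#' train replays the converged cycle echo by echo.
#'
#' @param tissue A [single_pool_tissue()].
#' @param seq A [seq_params()].
#' @return A [signal_curve()] of length `seq$n_readouts` with attributes
#'   `signed` (signed echoes, for zero-crossing logic), `cycles` and
#'   `residual` (convergence diagnostics).
#' @examples
#' wm <- single_pool_tissue(850, 70)
#' sq <- seq_params(30, tr_ms = 4, tinv_ms = 3000)
#' curve <- simulate_single_pool(wm, sq)
#' @seealso [simulate_two_pool()], [frame_average()]
#' @export
simulate_single_pool <- function(tissue, seq) {
  stopifnot(inherits(tissue, "single_pool_tissue"), inherits(seq, "seq_params"))
  t1 <- tissue$t1_ms; t2 <- tissue$t2_ms; m0 <- tissue$pd
  a <- seq$flip_angle_deg * pi / 180
  tr <- seq$tr_ms; te <- seq$te_ms; n <- seq$n_readouts

  rot <- function(th) matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  relax_A <- function(t) diag(c(exp(-t / t2), exp(-t / t1)))
  relax_b <- function(t) c(0, (1 - exp(-t / t1)) * m0)

  Atr <- relax_A(tr); btr <- relax_b(tr)
  Ah <- relax_A(tr / 2); bh <- relax_b(tr / 2)
  e2te <- exp(-te / t2)
  Rp <- rot(a); Rm <- rot(-a); Rc <- rot(-a / 2)
  SpA <- Atr %*% Rp; SmA <- Atr %*% Rm

  # compose one inversion cycle: inversion, catalyzation, n readout steps
  A <- matrix(c(0, 0, 0, -1), 2, 2)   # crush transverse, invert Mz
  b <- c(0, 0)
  if (seq$catalyze) {
    A <- Ah %*% Rc %*% A
    b <- as.vector(Ah %*% Rc %*% b) + bh
  }
  for (j in seq_len(n)) {
    if (j %% 2L == 1L) {
      A <- SpA %*% A; b <- as.vector(SpA %*% b) + btr
    } else {
      A <- SmA %*% A; b <- as.vector(SmA %*% b) + btr
    }
  }

  s <- c(0, m0)
  cycles <- 0L; residual <- 0
  converged <- m0 == 0
  for (ic in seq_len(seq$n_cycles_max)) {
    s2 <- as.vector(A %*% s) + b
    dmax <- max(abs(s2 - s)); smax <- max(abs(s2))
    s <- s2; cycles <- ic
    residual <- if (smax > 1e-300) dmax / smax else 0
    if (residual < seq$convergence_tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf(
      "periodic steady state not reached in %d cycles (relative residual %.3g)",
      seq$n_cycles_max, residual))

  # replay the converged cycle, recording echoes at TE
  s <- c(0, -s[2])
  t0 <- 0
  if (seq$catalyze) { s <- as.vector(Ah %*% (Rc %*% s)) + bh; t0 <- tr / 2 }
  ech <- numeric(n)
  for (j in seq_len(n)) {
    sp <- if (j %% 2L == 1L) Rp %*% s else Rm %*% s
    ech[j] <- sp[1] * e2te
    s <- as.vector(Atr %*% sp) + btr
  }
  ti <- t0 + (seq_len(n) - 1) * tr + te
  out <- signal_curve(ti, abs(ech))
  attr(out, "signed") <- ech
  attr(out, "cycles") <- cycles
  attr(out, "residual") <- residual
  out
}

#' Simulate the two-compartment (magnetization-transfer) IIR-bSSFP echo train
#'
#' Propagates a free water pool and a macromolecular bound pool coupled by
#' Bloch-McConnell longitudinal exchange through the same IIR-bSSFP sequence
#' as [simulate_single_pool()]. The free pool sees instantaneous rotations;
#' the bound pool has no observable transverse magnetization and is instead
#' saturated by each RF pulse at a rate set by its super-Lorentzian
#' absorption lineshape evaluated on resonance (see
#' [super_lorentzian_g0()]), for an equivalent rectangular pulse of duration
#' `seq$pulse_us`.
#'
#' With `mf = 0` and `k_exchange_per_s = 0` the model reduces exactly to the
#' single-compartment simulation.
#'
#' @inheritParams simulate_single_pool
#' @param tissue A [two_pool_tissue()].
#' @return A [signal_curve()] of length `seq$n_readouts` (attributes as in
#'   [simulate_single_pool()]).
#' @export
simulate_two_pool <- function(tissue, seq) {
  stopifnot(inherits(tissue, "two_pool_tissue"), inherits(seq, "seq_params"))
  sat <- bound_saturation(seq$flip_angle_deg, seq$pulse_us, tissue$t2b_us)
  res <- .cpp_two_pool_train(
    tissue$t1f_ms, tissue$t2f_ms, tissue$mf, tissue$t1b_ms,
    tissue$k_exchange_per_s, tissue$pd, seq$flip_angle_deg, seq$tr_ms,
    seq$te_ms, seq$n_readouts, sat$pulse, sat$catalyze, seq$catalyze,
    seq$invert_bound, seq$n_cycles_max, seq$convergence_tol)
  if (!res$converged && tissue$pd > 0)
    stop(sprintf(
      "periodic steady state not reached in %d cycles (relative residual %.3g)",
      seq$n_cycles_max, res$residual))
  t0 <- if (seq$catalyze) seq$tr_ms / 2 else 0
  ti <- t0 + (seq_len(seq$n_readouts) - 1) * seq$tr_ms + seq$te_ms
  out <- signal_curve(ti, abs(res$signed))
  attr(out, "signed") <- res$signed
  attr(out, "cycles") <- res$cycles
  attr(out, "residual") <- res$residual
  out
}

#' Average an echo train into equal inversion-time windows
#'
#' The inversion interval is split into `n_frames` windows of width
#' `tinv_ms / n_frames`; each output value is the mean of the echoes whose
#' time falls in that window and its TI is the window center. This mirrors
#' the temporal footprint of the frame-by-frame reconstruction (for
#' `tinv_ms = 3000` and 20 frames, 150 ms per TI).
#'
#' @param curve A [signal_curve()] echo train.
#' @param n_frames Number of output frames; must not exceed the train length.
#' @param tinv_ms Inversion interval spanned by the train (ms).
#' @return A [signal_curve()] with `n_frames` points.
#' @export
frame_average <- function(curve, n_frames, tinv_ms) {
  stopifnot(inherits(curve, "signal_curve"))
  n <- length(curve$values)
  if (n_frames > n) stop("n_frames must not exceed the echo-train length")
  w <- tinv_ms / n_frames
  idx <- pmin(pmax(ceiling(curve$ti_ms / w), 1L), n_frames)
  cnt <- tabulate(idx, nbins = n_frames)
  if (any(cnt == 0))
    stop("empty TI window; echo train does not cover all frames")
  vals <- as.vector(tapply(curve$values, factor(idx, levels = seq_len(n_frames)),
                           mean))
  out <- signal_curve((seq_len(n_frames) - 0.5) * w, vals)
  sg <- attr(curve, "signed")
  if (!is.null(sg))
    attr(out, "signed") <- as.vector(
      tapply(sg, factor(idx, levels = seq_len(n_frames)), mean))
  out
}

#' Apparent relaxation time of the bSSFP transient
#'
#' The approach of a balanced SSFP train to its steady state is exponential
#' with apparent rate `1/T1* = cos^2(a/2)/T1 + sin^2(a/2)/T2`. Used as an
#' independent oracle for the simulated transient envelope.
#'
#' @inheritParams simulate_single_pool
#' @return Apparent relaxation time T1* in ms.
#' @export
apparent_relaxation <- function(tissue, seq) {
  stopifnot(inherits(tissue, "single_pool_tissue"), inherits(seq, "seq_params"))
  a <- seq$flip_angle_deg * pi / 180
  1 / (cos(a / 2)^2 / tissue$t1_ms + sin(a / 2)^2 / tissue$t2_ms)
}

#' Closed-form on-resonance bSSFP steady-state amplitude
#'
#' `M0 sin(a) / ((T1/T2 + 1) - cos(a) (T1/T2 - 1))`, the TR << T1,T2 limit of
#' the balanced SSFP steady state at the centered echo. Serves as an
#' independent oracle for the late echoes of a long simulated train.
#'
#' @inheritParams simulate_single_pool
#' @param flip_angle_deg Flip angle in degrees.
#' @return Steady-state echo amplitude (same scale as `tissue$pd`).
#' @export
bssfp_steady_state <- function(tissue, flip_angle_deg) {
  stopifnot(inherits(tissue, "single_pool_tissue"))
  a <- flip_angle_deg * pi / 180
  r <- tissue$t1_ms / tissue$t2_ms
  tissue$pd * sin(a) / ((r + 1) - cos(a) * (r - 1))
}

#' Fit the transient decay rate of a simulated echo train
#'
#' De-alternates the signed echo train (the sign-alternating excitation makes
#' consecutive signed echoes alternate), takes the final echo as the steady
#' state, and fits `log |s(t) - s_inf|` against TI by least squares over the
#' early transient (TI below `t_max_ms`).
#'
#' @param curve A [signal_curve()] carrying a `signed` attribute, as returned
#'   by [simulate_single_pool()].
#' @param t_max_ms Upper TI bound of the fitting window (default: half the
#'   train).
#' @return Fitted apparent relaxation time in ms.
#' @export
fit_transient_rate <- function(curve, t_max_ms = max(curve$ti_ms) / 2) {
  sg <- attr(curve, "signed")
  if (is.null(sg)) stop("curve must carry a 'signed' attribute")
  q <- sg * rep_len(c(1, -1), length(sg))
  if (mean(utils::tail(q, 32)) < 0) q <- -q
  s_inf <- q[length(q)]
  res <- q - s_inf
  sel <- curve$ti_ms < t_max_ms & abs(res) > 1e-6 * abs(s_inf)
  if (sum(sel) < 8) stop("too few transient points to fit")
  fit <- stats::lm(log(abs(res[sel])) ~ curve$ti_ms[sel])
  -1 / stats::coef(fit)[[2]]
}

#' On-resonance super-Lorentzian lineshape value
#'
#' Absorption lineshape of the macromolecular pool, `G(delta)`, for bound-pool
#' transverse relaxation time `t2b_us`. The super-Lorentzian diverges at zero
#' offset, so the on-resonance value is obtained, as is standard practice, by
#' extrapolating a quadratic fitted to `G` over offsets of 1-2 kHz down to
#' 0 Hz.
#'
#' @param t2b_us Bound-pool T2 in microseconds.
#' @param fit_khz Offsets (kHz) used for the extrapolation.
#' @return Lineshape value at zero offset, in seconds.
#' @export
super_lorentzian_g0 <- function(t2b_us, fit_khz = seq(1, 2, by = 0.1)) {
  t2b <- t2b_us * 1e-6
  g <- vapply(fit_khz * 1000, function(delta) {
    stats::integrate(function(u) {
      x <- abs(3 * u^2 - 1)
      sqrt(2 / pi) * t2b / x * exp(-2 * (2 * pi * delta * t2b / x)^2)
    }, 0, 1, rel.tol = 1e-9, subdivisions = 600L)$value
  }, numeric(1))
  d <- fit_khz * 1000
  unname(stats::coef(stats::lm(g ~ d + I(d^2)))[1])
}

# per-pulse bound-pool saturation factors for the readout and catalyzation
# pulses: exp(-pi * w1^2 * G(0) * tau) with w1 = alpha / tau
bound_saturation <- function(fa_deg, pulse_us, t2b_us) {
  g0 <- super_lorentzian_g0(t2b_us)
  tau <- pulse_us * 1e-6
  w1 <- (fa_deg * pi / 180) / tau
  w1c <- w1 / 2
  list(pulse = exp(-pi * w1^2 * g0 * tau),
       catalyze = exp(-pi * w1c^2 * g0 * tau))
}
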