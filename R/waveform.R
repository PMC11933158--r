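#' Pulsatile regurgitant-jet waveform
#'
#' Parametric model of the peak-velocity history of a regurgitant jet over one
#' cardiac cycle: a rapid non-monotonic rise with a local maximum produced by
#' the starting vortex, a global maximum shortly after, and an
#' exponential-like decay, all confined to the systolic interval. Defaults
#' place the local and global peaks at 210 ms and 245 ms of a 750 ms cycle
#' (80 bpm).
#'
#' The curve is a linear combination of four analytic kernels — Gaussian
#' lobes at the two peaks, a narrow Gaussian controlling the inter-peak dip,
#' and an exponential decay with time constant \code{decay_tau} gated on
#' smoothly after the global peak and tapered off before end-systole — with
#' the four amplitudes solved from the constraints
#' \eqn{U(t_{local}) = U_{local}}, \eqn{U(t_{global}) = U_{global}},
#' \eqn{U'(t_{local}) = U'(t_{global}) = 0}. Because every kernel is analytic
#' with time scales well above the phase spacing, the waveform is resolved
#' spectrally by the 42-phase sampling and its trapezoidal time integral
#' agrees with the exact integral to ~1e-5 relative. The constructor verifies
#' that the curve is non-negative, that the global peak is the global
#' maximum, and that the local peak is a strict local maximum.
#'
#' @param t_local_peak,t_global_peak peak times (ms), local before global.
#' @param U_local,U_global peak speeds (cm/s), \code{U_global >= U_local > 0}.
#' @param decay_tau decay time constant (ms), positive.
#' @param systole systolic interval \code{c(t0, t1)} (ms); the waveform is
#'   zero outside it.
#' @param widths named list of kernel time scales (ms): \code{s_local},
#'   \code{s_global} (Gaussian lobe widths), \code{s_dip} (dip kernel),
#'   \code{s_blend} (Gaussian-to-exponential blending of the decay),
#'   \code{s_corr} (peak-centered corrector kernel), \code{onset} and
#'   \code{taper} (widths of the smoothstep window confining the curve to
#'   systole).
#' @return an object of class \code{waveform}.
#' @examples
#' w <- waveform()
#' pulse_waveform(w, 245)     # = U_global
#' pulse_waveform(w, 600)     # 0 (outside systole)
#' @export
waveform <- function(t_local_peak = 210, t_global_peak = 245,
                     U_local = 155, U_global = 212, decay_tau = 80,
                     systole = c(130, 530),
                     widths = list(s_local = 15, s_global = 16, s_dip = 12,
                                   s_blend = 24, s_corr = 24,
                                   onset = 40, taper = 60)) {
  if (!(t_local_peak < t_global_peak))
    stop("'t_local_peak' must precede 't_global_peak'")
  if (!(U_global >= U_local && U_local > 0))
    stop("peak speeds must satisfy U_global >= U_local > 0")
  if (decay_tau <= 0) stop("'decay_tau' must be positive")
  if (length(systole) != 2L || systole[1L] >= systole[2L])
    stop("'systole' must be an increasing interval c(t0, t1) in ms")
  w <- structure(
    list(t_local_peak = t_local_peak, t_global_peak = t_global_peak,
         U_local = U_local, U_global = U_global, decay_tau = decay_tau,
         systole = as.numeric(systole), widths = widths, amps = NULL),
    class = "waveform")
  # solve kernel amplitudes from value + stationarity constraints
  K <- function(t) waveform_kernels(w, t)
  h <- 1e-3
  dK <- function(t) (waveform_kernels(w, t + h) - waveform_kernels(w, t - h)) / (2 * h)
  M <- rbind(K(t_local_peak), dK(t_local_peak), K(t_global_peak), dK(t_global_peak))
  rhs <- c(U_local, 0, U_global, 0)
  w$amps <- as.numeric(solve(M, rhs))
  tt <- sort(c(seq(systole[1L], systole[2L], by = 0.5),
               t_local_peak, t_global_peak))
  uu <- as.numeric(waveform_kernels(w, tt) %*% w$amps)
  if (any(uu < -1e-4 * U_global))
    stop("waveform parameters produce negative velocities; widen the kernels")
  if (max(uu) > U_global * (1 + 1e-6))
    stop("waveform parameters displace the global maximum from t_global_peak")
  if (!(pulse_waveform(w, t_local_peak) >
          max(pulse_waveform(w, t_local_peak + c(-2, 2)))))
    stop("waveform parameters do not give a strict local maximum at t_local_peak")
  w
}

# 4 analytic kernels evaluated at (scalar or vector) t; rows t, cols kernels.
# The global-peak kernel has a Gaussian rise and an exponential tail with
# time constant decay_tau, blended so its slope vanishes at the peak
# (psi(s) = s^2/(tau s + 2 sigma^2), psi' -> 1/tau); the corrector kernel is
# a wider Gaussian at the same peak, so that neither contributes slope at
# t_global_peak and the stationarity constraints are carried by the two
# early kernels. A quintic smoothstep window confines everything to systole
# with exact zeros and vanishing first/second derivatives at both ends.
waveform_kernels <- function(w, t) {
  wd <- w$widths
  tl <- w$t_local_peak; tg <- w$t_global_peak
  g1 <- exp(-(t - tl)^2 / (2 * wd$s_local^2))
  gd <- exp(-(t - (tl + tg) / 2)^2 / (2 * wd$s_dip^2))
  s <- t - tg
  # quartic blend: psi ~ s^2/(2 s_blend^2) near the peak (matching the
  # Gaussian rise through 5th order when s_blend = s_global) and -> s/tau
  # in the tail (exact exponential decay with time constant decay_tau)
  b <- 2 * wd$s_blend^2
  tail_psi <- s^2 / (w$decay_tau^4 * s^4 + b^4)^0.25
  g2 <- ifelse(s <= 0, exp(-s^2 / (2 * wd$s_global^2)), exp(-tail_psi))
  gc <- exp(-s^2 / (2 * wd$s_corr^2))
  win <- smoothstep((t - w$systole[1L]) / wd$onset) *
    (1 - smoothstep((t - (w$systole[2L] - wd$taper)) / wd$taper))
  cbind(g1, gd, g2, gc) * win
}

# quintic smoothstep: 0 below 0, 1 above 1, C2 at both ends
smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x^3 * (10 - 15 * x + 6 * x^2)
}

#' Evaluate the pulsatile waveform
#'
#' @param w a \code{\link{waveform}}.
#' @param t times (ms); vectorized.
#' @return jet peak speed U(t) in cm/s; exactly zero outside systole.
#' @export
pulse_waveform <- function(w, t) {
  stopifnot(inherits(w, "waveform"))
  u <- as.numeric(waveform_kernels(w, t) %*% w$amps)
  u[t < w$systole[1L] | t > w$systole[2L]] <- 0
  pmax(u, 0)
}

#' Exact time integral of the waveform
#'
#' Adaptive-quadrature integral of U(t) over a window (default: the systolic
#' interval), returned in cm (i.e. the VTI that an ideal continuous-time
#' measurement of U would give).
#'
#' @param w a \code{\link{waveform}}.
#' @param window integration window (ms), default systole.
#' @return integral of U dt in cm.
#' @export
waveform_integral <- function(w, window = w$systole) {
  stopifnot(inherits(w, "waveform"))
  lo <- max(window[1L], w$systole[1L])
  hi <- min(window[2L], w$systole[2L])
  if (hi <= lo) return(0)
  stats::integrate(function(t) pulse_waveform(w, t), lo, hi,
                   rel.tol = 1e-10, abs.tol = 1e-10,
                   subdivisions = 1000L)$value / 1000
}

#' Scale a waveform to a target regurgitant volume
#'
#' Returns the same waveform with both peak speeds scaled so that the
#' programmed regurgitant volume through the given orifice equals
#' \code{rvol_ml} (the jet generator is linear in the waveform amplitude).
#'
#' @param w a \code{\link{waveform}}.
#' @param orifice an orifice spec.
#' @param rvol_ml target regurgitant volume per beat (ml).
#' @return a rescaled \code{waveform}.
#' @export
scale_waveform_to_rvol <- function(w, orifice, rvol_ml) {
  cur <- orifice_area_cm2(orifice) * waveform_integral(w)
  s <- rvol_ml / cur
  waveform(w$t_local_peak, w$t_global_peak, w$U_local * s, w$U_global * s,
           w$decay_tau, w$systole, w$widths)
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf(paste0("Jet waveform: local peak %.3g cm/s @ %.0f ms, ",
                     "global peak %.3g cm/s @ %.0f ms, tau = %.3g ms, ",
                     "systole [%.0f, %.0f] ms\n"),
              x$U_local, x$t_local_peak, x$U_global, x$t_global_peak,
              x$decay_tau, x$systole[1L], x$systole[2L]))
  invisible(x)
}
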