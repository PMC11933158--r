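#' Ultrasound beam specification
#'
#' The Doppler measurement returns only the velocity component aligned with
#' the beam. The beam is described by its tilt relative to the flow axis
#' (the -x direction, i.e. a probe viewing the orifice head-on from the jet
#' side) and the point it is aimed at (default the orifice centroid).
#'
#' @param tilt_deg tilt angle to the -x axis, in degrees, in [0, 90).
#' @param origin aim point (cm), default \code{c(0, 0)} (orifice centroid).
#' @return object of class \code{beam_spec} with the unit \code{direction}
#'   of beam propagation.
#' @export
beam_spec <- function(tilt_deg = 0, origin = c(0, 0)) {
  if (tilt_deg < 0 || tilt_deg >= 90)
    stop("'tilt_deg' must lie in [0, 90)")
  th <- tilt_deg * pi / 180
  structure(list(direction = c(-cos(th), -sin(th), 0),
                 origin = c(origin, 0)[1:3], tilt_deg = tilt_deg),
            class = "beam_spec")
}

#' @export
print.beam_spec <- function(x, ...) {
  cat(sprintf("Beam: tilt %.1f deg to the flow axis, origin (%.2f, %.2f) cm\n",
              x$tilt_deg, x$origin[1L], x$origin[2L]))
  invisible(x)
}

#' Project a velocity field onto the beam direction
#'
#' Pointwise inner product of the velocity with the beam direction, with the
#' sign convention that velocities toward the probe are positive (so the
#' converging flow upstream of the orifice projects positive for an aligned
#' beam).
#'
#' @param field a \code{\link{velocity_field}}.
#' @param beam a \code{\link{beam_spec}}.
#' @return object of class \code{projected_field}: the grid plus the scalar
#'   component \code{vp} (cm/s).
#' @export
beam_project <- function(field, beam = beam_spec()) {
  stopifnot(inherits(field, "velocity_field"), inherits(beam, "beam_spec"))
  d <- beam$direction
  vp <- -(field$u * d[1L] + field$v * d[2L])
  if (!is.null(field$w)) vp <- vp - field$w * d[3L]
  structure(list(x = field$x, y = field$y, z = field$z, vp = vp, beam = beam),
            class = "projected_field")
}

# projected velocity along the scan ray (-x axis from the beam origin) at
# distances s (cm); works for projected fields (interpolation) and for
# analytic convergence models (exact evaluation)
ray_profile <- function(obj, beam, s) {
  o <- beam$origin
  pts <- cbind(o[1L] - s, o[2L] + 0 * s, o[3L] + 0 * s)
  if (inherits(obj, "projected_field")) {
    interp_component(obj, if (is.null(obj$z)) pts[, 1:2] else pts, "vp")
  } else if (inherits(obj, "sink_flow_spec")) {
    vel <- sink_velocity(obj, pts)
    -as.numeric(vel %*% beam$direction)
  } else stop("unsupported object for ray evaluation")
}

#' Extract the PISA radius at an aliasing velocity
#'
#' Scans from the orifice center along the flow axis (the x axis, per the
#' color-Doppler practice of reading the first aliasing envelope on the
#' centerline) and returns the distance to the farthest contiguous point
#' whose beam-projected velocity still reaches the aliasing velocity,
#' refined sub-cell by linear interpolation between the bracketing samples.
#' Contiguity from the orifice guards against detached noise islands.
#'
#' @param projected a \code{\link{beam_project}} result, or a
#'   \code{\link{sink_flow_spec}} (evaluated analytically on the ray).
#' @param beam the \code{\link{beam_spec}} (also defines the scan origin).
#' @param Va aliasing velocity (cm/s), positive.
#' @param ds ray sampling step (cm); default half the finest grid spacing
#'   (0.005 cm for analytic models).
#' @param s_max maximum scan distance (cm); default the grid extent (8 cm
#'   for analytic models).
#' @return PISA radius r (cm).
#' @examples
#' g <- list(x = seq(-2.5, -0.05, by = 0.025), y = seq(-0.4, 0.4, by = 0.025))
#' pf <- beam_project(point_sink_field(244.9, g))
#' pisa_radius(pf, beam_spec(), Va = 20)   # ~1.396 = sqrt(Q / (2 pi Va))
#' @export
pisa_radius <- function(projected, beam = beam_spec(), Va, ds = NULL,
                        s_max = NULL) {
  if (Va <= 0) stop("'Va' must be positive")
  if (inherits(projected, "projected_field")) {
    sp <- min(c(if (length(projected$x) > 1L) diff(projected$x) else Inf,
                if (length(projected$y) > 1L) diff(projected$y) else Inf))
    if (is.null(ds)) ds <- sp / 2
    if (is.null(s_max)) s_max <- beam$origin[1L] - min(projected$x)
  } else {
    if (is.null(ds)) ds <- 0.005
    if (is.null(s_max)) s_max <- 8
  }
  s0 <- if (inherits(projected, "sink_flow_spec")) ray_start(projected) else ds
  s <- seq(max(ds, s0), s_max, by = ds)
  vp <- ray_profile(projected, beam, s)
  keep <- !is.na(vp)
  # the ray enters the grid at the first covered sample
  first <- which(keep)[1L]
  if (is.na(first)) stop("scan ray does not intersect the grid")
  last <- if (any(!keep[first:length(s)]))
    first + which(!keep[first:length(s)])[1L] - 2L else length(s)
  s <- s[first:last]; vp <- vp[first:last]
  radius_from_ray(s, vp, Va)
}

radius_from_ray <- function(s, vp, Va) {
  if (vp[1L] < Va)
    stop("aliasing velocity too high: no isovelocity crossing on the ray")
  below <- which(vp < Va)
  if (!length(below))
    stop("isovelocity contour outside the sampled domain; lower Va or extend the grid")
  k <- below[1L]
  s[k - 1L] + (vp[k - 1L] - Va) / (vp[k - 1L] - vp[k]) * (s[k] - s[k - 1L])
}

#' Regurgitant flow from the flow-convergence relation
#'
#' The hemispheric-shell relation \eqn{RFlow = 2\pi r^2 V_a}: the proximal
#' isovelocity surface area \eqn{2\pi r^2} times the aliasing velocity.
#'
#' @param r PISA radius (cm), >= 0.
#' @param Va aliasing velocity (cm/s), > 0.
#' @return regurgitant flow (ml/s).
#' @examples
#' regurgitant_flow(1.0, 40)    # 251.33 ml/s
#' @export
regurgitant_flow <- function(r, Va) {
  if (any(r < 0)) stop("'r' must be non-negative")
  if (any(Va <= 0)) stop("'Va' must be positive")
  2 * pi * r^2 * Va
}

#' Peak jet velocity and velocity-time integral
#'
#' Per phase, the maximum beam-projected velocity within 20 mm of the
#' orifice along the jet (the CW-Doppler envelope analog); the systolic
#' window then gives \eqn{V_{max}} (the window maximum) and VTI (the
#' trapezoidal time integral of the per-phase maxima). If the grid contains
#' no jet side (steady convergence-zone fields), the near-orifice region of
#' the convergence side is used.
#'
#' @param series a \code{\link{field_series}}, or a data frame with columns
#'   \code{t} (ms) and \code{v} (cm/s) giving a velocity trace directly.
#' @param window systolic window \code{c(t0, t1)} in ms. Required for
#'   single-phase (steady) series, where the trace is constant over the
#'   window; for measured series it defaults to the contiguous interval
#'   where the trace stays above 10\% of its peak.
#' @param beam a \code{\link{beam_spec}}.
#' @param reach search reach from the orifice plane (cm), default 2.
#' @return list with \code{Vmax} (cm/s), \code{VTI} (cm) and the per-phase
#'   \code{trace} data frame.
#' @export
vmax_and_vti <- function(series, window = NULL, beam = beam_spec(),
                         reach = 2) {
  if (is.data.frame(series)) {
    tr <- data.frame(t = series$t, v = series$v)
  } else {
    stopifnot(inherits(series, "field_series"))
    f0 <- series$fields[[1L]]
    xr <- if (any(f0$x >= 0)) f0$x >= 0 & f0$x <= reach else abs(f0$x) <= reach
    if (!any(xr)) stop("no grid points within the search reach of the orifice")
    vm <- vapply(series$fields, function(f) {
      pf <- beam_project(f, beam)
      sub <- if (is.null(f$z)) pf$vp[xr, , drop = FALSE] else
        pf$vp[xr, , , drop = FALSE]
      max(sub)
    }, numeric(1L))
    tr <- data.frame(t = series$times, v = vm)
  }
  if (nrow(tr) == 1L) {
    if (is.null(window))
      stop("'window' is required for a single-phase (steady) series")
    vmax <- max(tr$v, 0)
    return(list(Vmax = vmax, VTI = vmax * diff(window) / 1000, trace = tr))
  }
  if (is.null(window)) window <- systole_window(tr$t, tr$v)
  if (window[2L] <= window[1L]) stop("empty systolic window")
  vmax_t <- trace_in_window(tr$t, tr$v, window)
  vmax <- max(vmax_t$v, 0)
  vti <- pracma::trapz(vmax_t$t, vmax_t$v) / 1000
  list(Vmax = vmax, VTI = vti, trace = tr, window = window)
}

# contiguous interval around the trace peak where v >= 10% of the peak
systole_window <- function(t, v) {
  pk <- which.max(v)
  if (v[pk] <= 0) return(c(t[1L], t[1L]))
  thr <- 0.1 * v[pk]
  lo <- pk; while (lo > 1L && v[lo - 1L] >= thr) lo <- lo - 1L
  hi <- pk; while (hi < length(v) && v[hi + 1L] >= thr) hi <- hi + 1L
  c(t[lo], t[hi])
}

# clip a sampled trace to a window, interpolating the endpoints
trace_in_window <- function(t, v, window) {
  lo <- max(window[1L], min(t)); hi <- min(window[2L], max(t))
  inside <- t > lo & t < hi
  tt <- c(lo, t[inside], hi)
  vv <- c(stats::approx(t, v, lo)$y, v[inside], stats::approx(t, v, hi)$y)
  list(t = tt, v = vv)
}

#' Effective regurgitant orifice area
#'
#' \eqn{EROa = RFlow / V_{max}}: the regurgitant flow divided by the peak
#' jet velocity.
#'
#' @param RFlow regurgitant flow (ml/s), >= 0.
#' @param Vmax peak jet velocity (cm/s), > 0 (unless RFlow is 0, in which
#'   case EROa is 0).
#' @return EROa in cm^2.
#' @export
eroa <- function(RFlow, Vmax) {
  if (any(RFlow < 0)) stop("'RFlow' must be non-negative")
  if (any(Vmax <= 0 & RFlow > 0)) stop("'Vmax' must be positive")
  ifelse(RFlow == 0, 0, RFlow / Vmax)
}

#' Regurgitant volume per beat
#'
#' \eqn{RVol = EROa \cdot VTI}.
#'
#' @param EROa effective regurgitant orifice area (cm^2), >= 0.
#' @param VTI velocity-time integral (cm), >= 0.
#' @return RVol in ml.
#' @export
rvol <- function(EROa, VTI) {
  if (any(EROa < 0) || any(VTI < 0)) stop("inputs must be non-negative")
  EROa * VTI
}

#' Full clinical flow-convergence estimate
#'
#' Runs the complete chain a physician performs at the machine: beam-project
#' the field, read the PISA radius at the chosen aliasing velocity at the
#' phase of peak jet velocity, convert to regurgitant flow
#' (\eqn{2\pi r^2 V_a}), read \eqn{V_{max}} and VTI from the systolic
#' window, and chain to EROa and RVol.
#'
#' @param series a \code{\link{field_series}} (single-phase series represent
#'   steady flow and need an explicit \code{window}).
#' @param Va aliasing velocity (cm/s).
#' @param beam a \code{\link{beam_spec}}.
#' @param window systolic window (ms); see \code{\link{vmax_and_vti}}.
#' @param conv optional separate convergence-zone input used for the radius
#'   extraction: a \code{\link{velocity_field}} or a
#'   \code{\link{sink_flow_spec}} (evaluated analytically). Defaults to the
#'   series' own field at the phase of peak velocity.
#' @param phase_mode \code{"peak"} (freeze the frame at peak systole,
#'   clinical practice) or \code{"average"} (average the radius over the
#'   window phases).
#' @param ... passed to \code{\link{pisa_radius}}.
#' @return object of class \code{pisa_measurement} with fields \code{Va},
#'   \code{r}, \code{RFlow}, \code{Vmax}, \code{VTI}, \code{EROa},
#'   \code{RVol} and \code{phase_t}.
#' @export
pisa_estimate <- function(series, Va, beam = beam_spec(), window = NULL,
                          conv = NULL, phase_mode = c("peak", "average"),
                          ...) {
  stopifnot(inherits(series, "field_series"))
  phase_mode <- match.arg(phase_mode)
  vv <- vmax_and_vti(series, window = window, beam = beam)
  if (vv$Vmax <= 0) {
    out <- list(Va = Va, r = 0, RFlow = 0, Vmax = 0, VTI = 0, EROa = 0,
                RVol = 0, phase_t = NA_real_)
    class(out) <- "pisa_measurement"
    return(out)
  }
  pk <- which.max(vv$trace$v)
  radius_one <- function(obj) {
    proj <- if (inherits(obj, "velocity_field")) beam_project(obj, beam) else obj
    pisa_radius(proj, beam, Va, ...)
  }
  r <- if (!is.null(conv)) {
    radius_one(conv)
  } else if (phase_mode == "peak") {
    radius_one(series$fields[[pk]])
  } else {
    win <- vv$window %||% window
    in_win <- series$times >= win[1L] & series$times <= win[2L]
    mean(vapply(series$fields[in_win], radius_one, numeric(1L)))
  }
  RFlow <- regurgitant_flow(r, Va)
  ER <- eroa(RFlow, vv$Vmax)
  out <- list(Va = Va, r = r, RFlow = RFlow, Vmax = vv$Vmax, VTI = vv$VTI,
              EROa = ER, RVol = rvol(ER, vv$VTI),
              phase_t = vv$trace$t[pk])
  class(out) <- "pisa_measurement"
  out
}

#' @export
print.pisa_measurement <- function(x, ...) {
  cat(sprintf(paste0("PISA estimate @ Va = %.3g cm/s:\n",
                     "  r = %.3f cm, RFlow = %.1f ml/s\n",
                     "  Vmax = %.1f cm/s, VTI = %.2f cm\n",
                     "  EROa = %.3f cm^2, RVol = %.2f ml\n"),
              x$Va, x$r, x$RFlow, x$Vmax, x$VTI, x$EROa, x$RVol))
  invisible(x)
}

#' @export
as.data.frame.pisa_measurement <- function(x, ...) {
  data.frame(Va = x$Va, r = x$r, RFlow = x$RFlow, Vmax = x$Vmax,
             VTI = x$VTI, EROa = x$EROa, RVol = x$RVol)
}
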