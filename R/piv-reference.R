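# shared station quadrature: planar = trapezoidal integral of u over y
# (per unit depth); axisymmetric = revolution of the profile, pi*|y| weight
# over a two-sided profile or 2*pi*y over a half profile
flux_quadrature <- function(y, uy, mode = c("planar", "axisymmetric")) {
  mode <- match.arg(mode)
  if (mode == "planar") return(pracma::trapz(y, uy))
  if (min(y) < 0) pracma::trapz(y, uy * pi * abs(y)) else
    pracma::trapz(y, uy * 2 * pi * y)
}

# composite trapezoid weights so that sum(w * f) == trapz(x, f)
trapz_weights <- function(x) {
  n <- length(x)
  if (n == 1L) return(1)
  w <- numeric(n)
  dx <- diff(x)
  w[1L] <- dx[1L] / 2; w[n] <- dx[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (dx[-(n - 1L)] + dx[-1L]) / 2
  w
}

# weights applying trapezoidal integration over a clipped window to a
# sampled trace (linear endpoint interpolation); RVol stays linear in the
# per-phase values, which the bootstrap exploits
window_weights <- function(t, window) {
  lo <- max(window[1L], min(t)); hi <- min(window[2L], max(t))
  if (hi <= lo) stop("empty integration window")
  base <- diag(length(t))
  vapply(seq_along(t), function(i) {
    tw <- trace_in_window(t, base[, i], window)
    pracma::trapz(tw$t, tw$v)
  }, numeric(1L))
}

#' Streamwise flux through a station
#'
#' Integrates the streamwise velocity u across a station x = const:
#' \code{"planar"} gives the per-unit-depth flow \eqn{\int u\,dy} (ml/s per
#' cm) of one measurement plane; \code{"axisymmetric"} revolves the profile
#' around the jet axis, \eqn{\int u\,2\pi|y|\,dy} over the half profile,
#' giving the full flow (ml/s) from a single mid-plane. The station is
#' interpolated linearly between grid x positions.
#'
#' @param field a \code{\link{velocity_field}}.
#' @param x_station station position (cm), inside the grid.
#' @param mode \code{"planar"} or \code{"axisymmetric"}.
#' @param z_plane for 3D fields in planar mode: the plane to evaluate
#'   (interpolated in z); ignored for 2D fields.
#' @return flux (ml/s, or ml/s per cm for planar mode).
#' @export
station_flux <- function(field, x_station, mode = c("planar", "axisymmetric"),
                         z_plane = NULL) {
  stopifnot(inherits(field, "velocity_field"))
  mode <- match.arg(mode)
  if (x_station < min(field$x) - 1e-12 || x_station > max(field$x) + 1e-12)
    stop("'x_station' lies outside the grid")
  if (is.null(field$z)) {
    pts <- cbind(rep(x_station, length(field$y)), field$y)
  } else {
    zp <- z_plane %||% 0
    pts <- cbind(rep(x_station, length(field$y)), field$y,
                 rep(zp, length(field$y)))
  }
  prof <- interp_component(field, pts, "u")
  if (anyNA(prof)) stop("station profile leaves the grid")
  flux_quadrature(field$y, prof, mode)
}

#' Volume-flow time series from a field series
#'
#' The PIV evaluation of the instantaneous regurgitant flow: per phase, the
#' streamwise flux at the exit station, integrated across planes.
#' \code{"planar"} mode integrates the per-plane fluxes over the plane
#' positions by the trapezoidal rule (>= 2 distinct planes; duplicated
#' planes are ignored); \code{"axisymmetric"} revolves the single mid-plane
#' profile, as appropriate for circular orifices.
#'
#' @param series a \code{\link{field_series}}.
#' @param planes z positions (cm) of the sampling planes (planar mode).
#' @param mode \code{"planar"} or \code{"axisymmetric"}.
#' @param x_station station (cm); default one grid cell downstream of the
#'   orifice plane (the smallest non-negative grid x).
#' @return data frame with columns \code{t} (ms) and \code{Vdot} (ml/s).
#' @export
flow_rate_series <- function(series, planes = NULL,
                             mode = c("planar", "axisymmetric"),
                             x_station = NULL) {
  stopifnot(inherits(series, "field_series"))
  mode <- match.arg(mode)
  f0 <- series$fields[[1L]]
  if (is.null(x_station)) x_station <- default_station(f0$x)
  if (mode == "planar") {
    if (is.null(f0$z)) stop("planar multi-plane integration needs a 3D series")
    if (is.null(planes)) planes <- f0$z
    planes <- sort(unique(planes))
    if (length(planes) < 2L) stop("planar mode needs at least 2 distinct planes")
    vdot <- vapply(series$fields, function(f) {
      per_plane <- vapply(planes, function(zp)
        station_flux(f, x_station, "planar", z_plane = zp), numeric(1L))
      pracma::trapz(planes, per_plane)
    }, numeric(1L))
  } else {
    vdot <- vapply(series$fields, function(f)
      station_flux(f, x_station, "axisymmetric"), numeric(1L))
  }
  data.frame(t = series$times, Vdot = vdot)
}

default_station <- function(x) {
  nonneg <- x[x >= 0]
  if (length(nonneg)) min(nonneg) else max(x)
}

#' Reference regurgitant volume from a field series
#'
#' The ground-truth RVol of PIV practice: the volume-flow series integrated
#' over the systole window by the trapezoidal rule.
#'
#' @inheritParams flow_rate_series
#' @param window systole window \code{c(t0, t1)} (ms). Default: the
#'   contiguous interval where the flow stays above 10\% of its peak.
#' @return RVol in ml.
#' @examples
#' o <- make_orifice("circle", 12.2)
#' ser <- jet_exit_series(jet_spec(o, waveform()), jet_exit_grid(o))
#' reference_rvol(ser, mode = "axisymmetric")   # ~ ser$programmed_rvol
#' @export
reference_rvol <- function(series, planes = NULL,
                           mode = c("planar", "axisymmetric"),
                           window = NULL, x_station = NULL) {
  fr <- flow_rate_series(series, planes, mode, x_station)
  if (is.null(window)) window <- systole_window(fr$t, fr$Vdot)
  if (window[2L] <= window[1L]) stop("empty systole window")
  if (nrow(fr) == 1L) return(fr$Vdot * diff(window) / 1000)
  tw <- trace_in_window(fr$t, fr$Vdot, window)
  pracma::trapz(tw$t, tw$v) / 1000
}

#' Bootstrap 2-sigma uncertainty of the PIV regurgitant volume
#'
#' Resamples the frames of each phase with replacement, recomputes RVol for
#' each bootstrap replicate and reports the ensemble-mean RVol with a
#' 2-sigma (twice the replicate standard deviation) confidence half-width.
#' Because the flux is linear in the velocity field, the per-frame fluxes
#' are computed once and the replicates only resample phase-wise means.
#'
#' @param ensemble a \code{\link{piv_sample}} frame ensemble (>= 2 frames
#'   per phase).
#' @param planes,mode,window,x_station as in \code{\link{reference_rvol}}.
#' @param B number of bootstrap replicates (>= 200; default 1000).
#' @param seed integer seed for the resampling.
#' @return object of class \code{uncertain_estimate}: \code{value} (ml),
#'   \code{half_width_2sigma} (ml), \code{n_boot}, \code{seed}.
#' @export
bootstrap_ci <- function(ensemble, planes = NULL,
                         mode = c("planar", "axisymmetric"),
                         window = NULL, x_station = NULL,
                         B = 1000L, seed = 1L) {
  stopifnot(inherits(ensemble, "piv_ensemble"))
  mode <- match.arg(mode)
  B <- as.integer(B)
  if (B < 200L) stop("'B' must be at least 200")
  if (ensemble$n_frames < 2L) stop("bootstrap needs >= 2 frames per phase")
  if (is.null(x_station)) x_station <- default_station(ensemble$x)
  # station interpolation weights along x
  xw <- axis_interp_weights(ensemble$x, x_station)
  has_z <- !is.null(ensemble$z)
  if (mode == "planar") {
    if (!has_z) stop("planar multi-plane integration needs a 3D ensemble")
    if (is.null(planes)) planes <- ensemble$z
    planes <- sort(unique(planes))
    if (length(planes) < 2L) stop("planar mode needs at least 2 distinct planes")
    if (!all(vapply(planes, function(p) any(abs(ensemble$z - p) < 1e-9), logical(1L))))
      stop("planes must coincide with ensemble z positions")
    zi <- vapply(planes, function(p) which.min(abs(ensemble$z - p)), integer(1L))
    wy <- trapz_weights(ensemble$y)
    wz <- trapz_weights(planes)
    wyz <- as.vector(outer(wy, wz))
  } else {
    wy <- if (min(ensemble$y) < 0) trapz_weights(ensemble$y) * pi * abs(ensemble$y)
          else trapz_weights(ensemble$y) * 2 * pi * ensemble$y
  }
  n_ph <- length(ensemble$times)
  nf <- ensemble$n_frames
  flux <- matrix(NA_real_, n_ph, nf)
  for (p in seq_len(n_ph)) {
    u <- ensemble$frames[[p]]$u
    if (has_z) {
      # collapse x by the station weights -> (ny, nz, nf)
      prof <- apply_x_weights(u, xw)
      if (mode == "planar") {
        sub <- prof[, zi, , drop = FALSE]
        flux[p, ] <- colSums(matrix(sub, ncol = nf) * wyz)
      } else {
        z0 <- which.min(abs(ensemble$z))
        flux[p, ] <- colSums(matrix(prof[, z0, ], ncol = nf) * wy)
      }
    } else {
      prof <- apply_x_weights(u, xw)          # (ny, nf)
      flux[p, ] <- colSums(prof * wy)
    }
  }
  vbar <- rowMeans(flux)
  if (is.null(window)) window <- systole_window(ensemble$times, vbar)
  wt <- window_weights(ensemble$times, window) / 1000
  value <- sum(wt * vbar)
  set.seed(seed)
  reps <- vapply(seq_len(B), function(b) {
    idx <- sample.int(nf, nf, replace = TRUE)
    sum(wt * rowMeans(flux[, idx, drop = FALSE]))
  }, numeric(1L))
  structure(list(value = value, half_width_2sigma = 2 * stats::sd(reps),
                 n_boot = B, seed = as.integer(seed), window = window),
            class = "uncertain_estimate")
}

# linear-interpolation weights of a position on an axis
axis_interp_weights <- function(ax, x0) {
  if (length(ax) == 1L) {
    if (abs(ax - x0) > 1e-9) stop("station outside the grid")
    return(list(i = 1L, w = 1))
  }
  if (x0 < min(ax) - 1e-12 || x0 > max(ax) + 1e-12)
    stop("station outside the grid")
  i <- findInterval(x0, ax, rightmost.closed = TRUE)
  t <- (x0 - ax[i]) / (ax[i + 1L] - ax[i])
  list(i = c(i, i + 1L), w = c(1 - t, t))
}

# contract the first dimension of an array with interpolation weights
apply_x_weights <- function(arr, xw) {
  d <- dim(arr)
  m <- matrix(arr, nrow = d[1L])
  array(as.numeric(xw$w %*% m[xw$i, , drop = FALSE]), d[-1L])
}

#' @export
print.uncertain_estimate <- function(x, ...) {
  cat(sprintf("%.3f +/- %.3f (2 sigma, %d bootstrap replicates)\n",
              x$value, x$half_width_2sigma, x$n_boot))
  invisible(x)
}
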