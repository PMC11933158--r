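#' Synthetic pulsatile jet specification
#'
#' Bundles the orifice, waveform and sampling parameters of a synthetic
#' regurgitant jet. The exit-plane streamwise velocity is
#' \deqn{u(y, z, t) = U(t)\, c\, (1 + \beta\,\hat\rho^2)}
#' inside the orifice and 0 outside, where \eqn{\hat\rho} is the normalized
#' boundary distance (0 at the incenter, 1 on the boundary) so that
#' \eqn{\beta > 0} produces the saddle-backed profiles seen at sharp-edged
#' orifices, with \eqn{u(\mathrm{center})/u(\mathrm{max}) = 1/(1+\beta)}.
#' The amplitude \eqn{c} is calibrated per grid so that the station
#' quadrature of the generated field equals \eqn{U(t) \cdot A} exactly (see
#' the methods vignette); the programmed regurgitant volume is
#' \eqn{A \int U\,dt} with the integral taken by adaptive quadrature.
#'
#' @param orifice an orifice spec.
#' @param waveform a \code{\link{waveform}}.
#' @param beta saddle amplitude (dimensionless, >= 0).
#' @param noise_sd default PIV noise standard deviation (cm/s) for
#'   \code{\link{piv_sample}}.
#' @param n_frames default frames per phase for \code{\link{piv_sample}}.
#' @param seed default integer seed.
#' @return object of class \code{jet_spec}.
#' @export
jet_spec <- function(orifice, waveform, beta = 0.3, noise_sd = 0,
                     n_frames = 1L, seed = 1L) {
  stopifnot(inherits(orifice, "orifice_spec"), inherits(waveform, "waveform"))
  if (beta < 0) stop("'beta' must be >= 0")
  if (n_frames < 1L) stop("'n_frames' must be >= 1")
  structure(list(orifice = orifice, waveform = waveform, beta = beta,
                 noise_sd = noise_sd, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "jet_spec")
}

# normalized boundary distance of points (y, z) wrt the orifice polygon:
# 1 - d(p, boundary) / (h/2), clamped to [0, 1]; NA outside the orifice
normalized_boundary_distance <- function(orifice, y, z) {
  poly <- orifice_polygon_cm(orifice)
  g <- expand.grid(y = y, z = z)
  inside <- point_in_polygon(g$y, g$z, poly)
  d <- dist_to_polygon(g$y, g$z, poly)
  rho <- 1 - d / (orifice$h / 20)
  rho <- pmin(pmax(rho, 0), 1)
  rho[!inside] <- NA_real_
  matrix(rho, nrow = length(y))
}

# even-odd ray casting, vectorized over points
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1L]; ys <- poly[, 2L]
  xe <- c(xs[-1L], xs[1L]); ye <- c(ys[-1L], ys[1L])
  inside <- rep(FALSE, length(px))
  for (e in seq_len(n)) {
    crosses <- (ys[e] > py) != (ye[e] > py)
    if (any(crosses)) {
      xint <- xs[e] + (py[crosses] - ys[e]) / (ye[e] - ys[e]) * (xe[e] - xs[e])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
  }
  inside
}

# min distance from points to the polygon boundary (segment distances)
dist_to_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1L]; ys <- poly[, 2L]
  xe <- c(xs[-1L], xs[1L]); ye <- c(ys[-1L], ys[1L])
  d2 <- rep(Inf, length(px))
  for (e in seq_len(n)) {
    ex <- xe[e] - xs[e]; ey <- ye[e] - ys[e]
    len2 <- ex^2 + ey^2
    t <- ((px - xs[e]) * ex + (py - ys[e]) * ey) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- px - (xs[e] + t * ex); dy <- py - (ys[e] + t * ey)
    d2 <- pmin(d2, dx^2 + dy^2)
  }
  sqrt(d2)
}

#' Default exit-region grid for a synthetic jet
#'
#' A few streamwise stations just downstream of the orifice plane, a
#' cross-stream axis wide enough to cover the field of view around the jet,
#' and (for non-circular orifices) a plane-traversal axis across the short
#' orifice dimension.
#'
#' @param orifice an orifice spec.
#' @param spacing grid spacing in x and y (cm); default the PIV vector
#'   spacing 0.05323 cm.
#' @param y_halfwidth half-extent of the y axis (cm).
#' @param n_x number of downstream stations.
#' @param z_spacing plane separation (cm) for 3D grids; default 0.1 cm.
#' @param three_d force/suppress the z axis; default: 3D for non-circular
#'   orifices.
#' @return named list of axes \code{x}, \code{y} (and \code{z}).
#' @export
jet_exit_grid <- function(orifice, spacing = 0.05323, y_halfwidth = 3,
                          n_x = 3L, z_spacing = 0.1,
                          three_d = orifice$shape != "circle") {
  x <- spacing * seq_len(n_x)
  ny <- ceiling(y_halfwidth / spacing)
  y <- spacing * seq(-ny, ny)
  z <- NULL
  if (three_d) {
    zmax <- orifice$h / 20 + 2 * z_spacing   # short dimension + margin
    nz <- ceiling(zmax / z_spacing)
    z <- z_spacing * seq(-nz, nz)
  }
  list(x = x, y = y, z = z)
}

#' Generate a pulsatile jet exit-field series
#'
#' Evaluates the saddle-profile exit flow on a grid for each cardiac phase.
#' The streamwise component is uniform along the (short) x extent of the
#' grid, mimicking the near-exit jet column; the cross-stream components are
#' zero. 2D grids are only admitted for circular orifices (mid-plane of an
#' axisymmetric jet); elongated shapes need a z axis so that the programmed
#' flow is defined.
#'
#' @param jet a \code{\link{jet_spec}}.
#' @param grid named list of axes (see \code{\link{jet_exit_grid}}); the
#'   y (and z) axes must cover the orifice.
#' @param phases phase times (ms); default 42 uniform phases over a 750 ms
#'   cycle. Must cover systole.
#' @return a \code{\link{field_series}} with \code{programmed_rvol} set.
#' @examples
#' o <- make_orifice("circle", 12.2, label = "circle-L")
#' jt <- jet_spec(o, waveform(), beta = 0.3)
#' ser <- jet_exit_series(jt, jet_exit_grid(o))
#' ser$programmed_rvol
#' @export
jet_exit_series <- function(jet, grid, phases = cardiac_phases()) {
  stopifnot(inherits(jet, "jet_spec"))
  orf <- jet$orifice
  wv <- jet$waveform
  if (min(phases) > wv$systole[1L] || max(phases) < wv$systole[2L])
    stop("'phases' must cover the systolic interval")
  a_cm <- orf$h / 20
  if (max(grid$y) < a_cm || min(grid$y) > -a_cm)
    stop("grid y axis does not cover the orifice")
  if (is.null(grid$z)) {
    if (orf$shape != "circle")
      stop("a z axis is required for non-circular orifices ",
           "(mid-plane flux does not determine the programmed flow)")
    rho <- normalized_boundary_distance(orf, grid$y, 0)[, 1L]
    gprof <- ifelse(is.na(rho), 0, 1 + jet$beta * rho^2)
    qg <- flux_quadrature(grid$y, gprof, mode = "axisymmetric")
  } else {
    w_cm <- (orf$w %||% orf$h) / 20
    if (max(grid$z) < a_cm || min(grid$z) > -a_cm)
      stop("grid z axis does not cover the orifice")
    rho <- normalized_boundary_distance(orf, grid$y, grid$z)
    gprof <- ifelse(is.na(rho), 0, 1 + jet$beta * rho^2)
    per_plane <- apply(gprof, 2L, function(col) flux_quadrature(grid$y, col, "planar"))
    qg <- pracma::trapz(grid$z, per_plane)
  }
  if (qg <= 0) stop("grid too coarse to resolve the orifice")
  A <- orifice_area_cm2(orf)
  cc <- A / qg                                  # discrete flux calibration
  nx <- length(grid$x)
  dims <- c(nx, length(grid$y), if (!is.null(grid$z)) length(grid$z))
  base_u <- if (is.null(grid$z))
    array(rep(cc * gprof, each = nx), dims) else
    array(rep(as.vector(cc * gprof), each = nx), dims)
  zero <- array(0, dims)
  fields <- lapply(phases, function(t) {
    u_t <- pulse_waveform(wv, t)
    velocity_field(x = grid$x, y = grid$y, z = grid$z,
                   u = u_t * base_u, v = zero,
                   w = if (!is.null(grid$z)) zero else NULL,
                   meta = list(generator = "jet_exit", t_ms = t))
  })
  field_series(phases, fields,
               programmed_rvol = A * waveform_integral(wv),
               meta = list(orifice = orf$label, beta = jet$beta,
                           U_global = wv$U_global))
}

#' Uniform cardiac phase times
#'
#' @param n_phases number of phases (default 42).
#' @param cycle_ms cycle length in ms (default 750, i.e. 80 bpm).
#' @return phase times in ms.
#' @export
cardiac_phases <- function(n_phases = 42L, cycle_ms = 750) {
  cycle_ms * (seq_len(n_phases) - 1L) / n_phases
}

#' PIV-like sampling of a field series
#'
#' Resamples each phase field onto a coarser regular grid (the PIV vector
#' grid) and draws \code{n_frames} noisy frames per phase with independent
#' zero-mean Gaussian noise on every vector component. The result is
#' reproducible for a fixed seed.
#'
#' @param series a \code{\link{field_series}}.
#' @param spacing PIV grid spacing in x and y (cm); must be at least the
#'   native grid spacing. The z planes of 3D series are kept as-is.
#' @param noise_sd noise standard deviation (cm/s).
#' @param n_frames frames per phase (>= 1).
#' @param seed integer seed.
#' @return object of class \code{piv_ensemble}: the resampled axes, the
#'   per-phase frame arrays \code{u}, \code{v} with the frame index as last
#'   dimension, and the sampling parameters.
#' @export
piv_sample <- function(series, spacing, noise_sd = 0, n_frames = 1L,
                       seed = 1L) {
  stopifnot(inherits(series, "field_series"))
  f0 <- series$fields[[1L]]
  native <- min(c(if (length(f0$x) > 1L) diff(f0$x) else Inf,
                  if (length(f0$y) > 1L) diff(f0$y) else Inf))
  if (spacing < native - 1e-12)
    stop("'spacing' must be at least the native grid spacing (",
         format(native), " cm)")
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("'n_frames' must be >= 1")
  ax_new <- function(a) if (length(a) == 1L) a else
    seq(min(a), max(a) + 1e-12, by = spacing)
  x <- ax_new(f0$x); y <- ax_new(f0$y); z <- f0$z
  pts <- grid_points(list(x = x, y = y, z = z))
  dims <- c(length(x), length(y), if (!is.null(z)) length(z))
  set.seed(seed)
  frames <- lapply(series$fields, function(f) {
    u0 <- interp_component(f, pts, "u")
    v0 <- interp_component(f, pts, "v")
    nu <- array(rep(u0, n_frames), c(dims, n_frames))
    nv <- array(rep(v0, n_frames), c(dims, n_frames))
    if (noise_sd > 0) {
      nu <- nu + stats::rnorm(length(nu), sd = noise_sd)
      nv <- nv + stats::rnorm(length(nv), sd = noise_sd)
    }
    list(u = nu, v = nv)
  })
  structure(list(times = series$times, x = x, y = y, z = z,
                 frames = frames, noise_sd = noise_sd, n_frames = n_frames,
                 seed = as.integer(seed),
                 programmed_rvol = series$programmed_rvol),
            class = "piv_ensemble")
}

#' @export
print.piv_ensemble <- function(x, ...) {
  cat(sprintf("PIV frame ensemble: %d phases x %d frames, spacing %.4g cm, noise sd %.3g cm/s\n",
              length(x$times), x$n_frames,
              if (length(x$y) > 1L) x$y[2L] - x$y[1L] else NA_real_,
              x$noise_sd))
  invisible(x)
}

#' Phase-wise ensemble mean of a PIV ensemble
#'
#' Averages the frames of each phase, returning an ordinary
#' \code{\link{field_series}} (the "average of 100 images per phase" step of
#' PIV practice).
#'
#' @param ensemble a \code{\link{piv_sample}} result.
#' @return a \code{\link{field_series}}.
#' @export
ensemble_mean_series <- function(ensemble) {
  stopifnot(inherits(ensemble, "piv_ensemble"))
  nd <- if (is.null(ensemble$z)) 2L else 3L
  fields <- lapply(ensemble$frames, function(fr) {
    mu <- apply(fr$u, seq_len(nd), mean)
    mv <- apply(fr$v, seq_len(nd), mean)
    velocity_field(x = ensemble$x, y = ensemble$y, z = ensemble$z,
                   u = mu, v = mv,
                   w = if (nd == 3L) array(0, dim(mu)) else NULL)
  })
  field_series(ensemble$times, fields,
               programmed_rvol = ensemble$programmed_rvol)
}
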