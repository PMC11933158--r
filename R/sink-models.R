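#' Steady convergence-zone flow model specification
#'
#' Bundles an orifice, a volumetric flow rate and the choice of potential-flow
#' model for the convergence zone upstream of the orifice (x <= 0):
#' \describe{
#'   \item{\code{point_sink}}{idealized half-space sink on a wall — the flow
#'     the clinical flow-convergence method assumes. Speed \eqn{Q/(2\pi R^2)}
#'     directed toward the origin.}
#'   \item{\code{aperture_exact}}{potential flow through a circular aperture
#'     of the orifice's equal-area radius \eqn{a} in a plane wall; on the axis
#'     the velocity is exactly \eqn{Q/(2\pi(x^2+a^2))}.}
#'   \item{\code{sink_sheet}}{uniform-strength sink panels distributed over
#'     the orifice polygon; captures the orifice shape.}
#' }
#' A finite chamber can be emulated by mirror-image sinks across walls at
#' \code{y, z = +/- chamber_halfwidth}, truncated at \code{image_order}
#' reflections; the images elevate far-field velocities relative to the free
#' sink, which is what drives PISA over-estimation at low aliasing velocities.
#'
#' @param orifice an \code{\link{make_orifice}} spec.
#' @param Q volumetric flow rate through the orifice (ml/s), positive.
#' @param model convergence-zone model, see above.
#' @param chamber_halfwidth optional half-width of the confining chamber (cm);
#'   must exceed the orifice's largest half-dimension.
#' @param image_order number of image reflections per wall (>= 0; 0 means
#'   unconfined).
#' @param n_panels number of sink panels for \code{model = "sink_sheet"}.
#' @return object of class \code{sink_flow_spec}.
#' @export
sink_flow_spec <- function(orifice, Q,
                           model = c("point_sink", "aperture_exact", "sink_sheet"),
                           chamber_halfwidth = NULL, image_order = 0L,
                           n_panels = 512L) {
  model <- match.arg(model)
  stopifnot(inherits(orifice, "orifice_spec"))
  if (!is.numeric(Q) || length(Q) != 1L || !is.finite(Q) || Q <= 0)
    stop("'Q' must be a single positive flow rate (ml/s)")
  image_order <- as.integer(image_order)
  if (image_order < 0L) stop("'image_order' must be >= 0")
  if (!is.null(chamber_halfwidth)) {
    half_dim_cm <- max(orifice$h, orifice$w %||% 0) / 2 / 10
    if (chamber_halfwidth <= half_dim_cm)
      stop("'chamber_halfwidth' must exceed the orifice's largest half-dimension (",
           format(half_dim_cm), " cm)")
  } else if (image_order > 0L) {
    stop("'chamber_halfwidth' is required when image_order > 0")
  }
  sheet <- if (model == "sink_sheet") sink_sheet_panels(orifice, n_panels, Q = Q)
           else NULL
  structure(list(orifice = orifice, Q = Q, model = model,
                 chamber_halfwidth = chamber_halfwidth,
                 image_order = image_order, sheet = sheet),
            class = "sink_flow_spec")
}

#' @export
print.sink_flow_spec <- function(x, ...) {
  cat(sprintf("Convergence-zone model '%s', Q = %.4g ml/s, orifice '%s'%s\n",
              x$model, x$Q, x$orifice$label,
              if (x$image_order > 0L)
                sprintf(", chamber half-width %.3g cm (image order %d)",
                        x$chamber_halfwidth, x$image_order) else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# in-plane (y, z) offsets of the mirror-image sinks for a square chamber
image_offsets <- function(chamber_halfwidth, image_order) {
  if (is.null(chamber_halfwidth) || image_order < 1L)
    return(matrix(numeric(0), ncol = 2L))
  m <- seq(-image_order, image_order)
  g <- as.matrix(expand.grid(my = m, mz = m))
  g <- g[rowSums(g != 0) > 0, , drop = FALSE]
  2 * chamber_halfwidth * g
}

# velocity of a half-space point sink of strength q at in-plane position
# (0, cy, cz), evaluated at pts (columns x, y, z in cm); cm/s
point_sink_at <- function(pts, q, cy = 0, cz = 0) {
  dx <- pts[, 1L]; dy <- pts[, 2L] - cy; dz <- pts[, 3L] - cz
  r2 <- dx^2 + dy^2 + dz^2
  f <- -q / (2 * pi * r2^1.5)
  cbind(u = f * dx, v = f * dy, w = f * dz)
}

as_pts3 <- function(pts) {
  pts <- as.matrix(pts)
  if (ncol(pts) == 2L) pts <- cbind(pts, 0)
  pts
}

#' Evaluate a convergence-zone model at arbitrary points
#'
#' Returns the velocity vectors (cm/s) of the model at the given points.
#' The \code{aperture_exact} model is defined on the axis only (y = z = 0);
#' off-axis points raise an error for that model.
#'
#' @param spec a \code{\link{sink_flow_spec}}.
#' @param pts numeric matrix with columns x, y (and optionally z), in cm.
#' @return matrix with columns \code{u}, \code{v}, \code{w} (cm/s).
#' @export
sink_velocity <- function(spec, pts) {
  stopifnot(inherits(spec, "sink_flow_spec"))
  pts <- as_pts3(pts)
  vel <- switch(spec$model,
    point_sink = point_sink_at(pts, spec$Q),
    aperture_exact = {
      if (any(abs(pts[, 2L]) > 1e-9 | abs(pts[, 3L]) > 1e-9))
        stop("the aperture_exact model is defined on the axis only")
      a <- orifice_equiv_radius_cm(spec$orifice)
      # axial velocity directed toward the orifice (+x on the convergence side)
      u <- spec$Q / (2 * pi * (pts[, 1L]^2 + a^2))
      cbind(u = u, v = 0 * u, w = 0 * u)
    },
    sink_sheet = sheet_velocity(spec$sheet, pts))
  off <- image_offsets(spec$chamber_halfwidth, spec$image_order)
  if (nrow(off)) {
    for (i in seq_len(nrow(off)))
      vel <- vel + point_sink_at(pts, spec$Q, off[i, 1L], off[i, 2L])
  }
  vel
}

#' Ideal half-space point-sink field
#'
#' The idealized sink flow underlying the flow-convergence principle: on the
#' convergence side the speed at distance R from the orifice is
#' \eqn{Q/(2\pi R^2)}, directed toward the origin; the wall-normal velocity
#' vanishes on the wall (x = 0) away from the origin.
#'
#' @param Q flow rate (ml/s).
#' @param grid named list with strictly increasing axes \code{x}, \code{y}
#'   (and optionally \code{z}) in cm. The grid must exclude a ball of at
#'   least two grid cells around the singular origin.
#' @return a \code{\link{velocity_field}}.
#' @examples
#' g <- list(x = seq(-3, -0.2, by = 0.05), y = seq(-1, 1, by = 0.05))
#' f <- point_sink_field(244.9, g)
#' @export
point_sink_field <- function(Q, grid) {
  spec <- sink_flow_spec(make_orifice("circle", h = 1, label = "point"),
                         Q = Q, model = "point_sink")
  pts <- grid_points(grid)
  rmin <- min(sqrt(rowSums(pts^2)))
  hmin <- min_spacing(grid)
  if (rmin < 2 * hmin)
    stop("grid must exclude a ball of radius >= 2 grid cells around the origin")
  model_field(spec, grid)
}

#' Axial velocity of potential flow through a circular aperture
#'
#' The exact axial velocity of potential flow drawn through a circular
#' aperture of radius \code{a} in a plane wall at volumetric rate \code{Q}:
#' \eqn{u(x) = Q / (2\pi(x^2 + a^2))}. Its far field is the point sink; at
#' the aperture center it equals \eqn{Q/(2\pi a^2)}.
#'
#' @param Q flow rate (ml/s).
#' @param a aperture radius (cm), positive.
#' @param x distance from the aperture along the axis (cm), >= 0.
#' @return axial speed (cm/s).
#' @examples
#' aperture_axial_profile(244.9, 0.61, 0)      # ~104.7 cm/s
#' aperture_axial_profile(244.9, 0.61, 1.256)  # ~20 cm/s
#' @export
aperture_axial_profile <- function(Q, a, x) {
  if (a <= 0) stop("'a' must be positive")
  if (any(x < 0)) stop("'x' must be non-negative")
  Q / (2 * pi * (x^2 + a^2))
}

#' Sink-sheet panels over an orifice polygon
#'
#' Triangulates the orifice polygon by a centroid fan with radial refinement
#' and returns panel centroids and strengths; the panel strengths sum exactly
#' to \code{Q} so the sheet draws the configured flow rate.
#'
#' @param orifice an orifice spec.
#' @param n_panels requested minimum number of panels (>= 64).
#' @param Q total sink strength (ml/s); defaults to 1 (strengths are scaled
#'   by the caller).
#' @return object of class \code{sink_sheet} with fields \code{cy}, \code{cz}
#'   (panel centroids, cm), \code{q} (panel strengths, ml/s).
#' @keywords internal
sink_sheet_panels <- function(orifice, n_panels = 512L, Q = 1) {
  n_panels <- max(64L, as.integer(n_panels))
  poly <- orifice_polygon_cm(orifice, n = 256L)
  nv <- nrow(poly)
  # radial bands so that n_bands * nv >= n_panels (each fan cell is split
  # into band sub-triangles of equal radial fraction)
  n_bands <- max(1L, ceiling(n_panels / nv))
  lam <- seq(0, 1, length.out = n_bands + 1L)
  cy <- cz <- ar <- numeric(0)
  nxt <- c(seq_len(nv)[-1L], 1L)
  for (b in seq_len(n_bands)) {
    l0 <- lam[b]; l1 <- lam[b + 1L]
    # quad (l0*A, l0*B, l1*B, l1*A) per edge AB, centroid-scaled; use its
    # centroid and exact area (difference of similar triangles)
    ay <- poly[, 1L]; az <- poly[, 2L]
    by <- poly[nxt, 1L]; bz <- poly[nxt, 2L]
    tri_area <- abs(ay * bz - by * az) / 2       # full fan triangle area
    band_area <- tri_area * (l1^2 - l0^2)
    # centroid of the annular band piece of a triangle with apex at origin:
    # radial moment of lamina between similarity factors l0, l1
    cg <- (2 / 3) * (l1^3 - l0^3) / (l1^2 - l0^2)
    cy <- c(cy, cg * (ay + by) / 2)
    cz <- c(cz, cg * (az + bz) / 2)
    ar <- c(ar, band_area)
  }
  structure(list(cy = cy, cz = cz, q = Q * ar / sum(ar), area = sum(ar)),
            class = "sink_sheet")
}

# velocity of the panel sheet at pts (x, y, z), chunked for memory
sheet_velocity <- function(sheet, pts) {
  pts <- as_pts3(pts)
  n <- nrow(pts)
  out <- matrix(0, n, 3L, dimnames = list(NULL, c("u", "v", "w")))
  chunk <- max(1L, floor(2e6 / length(sheet$q)))
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    dx <- pts[i0:i1, 1L]
    dy <- outer(pts[i0:i1, 2L], sheet$cy, `-`)
    dz <- outer(pts[i0:i1, 3L], sheet$cz, `-`)
    r2 <- dx^2 + dy^2 + dz^2
    f <- sweep(1 / (2 * pi * r2^1.5), 2L, sheet$q, `*`)
    out[i0:i1, 1L] <- -rowSums(f) * dx
    out[i0:i1, 2L] <- -rowSums(f * dy)
    out[i0:i1, 3L] <- -rowSums(f * dz)
  }
  out
}

#' Sink-sheet velocity field for an arbitrary orifice shape
#'
#' Superposes uniform-strength half-space point-sink panels over the orifice
#' polygon (total strength \code{Q}). In the far field the sheet reduces to
#' the point sink for any shape; near the orifice it carries the shape's
#' signature, which is what the shape-sensitivity sweeps probe.
#'
#' @param orifice an orifice spec.
#' @param Q flow rate (ml/s).
#' @param grid named list of axes \code{x}, \code{y} (and optionally
#'   \code{z}) in cm; must lie strictly upstream of the orifice plane
#'   (standoff of at least one grid cell, i.e. max(x) <= -spacing).
#' @param n_panels number of sink panels (default 512).
#' @return a \code{\link{velocity_field}}.
#' @export
sink_sheet_field <- function(orifice, Q, grid, n_panels = 512L) {
  spec <- sink_flow_spec(orifice, Q, model = "sink_sheet", n_panels = n_panels)
  if (max(grid$x) > -min_spacing(grid) + 1e-12)
    stop("grid must lie strictly upstream of the orifice plane (standoff >= 1 cell)")
  model_field(spec, grid)
}

#' Confined convergence-zone field with wall-image sinks
#'
#' Evaluates the spec's model plus its mirror images across the chamber walls
#' on a grid. With \code{image_order = 0} the field is identical to the
#' unconfined model.
#'
#' @param spec a \code{\link{sink_flow_spec}} with \code{chamber_halfwidth}
#'   set (and \code{image_order >= 1} for any confinement effect).
#' @param grid named list of axes in cm.
#' @return a \code{\link{velocity_field}}.
#' @export
confined_sink_field <- function(spec, grid) {
  stopifnot(inherits(spec, "sink_flow_spec"))
  if (spec$image_order >= 1L && is.null(spec$chamber_halfwidth))
    stop("'chamber_halfwidth' must be set for a confined field")
  model_field(spec, grid)
}

# minimum sensible scan-ray standoff from the orifice plane: the panel
# near-field of a discretized sink sheet is not a smooth flow
ray_start <- function(spec) {
  if (spec$model == "sink_sheet")
    2 * sqrt(orifice_area_cm2(spec$orifice) / length(spec$sheet$q)) else 0
}

grid_points <- function(grid) {
  if (is.null(grid$z)) as.matrix(expand.grid(x = grid$x, y = grid$y)) else
    as.matrix(expand.grid(x = grid$x, y = grid$y, z = grid$z))
}

min_spacing <- function(grid) {
  sp <- c(if (length(grid$x) > 1L) diff(grid$x),
          if (length(grid$y) > 1L) diff(grid$y),
          if (!is.null(grid$z) && length(grid$z) > 1L) diff(grid$z))
  if (!length(sp)) stop("grid must have at least one axis with > 1 point")
  min(sp)
}

model_field <- function(spec, grid) {
  pts <- grid_points(grid)
  vel <- sink_velocity(spec, pts)
  dims <- c(length(grid$x), length(grid$y),
            if (!is.null(grid$z)) length(grid$z))
  velocity_field(x = grid$x, y = grid$y, z = grid$z,
                 u = array(vel[, 1L], dims), v = array(vel[, 2L], dims),
                 w = if (!is.null(grid$z)) array(vel[, 3L], dims) else NULL,
                 meta = list(model = spec$model, Q = spec$Q,
                             orifice = spec$orifice$label))
}

#' Flux of a convergence-zone model through a concentric hemisphere
#'
#' Integrates the inward normal velocity of the model over the hemisphere of
#' radius \code{R} centered at the orifice on the convergence side (x <= 0),
#' by Gauss-Legendre quadrature in the polar direction and a periodic rule in
#' azimuth. For any of the steady models this recovers the configured flow
#' rate (mass conservation), up to quadrature error.
#'
#' @param spec a \code{\link{sink_flow_spec}}.
#' @param R hemisphere radius (cm).
#' @param n_polar,n_azimuth quadrature resolution.
#' @return inward flux (ml/s), positive for converging flow.
#' @examples
#' sp <- sink_flow_spec(make_orifice("circle", 12.2), Q = 244.9,
#'                      model = "sink_sheet")
#' hemisphere_flux(sp, R = 3)   # ~244.9
#' @export
hemisphere_flux <- function(spec, R, n_polar = 48L, n_azimuth = 96L) {
  stopifnot(inherits(spec, "sink_flow_spec"), R > 0)
  gl <- pracma::gaussLegendre(n_polar, 0, 1)    # nodes in cos(alpha)
  phi <- seq(0, 2 * pi, length.out = n_azimuth + 1L)[-(n_azimuth + 1L)]
  g <- expand.grid(cu = gl$x, phi = phi)
  sa <- sqrt(pmax(0, 1 - g$cu^2))
  pts <- cbind(x = -R * g$cu, y = R * sa * cos(g$phi), z = R * sa * sin(g$phi))
  vel <- sink_velocity(spec, pts)
  vn <- rowSums(vel * pts) / R                  # outward normal component
  wts <- rep(gl$w, times = n_azimuth) * (2 * pi / n_azimuth)
  -sum(vn * wts) * R^2                          # inward flux
}
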