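#' Q-criterion vortex map of a planar velocity field
#'
#' The Q-criterion for 2D2C (planar, two-component) data: with the in-plane
#' velocity-gradient tensor from central differences,
#' \eqn{Q = \tfrac12(\|\Omega\|^2 - \|S\|^2)}, positive where rotation
#' dominates strain (vortex cores), negative in strain-dominated regions.
#' For solid-body rotation at angular rate \eqn{\omega} this gives
#' \eqn{Q = \omega^2}; for pure shear it vanishes. Q is computed on interior
#' nodes only (no one-sided boundary stencils) and is Galilean invariant.
#'
#' @param field a 2D \code{\link{velocity_field}} with at least a 3 x 3 grid.
#' @return object of class \code{vortex_map}: interior axes \code{x},
#'   \code{y} and the matrix \code{q} (s^-2).
#' @examples
#' g <- seq(-1, 1, by = 0.05)
#' om <- 10
#' f <- velocity_field(g, g, u = outer(g, g, function(x, y) -om * y),
#'                     v = outer(g, g, function(x, y) om * x))
#' range(q_criterion(f)$q)     # ~ c(100, 100)
#' @export
q_criterion <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  if (!is.null(field$z)) stop("q_criterion expects a planar (2D2C) field")
  nx <- length(field$x); ny <- length(field$y)
  if (nx < 3L || ny < 3L) stop("grid must be at least 3 x 3")
  ix <- 2:(nx - 1L); iy <- 2:(ny - 1L)
  ddx <- function(a) (a[ix + 1L, iy] - a[ix - 1L, iy]) /
    rep(field$x[ix + 1L] - field$x[ix - 1L], times = length(iy))
  ddy <- function(a) (a[ix, iy + 1L] - a[ix, iy - 1L]) /
    rep(field$y[iy + 1L] - field$y[iy - 1L], each = length(ix))
  ux <- ddx(field$u); uy <- ddy(field$u)
  vx <- ddx(field$v); vy <- ddy(field$v)
  omega2 <- 0.5 * (uy - vx)^2                   # ||Omega||^2
  s2 <- ux^2 + vy^2 + 0.5 * (uy + vx)^2         # ||S||^2
  structure(list(x = field$x[ix], y = field$y[iy],
                 q = 0.5 * (omega2 - s2), scheme = "central-2nd-order"),
            class = "vortex_map")
}

#' @export
print.vortex_map <- function(x, ...) {
  cat(sprintf("Q-criterion map (%d x %d interior nodes), Q in [%.3g, %.3g] s^-2\n",
              length(x$x), length(x$y), min(x$q), max(x$q)))
  invisible(x)
}

#' Exit-profile metrics: saddle index and block-profile excess
#'
#' Quantifies the saddle-backed shape of a jet exit profile:
#' \code{saddle_index} is the centerline velocity over the profile maximum
#' (1 for a flat profile, < 1 for a saddle), and \code{block_excess} is the
#' fraction by which a uniform block profile at \eqn{V_{max}} over the given
#' width would overstate the flow carried by the actual profile —
#' \eqn{(V_{max} w - \int u\,dy) / \int u\,dy}, the bias the uniform-profile
#' assumption feeds into the effective-orifice-area chain.
#'
#' @param y profile coordinate (cm), increasing.
#' @param u non-negative streamwise velocity profile (cm/s) with a positive
#'   maximum.
#' @param width block-profile width (cm); default the span of \code{y}.
#' @param center centerline coordinate (default 0).
#' @return list with \code{saddle_index} and \code{block_excess}.
#' @examples
#' y <- seq(-1, 1, by = 0.01)
#' u <- 100 * (1 - y^2)                    # Poiseuille-like
#' profile_metrics(y, u)$block_excess      # 0.5
#' @export
profile_metrics <- function(y, u, width = diff(range(y)), center = 0) {
  if (any(u < 0)) stop("profile must be non-negative")
  umax <- max(u)
  if (umax <= 0) stop("profile must have a positive maximum")
  flow <- pracma::trapz(y, u)
  list(saddle_index = stats::approx(y, u, xout = center)$y / umax,
       block_excess = (umax * width - flow) / flow)
}
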