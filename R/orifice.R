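#' Parametric regurgitant-orifice specification
#'
#' Constructs one of the three mitral-regurgitation orifice phantom (MROP)
#' shapes used on the bench: a circle, a slit (pointed oval, modelled as a
#' symmetric two-arc lens with sharp tips), or a drop (a disk joined to its
#' tangent wedge, an "ice-cream cone" of overall length \code{w}).
#' Dimensions follow the phantom-catalog convention and are given in mm;
#' all flow-side code works in cm via the unit accessors
#' (\code{\link{orifice_area_cm2}}, \code{\link{orifice_polygon_cm}}).
#'
#' The stored \code{area} is the shoelace area of a fine polygonization of the
#' boundary (8192 vertices); for the circle this agrees with \eqn{\pi h^2/4}
#' to well below 0.01\%.
#'
#' @param shape one of \code{"circle"}, \code{"slit"}, \code{"drop"}.
#' @param h height in mm (the diameter for a circle). Must be positive.
#' @param w width in mm; required for slit and drop and must exceed \code{h};
#'   must be absent (\code{NULL}) for a circle.
#' @param label optional free-text label (e.g. \code{"circle-L"}).
#' @return an object of class \code{orifice_spec} with fields \code{shape},
#'   \code{h}, \code{w}, \code{area} (mm^2) and \code{label}.
#' @examples
#' o <- make_orifice("circle", h = 12.2, label = "circle-L")
#' o$area            # ~116.9 mm^2
#' s <- make_orifice("slit", h = 7.3, w = 22.9)
#' @seealso \code{\link{polygonize}}, \code{\link{orifice_catalog}}
#' @export
make_orifice <- function(shape = c("circle", "slit", "drop"), h, w = NULL,
                         label = NULL) {
  shape <- match.arg(shape)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("'h' must be a single positive number (mm)")
  if (shape == "circle") {
    if (!is.null(w))
      stop("'w' must be absent for a circular orifice")
  } else {
    if (is.null(w) || !is.numeric(w) || length(w) != 1L || !is.finite(w))
      stop("'w' (mm) is required for shape '", shape, "'")
    if (w <= h)
      stop("'w' must exceed 'h' for shape '", shape, "' (got w = ", w,
           ", h = ", h, ")")
  }
  spec <- structure(
    list(shape = shape, h = h, w = w, area = NA_real_,
         label = if (is.null(label)) shape else label),
    class = "orifice_spec")
  spec$area <- abs(shoelace_area(polygonize(spec, n = 8192L)))
  spec
}

#' @export
print.orifice_spec <- function(x, ...) {
  dims <- if (is.null(x$w)) sprintf("h = %.2f mm", x$h) else
    sprintf("h = %.2f mm, w = %.2f mm", x$h, x$w)
  cat(sprintf("Orifice '%s': %s, %s, area = %.2f mm^2\n",
              x$label, x$shape, dims, x$area))
  invisible(x)
}

#' Polygonize an orifice boundary
#'
#' Returns a closed, counter-clockwise, non-self-intersecting boundary polygon
#' of the orifice in the orifice plane, centered at the area centroid.
#' Columns are the in-plane coordinates (y, z) in mm, with the long axis of
#' slit and drop along y. The closing vertex is implicit (first vertex is not
#' repeated).
#'
#' @param orifice an \code{\link{make_orifice}} spec.
#' @param n number of boundary vertices (>= 16).
#' @return an \code{n x 2} numeric matrix, columns \code{y}, \code{z} (mm).
#' @examples
#' p <- polygonize(make_orifice("circle", 10), n = 4096)
#' abs(shoelace_area(p)) / (25 * pi)   # -> 1 to within 1e-4
#' @export
polygonize <- function(orifice, n = 512L) {
  stopifnot(inherits(orifice, "orifice_spec"))
  n <- as.integer(n)
  if (n < 16L) stop("'n' must be at least 16")
  h <- orifice$h; w <- orifice$w
  poly <- switch(orifice$shape,
    circle = {
      th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
      cbind(y = h / 2 * cos(th), z = h / 2 * sin(th))
    },
    slit = {
      # two-arc lens: chord w along y, sagitta h/2 per arc
      R <- (w^2 + h^2) / (4 * h)
      th <- 2 * asin(w / (2 * R))          # arc opening angle
      zc <- h / 2 - R                      # upper-arc center (on z axis)
      m <- n %/% 2L
      # upper arc, traversed from +y tip to -y tip (counter-clockwise)
      phi <- seq(th / 2, -th / 2, length.out = m + 1L)[-(m + 1L)]
      upper <- cbind(y = R * sin(phi), z = zc + R * cos(phi))
      lower <- cbind(y = -upper[, 1L], z = -upper[, 2L])
      rbind(upper, lower)
    },
    drop = {
      # disk of radius h/2 + tangent wedge, apex at distance w from blunt end
      R <- h / 2
      d <- w - R                           # apex distance from disk center
      phi <- acos(R / d)                   # tangency angle from +y axis
      arc_len <- R * (2 * pi - 2 * phi)
      seg_len <- sqrt(d^2 - R^2)
      n_arc <- max(8L, round(n * arc_len / (arc_len + 2 * seg_len)))
      n_seg <- max(4L, (n - n_arc) %/% 2L)
      # arc from upper tangency point, over the blunt back (-y), to the lower
      # tangency point; CCW means decreasing angle here
      a <- seq(phi, 2 * pi - phi, length.out = n_arc + 1L)
      arc <- cbind(y = R * cos(a), z = -R * sin(a))   # z sign gives CCW order
      # straight edge lower tangency -> apex, then apex -> handled by closure
      tp_lo <- arc[n_arc + 1L, ]
      tp_hi <- arc[1L, ]
      apex <- c(y = d, z = 0)
      lam <- seq(0, 1, length.out = n_seg + 1L)[-1L]
      edge_lo <- cbind(y = tp_lo[1L] + lam * (apex[1L] - tp_lo[1L]),
                       z = tp_lo[2L] + lam * (apex[2L] - tp_lo[2L]))
      lam2 <- seq(0, 1, length.out = n_seg + 1L)
      lam2 <- lam2[-c(1L, n_seg + 1L)]
      edge_hi <- cbind(y = apex[1L] + lam2 * (tp_hi[1L] - apex[1L]),
                       z = apex[2L] + lam2 * (tp_hi[2L] - apex[2L]))
      rbind(arc, edge_lo, edge_hi)
    })
  # center at the area centroid and enforce counter-clockwise orientation
  cen <- polygon_centroid(poly)
  poly <- sweep(poly, 2L, cen)
  if (shoelace_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  dimnames(poly) <- list(NULL, c("y", "z"))
  poly
}

#' Shoelace (signed) polygon area
#'
#' Signed area of a simple polygon given as an ordered vertex matrix; positive
#' for counter-clockwise orientation. The closing edge is implicit.
#'
#' @param poly two-column numeric matrix of vertices.
#' @return signed area in the square of the vertex units.
#' @export
shoelace_area <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

polygon_centroid <- function(poly) {
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Orifice phantom catalog
#'
#' The nine bench phantoms (three shapes, three sizes each) with their
#' heights, widths and scanner-measured areas, as shipped in
#' \code{inst/extdata/orifice_catalog.csv}.
#'
#' @param as_specs if \code{TRUE}, return a named list of
#'   \code{\link{make_orifice}} specs instead of the data frame (the
#'   \code{area_mm2} column of the data frame is the printed scanner-measured
#'   area; the specs carry the parametric-model area).
#' @return a data frame with columns \code{label}, \code{shape}, \code{h_mm},
#'   \code{w_mm}, \code{area_mm2}, or a named list of orifice specs.
#' @examples
#' orifice_catalog()
#' specs <- orifice_catalog(as_specs = TRUE)
#' specs[["circle-L"]]
#' @export
orifice_catalog <- function(as_specs = FALSE) {
  path <- system.file("extdata", "orifice_catalog.csv", package = "pisaflow",
                      mustWork = TRUE)
  cat <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!as_specs) return(cat)
  specs <- lapply(seq_len(nrow(cat)), function(i) {
    w <- cat$w_mm[i]
    make_orifice(cat$shape[i], h = cat$h_mm[i],
                 w = if (is.na(w)) NULL else w, label = cat$label[i])
  })
  names(specs) <- cat$label
  specs
}

#' Orifice unit accessors (clinical cm units)
#'
#' Orifice dimensions are catalogued in mm; everything on the flow side of the
#' package (velocity fields, PISA chain, flux integration) works in cm, cm/s
#' and ml. These accessors are the only unit conversion point.
#'
#' @param orifice an orifice spec.
#' @return \code{orifice_area_cm2}: area in cm^2. \code{orifice_polygon_cm}:
#'   boundary polygon in cm. \code{orifice_equiv_radius_cm}: radius of the
#'   equal-area circle in cm (the aperture radius used by the closed-form
#'   convergence model).
#' @export
orifice_area_cm2 <- function(orifice) {
  stopifnot(inherits(orifice, "orifice_spec"))
  orifice$area / 100
}

#' @rdname orifice_area_cm2
#' @param n vertices for the polygon.
#' @export
orifice_polygon_cm <- function(orifice, n = 512L) {
  polygonize(orifice, n = n) / 10
}

#' @rdname orifice_area_cm2
#' @export
orifice_equiv_radius_cm <- function(orifice) {
  sqrt(orifice_area_cm2(orifice) / pi)
}
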