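#' Aliasing-velocity sensitivity curve
#'
#' For each aliasing velocity on a grid, extracts the PISA radius from the
#' convergence-zone model along the scan ray, converts it with the
#' hemispheric relation and reports the relative regurgitant-flow error
#' \eqn{(RFlow_{est} - Q)/Q}. Aliasing velocities without a contour crossing
#' inside the scan range are flagged, not failed.
#'
#' On the exact circular-aperture model the whole curve is the closed form
#' \eqn{-2\pi a^2 V_a / Q} — a linear underestimation growing with the
#' aliasing velocity and with orifice size. Adding chamber confinement
#' (image sinks) raises the low-Va end into over-estimation, giving the
#' characteristic error curve with an interior zero crossing.
#'
#' @param spec a \code{\link{sink_flow_spec}}.
#' @param beam a \code{\link{beam_spec}}.
#' @param va_grid strictly increasing aliasing velocities (cm/s); default
#'   5-60 cm/s in 1 cm/s steps, covering the clinical range.
#' @param ds,s_max ray sampling step and reach (cm); defaults 0.005 and
#'   min(8, 0.9 * chamber half-width).
#' @return object of class \code{sensitivity_curve}: data frame
#'   \code{$curve} with columns \code{Va}, \code{r}, \code{rel_error},
#'   \code{no_crossing}, plus the configuration.
#' @examples
#' sp <- sink_flow_spec(make_orifice("circle", 12.2), Q = 244.9,
#'                      model = "aperture_exact")
#' ec <- error_curve(sp)
#' ec$curve$rel_error[ec$curve$Va == 20]   # ~ -0.191
#' @export
error_curve <- function(spec, beam = beam_spec(), va_grid = seq(5, 60, by = 1),
                        ds = 0.005, s_max = NULL) {
  stopifnot(inherits(spec, "sink_flow_spec"))
  if (any(diff(va_grid) <= 0)) stop("'va_grid' must be strictly increasing")
  if (is.null(s_max))
    s_max <- if (!is.null(spec$chamber_halfwidth))
      min(8, 0.9 * spec$chamber_halfwidth) else 8
  s <- seq(max(ds, ray_start(spec)), s_max, by = ds)
  vp <- ray_profile(spec, beam, s)
  res <- lapply(va_grid, function(va) {
    r <- tryCatch(radius_from_ray(s, vp, va), error = function(e) NA_real_)
    data.frame(Va = va, r = r,
               rel_error = if (is.na(r)) NA_real_ else
                 (regurgitant_flow(r, va) - spec$Q) / spec$Q,
               no_crossing = is.na(r))
  })
  structure(list(curve = do.call(rbind, res), spec = spec, beam = beam),
            class = "sensitivity_curve")
}

#' @export
print.sensitivity_curve <- function(x, ...) {
  ok <- !x$curve$no_crossing
  cat(sprintf(paste0("Sensitivity curve for '%s' (%s, Q = %.4g ml/s): ",
                     "%d of %d aliasing velocities with a crossing,\n",
                     "  rel. error %.1f%% .. %.1f%%\n"),
              x$spec$orifice$label, x$spec$model, x$spec$Q,
              sum(ok), nrow(x$curve),
              100 * min(x$curve$rel_error[ok]), 100 * max(x$curve$rel_error[ok])))
  invisible(x)
}

#' @export
plot.sensitivity_curve <- function(x, ...) {
  ok <- !x$curve$no_crossing
  graphics::plot(x$curve$Va[ok], 100 * x$curve$rel_error[ok], type = "b",
                 xlab = "aliasing velocity Va [cm/s]",
                 ylab = "RFlow error [%]",
                 main = sprintf("%s (%s)", x$spec$orifice$label, x$spec$model),
                 ...)
  graphics::abline(h = 0, lty = 2)
}

#' Optimal aliasing velocity of an error curve
#'
#' The aliasing velocity at which the regurgitant-flow error changes sign
#' (linear interpolation between the bracketing grid points). If the curve
#' never changes sign, the velocity minimizing |error| is returned and
#' flagged as a boundary optimum.
#'
#' @param curve a \code{\link{error_curve}} result.
#' @return the optimal Va (cm/s) with attribute \code{boundary} (logical).
#' @export
optimal_aliasing <- function(curve) {
  stopifnot(inherits(curve, "sensitivity_curve"))
  cv <- curve$curve[!curve$curve$no_crossing, ]
  if (nrow(cv) < 3L) stop("curve needs at least 3 points with a crossing")
  e <- cv$rel_error; va <- cv$Va
  sgn <- which(e[-length(e)] * e[-1L] <= 0 & e[-length(e)] != 0)
  if (length(sgn)) {
    k <- sgn[1L]
    va_star <- va[k] + e[k] / (e[k] - e[k + 1L]) * (va[k + 1L] - va[k])
    return(structure(va_star, boundary = FALSE))
  }
  if (any(e == 0)) return(structure(va[which(e == 0)[1L]], boundary = FALSE))
  structure(va[which.min(abs(e))], boundary = TRUE)
}

#' Admissible aliasing-velocity band
#'
#' The maximal contiguous Va interval containing the optimal aliasing
#' velocity over which the magnitude of the regurgitant-flow error stays
#' within a tolerance (the clinical +/-20\% reasoning). Band edges are
#' refined by linear interpolation of the error between grid points.
#'
#' @param curve a \code{\link{error_curve}} result.
#' @param tol error tolerance as a fraction (default 0.2).
#' @return \code{c(Va_lo, Va_hi)} in cm/s.
#' @export
admissible_band <- function(curve, tol = 0.2) {
  stopifnot(inherits(curve, "sensitivity_curve"), tol > 0)
  cv <- curve$curve[!curve$curve$no_crossing, ]
  e <- cv$rel_error; va <- cv$Va
  ok <- abs(e) <= tol
  if (!any(ok)) stop("error tolerance exceeded over the whole Va grid")
  va_star <- as.numeric(optimal_aliasing(curve))
  anchor <- which.min(abs(va - va_star))
  if (!ok[anchor]) anchor <- which(ok)[which.min(abs(va[ok] - va_star))]
  lo <- anchor; while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
  hi <- anchor; while (hi < length(ok) && ok[hi + 1L]) hi <- hi + 1L
  edge <- function(i_in, i_out) {
    # interpolate |e| = tol between an inside and an outside grid point
    t_cross <- (tol * sign(e[i_out]) - e[i_in]) / (e[i_out] - e[i_in])
    va[i_in] + t_cross * (va[i_out] - va[i_in])
  }
  va_lo <- if (lo > 1L) edge(lo, lo - 1L) else va[1L]
  va_hi <- if (hi < length(ok)) edge(hi, hi + 1L) else va[length(ok)]
  c(va_lo, va_hi)
}

#' Catalog of circular orifices for size sweeps
#'
#' The three bench circles plus the two additional diameters (16 and 20 mm)
#' used to visualize the size trend.
#'
#' @return named list of orifice specs.
#' @export
circle_size_catalog <- function() {
  d <- c(4.7, 8.7, 12.2, 16, 20)
  lbl <- c("circle-S", "circle-M", "circle-L", "circle-16", "circle-20")
  specs <- Map(function(h, l) make_orifice("circle", h, label = l), d, lbl)
  names(specs) <- lbl
  specs
}

#' Sweep error curves over orifice shapes and sizes
#'
#' Builds one sensitivity curve per orifice and returns a long-form table:
#' one row per (orifice, Va) with the relative error, plus the per-orifice
#' optimal aliasing velocity and admissible band.
#'
#' @param orifices list of orifice specs (e.g.
#'   \code{\link{circle_size_catalog}()} or
#'   \code{\link{orifice_catalog}(as_specs = TRUE)}).
#' @param Q flow rate (ml/s), common to all orifices.
#' @param beam a \code{\link{beam_spec}}.
#' @param va_grid aliasing velocities (cm/s).
#' @param model convergence-zone model for all orifices.
#' @param chamber_halfwidth,image_order confinement parameters (optional).
#' @param tol admissible-band tolerance.
#' @param n_panels sink-sheet panel count.
#' @param equal_area if \code{TRUE}, isotropically rescale every orifice to
#'   the mean model area of the set before sweeping (pure shape comparison).
#' @return a long-form data frame with columns \code{label}, \code{shape},
#'   \code{area_mm2}, \code{Va}, \code{r}, \code{rel_error},
#'   \code{no_crossing}, \code{va_star}, \code{va_star_boundary},
#'   \code{band_lo}, \code{band_hi}.
#' @export
sweep_shapes_sizes <- function(orifices, Q, beam = beam_spec(),
                               va_grid = seq(5, 60, by = 1),
                               model = "sink_sheet",
                               chamber_halfwidth = NULL, image_order = 0L,
                               tol = 0.2, n_panels = 512L,
                               equal_area = FALSE) {
  if (!length(orifices)) stop("'orifices' must be a non-empty list")
  if (equal_area) {
    a_target <- mean(vapply(orifices, function(o) o$area, numeric(1L)))
    orifices <- lapply(orifices, function(o) {
      s <- sqrt(a_target / o$area)
      make_orifice(o$shape, o$h * s, if (is.null(o$w)) NULL else o$w * s,
                   label = o$label)
    })
  }
  rows <- lapply(orifices, function(o) {
    sp <- sink_flow_spec(o, Q, model = model,
                         chamber_halfwidth = chamber_halfwidth,
                         image_order = image_order, n_panels = n_panels)
    ec <- error_curve(sp, beam, va_grid)
    va_star <- tryCatch(optimal_aliasing(ec), error = function(e)
      structure(NA_real_, boundary = NA))
    band <- tryCatch(admissible_band(ec, tol), error = function(e)
      c(NA_real_, NA_real_))
    cbind(data.frame(label = o$label, shape = o$shape, area_mm2 = o$area),
          ec$curve,
          data.frame(va_star = as.numeric(va_star),
                     va_star_boundary = isTRUE(attr(va_star, "boundary")),
                     band_lo = band[1L], band_hi = band[2L]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
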