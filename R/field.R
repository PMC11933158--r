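#' Velocity field on a structured grid
#'
#' Container for velocity components on a structured, axis-aligned grid in the
#' convention used throughout the package: \code{x} is the beam/streamwise
#' axis (cm; the convergence zone occupies x <= 0, the regurgitant jet
#' x >= 0, the orifice plane is x = 0), \code{y} is the in-plane cross-stream
#' axis (cm) and \code{z}, when present, is the plane-traversal axis (cm).
#' Components \code{u} (along x) and \code{v} (along y) are in cm/s, stored as
#' arrays of dimension \code{(nx, ny)} or \code{(nx, ny, nz)}; \code{w}
#' (along z) is optional.
#'
#' @param x,y,z strictly increasing axis vectors (cm); \code{z} optional.
#' @param u,v,w velocity component arrays (cm/s), dimensions congruent with
#'   the axes; \code{w} optional.
#' @param meta named list of provenance metadata.
#' @return object of class \code{velocity_field}.
#' @examples
#' f <- velocity_field(x = -5:-1, y = -2:2,
#'                     u = matrix(1, 5, 5), v = matrix(0, 5, 5))
#' @export
velocity_field <- function(x, y, u, v, z = NULL, w = NULL, meta = list()) {
  check_axis <- function(a, nm) {
    if (!is.numeric(a) || length(a) < 1L || anyNA(a) ||
        (length(a) > 1L && any(diff(a) <= 0)))
      stop("axis '", nm, "' must be strictly increasing and finite")
  }
  check_axis(x, "x"); check_axis(y, "y")
  dims <- c(length(x), length(y))
  if (!is.null(z)) { check_axis(z, "z"); dims <- c(dims, length(z)) }
  for (nm in c("u", "v", "w")) {
    comp <- get(nm)
    if (is.null(comp)) next
    comp <- as.array(comp)
    if (!identical(unname(dim(comp)), as.integer(dims)))
      stop("component '", nm, "' has dimensions incompatible with the grid")
    if (!all(is.finite(comp)))
      stop("component '", nm, "' contains non-finite values")
    assign(nm, comp)
  }
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 z = if (is.null(z)) NULL else as.numeric(z),
                 u = u, v = v, w = w, meta = meta),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- if (is.null(x$z)) sprintf("%d x %d", length(x$x), length(x$y)) else
    sprintf("%d x %d x %d", length(x$x), length(x$y), length(x$z))
  cat(sprintf("Velocity field (%s grid), x in [%.3g, %.3g] cm, y in [%.3g, %.3g] cm%s\n",
              d, min(x$x), max(x$x), min(x$y), max(x$y),
              if (is.null(x$z)) "" else
                sprintf(", z in [%.3g, %.3g] cm", min(x$z), max(x$z))))
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Time-resolved series of velocity fields over one cardiac cycle
#'
#' @param times strictly increasing phase times (ms) within one cycle.
#' @param fields list of \code{\link{velocity_field}} objects, one per phase,
#'   all sharing one grid.
#' @param programmed_rvol optional known regurgitant volume (ml) when the
#'   series was generated synthetically.
#' @param meta named list of provenance metadata.
#' @return object of class \code{field_series}.
#' @export
field_series <- function(times, fields, programmed_rvol = NULL, meta = list()) {
  if (!is.numeric(times) || length(times) != length(fields))
    stop("'times' and 'fields' must have equal length")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("'times' must be strictly increasing within one cycle")
  if (!all(vapply(fields, inherits, logical(1L), "velocity_field")))
    stop("all elements of 'fields' must be velocity_field objects")
  g0 <- fields[[1L]]
  same <- vapply(fields, function(f)
    identical(f$x, g0$x) && identical(f$y, g0$y) && identical(f$z, g0$z),
    logical(1L))
  if (!all(same)) stop("all fields in a series must share one grid")
  structure(list(times = as.numeric(times), fields = fields,
                 programmed_rvol = programmed_rvol, meta = meta),
            class = "field_series")
}

#' @export
print.field_series <- function(x, ...) {
  cat(sprintf("Field series: %d phases, t in [%.1f, %.1f] ms%s\n",
              length(x$times), min(x$times), max(x$times),
              if (is.null(x$programmed_rvol)) "" else
                sprintf(", programmed RVol = %.3g ml", x$programmed_rvol)))
  invisible(x)
}

# multilinear interpolation of one component at arbitrary points.
# pts: matrix with columns x, y[, z]. Returns NA outside the grid hull.
interp_component <- function(field, pts, comp = "u") {
  arr <- field[[comp]]
  if (is.null(arr)) stop("field has no component '", comp, "'")
  pts <- matrix(pts, ncol = if (is.null(field$z)) 2L else 3L)
  axes <- if (is.null(field$z)) list(field$x, field$y) else
    list(field$x, field$y, field$z)
  nd <- length(axes)
  n <- nrow(pts)
  idx <- wt <- vector("list", nd)
  for (k in seq_len(nd)) {
    ax <- axes[[k]]
    i <- findInterval(pts[, k], ax, rightmost.closed = TRUE)
    bad <- i < 1L | i >= length(ax)
    # points exactly at the upper edge handled by rightmost.closed; a
    # degenerate single-point axis matches exactly or not at all
    if (length(ax) == 1L) {
      i <- rep(1L, n); t <- rep(0, n)
      bad <- abs(pts[, k] - ax) > 1e-9
    } else {
      i[bad] <- 1L
      t <- (pts[, k] - ax[i]) / (ax[i + 1L] - ax[i])
    }
    t[bad] <- NA_real_
    idx[[k]] <- i; wt[[k]] <- t
  }
  out <- numeric(n)
  corners <- as.matrix(expand.grid(rep(list(0:1), nd)))
  dm <- dim(arr)
  for (r in seq_len(nrow(corners))) {
    off <- corners[r, ]
    w <- rep(1, n)
    lin <- rep(1L, n); stride <- 1L
    for (k in seq_len(nd)) {
      t <- wt[[k]]
      w <- w * if (off[k] == 1L) t else (1 - t)
      ik <- pmin(idx[[k]] + off[k], dm[k])
      lin <- lin + (ik - 1L) * stride
      stride <- stride * dm[k]
    }
    out <- out + ifelse(is.na(w) | w == 0, 0, w * arr[lin])
  }
  out[Reduce(`|`, lapply(wt, is.na))] <- NA_real_
  out
}

#' Read and write velocity fields as delimited text
#'
#' The text dialect stores metadata as \code{# key=value} header lines
#' followed by whitespace-delimited columns \code{x y [z] u v [w]} (cm and
#' cm/s), one grid point per row. Values are written with full double
#' precision so that a write/read cycle reproduces the field exactly.
#' \code{format = "rds"} stores the object in R's binary serialization, which
#' round-trips bit-exactly.
#'
#' @param field a \code{\link{velocity_field}}.
#' @param path file path.
#' @param format \code{"text"} or \code{"rds"}.
#' @return \code{write_velocity_field} returns \code{path} invisibly;
#'   \code{read_velocity_field} returns the \code{velocity_field}.
#' @export
write_velocity_field <- function(field, path, format = c("text", "rds")) {
  stopifnot(inherits(field, "velocity_field"))
  format <- match.arg(format)
  if (format == "rds") { saveRDS(field, path); return(invisible(path)) }
  has_z <- !is.null(field$z)
  has_w <- !is.null(field$w)
  meta_lines <- sprintf("# %s=%s", names(field$meta),
                        vapply(field$meta, function(m)
                          paste(format(m), collapse = " "), character(1L)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# units_length=cm", "# units_velocity=cm/s", meta_lines), con)
  if (has_z) {
    g <- expand.grid(x = field$x, y = field$y, z = field$z)
  } else {
    g <- expand.grid(x = field$x, y = field$y)
  }
  cols <- cbind(g, u = as.vector(field$u), v = as.vector(field$v))
  if (has_w) cols$w <- as.vector(field$w)
  writeLines(paste(names(cols), collapse = " "), con)
  utils::write.table(format(cols, digits = 17, scientific = TRUE, trim = TRUE),
                     con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_velocity_field
#' @export
read_velocity_field <- function(path, format = c("text", "rds")) {
  format <- match.arg(format)
  if (format == "rds") return(readRDS(path))
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  kv <- regmatches(hdr, regexec("^#\\s*([^=]+)=(.*)$", hdr))
  for (m in kv) if (length(m) == 3L) meta[[trimws(m[2L])]] <- trimws(m[3L])
  meta$units_length <- meta$units_velocity <- NULL
  body <- lines[!grepl("^#", lines)]
  dat <- utils::read.table(text = body, header = TRUE)
  has_z <- "z" %in% names(dat)
  x <- sort(unique(dat$x)); y <- sort(unique(dat$y))
  z <- if (has_z) sort(unique(dat$z)) else NULL
  dims <- c(length(x), length(y), if (has_z) length(z))
  ord <- if (has_z)
    order(match(dat$z, z), match(dat$y, y), match(dat$x, x)) else
    order(match(dat$y, y), match(dat$x, x))
  shape <- function(col) array(col[ord], dim = dims)
  velocity_field(x = x, y = y, z = z,
                 u = shape(dat$u), v = shape(dat$v),
                 w = if ("w" %in% names(dat)) shape(dat$w) else NULL,
                 meta = meta)
}
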