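test_that("station_flux recovers uniform-profile closed forms", {
  g <- list(x = c(0.05, 0.1), y = seq(-1, 1, by = 0.05))
  W <- 2; U <- 80
  f <- velocity_field(g$x, g$y, u = matrix(U, 2, length(g$y)),
                      v = matrix(0, 2, length(g$y)))
  expect_equal(station_flux(f, 0.05, "planar"), U * W, tolerance = 1e-12)
  # uniform over radius a, axisymmetric -> U pi a^2
  a <- 0.6
  prof <- ifelse(abs(g$y) <= a, U, 0)
  f2 <- velocity_field(g$x, g$y, u = rbind(prof, prof),
                       v = matrix(0, 2, length(g$y)))
  expect_equal(station_flux(f2, 0.05, "axisymmetric"), U * pi * a^2,
               tolerance = 0.1)
  expect_error(station_flux(f, 5, "planar"), "outside the grid")
})

test_that("saddle-profile station flux matches fine quadrature", {
  beta <- 0.3; a <- 0.61; U <- 100
  gprof <- function(y) ifelse(abs(y) < a, 1 + beta * (y / a)^2, 0)
  y <- seq(-1, 1, by = 0.002)
  f <- velocity_field(c(0.05, 0.1), y, u = rbind(U * gprof(y), U * gprof(y)),
                      v = matrix(0, 2, length(y)))
  got <- station_flux(f, 0.05, "axisymmetric")
  want <- stats::integrate(function(r) U * (1 + beta * (r / a)^2) * 2 * pi * r,
                           0, a, rel.tol = 1e-10)$value
  expect_equal(got, want, tolerance = 5e-3)
})

test_that("flow-rate series is idempotent under duplicated planes and
           consistent across integration modes for a circular jet", {
  o <- circle_L()
  g3 <- jet_exit_grid(o, y_halfwidth = 1, z_spacing = 0.08, three_d = TRUE)
  ser <- jet_exit_series(jet_spec(o, waveform()), g3)
  fr <- flow_rate_series(ser, mode = "planar")
  fr_dup <- flow_rate_series(ser, planes = c(g3$z, g3$z), mode = "planar")
  expect_identical(fr$Vdot, fr_dup$Vdot)
  fr_ax <- flow_rate_series(ser, mode = "axisymmetric")
  pk <- which.max(fr$Vdot)
  expect_equal(fr_ax$Vdot[pk], fr$Vdot[pk], tolerance = 0.03)
  expect_error(flow_rate_series(ser, planes = 0, mode = "planar"),
               "2 distinct planes")
})

test_that("reference RVol recovers programmed volumes and is linear", {
  w <- waveform()
  o <- circle_L()
  for (target in c(5, 30, 60)) {
    ws <- scale_waveform_to_rvol(w, o, target)
    ser <- jet_exit_series(jet_spec(o, ws), jet_exit_grid(o, y_halfwidth = 1,
                                                          n_x = 1L))
    rv <- reference_rvol(ser, mode = "axisymmetric", window = ws$systole)
    expect_equal(rv, target, tolerance = 0.02)
  }
  # doubling U(t) doubles RVol exactly (trapezoids are linear)
  ser1 <- small_jet_series(w = w)
  w2 <- waveform(U_local = 2 * w$U_local, U_global = 2 * w$U_global)
  ser2 <- small_jet_series(w = w2)
  rv1 <- reference_rvol(ser1, mode = "axisymmetric", window = w$systole)
  rv2 <- reference_rvol(ser2, mode = "axisymmetric", window = w$systole)
  expect_equal(rv2, 2 * rv1, tolerance = 1e-9)
  # zero-flow series
  z <- waveform(U_local = 1e-9, U_global = 1e-9)
  ser0 <- small_jet_series(w = z)
  expect_equal(reference_rvol(ser0, mode = "axisymmetric",
                              window = z$systole), 0, tolerance = 1e-9)
})

test_that("plane-count refinement is converged at the bench's layer counts", {
  w <- waveform()
  o <- slit_L()
  g <- jet_exit_grid(o, y_halfwidth = 1.5, z_spacing = 0.0114, three_d = TRUE)
  ser <- jet_exit_series(jet_spec(o, w), g)
  rv <- function(np) reference_rvol(ser,
                                    planes = seq(min(g$z), max(g$z),
                                                 length.out = np),
                                    mode = "planar", window = w$systole)
  r7 <- rv(7); r9 <- rv(9); r33 <- rv(33)
  expect_equal(r7, r9, tolerance = 0.02)
  expect_equal(r9, r33, tolerance = 0.01)
  expect_equal(r33, ser$programmed_rvol, tolerance = 0.01)
})

test_that("bootstrap interval: zero width without noise, deterministic,
           guarded preconditions", {
  ser <- small_jet_series()
  w <- waveform()
  en0 <- piv_sample(ser, 0.05323, noise_sd = 0, n_frames = 3, seed = 1)
  ci0 <- bootstrap_ci(en0, mode = "axisymmetric", window = w$systole,
                      B = 300, seed = 2)
  expect_equal(ci0$half_width_2sigma, 0)
  expect_equal(ci0$value, ser$programmed_rvol, tolerance = 5e-3)
  en <- piv_sample(ser, 0.05323, noise_sd = 5, n_frames = 10, seed = 3)
  ciA <- bootstrap_ci(en, mode = "axisymmetric", window = w$systole,
                      B = 300, seed = 4)
  ciB <- bootstrap_ci(en, mode = "axisymmetric", window = w$systole,
                      B = 300, seed = 4)
  expect_identical(unclass(ciA), unclass(ciB))
  expect_gt(ciA$half_width_2sigma, 0)
  en1 <- piv_sample(ser, 0.05323, noise_sd = 5, n_frames = 1, seed = 5)
  expect_error(bootstrap_ci(en1, mode = "axisymmetric"), ">= 2 frames")
  expect_error(bootstrap_ci(en, B = 50, mode = "axisymmetric"), "at least 200")
})
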