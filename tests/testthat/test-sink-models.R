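test_that("point sink has the 1/(2 pi R^2) speed and sink symmetry", {
  sp <- sink_flow_spec(circle_L(), Q_REF, model = "point_sink")
  # on-axis speed at the radius where it equals 20 cm/s
  R <- sqrt(Q_REF / (2 * pi * 20))
  v <- sink_velocity(sp, cbind(-R, 0, 0))
  expect_equal(v[1L], 20, tolerance = 1e-12)
  # velocity anti-parallel to the position vector at random points
  set.seed(1)
  pts <- cbind(-runif(10, 0.5, 3), runif(10, -2, 2), runif(10, -2, 2))
  vel <- sink_velocity(sp, pts)
  cosang <- rowSums(vel * pts) / sqrt(rowSums(vel^2) * rowSums(pts^2))
  expect_equal(cosang, rep(-1, 10), tolerance = 1e-12)
})

test_that("point_sink_field refuses grids touching the singularity", {
  expect_error(point_sink_field(100, list(x = seq(-1, -0.05, by = 0.05),
                                          y = seq(-0.5, 0.5, by = 0.05))),
               "2 grid cells")
})

test_that("steady model fluxes are conserved through nested hemispheres", {
  sp_ps <- sink_flow_spec(circle_L(), Q_REF, model = "point_sink")
  sp_sh <- sink_flow_spec(circle_L(), Q_REF, model = "sink_sheet")
  for (R in c(2, 3, 4)) {
    expect_equal(hemisphere_flux(sp_ps, R), Q_REF, tolerance = 2e-3)
    expect_equal(hemisphere_flux(sp_sh, R), Q_REF, tolerance = 1e-2)
  }
})

test_that("aperture axial profile: center value, far field, preconditions", {
  a <- 0.61
  expect_equal(aperture_axial_profile(Q_REF, a, 0), Q_REF / (2 * pi * a^2))
  expect_equal(aperture_axial_profile(Q_REF, a, 1.256), 20, tolerance = 1e-3)
  # far-field ratio to the point sink -> 1
  x <- 50 * a
  expect_equal(aperture_axial_profile(Q_REF, a, x) * 2 * pi * x^2 / Q_REF, 1,
               tolerance = 5e-4)
  expect_error(aperture_axial_profile(100, -1, 1), "positive")
  expect_error(aperture_axial_profile(100, 1, -1), "non-negative")
})

test_that("sink sheet matches its uniform-density closed form on the axis and
           reduces to the point sink in the far field", {
  o <- circle_L()
  a <- orifice_equiv_radius_cm(o)
  sp <- sink_flow_spec(o, Q_REF, model = "sink_sheet", n_panels = 2000L)
  # uniform sheet axial velocity: Q/(pi a^2) (1 - x/sqrt(x^2+a^2))
  for (x in c(0.3, 0.61, 1, 2)) {
    u <- sink_velocity(sp, cbind(-x, 0, 0))[1L]
    u_exact <- Q_REF / (pi * a^2) * (1 - x / sqrt(x^2 + a^2))
    expect_equal(u, u_exact, tolerance = 5e-3)
  }
  # far field within 2% of the point sink at R = 10 a, for every shape
  for (o2 in list(circle_L(), slit_L(), drop_L())) {
    sp2 <- sink_flow_spec(o2, Q_REF, model = "sink_sheet")
    u <- sink_velocity(sp2, cbind(-10 * a, 0, 0))[1L]
    expect_equal(u * 2 * pi * (10 * a)^2 / Q_REF, 1, tolerance = 0.02)
  }
  # wall-plane points outside the orifice: no wall-normal component
  vw <- sink_velocity(sp, cbind(0, 2, 0.3))
  expect_equal(vw[1L], 0)
})

test_that("steady fields are discretely divergence-free away from the sink", {
  h <- 0.05
  g <- list(x = seq(-3, -1.5, by = h), y = seq(-0.6, 0.6, by = h),
            z = seq(-0.6, 0.6, by = h))
  for (f in list(point_sink_field(Q_REF, g),
                 sink_sheet_field(circle_L(), Q_REF, g))) {
    d <- dim(f$u)
    i <- 2:(d[1] - 1); j <- 2:(d[2] - 1); k <- 2:(d[3] - 1)
    ux <- (f$u[i + 1, j, k] - f$u[i - 1, j, k]) / (2 * h)
    vy <- (f$v[i, j + 1, k] - f$v[i, j - 1, k]) / (2 * h)
    wz <- (f$w[i, j, k + 1] - f$w[i, j, k - 1]) / (2 * h)
    div <- ux + vy + wz
    expect_lt(max(abs(div)) / max(abs(ux)), 0.01)
  }
})

test_that("confinement images elevate the far field monotonically", {
  o <- circle_L()
  sp <- function(k) sink_flow_spec(o, Q_REF, model = "aperture_exact",
                                   chamber_halfwidth = 4, image_order = k)
  u <- vapply(0:2, function(k) sink_velocity(sp(k), cbind(-3, 0, 0))[1L],
              numeric(1L))
  expect_true(all(diff(u) > 0))
  # image_order = 0 is identical to the unconfined model
  sp0 <- sink_flow_spec(o, Q_REF, model = "aperture_exact")
  expect_identical(sink_velocity(sp(0L), cbind(-2, 0, 0)),
                   sink_velocity(sp0, cbind(-2, 0, 0)))
  # grid constructor applies the images (point-sink core off-axis)
  spg <- function(k) sink_flow_spec(o, Q_REF, model = "point_sink",
                                    chamber_halfwidth = 4, image_order = k)
  g <- list(x = seq(-3, -1, by = 0.1), y = c(-0.1, 0, 0.1))
  f0 <- confined_sink_field(spg(0L), g)
  f2 <- confined_sink_field(spg(2L), g)
  expect_true(all(f2$u > f0$u))
})

test_that("spec constructor guards its preconditions", {
  expect_error(sink_flow_spec(circle_L(), -5), "positive")
  expect_error(sink_flow_spec(circle_L(), 100, chamber_halfwidth = 0.3),
               "half-dimension")
  expect_error(sink_flow_spec(circle_L(), 100, image_order = 2), "required")
  expect_error(sink_sheet_field(circle_L(), 100,
                                list(x = seq(-1, 0, by = 0.05),
                                     y = seq(-1, 1, by = 0.05))),
               "upstream")
})
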