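test_that("aperture error curve matches the -2 pi a^2 Va / Q closed form", {
  o <- circle_L()
  a <- orifice_equiv_radius_cm(o)
  ec <- error_curve(sink_flow_spec(o, Q_REF, model = "aperture_exact"))
  ok <- !ec$curve$no_crossing
  expect_true(all(ok))
  expect_lt(max(abs(ec$curve$rel_error + 2 * pi * a^2 * ec$curve$Va / Q_REF)),
            0.01)
  # at Va = 20 the error is ~ -19.1%
  expect_equal(ec$curve$rel_error[ec$curve$Va == 20], -0.191,
               tolerance = 5e-3)
  # point-sink curve is exact at every Va
  ec0 <- error_curve(sink_flow_spec(o, Q_REF, model = "point_sink"))
  expect_lt(max(abs(ec0$curve$rel_error)), 5e-3)
  # Va -> 0+ on the unconfined aperture model: error shrinks to 0
  ec_lo <- error_curve(sink_flow_spec(o, Q_REF, model = "aperture_exact"),
                       va_grid = c(0.5, 1, 2), s_max = 12)
  expect_true(all(diff(abs(ec_lo$curve$rel_error)) > 0))
  expect_lt(abs(ec_lo$curve$rel_error[1L]), 0.006)
})

test_that("optimal aliasing velocity: linear root, boundary flag,
           refinement-stable interior root", {
  # synthetic linear curve rel = 0.1 - 0.005 Va crosses zero at 20
  sp <- sink_flow_spec(circle_L(), Q_REF, model = "point_sink")
  fake <- structure(list(curve = data.frame(Va = c(10, 18, 22, 30),
                                            r = 1,
                                            rel_error = 0.1 - 0.005 * c(10, 18, 22, 30),
                                            no_crossing = FALSE),
                         spec = sp, beam = beam_spec()),
                    class = "sensitivity_curve")
  expect_equal(as.numeric(optimal_aliasing(fake)), 20)
  expect_false(attr(optimal_aliasing(fake), "boundary"))
  # monotone negative unconfined curve -> boundary optimum at min(va)
  ec <- error_curve(sink_flow_spec(circle_L(), Q_REF,
                                   model = "aperture_exact"))
  va_b <- optimal_aliasing(ec)
  expect_true(attr(va_b, "boundary"))
  expect_equal(as.numeric(va_b), min(ec$curve$Va))
  # confined curve has an interior root, stable under grid refinement
  spc <- sink_flow_spec(circle_L(), Q_REF, model = "aperture_exact",
                        chamber_halfwidth = 4, image_order = 2)
  v1 <- as.numeric(optimal_aliasing(error_curve(spc, va_grid = seq(5, 60, 2))))
  v2 <- as.numeric(optimal_aliasing(error_curve(spc, va_grid = seq(5, 60, 0.5))))
  expect_false(attr(optimal_aliasing(error_curve(spc)), "boundary"))
  expect_equal(v1, v2, tolerance = 0.05)
})

test_that("admissible band: closed-form edge, nesting, full grid at tol 1", {
  o <- circle_L()
  a <- orifice_equiv_radius_cm(o)
  ec <- error_curve(sink_flow_spec(o, Q_REF, model = "aperture_exact"))
  band <- admissible_band(ec, tol = 0.2)
  expect_equal(band[2L], 0.2 * Q_REF / (2 * pi * a^2), tolerance = 1e-3)
  full <- admissible_band(ec, tol = 1.0)
  expect_equal(full, range(ec$curve$Va))
  # shrinking tol shrinks the band monotonically
  b1 <- admissible_band(ec, 0.3); b2 <- admissible_band(ec, 0.15)
  expect_true(b2[1L] >= b1[1L] && b2[2L] <= b1[2L])
  expect_error(admissible_band(ec, tol = 1e-6), "exceeded")
})

test_that("|error| grows with circle diameter and the confined optimum
           shrinks with diameter", {
  sw <- sweep_shapes_sizes(circle_size_catalog(), Q_REF, va_grid = c(20),
                          model = "aperture_exact")
  expect_true(all(diff(abs(sw$rel_error)) > 0))
  stars <- vapply(c(8.7, 12.2, 16), function(d) {
    spc <- sink_flow_spec(make_orifice("circle", d), Q_REF,
                          model = "aperture_exact",
                          chamber_halfwidth = 4, image_order = 2)
    as.numeric(optimal_aliasing(error_curve(spc)))
  }, numeric(1L))
  expect_true(all(stars > 0))
  expect_true(all(diff(stars) < 0))
})

test_that("equal-area shape sweep orders slit >= drop >= circle in |error|", {
  specs <- list(circle_L(), slit_L(), drop_L())
  sw <- sweep_shapes_sizes(specs, Q_REF, va_grid = seq(10, 60, by = 10),
                          equal_area = TRUE, n_panels = 1000L)
  for (va in unique(sw$Va)) {
    e <- abs(sw$rel_error[sw$Va == va])
    names(e) <- sw$shape[sw$Va == va]
    expect_gte(e[["slit"]], e[["drop"]] - 0.005)
    expect_gte(e[["drop"]], e[["circle"]] - 0.005)
  }
})

test_that("unconfined error curves are dimensionally similar
           (depend on Va a^2 / Q only)", {
  o1 <- make_orifice("circle", 10)
  o2 <- make_orifice("circle", 20)           # a doubled
  ec1 <- error_curve(sink_flow_spec(o1, 100, model = "aperture_exact"),
                     va_grid = c(10, 20, 30))
  # lengths x2 => a^2 x4; scale Q by 4 at the same Va
  ec2 <- error_curve(sink_flow_spec(o2, 400, model = "aperture_exact"),
                     va_grid = c(10, 20, 30))
  expect_equal(ec1$curve$rel_error, ec2$curve$rel_error, tolerance = 1e-3)
})

test_that("no-crossing aliasing velocities are flagged, not dropped", {
  o <- make_orifice("circle", 20)
  ec <- error_curve(sink_flow_spec(o, Q_REF, model = "aperture_exact"),
                    va_grid = c(10, 20, 50))
  expect_identical(ec$curve$no_crossing, c(FALSE, FALSE, TRUE))
  expect_true(is.na(ec$curve$rel_error[3L]))
})
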