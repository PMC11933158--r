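test_that("beam projection follows the cosine of the beam angle", {
  g <- list(x = seq(-2, -1, by = 0.1), y = seq(-0.5, 0.5, by = 0.1))
  uni <- velocity_field(g$x, g$y,
                        u = matrix(10, 11, 11), v = matrix(0, 11, 11))
  expect_equal(beam_project(uni, beam_spec(0))$vp, matrix(10, 11, 11))
  expect_equal(beam_project(uni, beam_spec(60))$vp[1, 1], 5, tolerance = 1e-12)
  perp <- velocity_field(g$x, g$y,
                         u = matrix(0, 11, 11), v = matrix(3, 11, 11))
  expect_equal(max(abs(beam_project(perp, beam_spec(0))$vp)), 0)
  expect_error(beam_spec(95), "90")
})

test_that("pisa_radius recovers the point-sink and aperture closed forms", {
  f <- point_sink_field(Q_REF, sink_grid())
  pf <- beam_project(f)
  r <- pisa_radius(pf, beam_spec(), Va = 20)
  expect_equal(r, sqrt(Q_REF / (2 * pi * 20)), tolerance = 5e-4)
  sp <- sink_flow_spec(circle_L(), Q_REF, model = "aperture_exact")
  r2 <- pisa_radius(sp, beam_spec(), Va = 20)
  a <- orifice_equiv_radius_cm(circle_L())
  expect_equal(r2, sqrt(Q_REF / (2 * pi * 20) - a^2), tolerance = 1e-3)
})

test_that("pisa_radius signals out-of-range aliasing velocities", {
  f <- point_sink_field(Q_REF, sink_grid())
  pf <- beam_project(f)
  expect_error(pisa_radius(pf, beam_spec(), Va = 1e5), "too high")
  expect_error(pisa_radius(pf, beam_spec(), Va = 2), "outside the sampled")
  expect_error(pisa_radius(pf, beam_spec(), Va = -5), "positive")
})

test_that("r(Va) is strictly decreasing on a monotone-decaying ray", {
  f <- point_sink_field(Q_REF, sink_grid())
  pf <- beam_project(f)
  rr <- vapply(c(10, 20, 40, 60), function(v)
    pisa_radius(pf, beam_spec(), v), numeric(1L))
  expect_true(all(diff(rr) < 0))
})

test_that("flow-convergence arithmetic matches the hemispheric relations", {
  expect_equal(regurgitant_flow(1.0, 40), 2 * pi * 40, tolerance = 1e-12)
  expect_equal(regurgitant_flow(0, 25), 0)
  expect_equal(regurgitant_flow(sqrt(Q_REF / (2 * pi * 20)), 20), Q_REF)
  expect_error(regurgitant_flow(-1, 20), "non-negative")
  expect_equal(eroa(251.33, 500), 0.50266)
  expect_equal(eroa(100, 100), 1)
  expect_equal(eroa(0, 500), 0)
  expect_error(eroa(100, 0), "positive")
  expect_equal(rvol(0.5, 100), 50)
  expect_equal(rvol(0.4, 75), 30)
  expect_equal(rvol(0, 17), 0)
  expect_error(rvol(-0.1, 10), "non-negative")
})

test_that("vmax_and_vti integrates velocity traces correctly", {
  # rectangular trace: 100 cm/s over 0.3 s -> VTI 30 cm
  tr <- data.frame(t = seq(0, 400, by = 1),
                   v = ifelse(seq(0, 400, 1) <= 300, 100, 0))
  out <- vmax_and_vti(tr, window = c(0, 300))
  expect_equal(out$Vmax, 100)
  expect_equal(out$VTI, 30, tolerance = 1e-6)
  # half-sine peak 100 cm/s over 0.3 s -> VTI (2/pi)*30
  t2 <- seq(0, 300, by = 0.5)
  out2 <- vmax_and_vti(data.frame(t = t2, v = 100 * sin(pi * t2 / 300)),
                       window = c(0, 300))
  expect_equal(out2$VTI, 2 / pi * 30, tolerance = 1e-4)
  # all-zero trace
  out0 <- vmax_and_vti(data.frame(t = t2, v = 0 * t2), window = c(0, 300))
  expect_equal(out0$Vmax, 0)
  expect_equal(out0$VTI, 0)
})

test_that("full estimator chain is exact on the ideal sink", {
  ser <- steady_series(point_sink_field(Q_REF, sink_grid()))
  est <- pisa_estimate(ser, Va = 20, window = c(0, 300))
  expect_equal(est$RFlow, Q_REF, tolerance = 5e-3)
  expect_equal(est$RFlow, 2 * pi * est$r^2 * est$Va, tolerance = 1e-12)
  expect_equal(est$RVol, est$EROa * est$VTI, tolerance = 1e-12)
  expect_equal(est$EROa, est$RFlow / est$Vmax, tolerance = 1e-12)
})

test_that("a zero-flow series yields an all-zero measurement", {
  g <- sink_grid(dx = 0.1)
  zero <- velocity_field(g$x, g$y,
                         u = matrix(0, length(g$x), length(g$y)),
                         v = matrix(0, length(g$x), length(g$y)))
  est <- pisa_estimate(steady_series(zero), Va = 30, window = c(0, 300))
  expect_equal(unlist(est[c("r", "RFlow", "Vmax", "VTI", "EROa", "RVol")]),
               c(r = 0, RFlow = 0, Vmax = 0, VTI = 0, EROa = 0, RVol = 0))
})

test_that("a tilted beam lowers the measured regurgitant flow", {
  ser <- steady_series(point_sink_field(Q_REF, sink_grid()))
  est0 <- pisa_estimate(ser, 20, window = c(0, 300))
  estT <- pisa_estimate(ser, 20, beam = beam_spec(25.8), window = c(0, 300))
  expect_lt(estT$RFlow, est0$RFlow)
  # projection reduces the on-ray velocity by cos(25.8 deg) ~ 0.90
  expect_equal(estT$RFlow / est0$RFlow, cos(25.8 * pi / 180),
               tolerance = 1e-3)
})

test_that("estimate is invariant under grid refinement", {
  est1 <- pisa_estimate(steady_series(point_sink_field(Q_REF, sink_grid(0.05))),
                        20, window = c(0, 300))
  est2 <- pisa_estimate(steady_series(point_sink_field(Q_REF, sink_grid(0.025))),
                        20, window = c(0, 300))
  expect_equal(est1$RFlow, est2$RFlow, tolerance = 5e-3)
})
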