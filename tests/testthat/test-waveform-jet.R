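test_that("waveform hits its programmed peaks and is zero outside systole", {
  w <- waveform()
  expect_equal(pulse_waveform(w, w$t_global_peak), w$U_global)
  expect_equal(pulse_waveform(w, w$t_local_peak), w$U_local)
  expect_identical(pulse_waveform(w, c(0, 100, 600, 749)), rep(0, 4))
  # the local peak is a strict local maximum (finite differences)
  for (h in c(0.5, 2, 5))
    expect_true(all(pulse_waveform(w, w$t_local_peak) >
                      pulse_waveform(w, w$t_local_peak + c(-h, h))))
  # the global peak is the global maximum
  tt <- seq(w$systole[1L], w$systole[2L], by = 0.25)
  expect_lte(max(pulse_waveform(w, tt)), w$U_global * (1 + 1e-9))
  # a genuine dip exists between the peaks
  expect_lt(min(pulse_waveform(w, seq(211, 244, by = 0.5))), w$U_local)
})

test_that("the decay tail follows the programmed time constant", {
  w <- waveform()
  t1 <- w$t_global_peak + 100; t2 <- w$t_global_peak + 200
  slope <- (log(pulse_waveform(w, t2)) - log(pulse_waveform(w, t1))) / (t2 - t1)
  expect_equal(slope, -1 / w$decay_tau, tolerance = 0.3)
})

test_that("waveform invariants are enforced", {
  expect_error(waveform(t_local_peak = 250, t_global_peak = 245), "precede")
  expect_error(waveform(U_local = 200, U_global = 150), "U_global >= U_local")
  expect_error(waveform(decay_tau = -1), "positive")
})

test_that("42-phase trapezoidal sampling resolves the waveform integral", {
  w <- waveform()
  tt <- cardiac_phases()
  expect_equal(length(tt), 42L)
  tr <- pracma::trapz(tt, pulse_waveform(w, tt)) / 1000
  expect_equal(tr, waveform_integral(w), tolerance = 2e-3)
})

test_that("jet exit profile: block for beta=0, saddle algebra for beta>0", {
  o <- circle_L()
  a <- o$h / 20
  g <- jet_exit_grid(o, y_halfwidth = 1, n_x = 1L)
  w <- waveform()
  ser0 <- jet_exit_series(jet_spec(o, w, beta = 0), g)
  pk <- which.max(vapply(ser0$fields, function(f) max(f$u), numeric(1L)))
  inside <- abs(g$y) < a - 0.06
  prof0 <- ser0$fields[[pk]]$u[1L, ]
  expect_lt(diff(range(prof0[inside])) / max(prof0), 1e-9)   # flat block
  ser3 <- jet_exit_series(jet_spec(o, w, beta = 0.3), g)
  prof3 <- ser3$fields[[pk]]$u[1L, ]
  i0 <- which.min(abs(g$y))
  # center-to-max ratio 1/(1+beta); the sampled maximum sits one cell
  # inside the rim, hence the grid-scale tolerance
  expect_equal(prof3[i0] / max(prof3), 1 / 1.3, tolerance = 2e-2)
  # maximum sits at the orifice edge region
  expect_gt(abs(g$y[which.max(prof3)]), 0.8 * a)
})

test_that("programmed RVol follows U(t) * area closed form", {
  o <- circle_L()
  w <- waveform()
  ser <- small_jet_series(o, w = w)
  expect_equal(ser$programmed_rvol,
               orifice_area_cm2(o) * waveform_integral(w), tolerance = 1e-9)
  # linear scaling to a target volume
  w30 <- scale_waveform_to_rvol(w, o, 30)
  expect_equal(orifice_area_cm2(o) * waveform_integral(w30), 30,
               tolerance = 1e-6)
})

test_that("jet generator rejects grids that cannot program the flow", {
  o <- slit_L()
  expect_error(jet_exit_series(jet_spec(o, waveform()),
                               list(x = 0.05, y = seq(-2, 2, 0.05), z = NULL)),
               "z axis is required")
  o2 <- circle_L()
  expect_error(jet_exit_series(jet_spec(o2, waveform()),
                               list(x = 0.05, y = seq(0.7, 2, 0.05), z = NULL)),
               "cover the orifice")
})

test_that("piv_sample is reproducible and unbiased, with 1/sqrt(n) averaging", {
  ser <- small_jet_series()
  e1 <- piv_sample(ser, 0.05323, noise_sd = 5, n_frames = 4, seed = 42)
  e2 <- piv_sample(ser, 0.05323, noise_sd = 5, n_frames = 4, seed = 42)
  expect_identical(e1$frames, e2$frames)
  # noise-free single frame reproduces the (interpolated) truth
  e0 <- piv_sample(ser, 0.05323, noise_sd = 0, n_frames = 1, seed = 1)
  pk <- which.max(vapply(ser$fields, function(f) max(f$u), numeric(1L)))
  expect_equal(e0$frames[[pk]]$u[1, , 1], unname(ser$fields[[pk]]$u[1, ]),
               tolerance = 1e-9)
  # ensemble-mean error shrinks like 1/sqrt(n)
  rmse <- function(n) sqrt(mean(vapply(1:20, function(s) {
    e <- piv_sample(ser, 0.05323, noise_sd = 5, n_frames = n, seed = s)
    mean((apply(e$frames[[pk]]$u, 1:2, mean) - ser$fields[[pk]]$u)^2)
  }, numeric(1L))))
  expect_equal(rmse(4) / rmse(64), 4, tolerance = 0.25)
  expect_error(piv_sample(ser, 0.01), "native grid spacing")
})
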