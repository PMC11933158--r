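# shared fixtures; everything is generated in code, nothing is stored

Q_REF <- 244.9   # reference steady flow rate (ml/s) of the sensitivity study

circle_L <- function() make_orifice("circle", 12.2, label = "circle-L")
slit_L <- function() make_orifice("slit", 7.3, 22.9, label = "slit-L")
drop_L <- function() make_orifice("drop", 9.0, 19.8, label = "drop-L")

# convergence-side grid with the scan ray (y = 0) well resolved
sink_grid <- function(dx = 0.025, x_min = -2.6, y_half = 0.5) {
  list(x = seq(x_min, -2.4 * dx, by = dx),
       y = seq(-y_half, y_half, by = dx))
}

# single-phase steady series wrapping one field
steady_series <- function(field) field_series(0, list(field))

# small, fast default jet for structural tests (not paper-scale)
small_jet_series <- function(orifice = circle_L(), beta = 0.3,
                             y_halfwidth = 1, n_x = 1L,
                             w = waveform()) {
  jet_exit_series(jet_spec(orifice, w, beta = beta),
                  jet_exit_grid(orifice, y_halfwidth = y_halfwidth, n_x = n_x))
}

lamb_oseen_field <- function(h, Gamma = 10, rc = 0.3) {
  g <- seq(-1, 1, by = h)
  vth <- function(r) ifelse(r < 1e-12, 0,
                            Gamma / (2 * pi * r) * (1 - exp(-r^2 / rc^2)))
  u <- outer(g, g, function(x, y) {
    r <- sqrt(x^2 + y^2); -vth(r) * ifelse(r < 1e-12, 0, y / r) })
  v <- outer(g, g, function(x, y) {
    r <- sqrt(x^2 + y^2); vth(r) * ifelse(r < 1e-12, 0, x / r) })
  velocity_field(g, g, u, v)
}

lamb_oseen_q <- function(x, y, Gamma = 10, rc = 0.3) {
  r <- pmax(sqrt(x^2 + y^2), 1e-9)
  om <- Gamma / (pi * rc^2) * exp(-r^2 / rc^2)
  srt <- Gamma / (2 * pi * r^2) *
    ((r^2 / rc^2) * exp(-r^2 / rc^2) - (1 - exp(-r^2 / rc^2)))
  om^2 / 4 - srt^2
}

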