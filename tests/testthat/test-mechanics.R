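make_multisine <- function(Z, grid, fs = 256, duration = 8) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  flow <- rowSums(sapply(as.numeric(grid), function(f) sin(2 * pi * f * t)))
  pres <- rowSums(sapply(seq_along(grid), function(i) {
    f <- as.numeric(grid)[i]
    Mod(Z[i]) * sin(2 * pi * f * t + Arg(Z[i]))
  }))
  oscillation_record(t, pres, flow)
}

test_that("Z_rs from signals identifies elementary elements", {
  grid <- frequency_grid(2)
  fs <- 256; t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  flow <- sin(2 * pi * 2 * t)
  # purely resistive: pressure = R * flow
  rec <- oscillation_record(t, 7 * flow, flow)
  z <- zrs_from_signals(rec, grid)
  expect_equal(Re(z$Z), 7, tolerance = 1e-9)
  expect_equal(Im(z$Z), 0, tolerance = 1e-9)
  # purely elastic: pressure = E * integral(flow): X = -E/(2 pi f)
  E <- 50
  pres <- E * (1 - cos(2 * pi * 2 * t)) / (2 * pi * 2)
  z2 <- zrs_from_signals(oscillation_record(t, pres, flow), grid)
  expect_equal(Im(z2$Z), -E / (2 * pi * 2), tolerance = 1e-6)
  # off-grid frequency is an error
  expect_error(zrs_from_signals(rec, frequency_grid(2.1)), "transform grid")
})

test_that("multisine synthesis/analysis round trip recovers the spectrum", {
  grid <- default_frequencies()
  Z <- constant_phase_impedance(constant_phase_params(0.5, 0.01, 5, 30), grid)$Z
  rec <- make_multisine(Z, grid)
  zr <- zrs_from_signals(rec, grid)
  expect_lt(max(Mod(zr$Z - Z) / Mod(Z)), 1e-6)
  # linear in pressure, inverse-linear in flow amplitude
  rec2 <- oscillation_record(rec$time, 3 * rec$pressure, rec$flow)
  expect_equal(zrs_from_signals(rec2, grid)$Z, 3 * zr$Z, tolerance = 1e-9)
  rec3 <- oscillation_record(rec$time, rec$pressure, 2 * rec$flow)
  expect_equal(zrs_from_signals(rec3, grid)$Z, zr$Z / 2, tolerance = 1e-9)
})

test_that("constant-phase inverse fit recovers noise-free parameters", {
  grid <- default_frequencies()
  truth <- c(Rn = 0.5, I = 0.01, G = 5, H = 30)
  spec <- constant_phase_impedance(do.call(constant_phase_params, as.list(truth)), grid)
  fit <- fit_constant_phase(spec)
  expect_lt(max(abs(c(fit$Rn, fit$I, fit$G, fit$H) - truth) / truth), 1e-3)
  expect_true(attr(fit, "converged"))
  # eta is exactly the fitted G/H
  expect_identical(fit$eta, fit$G / fit$H)
  # degenerate all-zero spectrum is flagged, not fitted
  z0 <- impedance_spectrum(grid, rep(0 + 0i, 17))
  expect_true(attr(fit_constant_phase(z0), "degenerate"))
})

test_that("PV hysteresis area matches geometry and a quadrature oracle", {
  p <- seq(0, 10, length.out = 9)
  coincident <- pv_loop(data.frame(pressure = p, volume = p / 50),
                        data.frame(pressure = p, volume = p / 50), peep = 0)
  expect_equal(pv_loop_area(coincident), 0)
  # constant offset 0.1 mL over 10 cmH2O: rectangle of area 1.0
  rect <- pv_loop(data.frame(pressure = p, volume = p / 50),
                  data.frame(pressure = p, volume = p / 50 + 0.1), peep = 0)
  expect_equal(pv_loop_area(rect), 1.0, tolerance = 1e-12)
  # sign preserved when the expiratory limb lies below
  neg <- pv_loop(data.frame(pressure = p, volume = p / 50 + 0.05),
                 data.frame(pressure = p, volume = p / 50), peep = 0)
  expect_equal(pv_loop_area(neg), -0.5, tolerance = 1e-12)
  # random monotone limbs vs an independent trapezoid summation
  set.seed(31)
  vi <- cumsum(runif(9, 0.01, 0.05)); ve <- vi + runif(9, 0, 0.03)
  loop <- pv_loop(data.frame(pressure = p, volume = vi),
                  data.frame(pressure = p, volume = ve), peep = 0)
  d <- ve - vi
  oracle <- sum(diff(p) * (d[-9] + d[-1]) / 2)
  expect_equal(pv_loop_area(loop), oracle, tolerance = 1e-12)
  expect_error(pv_loop_area(pv_loop(data.frame(pressure = 1, volume = 1),
                                    data.frame(pressure = 1, volume = 1))),
               "2 points")
})

test_that("step elastances and E_min follow the inflation limb", {
  p <- seq(2, 12, length.out = 9)
  lin <- pv_loop(data.frame(pressure = p, volume = p / 50),
                 data.frame(pressure = p, volume = p / 50), peep = 2)
  el <- pv_elastances(lin)
  expect_equal(el$whole, 50, tolerance = 1e-9)
  expect_length(el$step, 8L)
  expect_equal(el$step, rep(50, 8), tolerance = 1e-9)
  expect_equal(el$E_min, 50, tolerance = 1e-9)
  # engineered nadir: step 5 has the designed compliance
  E_steps <- c(80, 70, 60, 50, 42, 55, 65, 90)
  v <- cumsum(c(0, diff(p) / E_steps))
  eng <- pv_loop(data.frame(pressure = p, volume = v),
                 data.frame(pressure = p, volume = v), peep = 2)
  el2 <- pv_elastances(eng)
  expect_equal(el2$E_min, 42, tolerance = 1e-9)
  expect_equal(which.min(el2$step), 5L)
  # zero-volume step reports infinite elastance and is excluded from E_min
  v3 <- v; v3[3] <- v3[2]
  el3 <- pv_elastances(pv_loop(data.frame(pressure = p, volume = v3),
                               data.frame(pressure = p, volume = v3), peep = 2))
  expect_true(is.infinite(el3$step[2]))
  expect_true(is.finite(el3$E_min))
})

test_that("open fraction is hyperbolic in H_CP and clipped to [0, 1]", {
  expect_equal(estimate_fopen(40, 40), 1)
  expect_equal(estimate_fopen(40, 80), 0.5)
  expect_equal(estimate_fopen(50, 40), 1)   # clipped, never exceeds 1
  # strictly decreasing in H_CP at fixed E_min
  H <- seq(45, 120, by = 5)
  f <- vapply(H, function(h) estimate_fopen(40, h), 0)
  expect_true(all(diff(f) < 0))
  expect_error(estimate_fopen(-1, 40), "E_min")
  expect_error(estimate_fopen(40, 0), "H_CP")
})

test_that("PV loop CSV interface round-trips", {
  p <- seq(3, 13, length.out = 9)
  loop <- pv_loop(data.frame(pressure = p, volume = p / 60),
                  data.frame(pressure = p, volume = p / 60 + 0.02), peep = 3)
  f <- tempfile(fileext = ".csv")
  d <- rbind(data.frame(limb = "insp", pressure_cmH2O = loop$insp$pressure,
                        volume_mL = loop$insp$volume),
             data.frame(limb = "exp", pressure_cmH2O = loop$exp$pressure,
                        volume_mL = loop$exp$volume))
  utils::write.csv(d, f, row.names = FALSE)
  back <- read_pv_loop(f, peep = 3)
  expect_equal(pv_loop_area(back), pv_loop_area(loop), tolerance = 1e-12)
  expect_equal(pv_elastances(back)$E_min, pv_elastances(loop)$E_min)
})
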