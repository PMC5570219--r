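test_that("constant-phase model evaluates to its closed form", {
  # at omega = 1 rad/s (f = 1/2pi Hz): Z = Rn + G + j(I - H)
  g1 <- frequency_grid(1 / (2 * pi))
  p <- constant_phase_params(0.5, 0.01, 5, 30)
  z <- constant_phase_impedance(p, g1)$Z
  expect_equal(Re(z), 0.5 + 5, tolerance = 1e-12)
  expect_equal(Im(z), 0.01 - 30, tolerance = 1e-12)

  # G -> 0: alpha -> 1 and the tissue term -> -jH/omega (pure elastance)
  p0 <- constant_phase_params(0, 0, 0, 30)
  expect_equal(p0$alpha, 1)
  g <- default_frequencies()
  z0 <- constant_phase_impedance(p0, g)$Z
  expect_equal(Im(z0), -30 / attr(g, "omega"), tolerance = 1e-12)
  expect_equal(Re(z0), rep(0, 17), tolerance = 1e-12)

  # independent closed-form evaluation at f = 2 Hz
  gf <- frequency_grid(2)
  pp <- constant_phase_params(0.5, 0.01, 5, 30)
  w <- 2 * pi * 2
  alpha <- (2 / pi) * atan(30 / 5)
  z_hand <- 0.5 + 1i * w * 0.01 + (5 - 30i) / w^alpha
  expect_equal(constant_phase_impedance(pp, gf)$Z, z_hand, tolerance = 1e-12)

  expect_error(constant_phase_params(0.5, 0.01, -1, 30), "non-negative")
})

test_that("segment impedance obeys Poiseuille/inertance scaling and additivity", {
  const <- physical_constants()
  a <- segment_impedance(0.4, 2, const)
  b <- segment_impedance(0.2, 2, const)
  expect_equal(b$R_seg / a$R_seg, 16, tolerance = 1e-12)
  expect_equal(b$I_seg / a$I_seg, 4, tolerance = 1e-12)
  # two half-length segments in series reproduce the full segment
  h <- segment_impedance(0.4, 1, const)
  expect_equal(2 * h$R_seg, a$R_seg, tolerance = 1e-12)
  expect_equal(2 * h$I_seg, a$I_seg, tolerance = 1e-12)
  expect_error(segment_impedance(-1, 2), "positive")
})

test_that("gas-compression shunt matches the hand-computed adiabatic form", {
  # |Z_g| at 1 Hz for V_seg = 0.01 mL: gamma P0 / (omega V)
  const <- physical_constants(adiabatic_index = 1.4, ambient_pressure = 1033)
  r <- 0.3; l <- 0.01 * 1000 / (pi * r^2)  # so that V = 0.01 mL
  comp <- segment_impedance(r, l, const)
  w <- 2 * pi * 1
  expect_equal(1 / (w * comp$C_g), 1.4 * 1033 / (w * 0.01), tolerance = 1e-9)
})

test_that("symmetric tree with negligible airway impedance gives Z_t / N", {
  tab <- balanced_ct(2)                      # 4 terminals
  tree <- build_tree(tab, seed = 1)
  vac <- physical_constants(air_viscosity = 1e-300, air_density = 1e-300)
  grid <- default_frequencies()
  Zt <- constant_phase_impedance(constant_phase_params(0.1, 1e-3, 20, 120), grid)$Z
  zin <- network_input_impedance(tree, Zt, vac, grid,
                                 gas_shunt = FALSE, wall_shunt = FALSE)
  expect_equal(zin$Z, Zt / 4, tolerance = 1e-9)
})

test_that("recursive network equals the explicit ladder enumeration oracle", {
  const <- physical_constants()
  grid <- default_frequencies()
  for (gens in 0:3) {
    tab <- balanced_ct(gens)
    tree <- build_tree(tab, seed = gens + 1)
    Zterm <- random_cp_terminals(tree$n_terminal, grid, seed = 100 + gens)
    fast <- network_input_impedance(tree, Zterm, const, grid)
    slow <- ladder_impedance(tree, Zterm, const, grid)
    expect_lt(max(Mod(fast$Z - slow) / Mod(slow)), 1e-9)
  }
})

test_that("collapsed subtrees are pruned exactly (open-circuit equivalence)", {
  const <- physical_constants()
  grid <- default_frequencies()
  # full tree: root -> (c1, c2); c1 -> 2 leaves; c2 -> 2 leaves
  full <- ct_only_table(data.frame(
    id = c("r", "c1", "c2", "l1", "l2", "l3", "l4"),
    parent = c(NA, "r", "r", "c1", "c1", "c2", "c2"),
    length_mm = c(6, 4, 3, 2, 2.2, 1.8, 2.1),
    radius_mm = c(0.9, 0.7, 0.75, 0.55, 0.6, 0.58, 0.62)))
  pruned <- ct_only_table(data.frame(
    id = c("r", "c2", "l3", "l4"),
    parent = c(NA, "r", "c2", "c2"),
    length_mm = c(6, 3, 1.8, 2.1),
    radius_mm = c(0.9, 0.75, 0.58, 0.62)))
  tree_f <- build_tree(full, seed = 1)
  tree_p <- build_tree(pruned, seed = 1)
  Zt <- constant_phase_impedance(constant_phase_params(0.1, 1e-3, 2e4, 1.2e5), grid)$Z
  Zm <- matrix(Zt, 4, 17, byrow = TRUE)
  Zm[1:2, ] <- complex(real = Inf, imaginary = Inf)  # l1, l2 collapsed
  z_collapsed <- network_input_impedance(tree_f, Zm, const, grid)
  z_pruned <- network_input_impedance(tree_p, matrix(Zt, 2, 17, byrow = TRUE),
                                      const, grid)
  expect_equal(z_collapsed$Z, z_pruned$Z, tolerance = 0)
  # fully non-ventilated lung is an explicit error
  Zm[] <- complex(real = Inf, imaginary = Inf)
  expect_error(network_input_impedance(tree_f, Zm, const, grid),
               "non-communicating")
})

test_that("simulated spectra are passive and 17 points on the default grid", {
  tab <- generate_morphometry_fixture()
  tree <- build_tree(tab, seed = 11)
  spec <- tissue_model_spec(0L, FALSE, H0 = 51.1, eta = 0.18)
  a <- assign_tissue_elastances(spec, tree$n_terminal,
                                p_collapse = 0.2, seed = 12)
  z <- simulate_lung_spectrum(tree, a)
  expect_length(z$Z, 17L)
  expect_true(all(Re(z$Z) > 0))
  expect_true(all(Im(z$Z)[1:5] < 0))  # elastance-dominated at low frequency
})

test_that("homogeneous recruited lung aggregates to the parallel closed form", {
  tab <- generate_morphometry_fixture()
  tree <- build_tree(tab, seed = 3)
  spec <- tissue_model_spec(0L, FALSE, H0 = 47, eta = 0.2)
  a <- assign_tissue_elastances(spec, tree$n_terminal)
  # with airway impedance suppressed the network is N identical elements in
  # parallel: the fit must recover the lung-scale values exactly
  vac <- physical_constants(air_viscosity = 1e-300, air_density = 1e-300)
  z <- simulate_lung_spectrum(tree, a, const = vac,
                              gas_shunt = FALSE, wall_shunt = FALSE)
  fit <- fit_constant_phase(z)
  expect_equal(fit$H, 47, tolerance = 1e-6)
  expect_equal(fit$eta, 0.2, tolerance = 1e-6)
  # with full airway physics the aggregate H is recovered within 2%
  fit2 <- fit_constant_phase(simulate_lung_spectrum(tree, a))
  expect_equal(fit2$H, 47, tolerance = 0.02)
})

test_that("wall shunt default perturbs a healthy lung by under 1%", {
  tab <- generate_morphometry_fixture()
  tree <- apply_radial_scale(build_tree(tab, seed = 4), 0.53)
  a <- assign_tissue_elastances(tissue_model_spec(0L, FALSE, H0 = 51.1, eta = 0.18),
                                tree$n_terminal)
  on <- simulate_lung_spectrum(tree, a)
  off <- simulate_lung_spectrum(tree, a, wall_shunt = FALSE)
  i1 <- which.min(abs(as.numeric(default_frequencies()) - 1))
  expect_lt(Mod(on$Z[i1] - off$Z[i1]) / Mod(off$Z[i1]), 0.01)
})
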