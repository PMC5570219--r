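test_that("total error sums squared R and X residuals over the grid", {
  grid <- default_frequencies()
  z <- constant_phase_impedance(constant_phase_params(0.5, 0.01, 5, 30), grid)
  expect_equal(model_error(z, z), 0)
  # R offset by 1 at all 17 frequencies, X equal -> 17
  z1 <- impedance_spectrum(grid, z$Z + 1)
  expect_equal(model_error(z, z1), 17)
  # random pair vs independent elementwise summation; invariant to frequency order
  set.seed(5)
  a <- impedance_spectrum(grid, complex(real = runif(17), imaginary = -runif(17)))
  b <- impedance_spectrum(grid, complex(real = runif(17), imaginary = -runif(17)))
  oracle <- sum((Re(a$Z) - Re(b$Z))^2) + sum((Im(a$Z) - Im(b$Z))^2)
  expect_equal(model_error(a, b), oracle, tolerance = 1e-12)
  expect_equal(model_error(a, b), model_error(b, a))
  expect_error(model_error(a, impedance_spectrum(frequency_grid(1:17), b$Z)),
               "grid")
})

test_that("likelihood ratio is the two-log form with natural logs", {
  expect_equal(likelihood_ratio(3, 3), 0)
  expect_equal(likelihood_ratio(3 / exp(1), 3), 2, tolerance = 1e-12)
  # hand-computed toy table preserves SSR ordering (smaller SSR, larger L)
  ssr <- c(0.5, 1.2, 0.02, 7)
  L <- vapply(ssr, likelihood_ratio, 0, ssr_0 = 1.2)
  expect_equal(L, -2 * log(ssr) + 2 * log(1.2), tolerance = 1e-12)
  expect_identical(order(L), order(ssr, decreasing = TRUE))
  # antisymmetry: swapping model and null negates L
  expect_equal(likelihood_ratio(0.5, 2), -likelihood_ratio(2, 0.5))
  expect_error(likelihood_ratio(0, 1), "positive")
})

test_that("radial scale bisection flags boundaries and responds monotonically", {
  tab <- generate_morphometry_fixture()
  cp <- constant_phase_params(0.2, 1e-4, 0.18 * 51.1, 51.1)
  tree_t <- build_tree(tab, seed = 500)
  a <- assign_tissue_elastances(tissue_model_spec(0L, FALSE, H0 = 51.1, eta = 0.18),
                                tree_t$n_terminal)
  # a target whose resistance is below anything the tree family can reach
  # pins every estimate at the upper boundary, flagged
  target1 <- simulate_lung_spectrum(tree_t, a)
  target_lo <- impedance_spectrum(target1$freq, target1$Z - 0.05,
                                  role = "experimental")
  est1 <- estimate_radius_scale(tab, target_lo, cp, replicates = 3, seed = 1)
  expect_gt(est1$mean, 0.99)
  expect_true(all(est1$boundary))
  # uniformly increasing target resistance decreases the estimate
  target_hiR <- impedance_spectrum(target1$freq, target1$Z + 0.5,
                                   role = "experimental")
  est2 <- estimate_radius_scale(tab, target_hiR, cp, replicates = 3, seed = 1)
  expect_lt(est2$mean, est1$mean)
})

test_that("scalar H0 optimisation self-fits with near-zero residual", {
  tab <- generate_morphometry_fixture()
  spec0 <- tissue_model_spec(0L, FALSE, H0 = 1, eta = 0.18)
  control <- simulate_lung_spectrum(
    apply_radial_scale(build_tree(tab, seed = 5), 0.53),
    assign_tissue_elastances(tissue_model_spec(0L, FALSE, H0 = 50, eta = 0.18),
                             1398, seed = 6))
  h0 <- estimate_H0(tab, spec0, control, r_over_r0 = 0.53,
                    replicates = 5, seed = 11)
  expect_equal(h0$mean, 50, tolerance = 0.02)
  # homogeneous model fit to homogeneous data: residual small vs |Z|^2 scale
  expect_lt(mean(h0$residuals), 0.05 * sum(Mod(control$Z)^2) / 17)
})

test_that("model comparison enumerates 8 models and is null-consistent on control", {
  tab <- generate_morphometry_fixture()
  h <- generate_histology(cohort_config(), seed = 21)
  lam0 <- mean(h$fibers$wt_8)
  models <- all_tissue_models(51.1, eta = 0.18, lambda0 = lam0)
  ctrl <- list(rac_dist = h$rac$wt_8, fiber_dist = h$fibers$wt_8,
               f_open = 0.79, r_over_r0 = 0.53)
  # data spectrum: any fixed target; with condition == control inputs the
  # replicate-matched null simulation is identical, so L == 0 exactly
  tree <- apply_radial_scale(build_tree(tab, seed = 77), 0.53)
  data_spec <- simulate_lung_spectrum(
    tree, assign_tissue_elastances(models[["RAC0"]], tree$n_terminal,
                                   p_collapse = 0.21, seed = 78))
  cmp <- run_model_comparison(tab,
    conditions = list(ctrl = c(list(spectrum = data_spec), ctrl)),
    control = ctrl, models = models, replicates = 3, seed = 9)
  expect_equal(nrow(cmp$summary), 8L)
  expect_setequal(cmp$summary$model, names(models))
  expect_equal(cmp$results$L, rep(0, nrow(cmp$results)))
  expect_true(all(cmp$results$phi >= 0))
})

test_that("PEEP error-variance ratio matches hand computation and flags degeneracy", {
  r <- peep_variance_ratio(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))
  expect_equal(r$var_with, 2.5)
  expect_equal(r$var_without, 10)
  expect_equal(r$ratio, 0.25)
  # recruitment removing all PEEP dependence: ratio 0
  r0 <- peep_variance_ratio(c(1, 1, 1, 1, 1), c(1, 2, 3, 4, 5))
  expect_equal(r0$ratio, 0)
  # identical flat errors in both arms: undefined and flagged
  rd <- peep_variance_ratio(rep(2, 5), rep(3, 5))
  expect_true(rd$undefined)
  expect_true(is.na(rd$ratio))
  expect_error(peep_variance_ratio(1, c(1, 2)), "2 PEEP")
})

test_that("modeled recruitment removes most PEEP dependence of the error", {
  # synthetic subject whose ground truth has PEEP-dependent recruitment;
  # simulate at each PEEP with and without the recruitment arm
  tab <- generate_morphometry_fixture()
  tree <- build_tree(tab, seed = 301)
  truth <- ground_truth(noise_sigma = 0)
  exper <- generate_experiment(truth, tree, seed = 302)
  spec0 <- tissue_model_spec(0L, FALSE, H0 = truth$H0, eta = truth$eta)
  phi <- function(with_recruitment) {
    vapply(as.character(truth$peeps), function(k) {
      sims <- vapply(1:6, function(r) {
        tr <- apply_radial_scale(build_tree(tab, seed = 400 + r), truth$r_over_r0[k])
        a <- assign_tissue_elastances(
          spec0, tr$n_terminal,
          p_collapse = if (with_recruitment) 1 - truth$f_open[k] else 0,
          seed = 500 + r)
        model_error(exper$spectra[[k]], simulate_lung_spectrum(tr, a))
      }, 0)
      mean(sims)
    }, 0)
  }
  res <- peep_variance_ratio(phi(TRUE), phi(FALSE))
  expect_lt(res$ratio, 0.1)
})
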