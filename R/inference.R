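#' Total model error between two impedance spectra
#'
#' Goodness of fit of a simulated spectrum to data: the sum over the
#' frequency grid of squared resistance and reactance residuals,
#' `phi_M = sum_K [(R_L - R_M)^2 + (X_L - X_M)^2]`.
#'
#' @param data,model `impedance_spectrum` objects sharing the same grid.
#' @return Non-negative scalar `phi_M`.
#' @export
model_error <- function(data, model) {
  stopifnot(inherits(data, "impedance_spectrum"),
            inherits(model, "impedance_spectrum"))
  if (length(data$freq) != length(model$freq) ||
      any(abs(as.numeric(data$freq) - as.numeric(model$freq)) > 1e-9))
    stop("spectra are not on the same frequency grid", call. = FALSE)
  sum((Re(data$Z) - Re(model$Z))^2 + (Im(data$Z) - Im(model$Z))^2)
}

#' Model likelihood ratio against the null model
#'
#' `L_M = -2 ln(ssr_M) + 2 ln(ssr_0)`, where `ssr_0` is the error of the
#' null-model spectra (control-distribution simulation) against the same
#' data.  Positive `L_M` means model M beats the null.
#'
#' @param ssr_M,ssr_0 Positive residual sums of squares.
#' @return Scalar `L_M`.
#' @export
likelihood_ratio <- function(ssr_M, ssr_0) {
  if (any(c(ssr_M, ssr_0) <= 0))
    stop("SSR values must be positive", call. = FALSE)
  -2 * log(ssr_M) + 2 * log(ssr_0)
}

# Airway component set of a tree plus closed-form radial rescaling:
# R ~ r^-4, I ~ r^-2, C_g ~ r^2, wall compliance ~ lateral area ~ r.
.tree_components <- function(tree, const) {
  seg <- tree$segments
  list(seg = seg, comp = segment_impedance(seg$radius, seg$length, const))
}

.scale_components <- function(comp, s) {
  data.frame(R_seg = comp$R_seg / s^4,
             I_seg = comp$I_seg / s^2,
             C_g = comp$C_g * s^2,
             G_w = comp$G_w / s,
             H_w = comp$H_w / s,
             alpha_w = comp$alpha_w)
}

# Homogeneous terminal admittance matrix from lung-scale constant-phase
# tissue values (shared by all open terminals).
.homogeneous_terminal_Y <- function(H, eta, n_terminal, grid) {
  alpha <- (2 / pi) * atan2(1, eta)
  w <- attr(grid, "omega")
  Ht <- H * n_terminal
  matrix(w^alpha / (complex(real = eta, imaginary = -1) * Ht),
         n_terminal, length(grid), byrow = TRUE)
}

#' Estimate the radial scale factor r/r0 by bisection
#'
#' Airway geometry is defined at total lung capacity; at each PEEP a
#' single multiplier `r/r0` in (0, 1] applied to all radii is estimated by
#' bisection to minimize the sum of squared residuals between the
#' simulated and target impedance spectra, with tissue properties fixed at
#' the constant-phase `H` and `eta` estimated from the data.  Because
#' airway geometry is stochastic, the optimization is repeated over
#' independently sampled trees and reported as mean and SD.
#'
#' @param table A [morphometry_table()] from which replicate trees are
#'   sampled.
#' @param target Target `impedance_spectrum` on the standard grid.
#' @param tissue_params [constant_phase_params()] whose `H` and `eta` set
#'   the terminal tissue elements (lung scale).
#' @param replicates Number of stochastic trees (100 in routine use).
#' @param const,grid,gas_shunt,wall_shunt Simulation settings.
#' @param seed Master seed; each replicate gets an independent sub-seed.
#' @param interval Search interval for `r/r0`.
#' @param tol Bisection interval-width tolerance.
#' @param max_iter Bisection iteration cap.
#' @return An object of class `radial_scale_estimate`: list with `mean`,
#'   `sd`, per-replicate `estimates` and `boundary` flags (estimates pinned
#'   at the interval ends).
#' @export
estimate_radius_scale <- function(table, target, tissue_params,
                                  replicates = 100,
                                  const = physical_constants(),
                                  grid = default_frequencies(),
                                  gas_shunt = TRUE, wall_shunt = TRUE,
                                  seed = NULL, interval = c(0.01, 1),
                                  tol = 1e-3, max_iter = 60) {
  stopifnot(inherits(tissue_params, "constant_phase_params"))
  if (tissue_params$H <= 0) stop("tissue H must be positive", call. = FALSE)
  eta <- if (is.finite(tissue_params$eta)) tissue_params$eta else 0
  seeds <- replicate_seeds(seed, replicates)
  est <- numeric(replicates); boundary <- logical(replicates)
  for (k in seq_len(replicates)) {
    tree <- build_tree(table, seed = seeds[[k]])
    parts <- .tree_components(tree, const)
    Yt <- .homogeneous_terminal_Y(tissue_params$H, eta, tree$n_terminal, grid)
    ssr <- function(s) {
      sim <- .network_eval(parts$seg, .scale_components(parts$comp, s),
                           Yt, grid, gas_shunt, wall_shunt)
      model_error(target, sim)
    }
    lo <- interval[1]; hi <- interval[2]
    for (it in seq_len(max_iter)) {
      if (hi - lo < tol) break
      m <- (lo + hi) / 2
      h <- min(1e-4, (hi - lo) / 8)
      if (ssr(m + h) > ssr(m - h)) hi <- m else lo <- m
    }
    est[k] <- (lo + hi) / 2
    boundary[k] <- est[k] > interval[2] - 2 * tol | est[k] < interval[1] + 2 * tol
  }
  structure(list(mean = mean(est), sd = stats::sd(est),
                 estimates = est, boundary = boundary,
                 replicates = replicates),
            class = "radial_scale_estimate")
}

#' @export
print.radial_scale_estimate <- function(x, ...) {
  cat(sprintf("<radial_scale_estimate> r/r0 = %.3f +/- %.3f (%d replicates%s)\n",
              x$mean, x$sd, x$replicates,
              if (any(x$boundary)) sprintf(", %d at boundary", sum(x$boundary)) else ""))
  invisible(x)
}

#' Estimate the baseline elastance H0 for a tissue model
#'
#' For a given tissue model, the baseline lung-scale elastance `H0` is the
#' single free parameter; it is estimated by least squares against the
#' impedance spectrum of the maximally recruited control, then frozen for
#' simulation of all other conditions.  Because geometry and tissue draws
#' are stochastic, the scalar optimization is repeated over replicate
#' trees/draws and reported as mean and SD.
#'
#' @param table A [morphometry_table()].
#' @param spec A [tissue_model_spec()]; its `H0` field is ignored (it is
#'   the quantity being estimated).
#' @param control_data Control `impedance_spectrum`.
#' @param rac_dist,fiber_dist,rac_crit_dist Distributions required by the
#'   model variant (control-condition pools).
#' @param p_collapse,obstruction_fraction Recruitment state of the control
#'   (defaults: fully recruited, unobstructed).
#' @param r_over_r0 Radial scale applied to the tree before fitting.
#' @param replicates Number of stochastic optimizations.
#' @param interval Search interval for `H0` (cmH2O/mL).
#' @param const,grid,gas_shunt,wall_shunt,seed Simulation settings.
#' @return Class `h0_estimate`: list with `mean`, `sd`, per-replicate
#'   `estimates` and `residuals`.
#' @export
estimate_H0 <- function(table, spec, control_data,
                        rac_dist = NULL, fiber_dist = NULL,
                        rac_crit_dist = NULL,
                        p_collapse = 0, obstruction_fraction = 0,
                        r_over_r0 = 1, replicates = 100,
                        interval = c(1, 300),
                        const = physical_constants(),
                        grid = default_frequencies(),
                        gas_shunt = TRUE, wall_shunt = TRUE,
                        seed = NULL) {
  stopifnot(inherits(spec, "tissue_model_spec"))
  spec1 <- spec; spec1$H0 <- 1   # draw unit-baseline elastances, scale later
  seeds <- replicate_seeds(seed, replicates)
  est <- numeric(replicates); res <- numeric(replicates)
  for (k in seq_len(replicates)) {
    tree <- build_tree(table, seed = seeds[[k]])
    if (r_over_r0 < 1) tree <- apply_radial_scale(tree, r_over_r0)
    a <- assign_tissue_elastances(spec1, tree$n_terminal,
                                  rac_dist = rac_dist, fiber_dist = fiber_dist,
                                  rac_crit_dist = rac_crit_dist,
                                  p_collapse = p_collapse,
                                  obstruction_fraction = obstruction_fraction,
                                  seed = seeds[[k]])
    base_H <- a$units$H
    ssr <- function(H0) {
      ak <- a; ak$units$H <- H0 * base_H
      sim <- simulate_lung_spectrum(tree, ak, const, grid,
                                    gas_shunt = gas_shunt, wall_shunt = wall_shunt)
      model_error(control_data, sim)
    }
    op <- stats::optimize(ssr, interval = interval, tol = 1e-3)
    est[k] <- op$minimum; res[k] <- op$objective
  }
  structure(list(mean = mean(est), sd = stats::sd(est),
                 estimates = est, residuals = res, label = spec$label),
            class = "h0_estimate")
}

#' @export
print.h0_estimate <- function(x, ...) {
  cat(sprintf("<h0_estimate> %s: H0 = %.3g +/- %.3g cmH2O/mL (mean residual %.3g)\n",
              x$label, x$mean, x$sd, mean(x$residuals)))
  invisible(x)
}

#' Monte-Carlo comparison of the eight tissue models across conditions
#'
#' For every condition and tissue model, runs replicate forward
#' simulations with the condition's histology distributions, recruitment
#' and radial scale, computes the total error `phi_M` against the
#' condition's measured spectrum, and the likelihood ratio `L_M` against
#' the null model (the same tissue model driven by control distributions
#' and control recruitment).  `L_M` is replicate-matched; the summary also
#' reports the ratio of mean errors.
#'
#' @param table A [morphometry_table()].
#' @param conditions Named list; each element a list with `spectrum`
#'   (`impedance_spectrum`), and the condition inputs `rac_dist`,
#'   `fiber_dist`, `f_open`, `obstruction`, `r_over_r0` (missing entries
#'   default to the control's).
#' @param control List with `rac_dist`, `fiber_dist`, `f_open`,
#'   `obstruction`, `r_over_r0` describing the null (control) simulation.
#' @param models List of [tissue_model_spec()]s, typically
#'   [all_tissue_models()] with per-model `H0` frozen from [estimate_H0()].
#' @param replicates Monte-Carlo replicates per condition and model.
#' @param const,grid,gas_shunt,wall_shunt,seed Simulation settings.
#' @return Class `model_comparison`: list with `results` (one row per
#'   condition x model x replicate: `phi`, `phi_null`, `L`) and `summary`
#'   (means/SDs per condition x model, plus `L_of_means`).
#' @export
run_model_comparison <- function(table, conditions, control, models,
                                 replicates = 100,
                                 const = physical_constants(),
                                 grid = default_frequencies(),
                                 gas_shunt = TRUE, wall_shunt = TRUE,
                                 seed = NULL) {
  stopifnot(is.list(conditions), length(conditions) > 0, is.list(models))
  fill <- function(x) {
    x$f_open <- x$f_open %||% 1
    x$obstruction <- x$obstruction %||% 0
    x$r_over_r0 <- x$r_over_r0 %||% 1
    x
  }
  control <- fill(control)
  conditions <- lapply(conditions, fill)
  seeds <- replicate_seeds(seed, replicates)
  rows <- vector("list", replicates)
  for (k in seq_len(replicates)) {
    tree <- build_tree(table, seed = seeds[[k]])
    tree_ctrl <- if (control$r_over_r0 < 1)
      apply_radial_scale(tree, control$r_over_r0) else tree
    null_sims <- lapply(seq_along(models), function(m) {
      a0 <- assign_tissue_elastances(
        models[[m]], tree$n_terminal,
        rac_dist = control$rac_dist, fiber_dist = control$fiber_dist,
        rac_crit_dist = control$rac_dist,
        p_collapse = 1 - control$f_open,
        obstruction_fraction = control$obstruction,
        seed = seeds[[k]])
      simulate_lung_spectrum(tree_ctrl, a0, const, grid,
                             gas_shunt = gas_shunt, wall_shunt = wall_shunt)
    })
    out_k <- list()
    for (ci in seq_along(conditions)) {
      cond <- conditions[[ci]]
      tree_c <- if (cond$r_over_r0 < 1)
        apply_radial_scale(tree, cond$r_over_r0) else tree
      for (m in seq_along(models)) {
        a <- assign_tissue_elastances(
          models[[m]], tree$n_terminal,
          rac_dist = cond$rac_dist, fiber_dist = cond$fiber_dist,
          rac_crit_dist = control$rac_dist,
          p_collapse = 1 - cond$f_open,
          obstruction_fraction = cond$obstruction,
          seed = seeds[[k]])
        sim <- simulate_lung_spectrum(tree_c, a, const, grid,
                                      gas_shunt = gas_shunt,
                                      wall_shunt = wall_shunt)
        phi <- model_error(cond$spectrum, sim)
        phi0 <- model_error(cond$spectrum, null_sims[[m]])
        out_k[[length(out_k) + 1L]] <- data.frame(
          condition = names(conditions)[ci] %||% as.character(ci),
          model = models[[m]]$label, replicate = k,
          phi = phi, phi_null = phi0,
          L = likelihood_ratio(phi, phi0),
          stringsAsFactors = FALSE)
      }
    }
    rows[[k]] <- do.call(rbind, out_k)
  }
  results <- do.call(rbind, rows)
  agg <- function(v) c(mean = mean(v), sd = stats::sd(v))
  key <- interaction(results$condition, results$model, drop = TRUE)
  summ <- do.call(rbind, lapply(split(results, key), function(d) {
    data.frame(condition = d$condition[1], model = d$model[1],
               phi_mean = mean(d$phi), phi_sd = stats::sd(d$phi),
               L_mean = mean(d$L), L_sd = stats::sd(d$L),
               L_of_means = likelihood_ratio(mean(d$phi), mean(d$phi_null)),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(results = results, summary = summ, replicates = replicates),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %d replicates\n", x$replicates))
  print(x$summary)
  invisible(x)
}

#' PEEP error-variance ratio for recruitment modeling
#'
#' Quantifies how much of the PEEP dependence of the model error is
#' explained by PV-based derecruitment: the variance of the model error
#' across PEEP levels is computed with and without recruitment in the
#' simulation, and expressed as their ratio (with / without).
#'
#' @param errors_with,errors_without Model errors at each PEEP level
#'   (same length, at least 2; 5 in routine use).
#' @return Class `peep_variance_result`: `var_with`, `var_without`,
#'   `ratio` (`NA` with `undefined = TRUE` when the denominator is 0).
#' @export
peep_variance_ratio <- function(errors_with, errors_without) {
  if (length(errors_with) < 2L || length(errors_without) < 2L)
    stop("need at least 2 PEEP levels per arm", call. = FALSE)
  vw <- stats::var(errors_with)
  vo <- stats::var(errors_without)
  undefined <- vo == 0
  structure(list(var_with = vw, var_without = vo,
                 ratio = if (undefined) NA_real_ else vw / vo,
                 undefined = undefined),
            class = "peep_variance_result")
}

#' @export
print.peep_variance_result <- function(x, ...) {
  cat(sprintf("<peep_variance_result> var with = %.4g, without = %.4g, ratio = %s\n",
              x$var_with, x$var_without,
              if (x$undefined) "undefined (zero denominator)" else sprintf("%.4g", x$ratio)))
  invisible(x)
}
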