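#' Packaged approximate mouse airway morphometry
#'
#' A documented, synthetic stand-in for literature mouse airway
#' morphometry: a CT stub (trachea and the two main bronchi, the only
#' murine airways above 1 mm diameter) plus a 15-order cast-style table
#' whose geometry was calibrated once so that the mean total tree volume
#' is ~0.152 mL, the model estimate of murine airway-tree volume at total
#' lung capacity (25 cmH2O).  Radii follow a geometric progression capped
#' at 0.48 mm (below the CT threshold); orders 13 and above branch with a
#' daughter-order offset of 2, smaller orders with 1, giving 1398 terminal
#' bronchioles.  Relative SDs are 8\% of the mean for orders >= 12 and
#' 15\% below, reflecting the tighter definition of larger cast orders.
#' The table is deterministic; `seed` is accepted for interface symmetry
#' (stochasticity enters when [build_tree()] samples geometry).
#'
#' Users with literature morphometry should load it with
#' [read_morphometry()] instead; this fixture is a calibrated approximation,
#' not a reproduction of published tables.
#'
#' @param seed Ignored (the table is deterministic).
#' @return A [morphometry_table()].
#' @examples
#' tab <- generate_morphometry_fixture()
#' build_tree(tab, seed = 1)
#' @export
generate_morphometry_fixture <- function(seed = NULL) {
  ct <- data.frame(
    id = c("trachea", "main_L", "main_R"),
    parent = c(NA, "trachea", "trachea"),
    length_mm = c(6.0, 4.0, 3.8),
    radius_mm = c(0.75, 0.55, 0.60),
    stringsAsFactors = FALSE)
  orders <- 1:15
  rad <- c(0.0867, 0.0980, 0.1107, 0.1251, 0.1414, 0.1598, 0.1806, 0.2040,
           0.2306, 0.2605, 0.2944, 0.3327, 0.3759, 0.4248, 0.4800)
  len <- c(0.7766, 0.8854, 1.0093, 1.1506, 1.3117, 1.4954, 1.7047, 1.9434,
           2.2154, 2.5256, 2.8792, 3.2823, 3.7418, 4.2657, 4.8628)
  sdf <- ifelse(orders >= 12, 0.08, 0.15)
  cast <- data.frame(
    order = orders,
    len_mean = len, len_sd = round(sdf * len, 4),
    rad_mean = rad, rad_sd = round(sdf * rad, 4),
    delta_n = ifelse(orders >= 13, 2L, 1L))
  morphometry_table(ct, cast, terminal_order = 1L)
}

#' Write a morphometry table to its two CSV files
#'
#' @param table A [morphometry_table()].
#' @param ct_file,cast_file Output CSV paths.
#' @export
write_morphometry <- function(table, ct_file, cast_file) {
  stopifnot(inherits(table, "morphometry_table"))
  utils::write.csv(table$ct, ct_file, row.names = FALSE, na = "")
  utils::write.csv(table$cast, cast_file, row.names = FALSE)
  invisible(c(ct_file, cast_file))
}

#' Ground truth for a synthetic experiment
#'
#' Bundles every generating parameter of a synthetic subject so pipeline
#' estimates can be scored against known values.
#'
#' @param H0 True lung-scale baseline elastance (cmH2O/mL).
#' @param eta True tissue hysteresivity.
#' @param peeps PEEP levels (cmH2O).
#' @param r_over_r0 Named radial scale factor per PEEP (names = PEEPs).
#' @param f_open Named open fraction of recruitable units per PEEP; also
#'   the recruitment curve evaluated at the PEEPs (must be non-decreasing
#'   in pressure, the generator's opening-pressure distribution).
#' @param obstruction_fraction Fraction of permanently obstructed units.
#' @param noise_sigma Multiplicative Gaussian measurement noise on R and X.
#' @param full_open_pressure Pressure (cmH2O) at which the recruitment
#'   curve reaches 1.
#' @param recruit_gap Opening-minus-closing pressure threshold gap
#'   (cmH2O, > 0 gives positive PV hysteresis).
#' @param stiffen_knee,stiffen_scale Strain-stiffening of tissue above
#'   `stiffen_knee` cmH2O with e-folding `stiffen_scale` cmH2O.
#' @param n_units Parallel elastance units in the PV generator.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(H0 = 51.1, eta = 0.18,
                         peeps = c(0, 1, 3, 6, 9),
                         r_over_r0 = c(`0` = 0.66, `1` = 0.64, `3` = 0.60,
                                       `6` = 0.53, `9` = 0.54),
                         f_open = c(`0` = 0.73, `1` = 0.735, `3` = 0.75,
                                    `6` = 0.79, `9` = 0.92),
                         obstruction_fraction = 0,
                         noise_sigma = 0.03,
                         full_open_pressure = 11,
                         recruit_gap = 1,
                         stiffen_knee = 12, stiffen_scale = 5,
                         n_units = 1000) {
  stopifnot_scalar(H0, "H0", positive = TRUE)
  stopifnot_scalar(eta, "eta", positive = TRUE)
  if (is.null(names(r_over_r0))) names(r_over_r0) <- peeps
  if (is.null(names(f_open))) names(f_open) <- peeps
  stopifnot(all(as.character(peeps) %in% names(r_over_r0)),
            all(as.character(peeps) %in% names(f_open)))
  if (any(r_over_r0 <= 0 | r_over_r0 > 1)) stop("r_over_r0 must be in (0,1]", call. = FALSE)
  if (any(f_open < 0 | f_open > 1)) stop("f_open must be in [0,1]", call. = FALSE)
  if (is.unsorted(f_open[as.character(sort(peeps))]))
    stop("f_open must be non-decreasing in PEEP (it is the recruitment curve)",
         call. = FALSE)
  structure(list(H0 = H0, eta = eta, peeps = peeps,
                 r_over_r0 = r_over_r0, f_open = f_open,
                 obstruction_fraction = obstruction_fraction,
                 noise_sigma = noise_sigma,
                 full_open_pressure = full_open_pressure,
                 recruit_gap = recruit_gap,
                 stiffen_knee = stiffen_knee, stiffen_scale = stiffen_scale,
                 n_units = n_units),
            class = "ground_truth")
}

#' Default synthetic cohort design
#'
#' Mirrors a two-genotype (wild type, Sftpd knockout), three-age (8, 27,
#' 80 weeks) design with 8 subjects per group and five PEEPs.  Each
#' condition perturbs the control histology: a leftward RAC shift (septal
#' loss), a fiber-thickness scale (thinning/thickening), and an airspace
#' obstruction fraction that is zero in wild type and progressive with age
#' in the knockout (3.4, 6.8, 13.8\%).
#'
#' @param n_subjects Subjects per condition.
#' @param peeps PEEP levels (cmH2O).
#' @return Class `cohort_config`: list with `conditions` data.frame
#'   (`name`, `genotype`, `age_wk`, `rac_shift`, `fiber_scale`,
#'   `obstruction`), the `control` condition name, RAC/fiber family
#'   parameters and pooled sample sizes.
#' @export
cohort_config <- function(n_subjects = 8, peeps = c(0, 1, 3, 6, 9)) {
  conditions <- data.frame(
    name = c("wt_8", "wt_27", "wt_80", "ko_8", "ko_27", "ko_80"),
    genotype = rep(c("WT", "Sftpd-KO"), each = 3),
    age_wk = rep(c(8, 27, 80), 2),
    rac_shift = c(0, 2, 2, 2, 3, 5),
    fiber_scale = c(1, 1, 0.65, 1.15, 1, 0.8),
    obstruction = c(0, 0, 0, 0.034, 0.068, 0.138),
    stringsAsFactors = FALSE)
  structure(list(conditions = conditions, control = "wt_8",
                 n_subjects = n_subjects, peeps = peeps,
                 rac_base = 4L, rac_size = 20L, rac_prob = 0.55,
                 fiber_mean = 1.0, fiber_shape = 16,
                 n_rac = 120L, n_fiber = 240L),
            class = "cohort_config")
}

#' Generate pooled synthetic histology distributions
#'
#' RAC values are drawn from a shifted binomial family (discrete, positive,
#' unimodal, like pooled radial alveolar counts); pathological conditions
#' subtract a configured leftward shift, so they are stochastically
#' dominated by control by construction.  Fiber thicknesses are gamma
#' distributed with condition-scaled mean.  Pooled sample sizes mimic a
#' histology campaign (3-4 mice, 15-20 counts each).
#'
#' @param config A [cohort_config()].
#' @param seed Optional seed.
#' @return List with `rac` and `fibers` (named lists of
#'   [empirical_distribution()] per condition) and `obstruction` (named
#'   numeric fractions).
#' @export
generate_histology <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  cond <- config$conditions
  local_seed(seed, {
    rac <- list(); fibers <- list()
    for (i in seq_len(nrow(cond))) {
      r <- config$rac_base + stats::rbinom(config$n_rac, config$rac_size,
                                           config$rac_prob) - cond$rac_shift[i]
      rac[[cond$name[i]]] <- empirical_distribution(pmax(r, 1L), "RAC",
                                                    cond$name[i])
      mu <- config$fiber_mean * cond$fiber_scale[i]
      f <- stats::rgamma(config$n_fiber, shape = config$fiber_shape,
                         rate = config$fiber_shape / mu)
      fibers[[cond$name[i]]] <- empirical_distribution(f, "fiber_thickness",
                                                       cond$name[i])
    }
    obstruction <- stats::setNames(cond$obstruction, cond$name)
    list(rac = rac, fibers = fibers, obstruction = obstruction)
  })
}

#' Write pooled histology distributions to CSV (`condition,kind,value`)
#' @param histology A [generate_histology()] result.
#' @param file Output CSV path.
#' @export
write_histology <- function(histology, file) {
  rows <- list()
  for (cond in names(histology$rac))
    rows[[length(rows) + 1L]] <- data.frame(
      condition = cond, kind = "RAC", value = histology$rac[[cond]]$values)
  for (cond in names(histology$fibers))
    rows[[length(rows) + 1L]] <- data.frame(
      condition = cond, kind = "fiber_thickness",
      value = round(histology$fibers[[cond]]$values, 4))
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}

# Recruitment curve F(P): fraction of recruitable units whose opening
# pressure is <= P.  Piecewise linear through the truth's (PEEP, f_open)
# points, 0 far below zero pressure, 1 at full_open_pressure.
.recruitment_curve <- function(truth) {
  p <- c(-20, sort(truth$peeps), truth$full_open_pressure)
  f <- c(0, truth$f_open[as.character(sort(truth$peeps))], 1)
  list(p = p, f = f)
}

# integrated compliance shape: s(P) = int_0^P du / g(u),
# g(u) = exp(max(0, u - knee)/scale)  (strain stiffening above the knee)
.pv_shape <- function(P, knee, scale) {
  ifelse(P <= knee, P, knee + scale * (1 - exp(-(P - knee) / scale)))
}

#' Generate a quasi-static PV loop from unit-level recruitment
#'
#' Simulates stepwise inflation from PEEP to PEEP + 10 cmH2O in 8
#' pressure-regulated steps and back.  Each of `n_units` parallel
#' elastance units opens when pressure first exceeds its opening threshold
#' (drawn from the truth's recruitment curve) and closes on deflation
#' below its closing threshold (`recruit_gap` lower, so hysteresis is
#' non-negative).  Open units inflate with elastance `H0 * n_units` and
#' exponential strain stiffening above the stiffening knee; the nadir of
#' the inflation step-elastance curve therefore approximates the fully
#' recruited lung elastance `H0`.
#'
#' @param truth A [ground_truth()].
#' @param peep PEEP (cmH2O).
#' @param steps Number of inflation pressure steps.
#' @param seed Optional seed.
#' @return A [pv_loop()].
#' @export
generate_pv_loop <- function(truth, peep, steps = 8, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  rc <- .recruitment_curve(truth)
  local_seed(seed, {
    u <- stats::runif(truth$n_units)
    Po <- stats::approx(rc$f, rc$p, xout = u, ties = "ordered", rule = 2)$y
    Pc <- Po - truth$recruit_gap
    Eu <- truth$H0 * truth$n_units
    s <- function(P) .pv_shape(P, truth$stiffen_knee, truth$stiffen_scale)
    p_up <- peep + 10 * (0:steps) / steps
    v_at <- function(P, open) {
      dv <- (s(P) - s(Pc[open])) / Eu
      sum(pmax(dv, 0))
    }
    V_up <- vapply(p_up, function(P) v_at(P, Po <= P), 0)
    p_dn <- rev(p_up)
    peak <- max(p_up)
    V_dn <- vapply(p_dn, function(P) v_at(P, Po <= peak & Pc <= P), 0)
    V0 <- V_up[1]
    pv_loop(data.frame(pressure = p_up, volume = V_up - V0),
            data.frame(pressure = p_dn, volume = V_dn - V0),
            peep = peep)
  })
}

#' Generate a full synthetic forced-oscillation + PV experiment
#'
#' For each PEEP: scales the airway tree by the true `r/r0`, assigns
#' homogeneous tissue at the true `H0` with derecruitment
#' `p_collapse = 1 - f_open(PEEP)` (after permanent obstruction), runs the
#' forward impedance simulation, adds multiplicative Gaussian measurement
#' noise independently to R and X, and generates the matching quasi-static
#' PV loop.
#'
#' @param truth A [ground_truth()].
#' @param tree An `airway_tree` (unscaled, TLC geometry).
#' @param grid A [frequency_grid()].
#' @param const A [physical_constants()] object.
#' @param seed Optional master seed.
#' @return Class `synthetic_experiment`: list with `spectra` and
#'   `pv_loops` (named by PEEP) and the `truth` serialized alongside.
#' @export
generate_experiment <- function(truth, tree, grid = default_frequencies(),
                                const = physical_constants(), seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(tree, "airway_tree"))
  if (!inherits(grid, "frequency_grid")) grid <- frequency_grid(grid)
  spec0 <- tissue_model_spec(0L, FALSE, H0 = truth$H0, eta = truth$eta)
  seeds <- replicate_seeds(seed, 3 * length(truth$peeps))
  spectra <- list(); loops <- list()
  for (i in seq_along(truth$peeps)) {
    peep <- truth$peeps[i]
    key <- as.character(peep)
    tr <- apply_radial_scale(tree, truth$r_over_r0[key])
    a <- assign_tissue_elastances(
      spec0, tree$n_terminal,
      p_collapse = 1 - truth$f_open[key],
      obstruction_fraction = truth$obstruction_fraction,
      seed = seeds[[3 * i - 2]])
    zl <- simulate_lung_spectrum(tr, a, const, grid)
    if (truth$noise_sigma > 0) {
      zl <- local_seed(seeds[[3 * i - 1]], {
        nf <- length(grid)
        eR <- stats::rnorm(nf, 0, truth$noise_sigma)
        eX <- stats::rnorm(nf, 0, truth$noise_sigma)
        impedance_spectrum(grid, complex(real = Re(zl$Z) * (1 + eR),
                                         imaginary = Im(zl$Z) * (1 + eX)),
                           role = "experimental")
      })
    } else {
      zl <- impedance_spectrum(grid, zl$Z, role = "experimental")
    }
    spectra[[key]] <- zl
    loops[[key]] <- generate_pv_loop(truth, peep, seed = seeds[[3 * i]])
  }
  structure(list(spectra = spectra, pv_loops = loops, truth = truth),
            class = "synthetic_experiment")
}
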