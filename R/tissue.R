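#' Pooled histology measurement distribution
#'
#' Histological measurements (radial alveolar counts, elastic fiber
#' thicknesses) naturally vary within the tissue; they are treated as a
#' discrete random variable, pooled across all samples within a condition,
#' and resampled with replacement when tissue properties are assigned.
#'
#' @param values Pooled measurements: positive integers for `"RAC"`,
#'   positive reals for `"fiber_thickness"`.
#' @param kind Measurement kind.
#' @param condition Optional source condition label.
#' @return An object of class `empirical_distribution`.
#' @export
empirical_distribution <- function(values, kind = c("RAC", "fiber_thickness"),
                                   condition = NA_character_) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values))
    stop("values must be non-empty and non-missing", call. = FALSE)
  if (any(values <= 0))
    stop("values must be positive", call. = FALSE)
  if (kind == "RAC" && any(values != round(values)))
    stop("RAC values must be positive integers", call. = FALSE)
  structure(list(values = values, kind = kind, condition = condition),
            class = "empirical_distribution")
}

#' @export
print.empirical_distribution <- function(x, ...) {
  cat(sprintf("<empirical_distribution> %s (%s): n=%d, mean=%.3g, sd=%.3g\n",
              x$kind, x$condition, length(x$values), mean(x$values),
              stats::sd(x$values)))
  invisible(x)
}

#' @export
mean.empirical_distribution <- function(x, ...) mean(x$values)

#' Sample from a pooled empirical distribution
#'
#' @param dist An [empirical_distribution()].
#' @param n Number of i.i.d. draws, with replacement.
#' @param seed Optional seed for reproducible draws.
#' @return Numeric vector of `n` draws.
#' @export
sample_empirical <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "empirical_distribution"))
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  local_seed(seed, dist$values[sample.int(length(dist$values), n, replace = TRUE)])
}

#' Read pooled histology measurements from CSV
#'
#' Fiber thicknesses are stored at micrometre resolution rounded to 4
#' decimals by [write_histology()].
#'
#' The file carries columns `condition,kind,value` with
#' `kind %in% c("RAC", "fiber_thickness")`.
#'
#' @param file CSV path.
#' @return Named list (by condition) of lists with `$rac` and `$fibers`
#'   [empirical_distribution()] entries (absent kinds are `NULL`).
#' @export
read_histology <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("condition", "kind", "value") %in% names(d)))
  out <- list()
  for (cond in unique(d$condition)) {
    di <- d[d$condition == cond, ]
    rac <- di$value[di$kind == "RAC"]
    fib <- di$value[di$kind == "fiber_thickness"]
    out[[cond]] <- list(
      rac = if (length(rac)) empirical_distribution(rac, "RAC", cond),
      fibers = if (length(fib)) empirical_distribution(fib, "fiber_thickness", cond))
  }
  out
}

#' Tissue model specification
#'
#' Eight candidate models for generating terminal elastance distributions:
#' the homogeneous lung plus three ways of incorporating the radial
#' alveolar count (RAC), each with or without an elastic-fiber thickness
#' contribution.
#'
#' RAC variants: `0` ignores RAC; `1` compares each drawn `RAC_i` to the
#' fixed threshold `RAC_crit` (default 12), assigning a septal factor
#' `Gamma_i = 1` above and `0.5` below; `2` is like 1 but draws `RAC_crit`
#' anew from the control RAC distribution for every unit; `3` scales
#' hyperbolically below the fixed threshold, `Gamma_i = RAC_i / RAC_crit`.
#'
#' @param rac_variant Integer in `0:3`.
#' @param fibers Logical: scale elastance by drawn fiber thickness
#'   relative to the control mean, `H_i ~ lambda_i / lambda_0`.
#' @param RAC_crit Fixed septal threshold (variants 1 and 3).
#' @param H0 Baseline lung-scale elastance (cmH2O/mL): the intrinsic
#'   stiffness of a reference alveolar unit on which the distribution of
#'   model stiffness is based.
#' @param eta Hysteresivity shared across tissue units (`G_i = eta H_i`).
#' @param lambda0 Reference (control-mean) fiber thickness; required when
#'   `fibers = TRUE`.
#' @return An object of class `tissue_model_spec`.
#' @seealso [all_tissue_models()]
#' @export
tissue_model_spec <- function(rac_variant, fibers, H0, eta,
                              RAC_crit = 12, lambda0 = NULL) {
  rac_variant <- as.integer(rac_variant)
  if (!rac_variant %in% 0:3) stop("rac_variant must be in 0:3", call. = FALSE)
  stopifnot(is.logical(fibers), length(fibers) == 1L)
  stopifnot_scalar(H0, "H0", positive = TRUE)
  stopifnot_scalar(eta, "eta", positive = TRUE)
  stopifnot_scalar(RAC_crit, "RAC_crit", positive = TRUE)
  if (fibers && !is.null(lambda0)) stopifnot_scalar(lambda0, "lambda0", positive = TRUE)
  structure(list(rac_variant = rac_variant, fibers = fibers, H0 = H0,
                 eta = eta, RAC_crit = RAC_crit, lambda0 = lambda0,
                 label = sprintf("RAC%d%s", rac_variant,
                                 if (fibers) "+fibers" else "")),
            class = "tissue_model_spec")
}

#' Enumerate the eight candidate tissue models
#'
#' @param H0 Baseline elastance(s): a scalar shared by all models, or a
#'   vector of 8 (ordered RAC variant 0..3 without fibers, then 0..3 with).
#' @inheritParams tissue_model_spec
#' @return Named list of 8 [tissue_model_spec()] objects.
#' @export
all_tissue_models <- function(H0, eta, RAC_crit = 12, lambda0 = NULL) {
  H0 <- rep_len(H0, 8)
  grid <- expand.grid(rac_variant = 0:3, fibers = c(FALSE, TRUE))
  specs <- lapply(seq_len(8), function(i)
    tissue_model_spec(grid$rac_variant[i], grid$fibers[i], H0 = H0[i],
                      eta = eta, RAC_crit = RAC_crit, lambda0 = lambda0))
  names(specs) <- vapply(specs, `[[`, "", "label")
  specs
}

#' Septal factor from a radial alveolar count
#'
#' @param variant RAC variant, 1, 2 or 3 (see [tissue_model_spec()]).
#' @param RAC_i Drawn radial alveolar count(s).
#' @param RAC_crit Threshold: the fixed value for variants 1 and 3, or the
#'   per-unit control draw for variant 2 (recycled against `RAC_i`).
#' @return `Gamma_i`: 1 where `RAC_i >= RAC_crit`; below threshold, 0.5
#'   (variants 1-2) or `RAC_i / RAC_crit` (variant 3).  Equality is mapped
#'   to 1 (the threshold rules are stated only for strict comparisons).
#' @examples
#' rac_gamma(1, 10, 12)  # 0.5
#' rac_gamma(3, 6, 12)   # 0.5
#' @export
rac_gamma <- function(variant, RAC_i, RAC_crit) {
  variant <- as.integer(variant)
  if (!variant %in% 1:3) stop("variant must be 1, 2 or 3", call. = FALSE)
  if (any(RAC_i <= 0) || any(RAC_crit <= 0))
    stop("RAC values must be positive", call. = FALSE)
  below <- RAC_i < RAC_crit
  if (variant %in% c(1L, 2L)) ifelse(below, 0.5, 1)
  else ifelse(below, RAC_i / RAC_crit, 1)
}

#' Assign per-terminal-unit tissue elastances
#'
#' Draws a lung-scale elastance `H_i` for each terminal unit:
#' `H_i = H0 * (lambda_i / lambda_0) * Gamma_i` for communicating units,
#' where the fiber factor applies only when the model includes fibers and
#' the septal factor only for RAC variants > 0.  A unit is first marked
#' obstructed with probability `obstruction_fraction` (permanent, stationary
#' obstruction by debris), otherwise collapsed with probability
#' `p_collapse` (PEEP-dependent derecruitment); both receive infinite
#' elastance.  The recruited share of all units is therefore
#' `(1 - obstruction_fraction) * (1 - p_collapse)`.
#'
#' @param spec A [tissue_model_spec()].
#' @param N_total Number of terminal units (the tree's terminal count).
#' @param rac_dist RAC [empirical_distribution()] for the condition
#'   (required for RAC variants > 0).
#' @param fiber_dist Fiber-thickness [empirical_distribution()] for the
#'   condition (required when the model includes fibers).
#' @param rac_crit_dist Control RAC distribution from which variant 2 draws
#'   its per-unit threshold.
#' @param p_collapse Probability a recruitable unit is derecruited at this
#'   PEEP, in `[0, 1]`.
#' @param obstruction_fraction Fraction of units permanently obstructed,
#'   in `[0, 1)`.
#' @param seed Optional seed.
#' @return An object of class `tissue_assignment`: `units` data.frame
#'   (`H`, `gamma`, `lambda`, `collapsed`, `obstructed`) plus the shared
#'   `eta` and the parameters used.
#' @export
assign_tissue_elastances <- function(spec, N_total,
                                     rac_dist = NULL, fiber_dist = NULL,
                                     rac_crit_dist = NULL,
                                     p_collapse = 0, obstruction_fraction = 0,
                                     seed = NULL) {
  stopifnot(inherits(spec, "tissue_model_spec"))
  N_total <- as.integer(N_total)
  if (N_total < 1L) stop("N_total must be >= 1", call. = FALSE)
  if (p_collapse < 0 || p_collapse > 1)
    stop("p_collapse must lie in [0, 1]", call. = FALSE)
  if (obstruction_fraction < 0 || obstruction_fraction >= 1)
    stop("obstruction_fraction must lie in [0, 1)", call. = FALSE)
  if (spec$rac_variant > 0 && is.null(rac_dist))
    stop("rac_dist is required for RAC variants > 0", call. = FALSE)
  if (spec$rac_variant == 2L && is.null(rac_crit_dist))
    stop("rac_crit_dist (control RAC distribution) is required for variant 2",
         call. = FALSE)
  if (spec$fibers && is.null(fiber_dist))
    stop("fiber_dist is required when the model includes fibers", call. = FALSE)
  lambda0 <- spec$lambda0
  if (spec$fibers && is.null(lambda0)) lambda0 <- mean(fiber_dist$values)

  local_seed(seed, {
    obstructed <- stats::runif(N_total) < obstruction_fraction
    collapsed <- !obstructed & stats::runif(N_total) < p_collapse
    lambda <- if (spec$fibers)
      sample_empirical(fiber_dist, N_total) else rep(NA_real_, N_total)
    gamma <- rep(1, N_total)
    if (spec$rac_variant > 0L) {
      rac <- sample_empirical(rac_dist, N_total)
      crit <- if (spec$rac_variant == 2L)
        sample_empirical(rac_crit_dist, N_total) else spec$RAC_crit
      gamma <- rac_gamma(spec$rac_variant, rac, crit)
    }
    H <- spec$H0 *
      (if (spec$fibers) lambda / lambda0 else 1) *
      gamma
    H[obstructed | collapsed] <- Inf
    structure(list(
      units = data.frame(H = H, gamma = gamma, lambda = lambda,
                         collapsed = collapsed, obstructed = obstructed),
      eta = spec$eta, spec_label = spec$label, H0 = spec$H0,
      p_collapse = p_collapse, obstruction_fraction = obstruction_fraction,
      lambda0 = lambda0, seed = seed),
      class = "tissue_assignment")
  })
}

#' @export
print.tissue_assignment <- function(x, ...) {
  u <- x$units
  cat(sprintf(
    "<tissue_assignment> %s: %d units (%d collapsed, %d obstructed), mean finite H = %.3g cmH2O/mL\n",
    x$spec_label, nrow(u), sum(u$collapsed), sum(u$obstructed),
    mean(u$H[is.finite(u$H)])))
  invisible(x)
}
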