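#' Constant-phase viscoelastic tissue parameters
#'
#' The constant-phase model describes respiratory tissue impedance as
#' `Z(w) = R_N + j w I + (G - j H) / w^alpha` with
#' `alpha = (2/pi) atan(H/G)`.  `G` (tissue damping) and `H` (tissue
#' elastance) share the exponent `alpha`, so the tissue compartment has a
#' frequency-independent phase; `eta = G/H` (hysteresivity) measures energy
#' dissipation relative to storage.
#'
#' @param Rn Newtonian (airway) resistance, cmH2O.s/mL.
#' @param I Inertance, cmH2O.s^2/mL.
#' @param G Tissue damping, cmH2O/mL; must be >= 0.
#' @param H Tissue elastance, cmH2O/mL; must be >= 0.
#' @return An object of class `constant_phase_params` with derived fields
#'   `alpha` and `eta`.
#' @examples
#' constant_phase_params(Rn = 0.5, I = 0.01, G = 5, H = 30)
#' @export
constant_phase_params <- function(Rn, I, G, H) {
  stopifnot_scalar(Rn, "Rn"); stopifnot_scalar(I, "I")
  stopifnot_scalar(G, "G"); stopifnot_scalar(H, "H")
  if (G < 0 || H < 0)
    stop("G and H must be non-negative", call. = FALSE)
  alpha <- if (G == 0 && H == 0) 1 else (2 / pi) * atan2(H, G)
  eta <- if (H > 0) G / H else NA_real_
  structure(list(Rn = Rn, I = I, G = G, H = H, alpha = alpha, eta = eta),
            class = "constant_phase_params")
}

#' @export
print.constant_phase_params <- function(x, ...) {
  cat(sprintf(
    "<constant_phase_params> Rn=%.4g I=%.4g G=%.4g H=%.4g (alpha=%.4g, eta=%.4g)\n",
    x$Rn, x$I, x$G, x$H, x$alpha, x$eta))
  invisible(x)
}

#' Complex impedance spectrum
#'
#' Container pairing a frequency grid with complex impedance values and a
#' role tag distinguishing experimental data, forward-model output and
#' null-model output.
#'
#' @param grid A [frequency_grid()] (or numeric vector of Hz).
#' @param Z Complex impedance at each grid frequency, cmH2O.s/mL.
#' @param role One of `"experimental"`, `"model"`, `"null"`.
#' @return An object of class `impedance_spectrum`.
#' @export
impedance_spectrum <- function(grid, Z, role = c("model", "experimental", "null")) {
  if (!inherits(grid, "frequency_grid")) grid <- frequency_grid(grid)
  role <- match.arg(role)
  Z <- as.complex(Z)
  if (length(Z) != length(grid))
    stop("Z length must match the frequency grid", call. = FALSE)
  structure(list(freq = grid, Z = Z, role = role), class = "impedance_spectrum")
}

#' @rdname impedance_spectrum
#' @param x An `impedance_spectrum`.
#' @export
resistance <- function(x) Re(x$Z)

#' @rdname impedance_spectrum
#' @export
reactance <- function(x) Im(x$Z)

#' @rdname impedance_spectrum
#' @details The elastance spectrum is defined as `E(f) = -2 pi f X(f)`,
#'   so a purely elastic element of elastance E has `E(f) = E` at every
#'   frequency (sign convention `exp(+j w t)`, elastic reactance negative).
#' @export
elastance_spectrum <- function(x) -2 * pi * as.numeric(x$freq) * Im(x$Z)

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf("<impedance_spectrum> role=%s, %d frequencies %.3g-%.3g Hz\n",
              x$role, length(x$freq), min(x$freq), max(x$freq)))
  print(utils::head(as.data.frame(x), 4))
  if (length(x$freq) > 4) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.impedance_spectrum <- function(x, ...) {
  data.frame(freq_hz = as.numeric(x$freq), R = Re(x$Z), X = Im(x$Z))
}

#' Read / write impedance spectra as CSV
#'
#' Files carry columns `freq_hz,R,X`, one file per subject/condition/PEEP.
#'
#' @param file Path to a CSV file.
#' @param role Role tag for the spectrum read.
#' @return `read_spectrum()` returns an `impedance_spectrum`.
#' @export
read_spectrum <- function(file, role = "experimental") {
  d <- utils::read.csv(file)
  impedance_spectrum(frequency_grid(d$freq_hz), complex(real = d$R, imaginary = d$X),
                     role = role)
}

#' @rdname read_spectrum
#' @param x An `impedance_spectrum` to write.
#' @export
write_spectrum <- function(x, file) {
  utils::write.csv(as.data.frame(x), file, row.names = FALSE)
  invisible(file)
}

#' Evaluate the constant-phase model on a frequency grid
#'
#' @param params A [constant_phase_params()] object.
#' @param grid A [frequency_grid()].
#' @param role Role tag for the returned spectrum.
#' @return An `impedance_spectrum` with
#'   `Z = Rn + j w I + (G - j H)/w^alpha`.
#' @export
constant_phase_impedance <- function(params, grid = default_frequencies(),
                                     role = "model") {
  stopifnot(inherits(params, "constant_phase_params"))
  if (!inherits(grid, "frequency_grid")) grid <- frequency_grid(grid)
  w <- attr(grid, "omega")
  Z <- params$Rn + 1i * w * params$I +
    complex(real = params$G, imaginary = -params$H) / w^params$alpha
  impedance_spectrum(grid, Z, role = role)
}

#' Per-segment airway impedance components
#'
#' Each airway segment carries a longitudinal impedance (Poiseuille
#' resistance plus gas inertance) and two shunt pathways acting at its
#' midpoint: adiabatic gas compression of the luminal volume, and
#' viscoelastic distension of the airway wall.
#'
#' @param radius_mm,length_mm Segment geometry (vectors are accepted).
#' @param const A [physical_constants()] object.
#' @return A data.frame with one row per segment: `R_seg` (cmH2O.s/mL),
#'   `I_seg` (cmH2O.s^2/mL), `C_g` (mL/cmH2O), and wall-shunt constant-phase
#'   parameters `G_w`, `H_w` (cmH2O/mL) and `alpha_w`.
#' @details `R_seg = 8 mu l / (pi r^4)` and `I_seg = rho l / (pi r^2)` in
#'   SI, converted to the cmH2O/mL/s system; `C_g = V_seg / (gamma P0)`;
#'   the wall shunt is a constant-phase element whose compliance is
#'   proportional to the lateral surface area `2 pi r l`.
#' @export
segment_impedance <- function(radius_mm, length_mm, const = physical_constants()) {
  if (any(radius_mm <= 0) || any(length_mm <= 0))
    stop("radius and length must be positive", call. = FALSE)
  r <- radius_mm * 1e-3   # m
  l <- length_mm * 1e-3   # m
  R_seg <- 8 * const$air_viscosity * l / (pi * r^4) * .SI_TO_CMH2O_ML
  I_seg <- const$air_density * l / (pi * r^2) * .SI_TO_CMH2O_ML
  V_seg <- pi * radius_mm^2 * length_mm / 1000     # mL
  C_g <- V_seg / (const$adiabatic_index * const$ambient_pressure)
  area <- 2 * pi * radius_mm * length_mm           # mm^2
  C_w <- const$wall_compliance_per_area * area
  H_w <- 1 / C_w
  G_w <- const$wall_eta * H_w
  data.frame(R_seg = R_seg, I_seg = I_seg, C_g = C_g,
             G_w = G_w, H_w = H_w,
             alpha_w = (2 / pi) * atan2(H_w, G_w))
}

# Terminal admittance matrix (n_terminal x n_freq) from a user mapping.
# `terminal_Z` may be a single complex vector (recycled to all terminals),
# an impedance_spectrum, or a complex matrix with one row per terminal.
# Infinite or NA impedances mark non-communicating branches (admittance 0).
.terminal_admittance <- function(terminal_Z, n_terminal, grid) {
  nf <- length(grid)
  if (inherits(terminal_Z, "impedance_spectrum")) terminal_Z <- terminal_Z$Z
  if (is.matrix(terminal_Z)) {
    if (nrow(terminal_Z) != n_terminal || ncol(terminal_Z) != nf)
      stop("terminal impedance matrix must be n_terminal x n_freq", call. = FALSE)
    Zm <- terminal_Z
  } else {
    if (length(terminal_Z) != nf)
      stop("terminal impedance vector must match the frequency grid", call. = FALSE)
    Zm <- matrix(terminal_Z, n_terminal, nf, byrow = TRUE)
  }
  Y <- 1 / Zm
  Y[!is.finite(Re(Zm)) | !is.finite(Im(Zm))] <- 0 + 0i
  Y
}

#' Input impedance of an airway tree
#'
#' Evaluates the complex input impedance at the trachea by combining, for
#' every segment from the terminals upward: the parallel admittances of its
#' daughters (or the terminal tissue element), in series with the distal
#' half of the segment's longitudinal impedance, in parallel with the gas
#' compression and wall distension shunts at the midpoint, in series with
#' the proximal half of the longitudinal impedance.  A terminal with
#' infinite impedance behaves as an open branch: the branch contributes
#' zero admittance (it is pruned, shunts included), and the result is
#' finite whenever at least one root-to-terminal path is open.
#'
#' @param tree An [build_tree()] result.
#' @param terminal_Z Terminal tissue impedance: a complex vector on the
#'   grid (recycled to all terminals), an `impedance_spectrum`, or a
#'   complex matrix with one row per terminal in tree order.  `Inf` (or
#'   non-finite) entries mark collapsed/obstructed units.
#' @param const A [physical_constants()] object.
#' @param grid A [frequency_grid()].
#' @param gas_shunt,wall_shunt Toggle the two shunt pathways.
#' @return An `impedance_spectrum` (role `"model"`).
#' @export
network_input_impedance <- function(tree, terminal_Z,
                                    const = physical_constants(),
                                    grid = default_frequencies(),
                                    gas_shunt = TRUE, wall_shunt = TRUE) {
  stopifnot(inherits(tree, "airway_tree"))
  if (!inherits(grid, "frequency_grid")) grid <- frequency_grid(grid)
  seg <- tree$segments
  comp <- segment_impedance(seg$radius, seg$length, const)
  Y <- .terminal_admittance(terminal_Z, tree$n_terminal, grid)
  .network_eval(seg, comp, Y, grid, gas_shunt, wall_shunt)
}

# Shared kernel call; `comp` columns as from segment_impedance().
.network_eval <- function(seg, comp, Yterm, grid, gas_shunt, wall_shunt) {
  term_row <- integer(nrow(seg))
  term_row[seg$terminal] <- seq_len(sum(seg$terminal))
  parent <- seg$parent
  parent[is.na(parent)] <- 0L
  Z <- network_impedance_cpp(as.integer(parent), as.integer(term_row),
                             comp$R_seg, comp$I_seg, comp$C_g,
                             comp$G_w, comp$H_w, comp$alpha_w,
                             Yterm, attr(grid, "omega"),
                             gas_shunt, wall_shunt)
  if (any(!is.finite(Re(Z))))
    stop("all terminal units are non-communicating: input impedance undefined",
         call. = FALSE)
  impedance_spectrum(grid, Z, role = "model")
}

#' Simulate the lung impedance spectrum for a tissue assignment
#'
#' Attaches a constant-phase tissue element to every terminal bronchiole.
#' Unit `i` of the assignment carries a lung-scale elastance `H_i`; its
#' terminal element receives elastance `H_i * N_total` (and damping
#' `eta * H_i * N_total`), so that a homogeneous, fully recruited lung
#' aggregates back to the lung-scale value.  Collapsed or obstructed units
#' get infinite impedance and their branches are pruned from the network.
#'
#' @param tree An `airway_tree`.
#' @param assignment A [assign_tissue_elastances()] result covering all
#'   terminals of `tree`.
#' @param const A [physical_constants()] object.
#' @param grid A [frequency_grid()]; the default carries the 17 stimulus
#'   frequencies.
#' @param gas_shunt,wall_shunt Toggle the airway shunt pathways.
#' @return An `impedance_spectrum` (role `"model"`).
#' @examples
#' tab <- generate_morphometry_fixture()
#' tree <- build_tree(tab, seed = 1)
#' spec <- tissue_model_spec(0, fibers = FALSE, H0 = 51.1, eta = 0.18)
#' a <- assign_tissue_elastances(spec, N_total = tree$n_terminal, seed = 2)
#' zl <- simulate_lung_spectrum(tree, a)
#' @export
simulate_lung_spectrum <- function(tree, assignment,
                                   const = physical_constants(),
                                   grid = default_frequencies(),
                                   gas_shunt = TRUE, wall_shunt = TRUE) {
  stopifnot(inherits(tree, "airway_tree"), inherits(assignment, "tissue_assignment"))
  if (!inherits(grid, "frequency_grid")) grid <- frequency_grid(grid)
  n <- tree$n_terminal
  if (nrow(assignment$units) != n)
    stop("assignment does not cover the tree's terminal units", call. = FALSE)
  H <- assignment$units$H
  eta <- assignment$eta
  alpha <- (2 / pi) * atan2(1, eta)
  w <- attr(grid, "omega")
  open <- is.finite(H)
  if (!any(open))
    stop("all terminal units are non-communicating: input impedance undefined",
         call. = FALSE)
  Y <- matrix(0 + 0i, n, length(grid))
  # Y_t = w^alpha / (G_t - j H_t), with H_t = H_i * N_total, G_t = eta H_t
  Ht <- H[open] * n
  walpha <- w^alpha
  Y[open, ] <- outer(1 / (complex(real = eta, imaginary = -1) * Ht), walpha)
  seg <- tree$segments
  comp <- segment_impedance(seg$radius, seg$length, const)
  .network_eval(seg, comp, Y, grid, gas_shunt, wall_shunt)
}
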