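#' Forced-oscillation pressure/flow record
#'
#' @param time Sample times (s), uniformly spaced.
#' @param pressure Airway-opening pressure (cmH2O).
#' @param flow Flow (mL/s).
#' @return An object of class `oscillation_record`.
#' @export
oscillation_record <- function(time, pressure, flow) {
  n <- length(time)
  if (length(pressure) != n || length(flow) != n)
    stop("time, pressure and flow must have equal length", call. = FALSE)
  if (n < 4L) stop("record too short", call. = FALSE)
  dt <- diff(time)
  if (any(abs(dt - dt[1]) > 1e-9 * dt[1]))
    stop("time vector must be uniformly spaced", call. = FALSE)
  structure(list(time = time, pressure = pressure, flow = flow,
                 fs = 1 / dt[1]), class = "oscillation_record")
}

#' Read an oscillation record from CSV (`t,pressure,flow`)
#' @param file CSV path.
#' @return An [oscillation_record()].
#' @export
read_oscillation <- function(file) {
  d <- utils::read.csv(file)
  oscillation_record(d$t, d$pressure, d$flow)
}

#' Respiratory input impedance from pressure and flow signals
#'
#' `Z_rs(f)` is the ratio of the Fourier-transformed pressure to flow
#' signals, evaluated at the stimulus frequencies only.  Each requested
#' frequency must fall on the record's discrete transform grid (i.e.
#' `f * duration` must be an integer), as it does for a broad-band
#' waveform synthesized over the record length.
#'
#' @param rec An [oscillation_record()].
#' @param grid A [frequency_grid()] of stimulus frequencies.
#' @return An `impedance_spectrum` with role `"experimental"`.
#' @export
zrs_from_signals <- function(rec, grid = default_frequencies()) {
  stopifnot(inherits(rec, "oscillation_record"))
  if (!inherits(grid, "frequency_grid")) grid <- frequency_grid(grid)
  n <- length(rec$time)
  duration <- n / rec$fs
  k <- as.numeric(grid) * duration
  if (any(abs(k - round(k)) > 1e-6))
    stop("stimulus frequencies do not fall on the record's transform grid",
         call. = FALSE)
  k <- as.integer(round(k))
  if (any(k >= n / 2))
    stop("stimulus frequencies exceed the Nyquist limit", call. = FALSE)
  P <- stats::fft(rec$pressure)[k + 1L]
  Q <- stats::fft(rec$flow)[k + 1L]
  if (any(Mod(Q) == 0))
    stop("flow has no energy at a stimulus frequency", call. = FALSE)
  impedance_spectrum(grid, P / Q, role = "experimental")
}

#' Fit the constant-phase model to an impedance spectrum
#'
#' Minimizes the sum of squared complex residuals over
#' `(Rn, I, G, H)` with `alpha = (2/pi) atan(H/G)` by Nelder-Mead simplex,
#' seeded from an alternating linear least-squares pass (the model is
#' linear in the four parameters at fixed `alpha`) and polished from two
#' perturbed restarts.  `eta` is reported as the fitted `G/H`.
#'
#' @param spec An `impedance_spectrum` with at least 4 frequencies.
#' @param restarts Number of perturbed Nelder-Mead restarts.
#' @return A [constant_phase_params()] object with attributes `ssr`
#'   (residual sum of squares), `converged` and `degenerate`.
#' @export
fit_constant_phase <- function(spec, restarts = 2) {
  stopifnot(inherits(spec, "impedance_spectrum"))
  if (length(spec$freq) < 4L)
    stop("at least 4 frequencies are required", call. = FALSE)
  w <- attr(spec$freq, "omega")
  R <- Re(spec$Z); X <- Im(spec$Z)
  if (all(R == 0) && all(X == 0)) {
    out <- constant_phase_params(0, 0, 0, 0)
    attr(out, "ssr") <- 0; attr(out, "converged") <- FALSE
    attr(out, "degenerate") <- TRUE
    return(out)
  }

  # alternating linear LS initialisation: at fixed alpha the real part is
  # linear in (Rn, G) and the imaginary part in (I, H)
  alpha <- 0.8
  par <- c(Rn = max(min(R), 1e-3), I = 1e-3, G = 1, H = 1)
  for (iter in 1:40) {
    b <- w^(-alpha)
    fr <- stats::lm.fit(cbind(1, b), R)$coefficients
    fx <- stats::lm.fit(cbind(w, -b), X)$coefficients
    G <- max(fr[2], 1e-8); H <- max(fx[2], 1e-8)
    par <- c(Rn = unname(fr[1]), I = unname(fx[1]), G = G, H = H)
    alpha_new <- (2 / pi) * atan2(H, G)
    if (abs(alpha_new - alpha) < 1e-12) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }

  obj <- function(p) {
    G <- p[3]; H <- p[4]
    if (G < 0 || H < 0) return(1e12 * (1 + abs(min(G, H))))
    a <- if (G == 0 && H == 0) 1 else (2 / pi) * atan2(H, G)
    Zm <- p[1] + 1i * w * p[2] + complex(real = G, imaginary = -H) / w^a
    sum((R - Re(Zm))^2 + (X - Im(Zm))^2)
  }

  best <- stats::optim(par, obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-14))
  for (r in seq_len(restarts)) {
    start <- best$par * (1 + 1e-3 * (r %% 2 * 2 - 1)) + 1e-6
    cand <- stats::optim(start, obj, method = "Nelder-Mead",
                         control = list(maxit = 5000, reltol = 1e-14))
    if (cand$value < best$value) best <- cand
  }
  p <- best$par
  out <- constant_phase_params(p[1], p[2], max(p[3], 0), max(p[4], 0))
  attr(out, "ssr") <- best$value
  attr(out, "converged") <- best$convergence == 0
  attr(out, "degenerate") <- FALSE
  out
}

#' Quasi-static pressure-volume loop
#'
#' Stepwise inflation from PEEP to PEEP + 10 cmH2O in equal
#' pressure-regulated steps, then deflation; the two limbs are stored as
#' (pressure, volume) tables.
#'
#' @param insp,exp data.frames with columns `pressure` (cmH2O) and
#'   `volume` (mL); the inspiratory limb must be sorted by increasing
#'   pressure.
#' @param peep PEEP at which the loop was acquired (cmH2O).
#' @return An object of class `pv_loop`.
#' @export
pv_loop <- function(insp, exp, peep = NA_real_) {
  for (limb in list(insp, exp))
    if (!all(c("pressure", "volume") %in% names(limb)))
      stop("limbs need `pressure` and `volume` columns", call. = FALSE)
  insp <- insp[order(insp$pressure), c("pressure", "volume")]
  exp <- exp[order(exp$pressure), c("pressure", "volume")]
  structure(list(insp = insp, exp = exp, peep = peep,
                 steps = nrow(insp) - 1L), class = "pv_loop")
}

#' Read a PV loop from CSV (`limb,pressure_cmH2O,volume_mL`)
#' @param file CSV path; `limb` is `"insp"` or `"exp"`.
#' @param peep Optional PEEP annotation (cmH2O).
#' @return A [pv_loop()].
#' @export
read_pv_loop <- function(file, peep = NA_real_) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("limb", "pressure_cmH2O", "volume_mL") %in% names(d)))
  pick <- function(l) data.frame(pressure = d$pressure_cmH2O[d$limb == l],
                                 volume = d$volume_mL[d$limb == l])
  pv_loop(pick("insp"), pick("exp"), peep = peep)
}

#' PV hysteresis area
#'
#' The area between the inspiratory and expiratory limbs, computed as the
#' trapezoidal integral of `V_exp(P) - V_insp(P)` over the common pressure
#' range.  The sign is preserved: a loop whose expiratory limb lies below
#' the inspiratory one yields a negative area.
#'
#' @param loop A [pv_loop()].
#' @return Area in cmH2O.mL.
#' @export
pv_loop_area <- function(loop) {
  stopifnot(inherits(loop, "pv_loop"))
  if (nrow(loop$insp) < 2L || nrow(loop$exp) < 2L)
    stop("each limb needs at least 2 points", call. = FALSE)
  lo <- max(min(loop$insp$pressure), min(loop$exp$pressure))
  hi <- min(max(loop$insp$pressure), max(loop$exp$pressure))
  p <- sort(unique(c(loop$insp$pressure, loop$exp$pressure)))
  p <- p[p >= lo & p <= hi]
  vi <- stats::approx(loop$insp$pressure, loop$insp$volume, p, ties = "ordered")$y
  ve <- stats::approx(loop$exp$pressure, loop$exp$volume, p, ties = "ordered")$y
  d <- ve - vi
  sum(diff(p) * (utils::head(d, -1) + utils::tail(d, -1)) / 2)
}

#' Whole-loop and step elastances from a PV loop
#'
#' Whole-loop elastance is the pressure excursion over the volume
#' excursion across the entire maneuver; step elastances are
#' `dP/dV` for each incremental pressure step of the inflation limb (the
#' progressive-recruitment phase).  The elastance of the fully recruited
#' lung, `E_min`, is estimated as the nadir of the step-elastance curve;
#' steps with zero volume change are reported as infinite and excluded
#' from the nadir.
#'
#' @param loop A [pv_loop()].
#' @return A list with `whole` (cmH2O/mL), `step` (one value per
#'   inflation step) and `E_min`.
#' @export
pv_elastances <- function(loop) {
  stopifnot(inherits(loop, "pv_loop"))
  insp <- loop$insp
  if (nrow(insp) < 2L)
    stop("inspiratory limb needs at least 2 points", call. = FALSE)
  dP <- diff(insp$pressure)
  dV <- diff(insp$volume)
  step <- ifelse(dV == 0, Inf, dP / dV)
  whole <- (insp$pressure[nrow(insp)] - insp$pressure[1]) /
    (insp$volume[nrow(insp)] - insp$volume[1])
  finite <- step[is.finite(step)]
  list(whole = whole, step = step,
       E_min = if (length(finite)) min(finite) else Inf)
}

#' Fraction of recruitable lung that is open
#'
#' A lung of many parallel elastance units has total elastance
#' hyperbolically related to the number of open pathways, so the open
#' fraction at a given PEEP is the ratio of the fully recruited elastance
#' (the PV-loop nadir `E_min`) to the constant-phase tissue elastance
#' `H_CP(PEEP)`, clipped to `[0, 1]`.
#'
#' @param E_min Fully recruited elastance (cmH2O/mL), from [pv_elastances()].
#' @param H_CP Constant-phase tissue elastance at the PEEP of interest.
#' @return `f_open` in `[0, 1]`.
#' @examples
#' estimate_fopen(40, 50)  # 0.8
#' @export
estimate_fopen <- function(E_min, H_CP) {
  stopifnot_scalar(E_min, "E_min", positive = TRUE)
  stopifnot_scalar(H_CP, "H_CP", positive = TRUE)
  min(max(E_min / H_CP, 0), 1)
}
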