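#' Physical constants for airway impedance calculations
#'
#' The simulator works throughout in the conventional respiratory-mechanics
#' unit system: pressures in cmH2O, volumes in mL, flows in mL/s, lengths in
#' mm and time in s, so impedances come out in cmH2O.s/mL.  Air properties
#' are supplied in SI and converted internally.
#'
#' @param air_viscosity Dynamic viscosity of humidified air at body
#'   temperature (Pa.s).
#' @param air_density Density of humidified air at body temperature (kg/m^3).
#' @param adiabatic_index Ratio of specific heats for air; gas compression in
#'   the airway lumen is treated as adiabatic at oscillation frequencies.
#' @param ambient_pressure Absolute ambient pressure (cmH2O); 1033 cmH2O is
#'   one atmosphere.
#' @param wall_compliance_per_area Airway-wall shunt compliance per unit
#'   lateral surface area (mL/cmH2O/mm^2).  The default is small enough that
#'   the wall shunt perturbs the input impedance of a healthy lung by well
#'   under 1\% at 1 Hz; it matters only when airway geometry is perturbed
#'   toward pathology.
#' @param wall_eta Hysteresivity of the viscoelastic airway-wall shunt
#'   (dimensionless ratio of its damping to its elastance).
#'
#' @return An object of class `physical_constants` (a validated list).
#' @examples
#' const <- physical_constants()
#' const$air_viscosity
#' @export
physical_constants <- function(air_viscosity = 1.9e-5,
                               air_density = 1.12,
                               adiabatic_index = 1.4,
                               ambient_pressure = 1033,
                               wall_compliance_per_area = 1e-7,
                               wall_eta = 0.2) {
  stopifnot_scalar(air_viscosity, "air_viscosity", positive = TRUE)
  stopifnot_scalar(air_density, "air_density", positive = TRUE)
  stopifnot_scalar(adiabatic_index, "adiabatic_index", positive = TRUE)
  stopifnot_scalar(ambient_pressure, "ambient_pressure", positive = TRUE)
  stopifnot_scalar(wall_compliance_per_area, "wall_compliance_per_area",
                   positive = TRUE)
  stopifnot_scalar(wall_eta, "wall_eta", positive = TRUE)
  structure(
    list(air_viscosity = air_viscosity,
         air_density = air_density,
         adiabatic_index = adiabatic_index,
         ambient_pressure = ambient_pressure,
         wall_compliance_per_area = wall_compliance_per_area,
         wall_eta = wall_eta,
         units = c(pressure = "cmH2O", volume = "mL", length = "mm",
                   time = "s")),
    class = "physical_constants")
}

# Pa.s/m^3 -> cmH2O.s/mL
.SI_TO_CMH2O_ML <- 1 / (98.0665 * 1e6)

#' Default forced-oscillation frequency grid
#'
#' Seventeen mutually prime, non-integer frequencies between 0.5 and 20 Hz,
#' matching the broad-band forced-oscillation waveform used on small-animal
#' ventilators.  The grid is built as the first seventeen primes times
#' 0.25 Hz: the integer multipliers are pairwise coprime so no stimulus
#' line is a harmonic of another, and none of the frequencies is a whole
#' number, which keeps nonlinear harmonic distortion off the measurement
#' lines.
#'
#' @return A `frequency_grid` of length 17 spanning 0.5 to 14.75 Hz.
#' @examples
#' default_frequencies()
#' @export
default_frequencies <- function() {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47, 53, 59)
  frequency_grid(primes / 4)
}

#' Construct a frequency grid
#'
#' @param freq_hz Strictly increasing vector of positive frequencies (Hz).
#' @return An object of class `frequency_grid`: the numeric frequency
#'   vector with an `omega` attribute holding angular frequencies (rad/s).
#' @export
frequency_grid <- function(freq_hz) {
  freq_hz <- as.numeric(freq_hz)
  if (length(freq_hz) < 1L || anyNA(freq_hz) || any(freq_hz <= 0))
    stop("frequencies must be positive and non-missing", call. = FALSE)
  if (is.unsorted(freq_hz, strictly = TRUE))
    stop("frequencies must be strictly increasing", call. = FALSE)
  structure(freq_hz, omega = 2 * pi * freq_hz, class = "frequency_grid")
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf("<frequency_grid> %d frequencies, %.3g-%.3g Hz\n",
              length(x), min(x), max(x)))
  print(as.numeric(x))
  invisible(x)
}
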