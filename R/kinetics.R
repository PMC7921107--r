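# Closed-form degradation kinetics for stored DNA: backbone scission,
# freeze-thaw decay, Arrhenius temperature scaling, and base-lesion
# accumulation, with the calibration helpers needed to anchor each model
# to measured decay data.

#' Gas constant used by the Arrhenius model, J/(mol K)
#' @keywords internal
R_GAS <- 8.314

#' First-order backbone breakage model
#'
#' Backbone scission is modeled as a homogeneous Poisson process along the
#' strand and through time, with a single per-nucleotide, per-year rate.
#' Fossil-DNA half-life estimates put this rate near `5.5e-6`/nt/yr for DNA
#' held at permafrost temperatures.
#'
#' @param rate_per_nt_per_year Scission rate per nucleotide per year
#'   (1/nt/yr), must be >= 0.
#' @return An object of class `first_order_breakage`.
#' @seealso [intact_fraction_breakage()], [rate_from_half_life()]
#' @export
#' @examples
#' fossil <- first_order_breakage(5.5e-6)
#' intact_fraction_breakage(fossil, length = 242, time = 500)
first_order_breakage <- function(rate_per_nt_per_year) {
  check_scalar(rate_per_nt_per_year, "rate_per_nt_per_year", lower = 0)
  structure(list(rate_per_nt_per_year = rate_per_nt_per_year),
            class = "first_order_breakage")
}

#' Probability a strand survives backbone breakage intact
#'
#' Returns `exp(-rate * length * time)`: the Poisson probability of zero
#' scission events over `length` nucleotides in `time` years. The survival
#' is multiplicative in both time and length, so doubling the strand length
#' squares the intact fraction.
#'
#' @param model A [first_order_breakage()] model.
#' @param length Strand length in nt (>= 1). Vectorized.
#' @param time Storage time in years (>= 0). Vectorized.
#' @return Intact fraction in \[0, 1\].
#' @export
intact_fraction_breakage <- function(model, length, time) {
  stopifnot(inherits(model, "first_order_breakage"))
  if (!is.numeric(length) || any(is.na(length)) || any(length < 1)) {
    stop("`length` must be >= 1 nt", call. = FALSE)
  }
  if (!is.numeric(time) || any(is.na(time)) || any(time < 0)) {
    stop("`time` must be >= 0 years", call. = FALSE)
  }
  exp(-model$rate_per_nt_per_year * length * time)
}

#' Per-nucleotide breakage rate implied by a strand half-life
#'
#' Inverts the Poisson survival model: a strand of `length` nt that has a
#' 50% chance of remaining intact after `half_life` years implies a
#' per-nucleotide rate of `log(2) / (length * half_life)`. Round-trips
#' exactly: `intact_fraction_breakage(rate_from_half_life(L, h), L, h)` is
#' 0.5.
#'
#' @param length Strand length in nt (>= 1).
#' @param half_life Strand half-life in years (> 0).
#' @return A [first_order_breakage()] model.
#' @export
rate_from_half_life <- function(length, half_life) {
  check_scalar(length, "length", lower = 1)
  check_scalar(half_life, "half_life", lower = 0, allow_lower = FALSE)
  first_order_breakage(log(2) / (length * half_life))
}

#' Exponential freeze-thaw decay model
#'
#' Repeated freeze-thaw cycling fragments DNA approximately exponentially
#' in the number of cycles: `intact = amplitude * exp(-decay * cycles)`.
#' The defaults are a published fit to lambda DNA in Tris-EDTA buffer
#' (amplitude 0.9484, decay 0.068 per cycle), under which one cycle
#' degrades ~11% of strands and twenty cycles ~76%.
#'
#' @param amplitude Intact fraction extrapolated to 0 cycles, in (0, 1].
#' @param decay_per_cycle Exponential decay constant per cycle (>= 0).
#' @return An object of class `freeze_thaw_model`.
#' @export
freeze_thaw_model <- function(amplitude = 0.9484, decay_per_cycle = 0.068) {
  check_scalar(amplitude, "amplitude", lower = 0, upper = 1,
               allow_lower = FALSE)
  check_scalar(decay_per_cycle, "decay_per_cycle", lower = 0)
  structure(list(amplitude = amplitude, decay_per_cycle = decay_per_cycle),
            class = "freeze_thaw_model")
}

#' Intact fraction after repeated freeze-thaw cycles
#'
#' @param model A [freeze_thaw_model()].
#' @param cycles Number of freeze-thaw cycles (non-negative integer,
#'   vectorized).
#' @return Intact fraction in \[0, 1\].
#' @export
#' @examples
#' freeze_thaw_intact(freeze_thaw_model(), cycles = c(0, 1, 20))
freeze_thaw_intact <- function(model, cycles) {
  stopifnot(inherits(model, "freeze_thaw_model"))
  check_count(cycles, "cycles")
  model$amplitude * exp(-model$decay_per_cycle * cycles)
}

#' Fit an exponential decay curve to intact-fraction measurements
#'
#' Fits `intact = A * exp(-k * cycles)` by ordinary least squares on
#' `log(intact)` versus `cycles` (log-linear fit: deterministic, no
#' starting values). With exactly two distinct points the fit passes
#' through both. A negative fitted decay is clamped to 0 and an amplitude
#' above 1 is clamped to 1, with a warning, so the returned model always
#' satisfies the freeze-thaw model's invariants.
#'
#' @param points A data frame (or two-column matrix) with columns `cycles`
#'   and `intact_fraction`; at least two distinct cycle counts, all intact
#'   fractions in (0, 1].
#' @return A [freeze_thaw_model()].
#' @export
fit_exponential_decay <- function(points) {
  points <- as.data.frame(points)
  if (ncol(points) < 2) stop("`points` needs columns cycles and intact_fraction",
                             call. = FALSE)
  if (!all(c("cycles", "intact_fraction") %in% names(points))) {
    names(points)[1:2] <- c("cycles", "intact_fraction")
  }
  x <- points$cycles
  y <- points$intact_fraction
  if (length(x) < 2 || length(unique(x)) < 2) {
    stop("need at least two points with distinct cycle counts", call. = FALSE)
  }
  if (any(!is.finite(y)) || any(y <= 0) || any(y > 1)) {
    stop("intact fractions must lie in (0, 1]", call. = FALSE)
  }
  fit <- stats::lm(log(y) ~ x)
  amplitude <- exp(unname(stats::coef(fit)[1]))
  decay <- -unname(stats::coef(fit)[2])
  if (decay < 0) {
    warning("fitted decay was negative; clamped to 0")
    decay <- 0
  }
  if (amplitude > 1) {
    warning("fitted amplitude exceeded 1; clamped to 1")
    amplitude <- 1
  }
  freeze_thaw_model(amplitude = amplitude, decay_per_cycle = decay)
}

#' Simulate noisy freeze-thaw decay measurements
#'
#' Draws synthetic intact-fraction measurements from a known model with
#' multiplicative log-normal noise, the standard error structure for a
#' quantity fit on the log scale. Intended for parameter-recovery checks
#' of [fit_exponential_decay()]. Uses the current RNG stream.
#'
#' @param model A [freeze_thaw_model()] generating the truth.
#' @param cycles Integer vector of cycle counts to measure at.
#' @param sd_log Standard deviation of the log-scale noise (default 0.02).
#' @return A data frame with columns `cycles` and `intact_fraction`.
#' @export
simulate_decay_points <- function(model, cycles, sd_log = 0.02) {
  stopifnot(inherits(model, "freeze_thaw_model"))
  check_count(cycles, "cycles")
  check_scalar(sd_log, "sd_log", lower = 0)
  y <- freeze_thaw_intact(model, cycles) *
    exp(stats::rnorm(length(cycles), 0, sd_log))
  data.frame(cycles = cycles, intact_fraction = pmin(y, 1))
}

#' Read a decay time course from CSV
#'
#' Expects a header `cycles,intact_fraction`.
#'
#' @param path Path to the CSV file.
#' @return A data frame suitable for [fit_exponential_decay()].
#' @export
read_decay_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("cycles", "intact_fraction") %in% names(df))) {
    stop("CSV must have columns `cycles` and `intact_fraction`", call. = FALSE)
  }
  df[c("cycles", "intact_fraction")]
}

#' Arrhenius temperature-scaling model
#'
#' Accelerated-aging studies measure degradation at elevated temperature
#' and extrapolate down assuming the rate is exponential in inverse
#' temperature. The activation energy is a required user input: published
#' aging studies of stored DNA invoke the model without printing a single
#' canonical Ea, and the extrapolation is meaningless without one.
#'
#' @param activation_energy Activation energy in J/mol (> 0).
#' @param reference_rate Measured rate at the reference temperature (any
#'   per-time unit; the scaled rate keeps the same unit).
#' @param reference_temperature Reference temperature in Kelvin (> 0).
#' @return An object of class `arrhenius_model`.
#' @seealso [celsius_to_kelvin()]
#' @export
arrhenius_model <- function(activation_energy, reference_rate,
                            reference_temperature) {
  check_scalar(activation_energy, "activation_energy", lower = 0,
               allow_lower = FALSE)
  check_scalar(reference_rate, "reference_rate", lower = 0)
  check_scalar(reference_temperature, "reference_temperature", lower = 0,
               allow_lower = FALSE)
  structure(list(activation_energy = activation_energy,
                 reference_rate = reference_rate,
                 reference_temperature = reference_temperature),
            class = "arrhenius_model")
}

#' Scale a degradation rate to a new temperature
#'
#' `rate(T2) = reference_rate * exp(-(Ea / R) * (1/T2 - 1/T1))` with
#' R = 8.314 J/(mol K). Returns the reference rate unchanged at the
#' reference temperature; for positive activation energy the rate is
#' strictly increasing in temperature.
#'
#' @param model An [arrhenius_model()].
#' @param new_temperature Target temperature in Kelvin (> 0, vectorized).
#' @return Rate at the new temperature, same units as the reference rate.
#' @export
arrhenius_scale <- function(model, new_temperature) {
  stopifnot(inherits(model, "arrhenius_model"))
  if (!is.numeric(new_temperature) || any(is.na(new_temperature)) ||
      any(new_temperature <= 0)) {
    stop("`new_temperature` must be > 0 K", call. = FALSE)
  }
  model$reference_rate *
    exp(-(model$activation_energy / R_GAS) *
          (1 / new_temperature - 1 / model$reference_temperature))
}

#' Convert Celsius to Kelvin
#' @param celsius Temperature in degrees Celsius.
#' @return Temperature in Kelvin.
#' @export
celsius_to_kelvin <- function(celsius) celsius + 273.15

#' Base-lesion accumulation model
#'
#' Depurination and oxidative guanine damage (8-oxo-dG) accumulate per
#' nucleotide 1-2 orders of magnitude faster than backbone scission; the
#' two chemistries are pooled into one rate because measurements report
#' them jointly. The default rate is calibrated so a 200-nt strand has a
#' 6% chance of developing at least one lesion per year at room
#' temperature, i.e. `-log(0.94) / 200` per nt per year.
#'
#' @param lesion_rate_per_nt_per_year Combined lesion rate (1/nt/yr, >= 0).
#' @return An object of class `lesion_model`.
#' @export
lesion_model <- function(lesion_rate_per_nt_per_year = -log(0.94) / 200) {
  check_scalar(lesion_rate_per_nt_per_year, "lesion_rate_per_nt_per_year",
               lower = 0)
  structure(list(lesion_rate_per_nt_per_year = lesion_rate_per_nt_per_year),
            class = "lesion_model")
}

#' Probability a strand develops at least one base lesion
#'
#' Poisson accumulation: `1 - exp(-rate * length * time)`.
#'
#' @param model A [lesion_model()].
#' @param length Strand length in nt (>= 1, vectorized).
#' @param time Time in years (>= 0, vectorized).
#' @return Probability in \[0, 1\].
#' @export
#' @examples
#' lesion_probability(lesion_model(), length = 200, time = 1) # 0.06
lesion_probability <- function(model, length, time) {
  stopifnot(inherits(model, "lesion_model"))
  if (!is.numeric(length) || any(is.na(length)) || any(length < 1)) {
    stop("`length` must be >= 1 nt", call. = FALSE)
  }
  if (!is.numeric(time) || any(is.na(time)) || any(time < 0)) {
    stop("`time` must be >= 0 years", call. = FALSE)
  }
  1 - exp(-model$lesion_rate_per_nt_per_year * length * time)
}

#' @export
print.first_order_breakage <- function(x, ...) {
  cat(sprintf("First-order breakage model: %.4g scissions/nt/yr\n",
              x$rate_per_nt_per_year))
  invisible(x)
}

#' @export
print.freeze_thaw_model <- function(x, ...) {
  cat(sprintf("Freeze-thaw decay: intact = %.4f * exp(-%.4f * cycles)\n",
              x$amplitude, x$decay_per_cycle))
  invisible(x)
}

#' @export
print.arrhenius_model <- function(x, ...) {
  cat(sprintf("Arrhenius model: Ea = %.3g kJ/mol, rate %.4g at %.2f K\n",
              x$activation_energy / 1000, x$reference_rate,
              x$reference_temperature))
  invisible(x)
}

#' @export
print.lesion_model <- function(x, ...) {
  cat(sprintf("Base-lesion model: %.4g lesions/nt/yr\n",
              x$lesion_rate_per_nt_per_year))
  invisible(x)
}
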