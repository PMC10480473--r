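# Beam and pulse-schedule descriptions shared by all solvers.

#' Square-wave pulse schedule
#'
#' @param duty_cycle Fraction of each period the source is ON, in `(0, 1]`.
#'   A duty cycle of exactly 1 is the continuous source.
#' @param frequency Pulse repetition rate, Hz.
#' @return A `pulse_schedule` list.
#' @export
#' @examples
#' pulse_schedule(0.5, 1)  # ON 0.5 s, OFF 0.5 s
pulse_schedule <- function(duty_cycle, frequency = 1) {
  if (!is.numeric(duty_cycle) || length(duty_cycle) != 1 ||
      duty_cycle <= 0 || duty_cycle > 1) {
    abort("`duty_cycle` must lie in (0, 1]")
  }
  check_positive(frequency, "frequency")
  structure(list(duty_cycle = duty_cycle, frequency = frequency),
            class = "pulse_schedule")
}

#' Continuous (unmodulated) schedule
#' @export
continuous <- function() pulse_schedule(1, 1)

is_continuous <- function(schedule) {
  is.null(schedule) || schedule$duty_cycle >= 1
}

#' Gaussian beam source
#'
#' The beam waist `waist` is the 1/e^2 *intensity radius* w, so the on-axis
#' peak irradiance is `2 P / (pi w^2)` and the surface profile is
#' `I(r) = (2P / pi w^2) exp(-2 r^2 / w^2)`.
#'
#' @param power Total beam power, W (>= 0).
#' @param waist 1/e^2 intensity radius, m (> 0).
#' @param pulse A [pulse_schedule()] or `NULL` for a continuous source.
#' @return A `source_spec` list.
#' @export
#' @examples
#' gaussian_source(0.1, 0.02)                       # 100 mW, 2 cm waist
#' gaussian_source(1, 0.02, pulse_schedule(0.5, 1)) # 1 W, 50% duty @ 1 Hz
gaussian_source <- function(power, waist, pulse = NULL) {
  check_nonneg(power, "power")
  check_positive(waist, "waist")
  if (!is.null(pulse) && !inherits(pulse, "pulse_schedule")) {
    abort("`pulse` must be a pulse_schedule() or NULL")
  }
  structure(list(power = power, waist = waist, profile = "gaussian",
                 pulse = pulse),
            class = "source_spec")
}

# surface irradiance of the beam at radius r (W/m^2)
beam_irradiance <- function(source, r) {
  2 * source$power / (pi * source$waist^2) * exp(-2 * r^2 / source$waist^2)
}

#' Square-wave pulse signal
#'
#' Unit ON/OFF state of a pulse schedule at time `t`: 1 while
#' `(t mod 1/f) < duty/f`, else 0. A continuous schedule (duty 1 or `NULL`)
#' is always ON.
#'
#' @param schedule A [pulse_schedule()] or `NULL`.
#' @param t Time(s), s (>= 0).
#' @return 0/1 vector of the same length as `t`.
#' @export
#' @examples
#' pulse_signal(pulse_schedule(0.5, 1), c(0.25, 0.75))
pulse_signal <- function(schedule, t) {
  if (any(t < 0)) abort("`t` must be >= 0")
  if (is_continuous(schedule)) return(rep(1, length(t)))
  period <- 1 / schedule$frequency
  phase <- t - floor(t / period) * period
  as.numeric(phase < schedule$duty_cycle * period - 1e-15 * period |
               abs(phase - period) < 1e-12 * period)
}
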