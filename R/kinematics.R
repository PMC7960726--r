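#' Pump-probe shock geometry
#'
#' Bundles the three quantities that map a two-pulse experiment on a liquid
#' microjet onto an equivalent high-repetition-rate measurement: the
#' pump-probe time delay, the upstream spatial offset of the probe focus
#' (positive toward the nozzle), and the jet speed.
#'
#' @param delay_ns pump-probe delay in ns (> 0).
#' @param offset_um probe offset upstream of the pump position in um (>= 0).
#' @param speed_m_s jet speed in m/s (> 0).
#' @return an object of class `shock_geometry`.
#' @examples
#' g <- shock_geometry(122.5, 5, 50)
#' effective_delay(g)        # 222.5 ns
#' equivalent_rep_rate(g)    # ~4.49 MHz
#' @export
shock_geometry <- function(delay_ns, offset_um, speed_m_s) {
  check_positive(delay_ns, "delay_ns")
  check_positive(offset_um, "offset_um", strict = FALSE)
  check_positive(speed_m_s, "speed_m_s")
  structure(list(delay_ns = delay_ns, offset_um = offset_um,
                 speed_m_s = speed_m_s),
            class = "shock_geometry")
}

#' @export
print.shock_geometry <- function(x, ...) {
  cat(sprintf(
    "shock geometry: delay %.8g ns, offset %.8g um upstream, jet %.8g m/s\n",
    x$delay_ns, x$offset_um, x$speed_m_s))
  cat(sprintf("  effective delay %.8g ns (~%.3g MHz equivalent), shock travel %.8g um\n",
              effective_delay(x), equivalent_rep_rate(x),
              shock_travel_distance(x)))
  invisible(x)
}

# 1 um / (1 m/s) = 1000 ns
.offset_time_ns <- function(offset_um, speed_m_s) 1000 * offset_um / speed_m_s

#' Effective pump-probe delay
#'
#' Time for jet material at the probe position to be reached by a
#' disturbance launched at the pump position: the set delay plus the
#' advection time over the upstream offset, `delay + offset/speed`.
#' This is the delay an equivalent non-offset measurement would use.
#'
#' @param g a [shock_geometry()].
#' @return effective delay in ns.
#' @export
effective_delay <- function(g) {
  stopifnot(inherits(g, "shock_geometry"))
  g$delay_ns + .offset_time_ns(g$offset_um, g$speed_m_s)
}

#' Delay required to emulate a given repetition rate
#'
#' Inverts [effective_delay()]: the pump-probe delay whose effective delay
#' equals the pulse spacing of `target_rate_mhz`, for a probe offset
#' `offset_um` and jet speed `speed_m_s`.
#'
#' @param target_rate_mhz repetition rate to emulate, MHz.
#' @param offset_um probe offset upstream, um.
#' @param speed_m_s jet speed, m/s.
#' @return required delay in ns; error if the offset advection time already
#'   exceeds the pulse spacing.
#' @export
required_delay <- function(target_rate_mhz, offset_um, speed_m_s) {
  check_positive(target_rate_mhz, "target_rate_mhz")
  check_positive(offset_um, "offset_um", strict = FALSE)
  check_positive(speed_m_s, "speed_m_s")
  dt <- 1000 / target_rate_mhz - .offset_time_ns(offset_um, speed_m_s)
  if (dt <= 0)
    stop("offset travel time exceeds the pulse spacing: ",
         "this geometry cannot emulate ", target_rate_mhz, " MHz",
         call. = FALSE)
  dt
}

#' Equivalent repetition rate of a pump-probe geometry
#'
#' @param g a [shock_geometry()].
#' @return the repetition rate (MHz) whose pulse spacing equals the
#'   effective delay.
#' @export
equivalent_rep_rate <- function(g) 1000 / effective_delay(g)

#' Shock travel distance
#'
#' Material-frame separation between the pump interaction site and the jet
#' segment probed at probe time: `speed * delay + offset`. Over this
#' distance the shock attenuates before reaching the probed sample.
#'
#' @param g a [shock_geometry()].
#' @return distance in um.
#' @export
shock_travel_distance <- function(g) {
  stopifnot(inherits(g, "shock_geometry"))
  g$speed_m_s * g$delay_ns * 1e-3 + g$offset_um
}

#' Phenomenological power-law shock attenuation
#'
#' Relative pressure `p_ref * (d / d_ref)^(-n)` after travelling distance
#' `d`. This is an explicitly phenomenological scaling utility; the exponent
#' is a required user parameter and no value is asserted as physical.
#'
#' @param d distance travelled, um (> 0); vectorised.
#' @param n power-law exponent (>= 0).
#' @param d_ref reference distance, um (> 0).
#' @param p_ref pressure at the reference distance (default 1, i.e. output
#'   is relative).
#' @return relative pressure(s).
#' @export
attenuation_scale <- function(d, n, d_ref, p_ref = 1) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 0)
    stop("'n' must be a single non-negative exponent", call. = FALSE)
  check_positive(d_ref, "d_ref")
  if (any(!is.finite(d)) || any(d <= 0))
    stop("'d' must be positive", call. = FALSE)
  p_ref * (d / d_ref)^(-n)
}
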