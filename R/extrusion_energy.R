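## Specific mechanical energy from extruder telemetry, and a simplified,
## clearly-labelled 1-D viscous-dissipation energy demonstrator.

#' An extrusion run's operating point
#'
#' @param screw_speed screw speed (rpm), >= 0.
#' @param feed_rate feed rate (kg/h), > 0.
#' @param torque measured torque per shaft (N m), >= 0.
#' @param idle_torque idling torque subtracted before the energy calculation
#'   (N m); default 1.2.
#' @return An object of class `extrusion_run`.
#' @export
extrusion_run <- function(screw_speed, feed_rate, torque, idle_torque = 1.2) {
  if (screw_speed < 0 || torque < 0 || idle_torque < 0)
    stop("speeds and torques must be non-negative")
  if (feed_rate <= 0) stop("`feed_rate` must be positive (kg/h)")
  structure(list(screw_speed = screw_speed, feed_rate = feed_rate,
                 torque = torque, idle_torque = idle_torque),
            class = "extrusion_run")
}

#' Specific mechanical energy of an extrusion run
#'
#' \deqn{SME = \frac{2\pi n (\tau - \tau_{idle})}{60\, \dot m}}
#' with screw speed n in rpm, net torque in N m and feed rate in kg/h, giving
#' W per (kg/h), i.e. W h/kg, numerically identical to kWh/t. A torque below
#' the idling torque clamps the net torque to zero (flagged).
#'
#' @param run an [extrusion_run()].
#' @return SME in kWh/t, with logical attribute `torque_clamped`.
#' @export
#' @examples
#' compute_sme(extrusion_run(100, 0.12, 2.2, 1.2))  # 87.27 kWh/t
compute_sme <- function(run) {
  stopifnot(inherits(run, "extrusion_run"))
  net <- run$torque - run$idle_torque
  clamped <- net < 0
  net <- max(net, 0)
  out <- 2 * pi * run$screw_speed * net / (60 * run$feed_rate)
  attr(out, "torque_clamped") <- clamped
  out
}

#' A twin-screw element
#'
#' @param kind "conveying" or "kneading".
#' @param length element length (mm), > 0.
#' @param pitch_or_stagger conveying pitch (mm) or kneading staggering angle
#'   (degrees), > 0.
#' @param channel_depth channel depth (mm), > 0; default 2.4 (0.2 x the 12 mm
#'   screw diameter).
#' @return An object of class `screw_element`.
#' @export
screw_element <- function(kind = c("conveying", "kneading"), length,
                          pitch_or_stagger, channel_depth = 2.4) {
  kind <- match.arg(kind)
  if (length <= 0 || pitch_or_stagger <= 0)
    stop("element dimensions must be positive")
  if (channel_depth <= 0) stop("zero or negative channel depth")
  structure(list(kind = kind, length = length,
                 pitch_or_stagger = pitch_or_stagger,
                 channel_depth = channel_depth),
            class = "screw_element")
}

#' Default 12 mm twin-screw configuration
#'
#' A 300 mm (25:1 L/D) layout of conveying elements (18, 12 and 9 mm pitch)
#' interleaved with kneading blocks (30, 60 and 90 degree staggering),
#' mirroring a typical small-scale pharmaceutical screw design.
#'
#' @return A list of [screw_element()] objects totalling 300 mm.
#' @export
default_screw_config <- function() {
  list(
    screw_element("conveying", 72, 18),
    screw_element("conveying", 48, 12),
    screw_element("kneading", 30, 30),
    screw_element("conveying", 36, 12),
    screw_element("kneading", 30, 60),
    screw_element("conveying", 36, 9),
    screw_element("kneading", 30, 90),
    screw_element("conveying", 18, 9))
}

#' Simplified 1-D extrusion energy balance (demonstrator)
#'
#' An openly simplified stand-in for full 1-D extrusion simulators, intended
#' for qualitative comparisons only (e.g. the ordering of energy demand
#' between formulations). Assumptions, all logged in the returned object:
#' fully filled channels; melt isothermal at the barrel temperature; mean
#' channel shear rate gamma = pi D N / h per element; viscous dissipation
#' power eta(gamma, T) * gamma^2 * V_channel; conduction taken as the
#' enthalpy to heat the feed to barrel temperature (cp * dT); melting energy
#' not considered (the melting/softening input is represented by the blend's
#' glass-transition temperature); no die/pressure back-flow coupling.
#'
#' @param screw list of [screw_element()] (default [default_screw_config()]).
#' @param flow the melt's [flow_curve_fit()].
#' @param wlf matching [wlf_params()] (same reference temperature).
#' @param run an [extrusion_run()].
#' @param barrel_temp barrel set temperature (degrees C).
#' @param material list with `density` (kg/m^3), `cp` (J/(g K)) and
#'   `thermal_conductivity` (W/(m K), default 0.18).
#' @param screw_diameter screw diameter (mm), default 12.
#' @param feed_temp feed (ambient) temperature (degrees C), default 25.
#' @return An object of class `energy_breakdown` with fields `sme`,
#'   `dissipated` and `conduction` (kWh/t; `sme = dissipated + conduction`,
#'   melting energy 0 by construction), plus `per_element` (data frame) and
#'   `assumptions` (character vector).
#' @export
simulate_energy_1d <- function(screw = default_screw_config(), flow, wlf, run,
                               barrel_temp,
                               material = list(density = 1191, cp = 1.72,
                                               thermal_conductivity = 0.18),
                               screw_diameter = 12, feed_temp = 25) {
  stopifnot(inherits(flow, "flow_curve_fit"), inherits(run, "extrusion_run"))
  for (el in screw) stopifnot(inherits(el, "screw_element"))
  d_m <- screw_diameter / 1000
  n_rev_s <- run$screw_speed / 60
  m_dot <- run$feed_rate / 3600            # kg/s

  per_el <- do.call(rbind, lapply(screw, function(el) {
    h_m <- el$channel_depth / 1000
    if (h_m <= 0) stop("zero channel depth in screw element")
    l_m <- el$length / 1000
    gamma <- pi * d_m * n_rev_s / h_m      # 1/s, mean channel shear rate
    eta <- eval_viscosity(flow, gamma, temperature = barrel_temp, wlf = wlf)
    vol <- pi * (d_m - h_m) * h_m * l_m    # m^3, annular channel volume
    data.frame(kind = el$kind, length_mm = el$length, gamma_dot = gamma,
               eta = eta, power_W = eta * gamma^2 * vol)
  }))
  dissipated <- sum(per_el$power_W) / m_dot / 3600    # J/kg -> Wh/kg = kWh/t
  # conduction: barrel-regulation heat flux bringing feed to barrel temperature
  conduction <- material$cp * max(barrel_temp - feed_temp, 0) / 3.6  # kJ/kg -> kWh/t
  structure(
    list(sme = dissipated + conduction, dissipated = dissipated,
         conduction = conduction, melting = 0, per_element = per_el,
         assumptions = c(
           "demonstrator model: qualitative comparisons only",
           "fully filled channels, no starve-feeding or back-flow",
           "melt isothermal at barrel temperature",
           sprintf("mean channel shear rate pi*D*N/h, D = %g mm", screw_diameter),
           "conduction = cp * (barrel - feed temperature)",
           "melting energy not considered (softening input = blend Tg)",
           sprintf("thermal conductivity %g W/(m K) (unused by the lumped terms)",
                   material$thermal_conductivity))),
    class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("<energy_breakdown> (simplified 1-D demonstrator)\n")
  cat(sprintf("  SME        : %.1f kWh/t\n", x$sme))
  cat(sprintf("  dissipated : %.1f kWh/t\n", x$dissipated))
  cat(sprintf("  conduction : %.1f kWh/t\n", x$conduction))
  cat("  assumptions:\n")
  for (a in x$assumptions) cat("   -", a, "\n")
  invisible(x)
}

#' Read a screw-configuration CSV
#'
#' Columns: `kind`, `length_mm`, `pitch_or_stagger`, `channel_depth_mm`
#' (optional, default 2.4).
#'
#' @param path CSV path.
#' @return List of [screw_element()] objects.
#' @export
read_screw_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required_cols(df, c("kind", "length_mm", "pitch_or_stagger"), "screw CSV")
  lapply(seq_len(nrow(df)), function(i) {
    screw_element(df$kind[i], df$length_mm[i], df$pitch_or_stagger[i],
                  if ("channel_depth_mm" %in% names(df))
                    df$channel_depth_mm[i] else 2.4)
  })
}
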