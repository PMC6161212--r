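## The core method: calibrate the exponential Tg -> zero-shear-viscosity
## correlation and generate a blend's full model-based flow curve from its Tg
## plus the pure polymer's Carreau-Yasuda / WLF description.

#' Calibrate the Tg to zero-shear-viscosity correlation
#'
#' Fits \eqn{\eta_0 = a e^{b T_g}} by ordinary least squares on
#' \eqn{\ln \eta_0 = \ln a + b T_g}. The prefactor `a` is specific to the
#' stated reference temperature (it carries the temperature dependence of the
#' correlation); `b` is treated as temperature-independent. Tg enters in
#' degrees C.
#'
#' @param points data frame with columns `tg` (degrees C) and `eta0` (Pa s);
#'   at least 2 points with distinct Tg.
#' @param t_ref reference temperature of the eta0 values (degrees C).
#' @return An object of class `tg_eta0_correlation` with fields `a_coeff`,
#'   `b_coeff`, `t_ref`, `calibration_points`, and attributes `r_squared`
#'   and `se` (standard errors of (ln a, b)).
#' @export
#' @examples
#' calibrate_correlation(data.frame(tg = c(90, 100), eta0 = c(100, 1000)), 150)
calibrate_correlation <- function(points, t_ref) {
  points <- as.data.frame(points)
  required_cols(points, c("tg", "eta0"), "correlation input")
  if (nrow(points) < 2L) stop("calibration needs at least 2 points")
  if (length(unique(points$tg)) < 2L)
    stop("calibration points must span at least 2 distinct Tg values")
  if (any(points$eta0 <= 0)) stop("eta0 values must be positive")
  fit <- lm(log(eta0) ~ tg, data = points)
  b <- coef(fit)[[2]]
  a <- exp(coef(fit)[[1]])
  if (b <= 0)
    warning("fitted b <= 0: zero-shear viscosity should increase with Tg; ",
            "check the calibration points")
  r2 <- if (nrow(points) > 2L) summary(fit)$r.squared else 1
  structure(list(a_coeff = a, b_coeff = b, t_ref = as.numeric(t_ref),
                 calibration_points = points),
            class = "tg_eta0_correlation",
            r_squared = r2,
            se = sqrt(diag(vcov(fit))))
}

#' @export
print.tg_eta0_correlation <- function(x, ...) {
  cat(sprintf(
    "<tg_eta0_correlation> eta0 = %.4g * exp(%.4f * Tg[degC]) Pa s at %.0f degC\n",
    x$a_coeff, x$b_coeff, x$t_ref))
  cat(sprintf("  calibrated on %d points; log-linear r^2 = %.4f\n",
              nrow(x$calibration_points), attr(x, "r_squared")))
  invisible(x)
}

#' Default correlation calibrated on the packaged reference blends
#'
#' Calibrates [calibrate_correlation()] on the five packaged blends with
#' model-estimated zero-shear viscosities at 150 degrees C (CXB 10/30%,
#' LOR 30%, NAP 10/30% in copovidone). Useful as a starting point when no
#' user calibration data are available; re-calibrate for other polymers or
#' reference temperatures.
#'
#' @param leave_out optional blend label(s) to exclude (for cross-validation).
#' @return A `tg_eta0_correlation` at 150 degrees C.
#' @export
default_tg_eta0_correlation <- function(leave_out = NULL) {
  fx <- load_paper_fixtures()
  pairs <- fx$viscosity_pairs
  pairs <- pairs[!(names(pairs) %in% leave_out)]
  pts <- data.frame(
    tg = vapply(pairs, `[[`, 0, "tg"),
    eta0 = vapply(pairs, `[[`, 0, "eta0_estimated"))
  pts <- pts[is.finite(pts$eta0), ]
  calibrate_correlation(pts, t_ref = 150)
}

#' Predict a blend's zero-shear viscosity from its Tg
#'
#' @param corr a `tg_eta0_correlation`.
#' @param tg_blend blend glass-transition temperature(s), degrees C
#'   (vectorised).
#' @return Zero-shear viscosity eta0 in Pa s at the correlation's reference
#'   temperature.
#' @export
predict_eta0 <- function(corr, tg_blend) {
  stopifnot(inherits(corr, "tg_eta0_correlation"))
  corr$a_coeff * exp(corr$b_coeff * tg_blend)
}

#' Generate a blend's model-based flow curve from its Tg
#'
#' The heart of the workflow: given the pure polymer's Carreau-Yasuda fit and
#' WLF parameters at a reference temperature, a calibrated Tg-eta0
#' correlation, and only the blend's measured Tg, builds the blend's full
#' flow curve. The zero-shear viscosity is set by the correlation, the
#' relaxation time is scaled by the same ratio
#' \deqn{a_{T,Tg} = \eta_{0,blend}/\eta_{0,polymer} = \lambda_{blend}/\lambda_{polymer},}
#' and the shape parameters n and a, as well as the WLF constants, are
#' inherited unchanged from the polymer.
#'
#' @param polymer_fit the polymer's [flow_curve_fit()].
#' @param polymer_wlf the polymer's [wlf_params()] (same reference
#'   temperature).
#' @param corr a `tg_eta0_correlation` at the same reference temperature.
#' @param tg_blend the blend's measured Tg (degrees C).
#' @param w_api optional API weight fraction; with `api_soluble = TRUE` and
#'   `w_api >= 0.3` a warning is emitted, since specific API-polymer
#'   interactions not captured by the correlation then degrade the
#'   prediction.
#' @param api_soluble optional flag: is the API soluble in the polymer at
#'   ambient temperature?
#' @return A [flow_curve_fit()] for the blend (same t_ref; the polymer's WLF
#'   parameters continue to apply), with attribute `eta0_ratio` = r.
#' @export
generate_model_flow_curve <- function(polymer_fit, polymer_wlf, corr, tg_blend,
                                      w_api = NULL, api_soluble = NA) {
  stopifnot(inherits(polymer_fit, "flow_curve_fit"),
            inherits(polymer_wlf, "wlf_params"),
            inherits(corr, "tg_eta0_correlation"))
  if (abs(polymer_fit$t_ref - corr$t_ref) > 1e-9 ||
      abs(polymer_fit$t_ref - polymer_wlf$t0) > 1e-9)
    stop("polymer flow curve, WLF parameters and correlation must share one ",
         "reference temperature")
  if (!is.null(w_api) && isTRUE(api_soluble) && w_api >= 0.3)
    warning("API weight fraction >= 30% of an API soluble in the polymer: ",
            "specific interactions may lower the true melt viscosity below ",
            "this prediction")
  eta0_blend <- predict_eta0(corr, tg_blend)
  r <- eta0_blend / polymer_fit$eta0
  out <- flow_curve_fit(eta0 = eta0_blend, lam = polymer_fit$lam * r,
                        a = polymer_fit$a, n = polymer_fit$n,
                        t_ref = polymer_fit$t_ref)
  attr(out, "eta0_ratio") <- r
  out
}

#' Tabulate a flow curve over a rate grid
#'
#' @param fit a [flow_curve_fit()].
#' @param gamma_dot shear-rate grid (1/s); default 50 log-spaced points over
#'   1e-3..1e3.
#' @return Data frame with columns `gamma_dot` and `eta`.
#' @export
tabulate_flow_curve <- function(fit, gamma_dot = 10^seq(-3, 3, length.out = 50)) {
  data.frame(gamma_dot = gamma_dot, eta = eval_viscosity(fit, gamma_dot))
}
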