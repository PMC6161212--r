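## Glass-transition mixing models: Couchman-Karasz prediction and the BCKV
## polynomial fit, plus deviation diagnostics between them.

C_TO_K <- 273.15

#' Couchman-Karasz prediction of a blend's glass-transition temperature
#'
#' Thermodynamic mixing rule
#' \deqn{T_g = \frac{w_1 T_{g,1} + k_{CK}(1-w_1) T_{g,2}}{w_1 + k_{CK}(1-w_1)},
#'   \qquad k_{CK} = \Delta C_{p,2} / \Delta C_{p,1},}
#' with subscript 1 the API and 2 the polymer. The mean is taken on the
#' absolute (Kelvin) scale, as the underlying entropy-continuity derivation
#' requires, and converted back to degrees C.
#'
#' @param blend a [blend_spec()]; both components need `tg` and `delta_cp`.
#' @param w_api optional weight fraction overriding `blend$w_api`.
#' @return Predicted blend Tg in degrees C.
#' @export
#' @examples
#' fx <- load_paper_fixtures()
#' ck_tg(blend_spec(fx$materials$Celecoxib, fx$materials$Copovidone, 0.30))
ck_tg <- function(blend, w_api = blend$w_api) {
  stopifnot(inherits(blend, "blend_spec"))
  if (blend$api$delta_cp <= 0 || blend$polymer$delta_cp <= 0)
    stop("Couchman-Karasz requires positive heat-capacity steps")
  if (any(w_api < 0 | w_api > 1)) stop("`w_api` must lie in [0, 1]")
  k_ck <- blend$polymer$delta_cp / blend$api$delta_cp
  tg1 <- blend$api$tg + C_TO_K
  tg2 <- blend$polymer$tg + C_TO_K
  tg_k <- (w_api * tg1 + k_ck * (1 - w_api) * tg2) /
    (w_api + k_ck * (1 - w_api))
  tg_k - C_TO_K
}

#' BCKV (Brostow-Chiu-Kalogeras-Vassilikou-Dova) parameter set
#'
#' The BCKV model extends linear Tg mixing with a composition-weighted
#' polynomial that captures positive or negative deviations:
#' \deqn{T_g(w_1) = w_1 T_{g,1} + (1-w_1) T_{g,2} +
#'   w_1(1-w_1)\left[a_0 + a_1(2w_1-1) + a_2(2w_1-1)^2\right].}
#' The correction vanishes at both endpoints, so pure-component Tgs are pinned.
#'
#' @param tg_api,tg_polymer pure-component glass transitions (degrees C).
#' @param a0,a1,a2 polynomial coefficients (degrees C).
#' @return An object of class `bckv_params`.
#' @export
bckv_params <- function(tg_api, tg_polymer, a0 = 0, a1 = 0, a2 = 0) {
  vals <- c(tg_api, tg_polymer, a0, a1, a2)
  if (!all(is.finite(vals))) stop("all BCKV parameters must be finite")
  structure(list(tg_api = tg_api, tg_polymer = tg_polymer,
                 a0 = a0, a1 = a1, a2 = a2),
            class = "bckv_params")
}

#' @export
print.bckv_params <- function(x, ...) {
  cat(sprintf(
    "<bckv_params> Tg_api = %.1f, Tg_polymer = %.1f degC; a0 = %.2f, a1 = %.2f, a2 = %.2f\n",
    x$tg_api, x$tg_polymer, x$a0, x$a1, x$a2))
  if (!is.null(attr(x, "adj_r_squared")))
    cat(sprintf("  adjusted r^2 = %.4f\n", attr(x, "adj_r_squared")))
  invisible(x)
}

#' Evaluate the BCKV composition curve
#'
#' @param params a [bckv_params()] object.
#' @param w_api API weight fraction(s) in \[0, 1\] (vectorised).
#' @return Blend Tg(s) in degrees C.
#' @export
bckv_tg <- function(params, w_api) {
  stopifnot(inherits(params, "bckv_params"))
  if (any(!is.finite(w_api)) || any(w_api < 0 | w_api > 1))
    stop("`w_api` must lie in [0, 1]")
  u <- 2 * w_api - 1
  w_api * params$tg_api + (1 - w_api) * params$tg_polymer +
    w_api * (1 - w_api) * (params$a0 + params$a1 * u + params$a2 * u^2)
}

#' Fit the BCKV composition curve to measured blend Tgs
#'
#' The endpoints are pinned to the supplied pure-component Tgs (the BCKV
#' correction vanishes there), so the fit is linear least squares in
#' (a0, a1, a2) on the interior points. With fewer than three interior points
#' the polynomial order is reduced (two points: a2 = 0; one point: a1 = a2 = 0).
#'
#' @param points data frame (or list coercible to one) with columns `w_api`
#'   and `tg` (degrees C); endpoint rows (w = 0 or 1) are ignored for fitting.
#' @param tg_api,tg_polymer pure-component glass transitions (degrees C).
#' @return A [bckv_params()] object with attributes `adj_r_squared`,
#'   `r_squared`, `residuals` and `n_fit`.
#' @export
fit_bckv <- function(points, tg_api, tg_polymer) {
  points <- as.data.frame(points)
  required_cols(points, c("w_api", "tg"), "BCKV input")
  interior <- points$w_api > 0 & points$w_api < 1
  w <- points$w_api[interior]
  tg <- points$tg[interior]
  n <- length(w)
  if (n < 1L) stop("BCKV fit needs at least one interior composition")
  linear <- w * tg_api + (1 - w) * tg_polymer
  y <- tg - linear
  u <- 2 * w - 1
  p <- min(3L, n)
  X <- cbind(w * (1 - w),
             if (p >= 2) w * (1 - w) * u,
             if (p >= 3) w * (1 - w) * u^2)
  fit <- lm.fit(X, y)
  a <- unname(c(fit$coefficients, 0, 0)[1:3])
  a[is.na(a)] <- 0
  fitted_tg <- linear + X %*% fit$coefficients[seq_len(p)]
  ss_res <- sum((tg - fitted_tg)^2)
  ss_tot <- sum((tg - mean(tg))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  adj <- if (n - p - 1 > 0) 1 - (1 - r2) * (n - 1) / (n - p - 1) else NA_real_
  out <- bckv_params(tg_api, tg_polymer, a[1], a[2], a[3])
  se <- rep(NA_real_, 3)
  if (n > p) {
    s2 <- ss_res / (n - p)
    xtx_inv <- try(solve(crossprod(X)), silent = TRUE)
    if (!inherits(xtx_inv, "try-error"))
      se[seq_len(p)] <- sqrt(diag(s2 * xtx_inv))
  }
  attr(out, "r_squared") <- r2
  attr(out, "adj_r_squared") <- adj
  attr(out, "residuals") <- as.numeric(tg - fitted_tg)
  attr(out, "se") <- se
  attr(out, "n_fit") <- n
  out
}

#' Deviation of a measured blend Tg from the Couchman-Karasz prediction
#'
#' @param record a [blend_record()] with a measured Tg; its components must
#'   carry `tg` and `delta_cp`.
#' @return Signed deviation `tg_measured - ck_tg(blend)` in degrees C
#'   (positive when the measurement lies above the CK prediction).
#' @export
#' @examples
#' fx <- load_paper_fixtures()
#' ck_deviation(fx$blends[["CXB 30%"]])  # approx +8.8 degC
ck_deviation <- function(record) {
  stopifnot(inherits(record, "blend_record"))
  record$tg_measured - ck_tg(record$blend)
}

#' Extremal gap between the BCKV and Couchman-Karasz composition curves
#'
#' Scans w in \[0, 1\] on a fine grid and returns the signed gap
#' `bckv_tg(w) - ck_tg(w)` of largest magnitude, an alternative deviation
#' diagnostic to evaluating at the measured compositions.
#'
#' @param params a [bckv_params()] object.
#' @param blend a [blend_spec()] supplying the CK constants (composition is
#'   scanned, not taken from the blend).
#' @param step grid resolution in weight fraction.
#' @return A list with `w_api` (location) and `gap` (signed degrees C).
#' @export
bckv_ck_extremum <- function(params, blend, step = 0.001) {
  w <- seq(0, 1, by = step)
  gap <- bckv_tg(params, w) - ck_tg(blend, w_api = w)
  i <- which.max(abs(gap))
  list(w_api = w[i], gap = gap[i])
}
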