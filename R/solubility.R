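## API-in-polymer solubility phase diagram from annealing DSC: invert the
## annealed-sample Tg to a soluble API fraction via the BCKV curve, fit the
## exponential phase boundary T_annealing = y0 + A * exp(R0 * x), and
## extrapolate the dissolved fraction to ambient temperature.

#' An annealing-DSC observation
#'
#' One annealed sample: nominal composition, annealing temperature, and the
#' glass transition measured after annealing (which reflects the API fraction
#' dissolved in the polymer at the annealing temperature).
#'
#' @param nominal_w_api nominal API weight fraction of the sample.
#' @param t_annealing annealing temperature (degrees C); must exceed the
#'   annealed Tg (annealing happens in the viscous regime).
#' @param tg_annealed Tg measured after annealing (degrees C).
#' @return An object of class `annealing_record`.
#' @export
annealing_record <- function(nominal_w_api, t_annealing, tg_annealed) {
  if (nominal_w_api < 0 || nominal_w_api > 1)
    stop("`nominal_w_api` must lie in [0, 1]")
  if (t_annealing <= tg_annealed)
    stop("`t_annealing` must exceed `tg_annealed`")
  structure(list(nominal_w_api = nominal_w_api, t_annealing = t_annealing,
                 tg_annealed = tg_annealed),
            class = "annealing_record")
}

#' Soluble API fraction from an annealed sample's Tg
#'
#' Numerically inverts the BCKV composition curve, `bckv_tg(w) = tg_annealed`,
#' on w in \[0, 1\]. BCKV curves with large polynomial coefficients can be
#' non-monotone; when several roots exist the one nearest the nominal fraction
#' is returned and the multiplicity is flagged.
#'
#' @param tg_annealed measured Tg of the annealed sample (degrees C).
#' @param bckv a [bckv_params()] object describing Tg vs composition.
#' @param nominal_w_api nominal composition used to disambiguate multiple
#'   roots (optional).
#' @param tol root-finding tolerance in weight fraction.
#' @return The soluble fraction, with attributes `n_roots` (number of distinct
#'   roots found) and `roots` (all of them).
#' @export
soluble_fraction_from_tg <- function(tg_annealed, bckv, nominal_w_api = NA_real_,
                                     tol = 1e-9) {
  stopifnot(inherits(bckv, "bckv_params"))
  grid <- seq(0, 1, length.out = 2001L)
  f <- bckv_tg(bckv, grid) - tg_annealed
  rng <- range(bckv_tg(bckv, grid))
  if (tg_annealed < rng[1] - 1e-8 || tg_annealed > rng[2] + 1e-8)
    stop(sprintf(
      "tg_annealed = %.2f degC is outside the attainable BCKV range [%.2f, %.2f]",
      tg_annealed, rng[1], rng[2]))
  roots <- grid[abs(f) < 1e-12]
  sgn <- sign(f)
  cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in cross) {
    r <- uniroot(function(w) bckv_tg(bckv, w) - tg_annealed,
                 lower = grid[i], upper = grid[i + 1], tol = tol)$root
    roots <- c(roots, r)
  }
  roots <- sort(unique(round(roots, 9)))
  if (!length(roots)) {
    # tg equals an extremum touched tangentially; take the grid minimiser
    roots <- grid[which.min(abs(f))]
  }
  pick <- if (is.finite(nominal_w_api)) which.min(abs(roots - nominal_w_api)) else 1L
  out <- roots[pick]
  attr(out, "n_roots") <- length(roots)
  attr(out, "roots") <- roots
  out
}

#' Fit the exponential solubility phase boundary
#'
#' Fits \eqn{T_{annealing} = y_0 + A \exp(R_0 x)} to (soluble fraction,
#' annealing temperature) points by nonlinear least squares. `y0` plays the
#' role of the API melting point but is fitted; it is initialised at
#' `y0_init` (typically the melting point) when supplied, and can be
#' constrained to a window around it (`y0_window`) reflecting the physical
#' requirement that the phase boundary terminates near the melting point --
#' without such an anchor `y0` is only weakly identified from the narrow
#' temperature range annealing experiments can probe, and the ambient-
#' temperature extrapolation becomes unstable. Both sign branches (A > 0,
#' R0 > 0, and A < 0, R0 < 0, the physically usual one for an API partly
#' soluble at ambient temperature) are explored via a y0-profiled log-linear
#' start, then polished with Levenberg-Marquardt.
#'
#' @param points data frame with columns `w_soluble` and `t_annealing`
#'   (degrees C); at least 4 points spanning at least 3 distinct temperatures.
#' @param y0_init optional starting value for `y0` (the API melting point).
#' @param y0_window half-width (degrees C) of the allowed interval around
#'   `y0_init`; default `Inf` (unconstrained). Ignored without `y0_init`.
#' @param residuals which variable carries the measurement error:
#'   `"t_annealing"` (default; least squares on temperature, the model's
#'   natural orientation) or `"w_soluble"` (least squares on the fraction,
#'   appropriate when the fractions are inverted from noisy Tg measurements
#'   while the annealing temperatures are set exactly).
#' @return An object of class `solubility_curve` with fields `y0`, `A`, `R0`
#'   and attributes `adj_r_squared`, `r_squared`, `residuals`.
#' @export
fit_solubility_curve <- function(points, y0_init = NULL, y0_window = Inf,
                                 residuals = c("t_annealing", "w_soluble")) {
  points <- as.data.frame(points)
  residuals <- match.arg(residuals)
  required_cols(points, c("w_soluble", "t_annealing"), "solubility input")
  x <- points$w_soluble
  temp <- points$t_annealing
  if (length(x) < 4L || length(unique(temp)) < 3L)
    stop("solubility fit needs >= 4 points spanning >= 3 distinct temperatures")

  # y0-profiled initialisation: for trial y0, ln|T - y0| is linear in x
  starts <- list()
  add_start <- function(y0) {
    d <- temp - y0
    if (all(d > 0) || all(d < 0)) {
      fit <- lm(log(abs(d)) ~ x)
      A0 <- sign(d[1]) * exp(coef(fit)[[1]])
      R00 <- coef(fit)[[2]]
      starts[[length(starts) + 1L]] <<- c(y0 = y0, A = A0, R0 = R00)
    }
  }
  span <- diff(range(temp))
  for (y0 in c(y0_init,
               min(temp) - span * c(0.05, 0.25, 1, 4),
               max(temp) + span * c(0.05, 0.25, 1, 4)))
    add_start(y0)
  lower <- c(-Inf, -Inf, -Inf); upper <- c(Inf, Inf, Inf)
  if (!is.null(y0_init) && is.finite(y0_window)) {
    lower[1] <- y0_init - y0_window
    upper[1] <- y0_init + y0_window
    starts <- Filter(function(s) s[1] >= lower[1] && s[1] <= upper[1], starts)
    if (!length(starts)) starts <- list(c(y0 = y0_init, A = -span, R0 = -1))
  }

  resid_fn <- if (residuals == "t_annealing") {
    function(p) temp - (p[1] + p[2] * exp(p[3] * x))
  } else {
    function(p) {
      q <- (temp - p[1]) / p[2]
      ifelse(q > 0, x - log(q) / p[3], 1e3 * (1 + abs(q)))
    }
  }
  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = pmin(pmax(s, lower), upper), lower = lower, upper = upper,
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500,
                                           ftol = 1e-15, ptol = 1e-15)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("solubility curve fit failed to converge; check the input points")
  p <- best$par
  res <- resid_fn(p)
  obs <- if (residuals == "t_annealing") temp else x
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
  n <- length(x)
  adj <- if (n - 4 > 0) 1 - (1 - r2) * (n - 1) / (n - 4) else NA_real_
  se <- sqrt(diag(vcov_nlslm(best)))
  structure(list(y0 = p[["y0"]], A = p[["A"]], R0 = p[["R0"]]),
            class = "solubility_curve",
            r_squared = r2, adj_r_squared = adj, residuals = res, se = se)
}

#' Construct a solubility curve from known parameters
#'
#' @param y0,A,R0 parameters of \eqn{T = y_0 + A \exp(R_0 x)} (`y0`, `A` in
#'   degrees C, `R0` per unit fraction).
#' @return An object of class `solubility_curve`.
#' @export
solubility_curve <- function(y0, A, R0) {
  stopifnot(is.finite(y0), is.finite(A), is.finite(R0))
  structure(list(y0 = y0, A = A, R0 = R0), class = "solubility_curve")
}

#' @export
print.solubility_curve <- function(x, ...) {
  cat(sprintf("<solubility_curve> T(x) = %.2f + %.4g * exp(%.4g * x)\n",
              x$y0, x$A, x$R0))
  if (!is.null(attr(x, "adj_r_squared")))
    cat(sprintf("  adjusted r^2 = %.4f\n", attr(x, "adj_r_squared")))
  s25 <- solubility_at(x, 25)
  cat(sprintf("  soluble fraction at 25 degC: %s\n",
              if (isTRUE(attr(s25, "insoluble"))) "insoluble"
              else sprintf("%.3f", as.numeric(s25))))
  invisible(x)
}

#' Soluble API fraction at a temperature
#'
#' Inverts the phase boundary: \eqn{x = \ln((T - y_0)/A)/R_0}. When
#' \eqn{(T - y_0)/A \le 0} the temperature lies beyond the curve's `y0`
#' asymptote and there is no solution: for a rising boundary (A > 0, R0 > 0)
#' that means the API is insoluble there (0 with an `insoluble` flag); for
#' the falling-coefficient branch (A < 0, R0 < 0) it means the temperature
#' is at or above the boundary's terminus near the melting point, so the API
#' is fully miscible (1, flagged `clipped`). Results outside \[0, 1\] are
#' clipped with a `clipped` flag.
#'
#' @param curve a `solubility_curve`.
#' @param temperature temperature of interest (degrees C); ambient solubility
#'   uses 25.
#' @return Soluble weight fraction with logical attributes `insoluble` and
#'   `clipped`.
#' @export
solubility_at <- function(curve, temperature = 25) {
  stopifnot(inherits(curve, "solubility_curve"))
  q <- (temperature - curve$y0) / curve$A
  if (q <= 0) {
    out <- if (curve$A > 0) 0 else 1
    attr(out, "insoluble") <- curve$A > 0
    attr(out, "clipped") <- curve$A < 0
    return(out)
  }
  x <- log(q) / curve$R0
  clipped <- x < 0 || x > 1
  out <- min(max(x, 0), 1)
  attr(out, "insoluble") <- FALSE
  attr(out, "clipped") <- clipped
  out
}

#' Build a solubility phase diagram from annealing-DSC records
#'
#' Full pipeline: invert each annealed Tg through the BCKV curve to a soluble
#' fraction, average replicates per annealing condition, keep the saturated
#' conditions (crystalline excess was present, so the dissolved fraction sits
#' on the phase boundary; fully dissolved samples only echo their nominal
#' loading), fit the exponential boundary, and extrapolate to ambient
#' temperature.
#'
#' Saturation is decided statistically when replicates are available: a
#' condition counts as saturated when the mean deficit `nominal - w_soluble`
#' exceeds 3 standard errors (estimated from the pooled replicate scatter)
#' as well as the absolute `saturation_margin`. The fit minimises residuals
#' in the fraction direction, where the Tg measurement noise lives, and
#' anchors `y0` near the supplied melting point (see
#' [fit_solubility_curve()]).
#'
#' @param records list of [annealing_record()] objects (or a data frame with
#'   columns `nominal_w_api`, `t_annealing`, `tg_annealed`).
#' @param bckv a [bckv_params()] object for the API/polymer pair.
#' @param melting_point API melting point (degrees C), used to anchor `y0`;
#'   optional but strongly recommended for ambient extrapolation.
#' @param y0_window allowed half-width around the melting point for `y0`
#'   (degrees C); default 2, about the accuracy of a DSC melting point.
#' @param saturation_margin minimum absolute deficit for saturation.
#' @return A list with `curve` (the fitted `solubility_curve`), `points`
#'   (per-condition data frame with a `saturated` column) and
#'   `solubility_25` (the extrapolated ambient soluble fraction).
#' @export
solubility_from_annealing <- function(records, bckv, melting_point = NULL,
                                      y0_window = 2, saturation_margin = 0.01) {
  if (is.data.frame(records)) {
    records <- lapply(seq_len(nrow(records)), function(i)
      annealing_record(records$nominal_w_api[i], records$t_annealing[i],
                       records$tg_annealed[i]))
  }
  raw <- do.call(rbind, lapply(records, function(r) {
    w <- soluble_fraction_from_tg(r$tg_annealed, bckv,
                                  nominal_w_api = r$nominal_w_api)
    data.frame(nominal_w_api = r$nominal_w_api,
               t_annealing = r$t_annealing,
               tg_annealed = r$tg_annealed,
               w_soluble = as.numeric(w),
               n_roots = attr(w, "n_roots"))
  }))
  key <- interaction(raw$nominal_w_api, raw$t_annealing, drop = TRUE)
  pts <- do.call(rbind, lapply(split(raw, key), function(g) {
    data.frame(nominal_w_api = g$nominal_w_api[1],
               t_annealing = g$t_annealing[1],
               w_soluble = mean(g$w_soluble),
               n_rep = nrow(g),
               rep_var = if (nrow(g) > 1) stats::var(g$w_soluble) else NA_real_)
  }))
  rownames(pts) <- NULL
  # pooled replicate noise -> standard error of each condition mean
  pool <- pts$rep_var[is.finite(pts$rep_var)]
  sigma_x <- if (length(pool)) sqrt(mean(pool)) else NA_real_
  deficit <- pts$nominal_w_api - pts$w_soluble
  thresh <- if (is.finite(sigma_x))
    pmax(saturation_margin, 3 * sigma_x / sqrt(pts$n_rep))
  else saturation_margin
  pts$saturated <- deficit > thresh
  use <- pts[pts$saturated, , drop = FALSE]
  if (nrow(use) < 4L)
    stop("fewer than 4 saturated annealing conditions; cannot fit a phase boundary")
  curve <- fit_solubility_curve(
    data.frame(w_soluble = use$w_soluble, t_annealing = use$t_annealing),
    y0_init = melting_point, y0_window = y0_window,
    residuals = "w_soluble")
  list(curve = curve, points = pts,
       solubility_25 = solubility_at(curve, 25))
}
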