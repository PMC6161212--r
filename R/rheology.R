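## SAOS frequency-sweep handling, time-temperature superposition (TTS) master
## curves, Carreau-Yasuda flow-curve fitting, and WLF shift-factor fitting.
##
## Conventions: angular frequency omega in rad/s throughout (Hz converted on
## ingestion, omega = 2*pi*f); complex-viscosity magnitude |eta*| in Pa s.
## The Cox-Merz rule is applied when flow curves are fitted to SAOS data:
## |eta*|(omega) is read as eta(gamma_dot) with gamma_dot == omega.

#' An isothermal SAOS frequency sweep
#'
#' @param temperature measurement temperature (degrees C).
#' @param omega angular frequencies (rad/s), strictly monotone.
#' @param eta_star complex-viscosity magnitudes (Pa s), positive, same length
#'   as `omega`.
#' @return An object of class `frequency_sweep`.
#' @export
frequency_sweep <- function(temperature, omega, eta_star) {
  if (length(omega) != length(eta_star))
    stop("`omega` and `eta_star` must have equal length")
  d <- diff(omega)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("`omega` must be strictly monotone")
  if (any(eta_star <= 0)) stop("`eta_star` must be positive")
  structure(list(temperature = as.numeric(temperature),
                 omega = as.numeric(omega), eta_star = as.numeric(eta_star)),
            class = "frequency_sweep")
}

#' @export
print.frequency_sweep <- function(x, ...) {
  cat(sprintf("<frequency_sweep> %.1f degC, %d points, omega %.3g..%.3g rad/s\n",
              x$temperature, length(x$omega), min(x$omega), max(x$omega)))
  invisible(x)
}

#' Read SAOS frequency sweeps from CSV
#'
#' Accepts `temperature_C` plus either `omega_rad_s` or `frequency_Hz`
#' (converted as omega = 2 pi f), and either `eta_star_Pa_s` or the moduli
#' pair `g_prime_Pa` + `g_double_prime_Pa`, from which
#' |eta*| = sqrt(G'^2 + G''^2) / omega is computed.
#'
#' @param path CSV path.
#' @return A list of [frequency_sweep()] objects, one per temperature, each
#'   with omega sorted descending (sweep order: high to low frequency).
#' @export
read_saos_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required_cols(df, "temperature_C", "SAOS CSV")
  omega <- if ("omega_rad_s" %in% names(df)) {
    num_col(df, "omega_rad_s", "SAOS CSV")
  } else if ("frequency_Hz" %in% names(df)) {
    2 * pi * num_col(df, "frequency_Hz", "SAOS CSV")
  } else stop("SAOS CSV needs an 'omega_rad_s' or 'frequency_Hz' column")
  eta <- if ("eta_star_Pa_s" %in% names(df)) {
    num_col(df, "eta_star_Pa_s", "SAOS CSV")
  } else if (all(c("g_prime_Pa", "g_double_prime_Pa") %in% names(df))) {
    sqrt(num_col(df, "g_prime_Pa", "SAOS CSV")^2 +
           num_col(df, "g_double_prime_Pa", "SAOS CSV")^2) / omega
  } else stop("SAOS CSV needs 'eta_star_Pa_s' or 'g_prime_Pa' + 'g_double_prime_Pa'")
  temps <- num_col(df, "temperature_C", "SAOS CSV")
  lapply(sort(unique(temps)), function(tt) {
    i <- which(temps == tt)
    i <- i[order(omega[i], decreasing = TRUE)]
    frequency_sweep(tt, omega[i], eta[i])
  })
}

#' Write SAOS sweeps to CSV
#'
#' @param sweeps list of [frequency_sweep()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_saos_csv <- function(sweeps, path) {
  df <- do.call(rbind, lapply(sweeps, function(s)
    data.frame(temperature_C = s$temperature, omega_rad_s = s$omega,
               eta_star_Pa_s = s$eta_star)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

## squared log-log distance of a shifted sweep to the current master curve;
## cubic-spline interpolation keeps the interpolation bias on smoothly curved
## flow curves well below typical measurement noise
overlap_sse <- function(log_a, sweep, master_fn, master_range) {
  lw <- log10(sweep$omega) + log_a
  inside <- lw >= master_range[1] & lw <= master_range[2]
  if (sum(inside) < 2L) return(NA_real_)
  pred <- master_fn(lw[inside])
  sum((log10(sweep$eta_star[inside]) - pred)^2)
}

shift_one <- function(sweep, master, label_pair) {
  ord <- order(master$omega)
  mlw <- log10(master$omega[ord])
  mle <- log10(master$eta_star[ord])
  keep <- !duplicated(mlw)
  master_fn <- splinefun(mlw[keep], mle[keep], method = "fmm")
  rng <- range(mlw)
  grid <- seq(-8, 8, by = 0.05)
  sse <- vapply(grid, overlap_sse, 0, sweep = sweep,
                master_fn = master_fn, master_range = rng)
  if (all(is.na(sse)))
    stop("no frequency overlap after shifting between ", label_pair,
         "; cannot superpose these sweeps")
  i <- which.min(sse)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  f <- function(la) {
    v <- overlap_sse(la, sweep, master_fn, rng)
    if (is.na(v)) 1e30 else v
  }
  opt <- optimize(f, interval = c(lo, hi), tol = 1e-10)
  la_hat <- opt$minimum
  # per-shift variance from the curvature of the overlap objective
  d <- 1e-3
  hess <- (f(la_hat + d) - 2 * f(la_hat) + f(la_hat - d)) / d^2
  lw <- log10(sweep$omega) + la_hat
  m <- sum(lw >= rng[1] & lw <= rng[2])
  s2 <- opt$objective / max(m - 1, 1)
  var_step <- if (is.finite(hess) && hess > 0) 2 * s2 / hess else NA_real_
  list(a = 10^la_hat, var_step = var_step)
}

#' Build a TTS master curve from isothermal frequency sweeps
#'
#' Horizontally shifts each sweep (in log omega) onto the sweep measured at
#' the reference temperature, choosing each shift factor a_T to minimise the
#' squared log-log distance to the growing master curve in the overlap
#' window. Sweeps are processed outward from the reference temperature in
#' temperature order (pairwise sequential shifting); a_T(t_ref) = 1.
#'
#' @param sweeps list of [frequency_sweep()] objects at distinct temperatures.
#' @param t_ref reference temperature (degrees C); must match one sweep's
#'   temperature.
#' @return An object of class `master_curve` with fields `t_ref`,
#'   `shift_factors` (named numeric, names are temperatures) and `points`
#'   (data frame `omega` = omega * a_T, `eta_star`, `temperature`).
#' @export
build_master_curve <- function(sweeps, t_ref) {
  stopifnot(length(sweeps) >= 1L)
  temps <- vapply(sweeps, `[[`, 0, "temperature")
  if (anyDuplicated(temps)) stop("sweep temperatures must be distinct")
  iref <- which(abs(temps - t_ref) < 1e-9)
  if (length(iref) != 1L)
    stop("`t_ref` must equal one of the sweep temperatures")
  ord <- order(temps)
  temps_sorted <- temps[ord]
  sweeps <- sweeps[ord]
  iref <- which(abs(temps_sorted - t_ref) < 1e-9)

  a_t <- setNames(rep(NA_real_, length(sweeps)), temps_sorted)
  var_cum <- setNames(rep(0, length(sweeps)), temps_sorted)
  a_t[iref] <- 1
  ref <- sweeps[[iref]]
  master <- data.frame(omega = ref$omega, eta_star = ref$eta_star,
                       temperature = ref$temperature)
  add <- function(idx, prev_idx) {
    s <- sweeps[[idx]]
    res <- shift_one(s, master,
                     sprintf("%.1f degC and %.1f degC sweeps",
                             temps_sorted[prev_idx], temps_sorted[idx]))
    a_t[idx] <<- res$a
    var_cum[idx] <<- var_cum[prev_idx] + res$var_step
    master <<- rbind(master,
                     data.frame(omega = s$omega * res$a, eta_star = s$eta_star,
                                temperature = s$temperature))
  }
  if (iref < length(sweeps))
    for (i in (iref + 1L):length(sweeps)) add(i, i - 1L)
  if (iref > 1L)
    for (i in (iref - 1L):1L) add(i, i + 1L)

  master <- master[order(master$omega), ]
  rownames(master) <- NULL
  structure(list(t_ref = t_ref, shift_factors = a_t, points = master,
                 log10_a_var = var_cum),
            class = "master_curve")
}

#' @export
print.master_curve <- function(x, ...) {
  cat(sprintf("<master_curve> t_ref = %.1f degC, %d points, %d temperatures\n",
              x$t_ref, nrow(x$points), length(x$shift_factors)))
  sf <- format(signif(x$shift_factors, 4))
  cat("  log10 a_T:", paste(sprintf("%s degC: %.3f", names(x$shift_factors),
                                    log10(x$shift_factors)), collapse = "; "), "\n")
  invisible(x)
}

#' Carreau-Yasuda flow-curve parameter set
#'
#' The reduced Carreau-Yasuda model (no infinite-shear viscosity term)
#' \deqn{\eta(\dot\gamma) = \eta_0 \left[1 + (\lambda\dot\gamma)^a\right]^{(n-1)/a}}
#' with zero-shear viscosity eta0 (Pa s), relaxation time lambda (s),
#' transition breadth a, and power-law index n (0 < n <= 1 for shear-thinning
#' melts).
#'
#' @param eta0 zero-shear viscosity (Pa s), >= 0 (0 is the degenerate inviscid
#'   limit, accepted for energy-balance bookkeeping).
#' @param lam relaxation time (s), > 0.
#' @param a transition-breadth parameter, > 0.
#' @param n power-law index in (0, 1].
#' @param t_ref reference temperature of the parameter set (degrees C).
#' @return An object of class `flow_curve_fit`.
#' @export
flow_curve_fit <- function(eta0, lam, a, n, t_ref) {
  if (eta0 < 0) stop("`eta0` must be non-negative")
  if (lam <= 0 || a <= 0) stop("`lam` and `a` must be positive")
  if (n <= 0 || n > 1) stop("`n` must lie in (0, 1]")
  structure(list(eta0 = eta0, lam = lam, a = a, n = n,
                 t_ref = as.numeric(t_ref)),
            class = "flow_curve_fit")
}

#' @export
print.flow_curve_fit <- function(x, ...) {
  cat(sprintf(
    "<flow_curve_fit> at %.1f degC: eta0 = %.4g Pa s, lambda = %.4g s, a = %.3f, n = %.3f\n",
    x$t_ref, x$eta0, x$lam, x$a, x$n))
  if (!is.null(attr(x, "rms_log_resid")))
    cat(sprintf("  RMS log10 residual = %.4g\n", attr(x, "rms_log_resid")))
  if (isTRUE(attr(x, "reduced")))
    cat("  (reduced fit: a fixed at 2)\n")
  invisible(x)
}

#' Evaluate a Carreau-Yasuda flow curve
#'
#' Closed-form evaluation of the reduced Carreau-Yasuda model. With a
#' `wlf` parameter set and a target `temperature`, the curve is shifted via
#' the TTS shift factor: eta(gamma_dot, T) = eta_ref(gamma_dot * a_T),
#' matching the horizontal-shift master-curve convention used throughout.
#'
#' @param fit a [flow_curve_fit()].
#' @param gamma_dot shear rate(s), 1/s, non-negative (vectorised).
#' @param temperature optional evaluation temperature (degrees C); requires
#'   `wlf`.
#' @param wlf optional [wlf_params()] used to shift to `temperature`.
#' @return Viscosity eta in Pa s.
#' @export
#' @examples
#' eval_viscosity(flow_curve_fit(1000, 1, 2, 0.5, 150), 1)  # 1000 * 2^-0.25
eval_viscosity <- function(fit, gamma_dot, temperature = NULL, wlf = NULL) {
  stopifnot(inherits(fit, "flow_curve_fit"))
  if (any(gamma_dot < 0)) stop("`gamma_dot` must be non-negative")
  if (!is.null(temperature)) {
    if (is.null(wlf)) stop("shifting to a temperature requires `wlf`")
    if (abs(wlf$t0 - fit$t_ref) > 1e-9)
      stop("WLF reference temperature does not match the flow curve's t_ref")
    gamma_dot <- gamma_dot * shift_factor_at(wlf, temperature)
  }
  fit$eta0 * (1 + (fit$lam * gamma_dot)^fit$a)^((fit$n - 1) / fit$a)
}

#' Fit the Carreau-Yasuda model to a flow curve
#'
#' Least squares in log viscosity via Levenberg-Marquardt. Input is either a
#' [build_master_curve()] result (Cox-Merz: omega read as shear rate) or a
#' data frame with columns `gamma_dot` and `eta`. With fewer than 5 points,
#' or no resolved shear-thinning region, a reduced fit with the transition
#' breadth fixed at a = 2 is used and flagged.
#'
#' @param curve `master_curve` or data frame (`gamma_dot`, `eta`).
#' @param t_ref reference temperature; defaults to the master curve's.
#' @return A [flow_curve_fit()] with attributes `rms_log_resid`, `reduced`,
#'   `se` (parameter standard errors on (log eta0, log lambda, log a, n),
#'   NA where fixed) and `n_points`.
#' @export
fit_carreau_yasuda <- function(curve, t_ref = NULL) {
  if (inherits(curve, "master_curve")) {
    pts <- data.frame(gamma_dot = curve$points$omega,
                      eta = curve$points$eta_star)
    if (is.null(t_ref)) t_ref <- curve$t_ref
  } else {
    pts <- as.data.frame(curve)
    required_cols(pts, c("gamma_dot", "eta"), "flow-curve input")
    if (is.null(t_ref)) stop("`t_ref` must be given for raw point input")
  }
  pts <- pts[order(pts$gamma_dot), ]
  g <- pts$gamma_dot; eta <- pts$eta
  if (any(g <= 0) || any(eta <= 0)) stop("rates and viscosities must be positive")
  n_pts <- length(g)
  leta <- log(eta)

  # starts: plateau from max eta, n from the high-rate log-log slope
  eta0_0 <- max(eta)
  k <- min(3L, n_pts - 1L)
  hi <- seq(n_pts - k, n_pts)
  slope <- if (n_pts >= 2)
    coef(lm(log(eta[hi]) ~ log(g[hi])))[[2]] else 0
  n_0 <- min(max(1 + slope, 0.05), 1)
  below <- which(eta < 0.7 * eta0_0)
  lam_0 <- if (length(below)) 1 / g[below[1]] else 1 / max(g)

  reduced <- n_pts < 5L
  if (!reduced && (max(eta) / min(eta) < 1.2)) {
    # essentially flat data: breadth is unidentifiable, keep a fixed
    reduced <- TRUE
  }
  model <- function(p, fixed_a = NULL) {
    a <- if (is.null(fixed_a)) exp(p[3]) else fixed_a
    n <- p[length(p)]
    p[1] + ((n - 1) / a) * log1p((exp(p[2]) * g)^a)
  }
  run <- function(par, lower, upper, fixed_a = NULL) {
    minpack.lm::nls.lm(
      par = par, lower = lower, upper = upper,
      fn = function(p) leta - model(p, fixed_a),
      control = minpack.lm::nls.lm.control(maxiter = 1000,
                                           ftol = 1e-15, ptol = 1e-15))
  }
  if (reduced) {
    fit <- run(c(log(eta0_0), log(lam_0), n_0),
               lower = c(-Inf, -Inf, 1e-3), upper = c(Inf, Inf, 1),
               fixed_a = 2)
    p <- fit$par
    out <- flow_curve_fit(exp(p[1]), exp(p[2]), 2, p[3], t_ref)
    se <- c(sqrt(diag(vcov_nlslm(fit)))[1:2], NA_real_,
            sqrt(diag(vcov_nlslm(fit)))[3])
  } else {
    fit <- run(c(log(eta0_0), log(lam_0), log(2), n_0),
               lower = c(-Inf, -Inf, log(0.05), 1e-3),
               upper = c(Inf, Inf, log(50), 1))
    p <- fit$par
    out <- flow_curve_fit(exp(p[1]), exp(p[2]), exp(p[3]), p[4], t_ref)
    se <- sqrt(diag(vcov_nlslm(fit)))
  }
  if (fit$info == 0 || fit$info == 5)
    stop("Carreau-Yasuda fit did not converge: ", fit$message)
  attr(out, "rms_log_resid") <- sqrt(fit$deviance / n_pts) / log(10)
  attr(out, "reduced") <- reduced
  attr(out, "se") <- se
  attr(out, "n_points") <- n_pts
  out
}

## covariance of nls.lm parameters (deviance-scaled inverse of J'J)
vcov_nlslm <- function(fit) {
  np <- length(fit$par)
  nres <- length(fit$fvec)
  s2 <- fit$deviance / max(nres - np, 1)
  h <- try(solve(fit$hessian), silent = TRUE)
  if (inherits(h, "try-error")) matrix(NA_real_, np, np) else s2 * 2 * h
}

#' WLF (Williams-Landel-Ferry) shift-factor parameter set
#'
#' \deqn{\log_{10} a_T = \frac{-C_1 (T - T_0)}{C_2 + (T - T_0)}}
#'
#' @param c1 dimensionless constant, > 0.
#' @param c2 constant in K, > 0.
#' @param t0 reference temperature (degrees C), where a_T = 1.
#' @return An object of class `wlf_params`.
#' @export
wlf_params <- function(c1, c2, t0) {
  if (c1 <= 0 || c2 <= 0) stop("`c1` and `c2` must be positive")
  structure(list(c1 = c1, c2 = c2, t0 = as.numeric(t0)), class = "wlf_params")
}

#' @export
print.wlf_params <- function(x, ...) {
  cat(sprintf("<wlf_params> C1 = %.3f, C2 = %.1f K, T0 = %.1f degC\n",
              x$c1, x$c2, x$t0))
  invisible(x)
}

#' Evaluate a WLF shift factor
#'
#' @param wlf a [wlf_params()].
#' @param temperature temperature(s) in degrees C (vectorised).
#' @return a_T (dimensionless); 1 at `t0`, decreasing above it.
#' @export
shift_factor_at <- function(wlf, temperature) {
  stopifnot(inherits(wlf, "wlf_params"))
  dt <- temperature - wlf$t0
  10^(-wlf$c1 * dt / (wlf$c2 + dt))
}

#' Fit the WLF equation to TTS shift factors
#'
#' Least squares on log10 a_T. Initialised by the exact linearisation
#' (T - T0)/log10 a_T = -(C2 + (T - T0))/C1, then polished with
#' Levenberg-Marquardt under positivity bounds.
#'
#' @param shift_factors a `master_curve` (preferred: the per-shift
#'   uncertainties it carries are then propagated into the parameter
#'   covariance via generalised least squares, accounting for their
#'   accumulation along the sweep chain), a named numeric (names =
#'   temperatures in degrees C), or a data frame with columns `temperature`
#'   and `a_t`.
#' @param t0 reference temperature (degrees C); a_T(t0) = 1 is fixed, and at
#'   least 3 other temperatures are required. Defaults to the master curve's.
#' @return A [wlf_params()] with attributes `se` (standard errors of (C1, C2))
#'   and `rms_log_resid`.
#' @export
fit_wlf <- function(shift_factors, t0 = NULL) {
  chain_var <- NULL
  if (inherits(shift_factors, "master_curve")) {
    if (is.null(t0)) t0 <- shift_factors$t_ref
    chain_var <- shift_factors$log10_a_var
    shift_factors <- shift_factors$shift_factors
  }
  if (is.null(t0)) stop("`t0` must be given")
  if (is.data.frame(shift_factors)) {
    temps <- shift_factors$temperature
    a_t <- shift_factors$a_t
  } else {
    temps <- as.numeric(names(shift_factors))
    a_t <- as.numeric(shift_factors)
  }
  keep <- abs(temps - t0) > 1e-9
  temps <- temps[keep]; a_t <- a_t[keep]
  if (!is.null(chain_var)) chain_var <- chain_var[keep]
  if (length(temps) < 3L)
    stop("WLF fit needs at least 3 temperatures besides the reference")
  la <- log10(a_t)
  dt <- temps - t0

  # whitening for the chain covariance: shifts on the same side of t0 share
  # the error of every link closer to the reference
  white <- diag(length(la))
  known_var <- FALSE
  if (!is.null(chain_var) && all(is.finite(chain_var)) && all(chain_var > 0)) {
    V <- matrix(0, length(la), length(la))
    for (i in seq_along(la)) for (j in seq_along(la)) {
      if (sign(dt[i]) == sign(dt[j]))
        V[i, j] <- min(chain_var[i], chain_var[j])
    }
    ch <- try(chol(V + diag(1e-14, nrow(V))), silent = TRUE)
    if (!inherits(ch, "try-error")) {
      white <- backsolve(ch, diag(nrow(V)), transpose = TRUE)
      known_var <- TRUE
    }
  }

  lin <- lm(I(dt / la) ~ dt)
  c1_0 <- -1 / coef(lin)[[2]]
  c2_0 <- -coef(lin)[[1]] * c1_0
  if (!is.finite(c1_0) || c1_0 <= 0) c1_0 <- 8
  if (!is.finite(c2_0) || c2_0 <= 0) c2_0 <- 100
  fit <- minpack.lm::nls.lm(
    par = c(c1 = c1_0, c2 = c2_0), lower = c(1e-6, 1e-6),
    fn = function(p) drop(white %*% (la - (-p[1] * dt / (p[2] + dt)))),
    control = minpack.lm::nls.lm.control(maxiter = 1000,
                                         ftol = 1e-15, ptol = 1e-15))
  out <- wlf_params(fit$par[[1]], fit$par[[2]], t0)
  attr(out, "se") <- if (known_var) {
    # residuals are whitened to unit variance: unscaled (J'J)^-1
    h <- try(solve(fit$hessian), silent = TRUE)
    if (inherits(h, "try-error")) c(NA_real_, NA_real_) else sqrt(diag(2 * h))
  } else sqrt(diag(vcov_nlslm(fit)))
  attr(out, "rms_log_resid") <- sqrt(sum((la - (-out$c1 * dt / (out$c2 + dt)))^2) /
                                       length(la))
  out
}

#' Re-reference a master curve's shift factors
#'
#' Shift factors referenced at `t_ref_new` equal the original ones divided by
#' a_T(t_ref_new).
#'
#' @param curve a `master_curve`.
#' @param t_ref_new new reference temperature; must be one of the sweep
#'   temperatures.
#' @return Named numeric of re-referenced shift factors.
#' @export
rereference_shift_factors <- function(curve, t_ref_new) {
  stopifnot(inherits(curve, "master_curve"))
  key <- which(abs(as.numeric(names(curve$shift_factors)) - t_ref_new) < 1e-9)
  if (length(key) != 1L) stop("`t_ref_new` must be one of the sweep temperatures")
  curve$shift_factors / curve$shift_factors[[key]]
}
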