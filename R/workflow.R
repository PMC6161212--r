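## Workflow binding: characterize polymer -> measure blend Tg -> predict blend
## viscosity -> estimate extrusion energy; configuration, report writing.

#' Read a workflow configuration file
#'
#' Flat key-value YAML. Recognised keys: `saos_csv` (polymer SAOS export) or
#' `polymer_cy`/`polymer_wlf` (inline parameter maps), `reference_temperature`,
#' `blend_tg`, `blend_label`, `w_api`, `api_soluble`, `calibration_csv`
#' (columns `tg`, `eta0`; default: packaged calibration), `screw_speed`,
#' `feed_rate`, `torque`, `idle_torque`, `barrel_temp`, `output_dir`, `seed`.
#'
#' @param path YAML file path.
#' @return A named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  # keep YAML 1.1 boolean-like scalars (the CY parameter key "n"!) literal
  cfg <- yaml::read_yaml(path, handlers = list(
    "bool#no" = function(x) x, "bool#yes" = function(x) x))
  structure(cfg, class = "run_config")
}

#' Run the full model-based viscosity workflow
#'
#' Executes the experimental short-cut this package operationalises: with the
#' pure polymer characterised once (SAOS sweeps -> TTS master curve ->
#' Carreau-Yasuda + WLF fits), only the blend's glass-transition temperature
#' has to be measured to predict its full flow curve, and optionally the
#' extrusion energy demand. Every default and assumption used is logged in
#' the report.
#'
#' @param config a list / `run_config` (see [read_run_config()]).
#' @return The report (list), invisibly written as `report.json` and
#'   `summary.txt` under `config$output_dir` when set.
#' @export
run_workflow <- function(config) {
  cfg <- unclass(config)
  log <- character()
  note <- function(msg) log <<- c(log, msg)

  t_ref <- cfg$reference_temperature
  if (is.null(t_ref)) stop("`reference_temperature` (degC) is required")
  if (is.null(cfg$blend_tg))
    stop("missing input: the blend glass-transition temperature (`blend_tg`) ",
         "is the one measurement this workflow requires")

  # -- polymer rheology -------------------------------------------------
  if (!is.null(cfg$saos_csv)) {
    sweeps <- read_saos_csv(cfg$saos_csv)
    mc <- build_master_curve(sweeps, t_ref = t_ref)
    poly_cy <- fit_carreau_yasuda(mc)
    poly_wlf <- fit_wlf(mc$shift_factors, t0 = t_ref)
    note(sprintf("polymer rheology fitted from %s (%d sweeps)",
                 cfg$saos_csv, length(sweeps)))
  } else if (!is.null(cfg$polymer_cy) && !is.null(cfg$polymer_wlf)) {
    p <- cfg$polymer_cy
    poly_cy <- flow_curve_fit(p$eta0, p$lam, p$a, p$n, t_ref)
    q <- cfg$polymer_wlf
    poly_wlf <- wlf_params(q$c1, q$c2, t_ref)
    note("polymer rheology taken from supplied CY/WLF parameters")
  } else {
    stop("missing input: polymer rheology (either `saos_csv` or ",
         "`polymer_cy` + `polymer_wlf`)")
  }

  # -- Tg - eta0 correlation -------------------------------------------
  if (!is.null(cfg$calibration_csv)) {
    pts <- read.csv(cfg$calibration_csv, stringsAsFactors = FALSE)
    corr <- calibrate_correlation(pts, t_ref = t_ref)
    note(sprintf("correlation calibrated from %s", cfg$calibration_csv))
  } else {
    if (abs(t_ref - 150) > 1e-9)
      stop("the packaged default calibration is valid at 150 degC only; ",
           "supply `calibration_csv` for other reference temperatures")
    corr <- default_tg_eta0_correlation()
    note("correlation: packaged default calibration at 150 degC")
  }

  # -- blend flow curve -------------------------------------------------
  blend_fit <- generate_model_flow_curve(
    poly_cy, poly_wlf, corr, tg_blend = cfg$blend_tg,
    w_api = cfg$w_api, api_soluble = if (is.null(cfg$api_soluble)) NA
    else cfg$api_soluble)
  note("blend lambda scaled by eta0 ratio; n, a and WLF inherited from polymer")
  flow_tab <- tabulate_flow_curve(blend_fit)

  # -- optional energy estimate ----------------------------------------
  energy <- NULL
  if (!is.null(cfg$screw_speed) && !is.null(cfg$feed_rate)) {
    run <- extrusion_run(cfg$screw_speed, cfg$feed_rate,
                         torque = if (is.null(cfg$torque)) 0 else cfg$torque,
                         idle_torque = if (is.null(cfg$idle_torque)) 1.2
                         else cfg$idle_torque)
    barrel <- if (is.null(cfg$barrel_temp)) t_ref else cfg$barrel_temp
    energy <- simulate_energy_1d(flow = blend_fit, wlf = poly_wlf, run = run,
                                 barrel_temp = barrel)
    note(sprintf("1-D demonstrator energy balance at %.0f degC barrel", barrel))
    if (!is.null(cfg$torque)) {
      sme_meas <- compute_sme(run)
      energy$sme_measured <- as.numeric(sme_meas)
      note("measured SME computed from run telemetry")
    }
  }

  report <- list(
    config = cfg,
    polymer = list(cy = unclass(poly_cy), wlf = unclass(poly_wlf)),
    correlation = list(a_coeff = corr$a_coeff, b_coeff = corr$b_coeff,
                       t_ref = corr$t_ref,
                       r_squared = attr(corr, "r_squared")),
    blend = list(tg = cfg$blend_tg, cy = unclass(blend_fit),
                 eta0_ratio = attr(blend_fit, "eta0_ratio")),
    flow_curve = flow_tab,
    energy = if (!is.null(energy)) {
      list(sme = energy$sme, dissipated = energy$dissipated,
           conduction = energy$conduction,
           sme_measured = energy$sme_measured,
           assumptions = energy$assumptions)
    },
    assumptions_log = log)

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(cfg$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(workflow_summary(report),
               file.path(cfg$output_dir, "summary.txt"))
  }
  invisible(report)
}

#' Human-readable one-screen summary of a workflow report
#'
#' @param report result of [run_workflow()].
#' @return Character vector of summary lines.
#' @export
workflow_summary <- function(report) {
  b <- report$blend
  out <- c(
    "model-based melt viscosity workflow",
    sprintf("blend Tg: %.1f degC", b$tg),
    sprintf("predicted eta0: %.4g Pa s at %.0f degC", b$cy$eta0, b$cy$t_ref),
    sprintf("blend CY: lambda = %.4g s, a = %.3f, n = %.3f",
            b$cy$lam, b$cy$a, b$cy$n))
  if (!is.null(report$energy))
    out <- c(out, sprintf("estimated SME (demonstrator): %.1f kWh/t",
                          report$energy$sme))
  c(out, "assumptions:", paste(" -", report$assumptions_log))
}
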