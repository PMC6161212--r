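## Ground-truth generators: every fitting stage in the package can be tested
## without measurement data. All generators are pure functions of their
## arguments plus `seed` (a fixed seed gives byte-identical output).
##
## Noise models: multiplicative log-normal for viscosities (rheometer-typical
## relative error), additive Gaussian in K for temperatures/Tg.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Default copovidone-like synthetic melt description
#'
#' A realistic amorphous-polymer melt at 150 degrees C used as the standard
#' ground truth in tests and examples: eta0 = 1e4 Pa s, lambda = 0.5 s,
#' a = 2, n = 0.3, with WLF constants C1 = 8, C2 = 120 K.
#'
#' @return List with `cy` (a [flow_curve_fit()]) and `wlf` (a
#'   [wlf_params()]), both referenced at 150 degrees C.
#' @export
default_polymer_truth <- function() {
  list(cy = flow_curve_fit(1e4, 0.5, 2, 0.3, t_ref = 150),
       wlf = wlf_params(8, 120, t0 = 150))
}

#' Generate synthetic SAOS frequency sweeps from known ground truth
#'
#' Emulates a frequency-sweep campaign (10 Hz down to 0.1 Hz, one sweep per
#' temperature): |eta*|(omega, T) is the Carreau-Yasuda curve evaluated at
#' omega * a_T(T) (horizontal TTS convention), with multiplicative log-normal
#' noise.
#'
#' @param cy ground-truth [flow_curve_fit()].
#' @param wlf ground-truth [wlf_params()] (same reference temperature).
#' @param temperatures sweep temperatures (degrees C), >= 3 recommended;
#'   default 130-170 in 10 K steps.
#' @param frequencies_hz frequency grid (Hz), descending; default 9
#'   log-spaced points from 10 to 0.1 Hz.
#' @param noise_sigma relative (log-normal sigma) viscosity noise; default
#'   0.02.
#' @param seed RNG seed.
#' @return List of [frequency_sweep()] objects.
#' @export
make_saos_dataset <- function(cy, wlf,
                              temperatures = seq(130, 170, by = 10),
                              frequencies_hz = 10^seq(1, -1, length.out = 9),
                              noise_sigma = 0.02, seed = 1) {
  stopifnot(inherits(cy, "flow_curve_fit"), inherits(wlf, "wlf_params"))
  omega <- 2 * pi * frequencies_hz
  with_seed(seed, {
    lapply(temperatures, function(tt) {
      eta <- eval_viscosity(cy, omega, temperature = tt, wlf = wlf)
      eta <- eta * exp(rnorm(length(eta), 0, noise_sigma))
      frequency_sweep(tt, omega, eta)
    })
  })
}

#' Generate a synthetic Tg-vs-composition data set
#'
#' BCKV-generated blend Tgs with additive Gaussian noise (K).
#'
#' @param bckv ground-truth [bckv_params()].
#' @param w_api composition grid; default 0.1..0.9 in steps of 0.1.
#' @param noise_sigma Tg noise standard deviation (K); default 0.5.
#' @param seed RNG seed.
#' @return Data frame with columns `w_api` and `tg`.
#' @export
make_tg_dataset <- function(bckv, w_api = seq(0.1, 0.9, by = 0.1),
                            noise_sigma = 0.5, seed = 1) {
  stopifnot(inherits(bckv, "bckv_params"))
  with_seed(seed, {
    data.frame(w_api = w_api,
               tg = bckv_tg(bckv, w_api) + rnorm(length(w_api), 0, noise_sigma))
  })
}

#' Generate a synthetic annealing-DSC data set
#'
#' Emulates the annealing protocol used to build solubility phase diagrams:
#' each sample of nominal composition w is annealed about `anneal_offset`
#' degrees above its predicted blend Tg. The API fraction actually dissolved
#' at that temperature is `min(w, x_s(T_annealing))` with x_s from the
#' ground-truth solubility curve, and the recorded annealed Tg is the BCKV
#' curve at that dissolved fraction plus Gaussian noise.
#'
#' @param curve ground-truth [solubility_curve()].
#' @param bckv ground-truth [bckv_params()] (same API/polymer pair).
#' @param nominal_w_api nominal compositions; default 0.5..0.9 in steps of
#'   0.05 (high loadings, so crystalline excess remains and the points sit on
#'   the phase boundary).
#' @param anneal_offset annealing temperature above predicted blend Tg
#'   (degrees C); default 60.
#' @param noise_sigma Tg noise (K); default 0.5.
#' @param replicates samples per composition; default 3.
#' @param seed RNG seed.
#' @return List of [annealing_record()] objects.
#' @export
make_annealing_dataset <- function(curve, bckv,
                                   nominal_w_api = seq(0.5, 0.9, by = 0.05),
                                   anneal_offset = 60, noise_sigma = 0.5,
                                   replicates = 3, seed = 1) {
  stopifnot(inherits(curve, "solubility_curve"), inherits(bckv, "bckv_params"))
  with_seed(seed, {
    out <- list()
    for (w in nominal_w_api) {
      t_ann <- bckv_tg(bckv, w) + anneal_offset
      x_s <- solubility_at(curve, t_ann)
      w_diss <- min(w, as.numeric(x_s))
      tg_true <- bckv_tg(bckv, w_diss)
      for (r in seq_len(replicates)) {
        out[[length(out) + 1L]] <- annealing_record(
          nominal_w_api = w, t_annealing = t_ann,
          tg_annealed = tg_true + rnorm(1, 0, noise_sigma))
      }
    }
    out
  })
}

#' CXB-in-copovidone-like synthetic ground truth
#'
#' A solubility curve with upper asymptote at the API melting point
#' (y0 = 160.9 degrees C, A = -1368.6, R0 = -7) giving a soluble fraction of
#' 0.33 at 25 degrees C, together with a BCKV composition curve showing a
#' modest positive deviation. Used as the standard end-to-end solubility
#' test case.
#'
#' @return List with `curve` (a [solubility_curve()]) and `bckv`
#'   (a [bckv_params()]).
#' @export
cxb_like_truth <- function() {
  list(curve = solubility_curve(y0 = 160.9, A = -1368.6, R0 = -7),
       bckv = bckv_params(tg_api = 56.8, tg_polymer = 107,
                          a0 = 25, a1 = 5, a2 = 0))
}

#' Write annealing records to CSV
#'
#' Columns: `nominal_w_api`, `t_annealing_C`, `tg_annealed_C`.
#'
#' @param records list of [annealing_record()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annealing_csv <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(nominal_w_api = r$nominal_w_api, t_annealing_C = r$t_annealing,
               tg_annealed_C = r$tg_annealed)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read annealing records from CSV
#'
#' @param path CSV with columns `nominal_w_api`, `t_annealing_C`,
#'   `tg_annealed_C`.
#' @return List of [annealing_record()] objects.
#' @export
read_annealing_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required_cols(df, c("nominal_w_api", "t_annealing_C", "tg_annealed_C"),
                "annealing CSV")
  lapply(seq_len(nrow(df)), function(i)
    annealing_record(df$nominal_w_api[i], df$t_annealing_C[i],
                     df$tg_annealed_C[i]))
}
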