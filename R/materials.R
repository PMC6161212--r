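## Domain types for substances, blends and the packaged reference data set.
## Temperatures are degrees Celsius throughout; Kelvin conversions happen at
## the point of use (Couchman-Karasz evaluation).

#' Physicochemical properties of a pure substance
#'
#' Container for the thermal constants of an API or polymer: glass-transition
#' temperature, heat-capacity step at Tg, and (for crystalline APIs) the
#' melting point.
#'
#' @param name substance name.
#' @param tg glass-transition temperature (degrees C).
#' @param delta_cp heat-capacity step at Tg, J/(g K); must be positive.
#' @param melting_point melting point (degrees C), `NA` for amorphous polymers.
#' @param molecular_weight molecular weight (g/mol), optional.
#' @param tg_note optional provenance note on how Tg was obtained.
#'
#' @return An object of class `material_props`.
#' @export
#' @examples
#' material_props("Celecoxib", tg = 56.8, delta_cp = 0.39, melting_point = 160.9)
material_props <- function(name, tg, delta_cp, melting_point = NA_real_,
                           molecular_weight = NA_real_, tg_note = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L)
  tg <- as.numeric(tg); delta_cp <- as.numeric(delta_cp)
  melting_point <- as.numeric(melting_point)
  if (!is.finite(tg)) stop("`tg` must be a finite temperature in degrees C")
  if (!is.finite(delta_cp) || delta_cp <= 0)
    stop("`delta_cp` must be > 0 J/(g K)")
  if (is.finite(melting_point) && tg >= melting_point)
    stop("`tg` must lie below `melting_point` when both are given")
  structure(
    list(name = name, tg = tg, delta_cp = delta_cp,
         melting_point = melting_point,
         molecular_weight = as.numeric(molecular_weight),
         tg_note = tg_note),
    class = "material_props")
}

#' @export
print.material_props <- function(x, ...) {
  cat(sprintf("<material_props> %s\n", x$name))
  cat(sprintf("  Tg        : %.1f degC\n", x$tg))
  cat(sprintf("  delta Cp  : %.2f J/(g K)\n", x$delta_cp))
  if (is.finite(x$melting_point))
    cat(sprintf("  Tm        : %.1f degC\n", x$melting_point))
  if (!is.na(x$tg_note)) cat(sprintf("  note      : %s\n", x$tg_note))
  invisible(x)
}

#' Specify an API/polymer blend by composition
#'
#' @param api,polymer `material_props` objects for the API and the polymer.
#' @param w_api weight fraction of API in the blend, in \[0, 1\].
#'
#' @return An object of class `blend_spec`.
#' @export
blend_spec <- function(api, polymer, w_api) {
  stopifnot(inherits(api, "material_props"), inherits(polymer, "material_props"))
  w_api <- as.numeric(w_api)
  if (!is.finite(w_api) || w_api < 0 || w_api > 1)
    stop("`w_api` must be a weight fraction in [0, 1]")
  structure(list(api = api, polymer = polymer, w_api = w_api),
            class = "blend_spec")
}

#' @export
print.blend_spec <- function(x, ...) {
  cat(sprintf("<blend_spec> %.0f%% %s in %s\n",
              100 * x$w_api, x$api$name, x$polymer$name))
  invisible(x)
}

#' A characterised blend: composition plus measured bulk properties
#'
#' @param blend a `blend_spec`.
#' @param tg_measured measured blend glass-transition temperature (degrees C).
#' @param density_powder,density_extrudate true densities (kg/m^3), optional.
#' @param cp_25,cp_150 specific heat capacities at 25 and 150 degrees C,
#'   J/(g K), optional.
#' @param label display label (defaults to "API x%").
#'
#' @return An object of class `blend_record`.
#' @export
blend_record <- function(blend, tg_measured, density_powder = NA_real_,
                         density_extrudate = NA_real_, cp_25 = NA_real_,
                         cp_150 = NA_real_, label = NULL) {
  stopifnot(inherits(blend, "blend_spec"))
  dens <- c(density_powder, density_extrudate)
  if (any(is.finite(dens) & dens <= 0)) stop("densities must be positive")
  if (is.finite(cp_25) && is.finite(cp_150) && cp_150 <= cp_25)
    stop("cp_150 must exceed cp_25 when both are present")
  if (is.null(label))
    label <- sprintf("%s %.0f%%", blend$api$name, 100 * blend$w_api)
  structure(
    list(label = label, blend = blend, tg_measured = as.numeric(tg_measured),
         density_powder = as.numeric(density_powder),
         density_extrudate = as.numeric(density_extrudate),
         cp_25 = as.numeric(cp_25), cp_150 = as.numeric(cp_150)),
    class = "blend_record")
}

#' @export
print.blend_record <- function(x, ...) {
  cat(sprintf("<blend_record> %s: Tg = %.1f degC\n", x$label, x$tg_measured))
  invisible(x)
}

#' Measured vs model-estimated zero-shear viscosity of a blend
#'
#' @param blend_label blend label.
#' @param tg blend glass-transition temperature (degrees C).
#' @param eta0_measured,eta0_estimated zero-shear viscosities (Pa s); either
#'   may be `NA` when not available.
#' @param temperature reference temperature of the viscosities (degrees C).
#'
#' @return An object of class `viscosity_pair`.
#' @export
viscosity_pair <- function(blend_label, tg, eta0_measured = NA_real_,
                           eta0_estimated = NA_real_, temperature = 150) {
  v <- c(eta0_measured, eta0_estimated)
  if (any(is.finite(v) & v <= 0)) stop("viscosities must be positive")
  structure(
    list(blend_label = blend_label, tg = as.numeric(tg),
         eta0_measured = as.numeric(eta0_measured),
         eta0_estimated = as.numeric(eta0_estimated),
         temperature = as.numeric(temperature)),
    class = "viscosity_pair")
}

required_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")))
}

num_col <- function(df, col, what) {
  raw <- df[[col]]
  x <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.na(raw) & raw != "" & is.na(x))
  if (length(bad))
    stop(sprintf("%s: non-numeric value in column '%s' at data row %d ('%s')",
                 what, col, bad[1], raw[bad[1]]))
  x
}

#' Read a materials CSV
#'
#' Expects a header with columns `name`, `tg_C`, `delta_cp_J_per_gK`,
#' `melting_point_C`, `molecular_weight` (an optional `tg_note` column is
#' honoured). Empty optional cells yield `NA` fields.
#'
#' @param path path to a UTF-8, comma-separated, dot-decimal CSV file.
#' @return A list of [material_props()] objects, named by substance.
#' @export
read_materials_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required_cols(df, c("name", "tg_C", "delta_cp_J_per_gK",
                      "melting_point_C", "molecular_weight"),
                "materials CSV")
  if (nrow(df) == 0L) return(setNames(list(), character()))
  note <- if ("tg_note" %in% names(df)) df$tg_note else rep(NA_character_, nrow(df))
  note[!is.na(note) & note == ""] <- NA_character_
  out <- lapply(seq_len(nrow(df)), function(i) {
    material_props(
      name = df$name[i],
      tg = num_col(df, "tg_C", "materials CSV")[i],
      delta_cp = num_col(df, "delta_cp_J_per_gK", "materials CSV")[i],
      melting_point = num_col(df, "melting_point_C", "materials CSV")[i],
      molecular_weight = num_col(df, "molecular_weight", "materials CSV")[i],
      tg_note = note[i])
  })
  setNames(out, df$name)
}

#' Write materials to CSV
#'
#' Inverse of [read_materials_csv()]; `read_materials_csv(write_materials_csv(x, p))`
#' round-trips.
#'
#' @param materials list of [material_props()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_materials_csv <- function(materials, path) {
  df <- data.frame(
    name = vapply(materials, `[[`, "", "name"),
    tg_C = vapply(materials, `[[`, 0, "tg"),
    delta_cp_J_per_gK = vapply(materials, `[[`, 0, "delta_cp"),
    melting_point_C = vapply(materials, `[[`, 0, "melting_point"),
    molecular_weight = vapply(materials, `[[`, 0, "molecular_weight"),
    tg_note = vapply(materials, `[[`, "", "tg_note"))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a blends CSV into blend records
#'
#' Expects columns `label`, `api_name`, `w_api`, `tg_C` and optionally
#' `density_powder_kg_m3`, `density_extrudate_kg_m3`, `cp_25_J_per_gK`,
#' `cp_150_J_per_gK`. Rows with `w_api = 0` describe the pure polymer.
#'
#' @param path path to the CSV.
#' @param materials named list of [material_props()] providing the components;
#'   must contain every `api_name` plus `polymer_name`.
#' @param polymer_name name of the polymer matrix entry in `materials`.
#' @return A named list of [blend_record()] objects.
#' @export
read_blends_csv <- function(path, materials, polymer_name = "Copovidone") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required_cols(df, c("label", "api_name", "w_api", "tg_C"), "blends CSV")
  polymer <- materials[[polymer_name]]
  if (is.null(polymer)) stop("polymer '", polymer_name, "' not found in materials")
  opt <- function(col, i) if (col %in% names(df)) num_col(df, col, "blends CSV")[i] else NA_real_
  out <- lapply(seq_len(nrow(df)), function(i) {
    w <- num_col(df, "w_api", "blends CSV")[i]
    api <- if (w > 0) {
      a <- materials[[df$api_name[i]]]
      if (is.null(a)) stop("API '", df$api_name[i], "' not found in materials")
      a
    } else polymer
    blend_record(
      blend = blend_spec(api, polymer, w),
      tg_measured = num_col(df, "tg_C", "blends CSV")[i],
      density_powder = opt("density_powder_kg_m3", i),
      density_extrudate = opt("density_extrudate_kg_m3", i),
      cp_25 = opt("cp_25_J_per_gK", i),
      cp_150 = opt("cp_150_J_per_gK", i),
      label = df$label[i])
  })
  setNames(out, df$label)
}

#' Load the packaged reference data set
#'
#' Returns the thermal constants of copovidone and the four model APIs
#' (celecoxib, loratadine, naproxen, praziquantel), the nine characterised
#' blend records (pure polymer plus 10% and 30% blends of each API), and the
#' five blends with both measured and model-estimated zero-shear viscosities
#' at 150 degrees C. These serve as canonical inputs for the Tg-viscosity
#' correlation and as worked-example data.
#'
#' @return A list with components `materials` (named list of
#'   [material_props()]), `blends` (named list of [blend_record()]) and
#'   `viscosity_pairs` (named list of [viscosity_pair()]).
#' @export
#' @examples
#' fx <- load_paper_fixtures()
#' fx$materials[["Copovidone"]]$tg
#' fx$blends[["NAP 30%"]]$tg_measured
load_paper_fixtures <- function() {
  ext <- function(f) system.file("extdata", f, package = "meltrheo", mustWork = TRUE)
  materials <- read_materials_csv(ext("materials.csv"))
  blends <- read_blends_csv(ext("blends.csv"), materials)
  vp <- read.csv(ext("viscosity_pairs.csv"), stringsAsFactors = FALSE)
  pairs <- lapply(seq_len(nrow(vp)), function(i) {
    viscosity_pair(vp$blend_label[i], vp$tg_C[i],
                   vp$eta0_measured_Pa_s[i], vp$eta0_estimated_Pa_s[i],
                   vp$temperature_C[i])
  })
  list(materials = materials, blends = blends,
       viscosity_pairs = setNames(pairs, vp$blend_label))
}
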