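# Configuration handling and the end-to-end pipeline: beam -> ionization
# dynamics -> effective scattering strengths (LF, HF, gated, double-Gaussian
# spatial) -> contrast report, with a manifest for reproducibility.

#' Read a pipeline configuration
#'
#' Configurations are JSON (see [fixture_configs()] for the schema).
#'
#' @param path Config file path.
#' @return Nested configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}

.KNOWN_KEYS <- c("atom", "beam_lf", "beam_hf", "spatial_alt", "gate_hf_fs",
                 "std", "seed")

#' Validate a pipeline configuration
#'
#' Returns a character vector of diagnostics, each naming the offending
#' field with a JSON-pointer-style path; an empty vector means valid.
#' Unknown top-level keys produce warnings (attribute `"warnings"`), not
#' errors, for forward compatibility.
#'
#' @param config Config list or path to a JSON config file.
#' @return Character vector of diagnostics (empty = valid), with a
#'   `warnings` attribute.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  diags <- character(0)
  warns <- character(0)
  need_pos <- function(x, path) {
    if (is.null(x) || !is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
      sprintf("%s: must be a positive number", path)
    } else character(0)
  }
  check_beam <- function(b, path) {
    d <- character(0)
    if (is.null(b)) return(sprintf("%s: missing", path))
    d <- c(d, need_pos(b$photon_energy_kev, paste0(path, "/photon_energy_kev")))
    d <- c(d, need_pos(b$pulse_energy_mj, paste0(path, "/pulse_energy_mj")))
    for (f in c("optics_transmission", "attenuation")) {
      v <- b[[f]]
      if (is.null(v) || !is.numeric(v) || v <= 0 || v > 1) {
        d <- c(d, sprintf("%s/%s: must be in (0, 1]", path, f))
      }
    }
    tp <- b$temporal
    if (is.null(tp) || is.null(tp$duration_fs) || !is.numeric(tp$duration_fs) ||
        tp$duration_fs <= 0) {
      d <- c(d, sprintf("%s/temporal/duration_fs: must be a positive number", path))
    }
    sp <- b$spatial
    if (is.null(sp) || is.null(sp$kind)) {
      d <- c(d, sprintf("%s/spatial/kind: missing", path))
    } else if (sp$kind %in% c("gaussian", "double_gaussian")) {
      fr <- vapply(sp$components, function(cc) cc$photon_fraction %||% NA_real_,
                   numeric(1))
      fw <- vapply(sp$components, function(cc) cc$fwhm_um %||% NA_real_, numeric(1))
      if (anyNA(fr) || abs(sum(fr) - 1) > 1e-9) {
        d <- c(d, sprintf("%s/spatial/components: photon fractions must sum to 1", path))
      }
      if (anyNA(fw) || any(fw <= 0)) {
        d <- c(d, sprintf("%s/spatial/components: fwhm_um must be > 0", path))
      }
    }
    d
  }
  if (is.null(config$atom) || is.null(config$atom$element)) {
    diags <- c(diags, "/atom/element: missing")
  }
  if (!is.null(config$atom$table) && !file.exists(config$atom$table)) {
    diags <- c(diags, sprintf("/atom/table: file not found (%s)", config$atom$table))
  }
  diags <- c(diags, check_beam(config$beam_lf, "/beam_lf"))
  diags <- c(diags, check_beam(config$beam_hf, "/beam_hf"))
  if (!is.null(config$gate_hf_fs)) {
    diags <- c(diags, need_pos(config$gate_hf_fs, "/gate_hf_fs"))
  }
  unknown <- setdiff(names(config), .KNOWN_KEYS)
  if (length(unknown)) {
    warns <- sprintf("unknown key '/%s' ignored", unknown)
  }
  structure(diags, warnings = warns)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a beam_model from a config block, with an optional spatial override.
.beam_from_config <- function(b, spatial_override = NULL) {
  sp_cfg <- spatial_override %||% b$spatial
  comps <- do.call(rbind, lapply(sp_cfg$components, function(cc) {
    data.frame(photon_fraction = cc$photon_fraction, fwhm = cc$fwhm_um)
  }))
  sp <- spatial_profile(sp_cfg$kind, components = comps)
  beam_model(b$photon_energy_kev, b$pulse_energy_mj, b$optics_transmission,
             b$attenuation, sp, temporal_profile(b$temporal$duration_fs))
}

.atom_from_config <- function(a) {
  pmf <- NULL
  if (!is.null(a$cascade)) {
    sizes <- seq(a$cascade$min, a$cascade$max)
    pmf <- stats::setNames(rep(1 / length(sizes), length(sizes)), sizes)
  }
  load_atom_model(table_path = a$table, element = a$element,
                  photon_energy = a$photon_energy_kev %||% 8.48,
                  cascade_pmf = pmf, q_floor = a$q_floor)
}

#' Run the ionization-contrast pipeline
#'
#' Executes beam arithmetic, charge-state dynamics and effective scattering
#' strengths for the configured low- and high-fluence conditions (point
#' mode), the gated high-fluence case, the alternative spatial profile when
#' configured, and Monte Carlo fluctuations when `std$n > 0`; writes
#' `report.json` and `manifest.json` to `out_dir`.
#'
#' @param config Path to a JSON configuration (see [fixture_configs()]), or
#'   an equivalent list.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the config seed.
#' @return The report list, invisibly.
#' @export
run_pipeline <- function(config, out_dir = tempfile("hip_run_"), seed = NULL) {
  config_path <- if (is.character(config)) config else NA_character_
  if (is.character(config)) config <- read_config(config)
  diags <- validate_config(config)
  if (length(diags)) {
    .stopf("invalid configuration:\n%s", paste(" -", diags, collapse = "\n"))
  }
  seed <- as.integer(seed %||% config$seed %||% 1)
  atom <- .atom_from_config(config$atom)
  beam_lf <- .beam_from_config(config$beam_lf)
  beam_hf <- .beam_from_config(config$beam_hf)

  report <- list(units = list(fluence = "photons um^-2", f_eff = "electrons",
                              dose = "Gy", energy = "keV"))
  report$beam <- list(
    photons_per_pulse_hf = photons_per_pulse(beam_hf),
    peak_fluence_hf = peak_fluence(beam_hf),
    peak_fluence_lf = peak_fluence(beam_lf),
    saturation_fluence = saturation_fluence(atom),
    fluence_ratio_hf_to_saturation =
      fluence_ratio_to_saturation(peak_fluence(beam_hf), saturation_fluence(atom)),
    average_dose_hf_Gy = average_dose(peak_fluence(beam_hf), beam_hf$photon_energy),
    average_dose_lf_Gy = average_dose(peak_fluence(beam_lf), beam_lf$photon_energy))

  lf <- effective_scattering_strength(atom, beam_lf, mode = "point")
  hf <- effective_scattering_strength(atom, beam_hf, mode = "point")
  report$point <- list(f_eff_lf = lf$f_eff, f_eff_hf = hf$f_eff,
                       contrast = ionization_contrast(lf, hf))
  if (!is.null(config$gate_hf_fs)) {
    report$point$gated_contrast <-
      gated_contrast(atom, beam_lf, beam_hf, config$gate_hf_fs, mode = "point")
  }
  if (!is.null(config$spatial_alt)) {
    blf <- .beam_from_config(config$beam_lf, config$spatial_alt)
    bhf <- .beam_from_config(config$beam_hf, config$spatial_alt)
    slf <- effective_scattering_strength(atom, blf, mode = "spatial")
    shf <- effective_scattering_strength(atom, bhf, mode = "spatial")
    report$spatial_alt <- list(f_eff_lf = slf$f_eff, f_eff_hf = shf$f_eff,
                               contrast = ionization_contrast(slf, shf))
    if (!is.null(config$gate_hf_fs)) {
      report$spatial_alt$gated_contrast <-
        gated_contrast(atom, blf, bhf, config$gate_hf_fs, mode = "spatial")
    }
  }
  n_std <- config$std$n %||% 0
  if (n_std > 0) {
    report$fluctuation <- list(
      std_lf = scattering_strength_std(atom, beam_lf, mode = "point",
                                       n = n_std, seed = seed)$std,
      std_hf = scattering_strength_std(atom, beam_hf, mode = "point",
                                       n = n_std, seed = seed + 1)$std,
      n = n_std)
  }

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(
    tool = "hipxfel", version = as.character(packageVersion("hipxfel")),
    config_path = config_path,
    config_md5 = if (!is.na(config_path)) unname(md5sum(config_path)) else
      unname(md5sum(textConnection2file(config))),
    seed = seed, outputs = report_path,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}

# Hash an in-memory config by serializing it to a temp file.
textConnection2file <- function(config) {
  tf <- tempfile(fileext = ".json")
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
  tf
}
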