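#' Reduced heavy-atom model
#'
#' An `atom_model` describes one element by its subshell structure (labels,
#' occupancies, binding energies), its total photoabsorption cross section at a
#' single reference photon energy, and a reduced charge-state ladder used for
#' ionization dynamics:
#'
#' * the per-charge cross section declines linearly from `sigma_total` at
#'   `q = 0` to zero at the charge floor `q_floor` (the charge at which the
#'   remaining binding energies exceed the photon energy, so photoionization
#'   ceases);
#' * every photoabsorption ejects the photoelectron plus an Auger-cascade
#'   burst of `A` additional electrons, `A` drawn from `cascade_pmf`;
#' * per charge state, forward scattering coefficients default to the bound
#'   electron count, `f0_q = Z - q`, with dispersion corrections
#'   `f' = f'' = 0` (a user-supplied `scattering_table` may override all
#'   three).
#'
#' `q_floor = Inf` is accepted and means "no floor": the cross section stays
#' at `sigma_total` for every charge state. This expresses the
#' constant-cross-section limit in which the absorption count is exactly
#' Poisson, used as an analytic oracle.
#'
#' @param element Element symbol, e.g. `"Gd"`.
#' @param Z Atomic number (total electrons when neutral).
#' @param subshells `data.frame` with columns `label`, `occupancy`,
#'   `binding_energy_keV`. Occupancies must sum to `Z`.
#' @param sigma_total Total photoabsorption cross section in barn at
#'   `photon_energy`.
#' @param photon_energy Reference photon energy in keV.
#' @param q_floor Charge state at which photoionization ceases (or `Inf`).
#' @param cascade_pmf Named numeric vector: probability mass over the number
#'   of *extra* electrons ejected per photoabsorption (names are the integer
#'   cascade sizes). Must be nonnegative and sum to 1.
#' @param scattering_table Optional `data.frame` with columns `q`, `f0`,
#'   `fprime`, `fdprime` overriding the default coefficients for the listed
#'   charge states.
#' @return An object of class `atom_model`.
#' @examples
#' gd <- load_atom_model(element = "Gd")
#' cross_section(gd, 0)
#' saturation_fluence(gd)
#' @export
atom_model <- function(element, Z, subshells, sigma_total, photon_energy,
                       q_floor, cascade_pmf, scattering_table = NULL) {
  if (!is.character(element) || length(element) != 1L) {
    .stopf("element must be a single symbol string")
  }
  if (!.is_number(Z) || Z != round(Z) || Z <= 0) .stopf("Z must be a positive integer")
  need <- c("label", "occupancy", "binding_energy_keV")
  if (!is.data.frame(subshells) || !all(need %in% names(subshells))) {
    .stopf("subshells must be a data.frame with columns %s", paste(need, collapse = ", "))
  }
  if (any(subshells$occupancy < 0)) .stopf("subshell occupancies must be >= 0")
  if (any(subshells$binding_energy_keV <= 0)) .stopf("binding energies must be > 0")
  if (sum(subshells$occupancy) != Z) {
    .stopf("subshell occupancies sum to %s, expected Z = %d",
           sum(subshells$occupancy), Z)
  }
  if (!.is_number(sigma_total) && !identical(sigma_total, NA_real_)) {
    .stopf("sigma_total must be a single number (barn)")
  }
  if (sigma_total <= 0) .stopf("sigma_total must be > 0")
  if (!.is_number(photon_energy) || photon_energy <= 0) {
    .stopf("photon_energy must be > 0 (keV)")
  }
  if (!(is.infinite(q_floor) && q_floor > 0)) {
    if (!.is_number(q_floor) || q_floor != round(q_floor) ||
        q_floor < 0 || q_floor > Z) {
      .stopf("q_floor must be an integer in [0, Z] or Inf")
    }
  }
  sizes <- suppressWarnings(as.integer(names(cascade_pmf)))
  if (length(cascade_pmf) == 0L || anyNA(sizes)) {
    .stopf("cascade_pmf must be a named vector with integer cascade sizes as names")
  }
  if (any(cascade_pmf < 0) || abs(sum(cascade_pmf) - 1) > 1e-9) {
    .stopf("cascade_pmf must be nonnegative and sum to 1")
  }
  if (any(sizes < 0) || any(sizes > Z)) .stopf("cascade sizes must lie in [0, Z]")
  if (!is.null(scattering_table)) {
    st_need <- c("q", "f0", "fprime", "fdprime")
    if (!is.data.frame(scattering_table) || !all(st_need %in% names(scattering_table))) {
      .stopf("scattering_table needs columns %s", paste(st_need, collapse = ", "))
    }
  }
  structure(
    list(element = element, Z = as.integer(Z), subshells = subshells,
         sigma_total = sigma_total, photon_energy = photon_energy,
         q_floor = q_floor,
         cascade_pmf = stats::setNames(as.numeric(cascade_pmf), sizes),
         scattering_table = scattering_table),
    class = "atom_model")
}

#' @export
print.atom_model <- function(x, ...) {
  cat(sprintf("<atom_model> %s (Z = %d)\n", x$element, x$Z))
  cat(sprintf("  sigma_total: %.4g barn at %.3g keV; q_floor: %s\n",
              x$sigma_total, x$photon_energy, format(x$q_floor)))
  cat(sprintf("  cascade sizes: {%s}\n", paste(names(x$cascade_pmf), collapse = ",")))
  invisible(x)
}

#' Load an atom model from a shipped or user CSV table
#'
#' Reads the subshell/cross-section table (see
#' `system.file("extdata", "atomic_subshells.csv", package = "hipxfel")` for
#' the shipped format: per-subshell rows plus one `(total)` row per element
#' carrying `sigma_total_barn`, `reference_energy_keV` and `q_floor`) and
#' assembles a validated [atom_model()].
#'
#' The default cascade distribution is the frozen calibration for Gd:
#' uniform on \{4..12\} extra electrons per photoabsorption (so each event
#' removes 5-13 electrons in total, mean 9). For other elements the default
#' is a single Auger electron (`A = 1`).
#'
#' @param table_path Path to the CSV table; default is the shipped table.
#' @param element Element symbol to load.
#' @param photon_energy Photon energy in keV; must match the table's
#'   reference energy to within 1e-6 keV.
#' @param cascade_pmf Optional override of the cascade distribution.
#' @param q_floor Optional override of the charge floor.
#' @return An [atom_model()].
#' @export
load_atom_model <- function(table_path = NULL, element, photon_energy = 8.48,
                            cascade_pmf = NULL, q_floor = NULL) {
  if (is.null(table_path)) {
    table_path <- system.file("extdata", "atomic_subshells.csv", package = "hipxfel")
  }
  if (!file.exists(table_path)) .stopf("atom table not found: %s", table_path)
  tab <- tryCatch(
    read.csv(table_path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) .stopf("malformed atom table %s: %s", table_path, conditionMessage(e)))
  need <- c("element", "Z", "subshell", "occupancy", "binding_energy_keV",
            "sigma_total_barn", "reference_energy_keV", "q_floor")
  if (!all(need %in% names(tab))) {
    .stopf("atom table %s lacks columns: %s", table_path,
           paste(setdiff(need, names(tab)), collapse = ", "))
  }
  rows <- tab[tab$element == element, , drop = FALSE]
  if (nrow(rows) == 0L) {
    .stopf("element '%s' not present in %s", element, table_path)
  }
  tot <- rows[rows$subshell == "(total)", , drop = FALSE]
  sub <- rows[rows$subshell != "(total)", , drop = FALSE]
  if (nrow(tot) != 1L) {
    .stopf("atom table %s: element %s needs exactly one '(total)' row (found %d)",
           table_path, element, nrow(tot))
  }
  for (i in seq_len(nrow(sub))) {
    if (is.na(sub$occupancy[i]) || is.na(sub$binding_energy_keV[i])) {
      .stopf("atom table %s: row %d (subshell %s) has missing values",
             table_path, i, sub$subshell[i])
    }
  }
  if (abs(tot$reference_energy_keV - photon_energy) > 1e-6) {
    .stopf("table reference energy %.4g keV does not match requested %.4g keV",
           tot$reference_energy_keV, photon_energy)
  }
  if (is.null(q_floor)) q_floor <- tot$q_floor
  if (is.null(cascade_pmf)) {
    cascade_pmf <- if (identical(element, "Gd")) {
      stats::setNames(rep(1 / 9, 9), 4:12)
    } else {
      stats::setNames(1, 1)
    }
  }
  atom_model(
    element = element, Z = sub$Z[1],
    subshells = data.frame(label = sub$subshell,
                           occupancy = sub$occupancy,
                           binding_energy_keV = sub$binding_energy_keV,
                           stringsAsFactors = FALSE),
    sigma_total = tot$sigma_total_barn, photon_energy = photon_energy,
    q_floor = q_floor, cascade_pmf = cascade_pmf)
}

# Common spectroscopic aliases accepted by photoelectron_energy().
.SUBSHELL_ALIASES <- c("1s" = "K", "2s" = "LI", "2p1/2" = "LII", "2p3/2" = "LIII")

#' Photoelectron energy for a subshell
#'
#' Energy of the photoelectron ejected from `subshell` at `photon_energy`,
#' i.e. `photon_energy - binding_energy`. Returns `NULL` when the subshell is
#' inaccessible (binding energy above the photon energy).
#'
#' @param atom An [atom_model()].
#' @param subshell Subshell label as in the table (aliases `"1s"` for `K`
#'   etc. are accepted).
#' @param photon_energy Photon energy in keV.
#' @return Photoelectron energy in keV, or `NULL`.
#' @examples
#' c_atom <- load_atom_model(element = "C")
#' photoelectron_energy(c_atom, "1s", 8.48)   # ~8.2 keV
#' @export
photoelectron_energy <- function(atom, subshell, photon_energy) {
  stopifnot(inherits(atom, "atom_model"))
  lab <- subshell
  if (!(lab %in% atom$subshells$label) && lab %in% names(.SUBSHELL_ALIASES)) {
    lab <- .SUBSHELL_ALIASES[[lab]]
  }
  i <- match(lab, atom$subshells$label)
  if (is.na(i)) .stopf("unknown subshell '%s' for %s", subshell, atom$element)
  e <- photon_energy - atom$subshells$binding_energy_keV[i]
  if (e > 0) e else NULL
}

#' Per-charge photoabsorption cross section of the reduced ladder
#'
#' `sigma(q) = sigma_total * max(0, (q_floor - q) / q_floor)`: linear decline
#' to exactly zero at the charge floor. With `q_floor = Inf` the cross
#' section is constant (`sigma_total` for all `q`).
#'
#' @param atom An [atom_model()].
#' @param q Charge state(s), integers in `[0, Z]`.
#' @return Cross section(s) in barn.
#' @export
cross_section <- function(atom, q) {
  stopifnot(inherits(atom, "atom_model"))
  if (any(q < 0 | q > atom$Z)) .stopf("charge q out of range [0, %d]", atom$Z)
  if (is.infinite(atom$q_floor)) return(rep(atom$sigma_total, length(q)))
  atom$sigma_total * pmax(0, (atom$q_floor - q) / atom$q_floor)
}

#' Saturation fluence
#'
#' Fluence at which every atom absorbs one photon on average: the reciprocal
#' of the neutral-atom cross section, expressed in photons per square
#' micrometre (1 barn = 1e-16 um^2).
#'
#' @param atom An [atom_model()].
#' @return Saturation fluence in photons um^-2.
#' @export
saturation_fluence <- function(atom) {
  stopifnot(inherits(atom, "atom_model"))
  if (atom$sigma_total <= 0) .stopf("sigma_total must be positive")
  1 / (atom$sigma_total * .UM2_PER_BARN)
}
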