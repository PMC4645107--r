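# Effective scattering strengths: population-weighted dynamical form factors
# averaged over the temporal pulse shape and (in spatial mode) over the
# photon-weighted fluence distribution of the focus, with optional
# Bragg-termination gating.

#' Scattering query
#'
#' Momentum transfer and photon energy at which form factors are evaluated.
#' With the default per-charge coefficients (`f0_q = Z - q`, no dispersion)
#' only the forward direction `Q = 0` is meaningful; `Q`-dependence enters
#' only through a user-supplied scattering table.
#'
#' @param Q Momentum-transfer magnitude in 1/Angstrom (0 = forward).
#' @param photon_energy keV.
#' @return Object of class `scattering_query`.
#' @export
scattering_query <- function(Q = 0, photon_energy = 8.48) {
  if (!.is_number(Q) || Q < 0) .stopf("Q must be >= 0")
  if (!.is_number(photon_energy) || photon_energy <= 0) .stopf("photon_energy must be > 0")
  structure(list(Q = Q, photon_energy = photon_energy), class = "scattering_query")
}

# Complex per-charge form factors f0_q + f'_q + i f''_q for q = 0..Z.
.charge_form_factors <- function(atom, query) {
  f <- complex(real = atom$Z - 0:atom$Z, imaginary = 0)
  st <- atom$scattering_table
  if (!is.null(st)) {
    idx <- st$q + 1L
    f[idx] <- complex(real = st$f0 + st$fprime, imaginary = st$fdprime)
  }
  f
}

#' Dynamical form factor along a trajectory
#'
#' `f(t) = sum_q P_q(t) [f0_q(Q) + f'_q(w) + i f''_q(w)]`: the
#' population-weighted atomic form factor, which decays during the pulse as
#' the atom ionizes.
#'
#' @param atom An [atom_model()].
#' @param traj A `charge_trajectory` from [evolve_populations()].
#' @param query A [scattering_query()].
#' @return Object of class `dynamical_form_factor` with `times` (fs) and
#'   complex `values`.
#' @export
dynamical_form_factor <- function(atom, traj, query = scattering_query()) {
  stopifnot(inherits(atom, "atom_model"), inherits(traj, "charge_trajectory"))
  pop_support <- which(colSums(traj$populations) > 0) - 1L
  st <- atom$scattering_table
  if (!is.null(st)) {
    missing_q <- setdiff(pop_support, st$q)
    # default coefficients cover all q, so a partial table is only an error
    # if the user supplied one intending full coverage via attribute
    if (isTRUE(attr(st, "exclusive")) && length(missing_q)) {
      .stopf("scattering table lacks coefficients for populated charge states: %s",
             paste(missing_q, collapse = ", "))
    }
  }
  fq <- .charge_form_factors(atom, query)
  vals <- as.vector(traj$populations %*% fq)
  structure(list(times = traj$times, values = vals, query = query,
                 element = atom$element), class = "dynamical_form_factor")
}

# Trapezoid time-average of a sampled curve over [0, gate], inserting an
# interpolated sample exactly at the gate. Under a flat-top profile g(t) is
# constant, so the signal-weighted average is the plain time average.
.time_average <- function(times, values, gate) {
  if (gate >= max(times) - 1e-12) {
    x <- times; y <- values
  } else {
    keep <- times < gate
    x <- c(times[keep], gate)
    y <- c(values[keep], approx(times, values, xout = gate)$y)
  }
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2) / (max(x) - min(x))
}

# Resolve a requested gate against the pulse duration; warn-and-clip beyond.
.resolve_gate <- function(gate, temporal) {
  warn <- NULL
  if (is.null(gate)) gate <- temporal$duration
  if (gate > temporal$duration) {
    warn <- sprintf("gate %.3g fs exceeds pulse duration %.3g fs; clipped",
                    gate, temporal$duration)
    warning(warn, call. = FALSE)
    gate <- temporal$duration
  }
  if (gate <= 0) .stopf("gate must be > 0 fs")
  list(gate = gate, warning = warn)
}

#' Effective scattering strength
#'
#' The spatio-temporally weighted average of the real part of the dynamical
#' form factor:
#' `f_eff = [sum_i w_i int g(t) Re f_i(t) dt] / [sum_i w_i int g(t) dt]`,
#' where the fluence nodes `F_i` with photon weights `w_i` come from
#' [fluence_quadrature()] in `"spatial"` mode, or collapse to the single peak
#' fluence in `"point"` mode. With `gate` set, both integrals are restricted
#' to `[0, gate]` (Bragg termination: signal is only recorded while lattice
#' coherence persists).
#'
#' @param atom An [atom_model()].
#' @param beam A [beam_model()].
#' @param query A [scattering_query()].
#' @param mode `"point"` (hot-spot peak fluence, temporal weighting only) or
#'   `"spatial"` (photon-weighted average over the focus).
#' @param gate Optional gate time in fs; requests beyond the pulse duration
#'   are clipped with a warning.
#' @param n_nodes Quadrature nodes per spatial component.
#' @param dt Master-equation time step in fs.
#' @return Object of class `eff_scattering`: `f_eff` (electrons), `std`
#'   (`NA`; see [scattering_strength_std()]), `mode`, `gate_time`, and
#'   provenance (`nodes`, `warnings`).
#' @examples
#' gd <- load_atom_model(element = "Gd")
#' lf <- beam_model(8.48, 1.6, 0.3, 0.0173,
#'                  spatial_profile("gaussian", fwhm = 0.2), temporal_profile(40))
#' effective_scattering_strength(gd, lf)$f_eff   # ~57-58 electrons
#' @export
effective_scattering_strength <- function(atom, beam, query = scattering_query(),
                                          mode = c("point", "spatial"),
                                          gate = NULL, n_nodes = 32, dt = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(atom, "atom_model"), inherits(beam, "beam_model"))
  g <- .resolve_gate(gate, beam$temporal)
  n_ph <- photons_per_pulse(beam)
  feff_at <- function(F) {
    tr <- evolve_populations(atom, F, beam$temporal, dt = dt)
    ff <- dynamical_form_factor(atom, tr, query)
    .time_average(ff$times, Re(ff$values), g$gate)
  }
  if (mode == "point") {
    Fpk <- peak_fluence(beam)
    f_eff <- feff_at(Fpk)
    nodes <- list(nodes = Fpk, weights = 1)
  } else {
    quad <- fluence_quadrature(beam$spatial, n_ph, n_nodes = n_nodes)
    vals <- vapply(quad$nodes, feff_at, numeric(1))
    f_eff <- sum(quad$weights * vals)
    nodes <- quad
  }
  structure(list(f_eff = f_eff, std = NA_real_, mode = mode,
                 gate_time = if (is.null(gate)) NULL else g$gate,
                 query = query, element = atom$element,
                 nodes = nodes, warnings = g$warning),
            class = "eff_scattering")
}

#' @export
print.eff_scattering <- function(x, ...) {
  cat(sprintf("<eff_scattering> %s: f_eff = %.2f e- (%s mode%s)\n",
              x$element, x$f_eff, x$mode,
              if (is.null(x$gate_time)) "" else sprintf(", gated at %.3g fs", x$gate_time)))
  invisible(x)
}

#' Fluctuation of the effective scattering strength
#'
#' Standard deviation, over Monte Carlo realizations of the ionization jump
#' process (and over the photon-weighted fluence distribution in `"spatial"`
#' mode), of the per-realization signal-weighted time-averaged forward
#' scattering strength. The mean of the same sample estimates
#' [effective_scattering_strength()].
#'
#' @inheritParams effective_scattering_strength
#' @param n Number of Monte Carlo realizations (>= 100).
#' @param seed Integer seed (same seed, same value).
#' @param rel_precision Target relative precision of the std estimate; a
#'   `precision` note is recorded in the result when `n` is too small for it.
#' @return Object of class `scattering_fluctuation` with `std`, `mean`, `n`,
#'   `seed`, `mode`, `gate_time` and any `notes`.
#' @export
scattering_strength_std <- function(atom, beam, query = scattering_query(),
                                    mode = c("point", "spatial"), gate = NULL,
                                    n = 10000, seed = 1, rel_precision = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(atom, "atom_model"), inherits(beam, "beam_model"))
  if (!.is_number(n) || n < 100) .stopf("n must be >= 100")
  n <- as.integer(n)
  g <- .resolve_gate(gate, beam$temporal)
  samples <- if (mode == "point") {
    ens <- simulate_monte_carlo(atom, peak_fluence(beam), beam$temporal, n, seed)
    .mc_time_averaged_bound(ens, g$gate)
  } else {
    # photon-weighted fluence sampling: pick a component by photon fraction,
    # then a fluence uniform on (0, F_peak_c]; one trajectory per draw
    comps <- beam$spatial$components
    peaks <- component_peak_fluences(photons_per_pulse(beam), beam$spatial)
    .with_seed(seed, {
      ci <- sample.int(length(peaks), n, replace = TRUE, prob = comps$photon_fraction)
      Fs <- runif(n) * peaks[ci]
      vapply(Fs, function(F) {
        ens <- .one_realization(atom, F, beam$temporal)
        .mc_path_average(ens, atom$Z, g$gate)
      }, numeric(1))
    })
  }
  notes <- character(0)
  # relative standard error of a normal-ish sd estimate ~ 1/sqrt(2(n-1))
  if (1 / sqrt(2 * (n - 1)) > rel_precision) {
    notes <- sprintf("n = %d gives sd relative precision ~%.3f, above target %.3f",
                     n, 1 / sqrt(2 * (n - 1)), rel_precision)
  }
  structure(list(std = sd(samples), mean = mean(samples), n = n, seed = seed,
                 mode = mode, gate_time = if (is.null(gate)) NULL else g$gate,
                 notes = c(notes, g$warning)),
            class = "scattering_fluctuation")
}

# One event-driven realization (times and post-event charges), no seeding.
.one_realization <- function(atom, fluence, temporal) {
  t <- 0; q <- 0L
  ev_t <- numeric(0); ev_q <- integer(0)
  repeat {
    r <- cross_section(atom, q) * .UM2_PER_BARN * fluence / temporal$duration
    if (r <= 0) break
    t <- t + rexp(1L, r)
    if (t >= temporal$duration) break
    tg <- .jump_targets(atom, q)
    q <- if (length(tg$q) == 1L) tg$q else tg$q[sample.int(length(tg$q), 1L, prob = tg$p)]
    ev_t <- c(ev_t, t); ev_q <- c(ev_q, q)
  }
  list(t = ev_t, q = ev_q)
}

.mc_path_average <- function(path, Z, gate) {
  keep <- path$t < gate
  bounds <- c(0, path$t[keep], gate)
  qpath <- c(0L, path$q[keep])
  Z - sum(qpath * diff(bounds)) / gate
}

#' @export
print.scattering_fluctuation <- function(x, ...) {
  cat(sprintf("<scattering_fluctuation> std = %.2f e- (mean %.2f, n = %d, %s mode)\n",
              x$std, x$mean, x$n, x$mode))
  invisible(x)
}

#' Ionization contrast between two conditions
#'
#' Difference of effective scattering strengths, `lf$f_eff - hf$f_eff`. Both
#' results must have been computed under the same mode and scattering query.
#'
#' @param lf,hf `eff_scattering` results for the low- and high-fluence
#'   conditions.
#' @return Contrast in electrons.
#' @export
ionization_contrast <- function(lf, hf) {
  stopifnot(inherits(lf, "eff_scattering"), inherits(hf, "eff_scattering"))
  if (!identical(lf$mode, hf$mode)) {
    .stopf("cannot compare f_eff computed in '%s' and '%s' modes", lf$mode, hf$mode)
  }
  if (!isTRUE(all.equal(lf$query, hf$query))) {
    .stopf("cannot compare f_eff computed for different scattering queries")
  }
  lf$f_eff - hf$f_eff
}

#' Gated contrast (Bragg termination on the high-fluence arm only)
#'
#' At high fluence the Bragg signal terminates early (lattice disorder), so
#' only the first `gate_hf` fs of the pulse are averaged; at low fluence the
#' signal persists for the whole pulse and no gate is applied.
#'
#' @param atom An [atom_model()].
#' @param beam_lf,beam_hf Beam models for the two conditions.
#' @param gate_hf Gate time in fs applied to the high-fluence computation.
#' @param mode,query,n_nodes,dt Passed to [effective_scattering_strength()].
#' @return Contrast in electrons.
#' @export
gated_contrast <- function(atom, beam_lf, beam_hf, gate_hf,
                           mode = c("point", "spatial"),
                           query = scattering_query(), n_nodes = 32, dt = 0.05) {
  mode <- match.arg(mode)
  lf <- effective_scattering_strength(atom, beam_lf, query, mode = mode,
                                      gate = NULL, n_nodes = n_nodes, dt = dt)
  hf <- effective_scattering_strength(atom, beam_hf, query, mode = mode,
                                      gate = gate_hf, n_nodes = n_nodes, dt = dt)
  ionization_contrast(lf, hf)
}
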