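#' Spatial beam profile
#'
#' Describes the transverse fluence distribution at the interaction region.
#' `gaussian` is a single 2-D Gaussian; `double_gaussian` is a concentric
#' mixture (the classic "hot spot plus pedestal" XFEL focus); `point`
#' evaluates everything at a single fluence (no spatial averaging);
#' `uniform` is a flat profile at one effective fluence.
#'
#' @param kind One of `"point"`, `"gaussian"`, `"double_gaussian"`, `"uniform"`.
#' @param components For (double-)Gaussian kinds, a data.frame or list of
#'   lists with `photon_fraction` and `fwhm` (micrometres). Fractions must
#'   sum to 1.
#' @return Object of class `spatial_profile`.
#' @examples
#' spatial_profile("gaussian", fwhm = 0.2)
#' spatial_profile("double_gaussian",
#'   components = data.frame(photon_fraction = c(0.5, 0.5), fwhm = c(0.2, 0.6)))
#' @param fwhm Convenience shortcut for a single-Gaussian profile.
#' @export
spatial_profile <- function(kind = c("gaussian", "double_gaussian", "point", "uniform"),
                            components = NULL, fwhm = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("gaussian", "double_gaussian")) {
    if (is.null(components)) {
      if (is.null(fwhm)) .stopf("a Gaussian profile needs `components` or `fwhm`")
      components <- data.frame(photon_fraction = 1, fwhm = fwhm)
    }
    if (is.list(components) && !is.data.frame(components)) {
      components <- do.call(rbind, lapply(components, as.data.frame))
    }
    if (!all(c("photon_fraction", "fwhm") %in% names(components))) {
      .stopf("components need photon_fraction and fwhm columns")
    }
    if (any(components$fwhm <= 0)) .stopf("all fwhm must be > 0")
    if (abs(sum(components$photon_fraction) - 1) > 1e-9) {
      .stopf("photon fractions must sum to 1")
    }
    if (kind == "gaussian" && nrow(components) != 1L) {
      .stopf("kind 'gaussian' takes exactly one component")
    }
  } else {
    components <- NULL
  }
  structure(list(kind = kind, components = components), class = "spatial_profile")
}

#' Temporal pulse profile
#'
#' Only the flat-top shape is modelled: instantaneous flux is constant over
#' `duration` and the shape integrates to 1. `gate_time` expresses Bragg
#' termination: the diffraction measurement only integrates signal over
#' `[0, gate_time]` because lattice disorder extinguishes coherent Bragg
#' scattering later in the pulse.
#'
#' @param duration Pulse duration in fs.
#' @param gate_time Optional gate in fs, in `(0, duration]`.
#' @return Object of class `temporal_profile`.
#' @export
temporal_profile <- function(duration, gate_time = NULL) {
  if (!.is_number(duration) || duration <= 0) .stopf("duration must be > 0 fs")
  if (!is.null(gate_time)) {
    if (!.is_number(gate_time) || gate_time <= 0 || gate_time > duration) {
      .stopf("gate_time must lie in (0, duration]")
    }
  }
  structure(list(kind = "flat_top", duration = duration, gate_time = gate_time),
            class = "temporal_profile")
}

#' Beam model
#'
#' Bundles the pulse parameters measured upstream (photon energy, pulse
#' energy, focusing-optics transmission, attenuation) with the spatial and
#' temporal profiles at the interaction region.
#'
#' @param photon_energy keV.
#' @param pulse_energy mJ (as delivered by the machine, before optics).
#' @param optics_transmission Fraction of pulse energy surviving the
#'   focusing optics, in (0, 1].
#' @param attenuation Deliberate attenuation fraction in (0, 1] (1 =
#'   unattenuated).
#' @param spatial A [spatial_profile()].
#' @param temporal A [temporal_profile()].
#' @return Object of class `beam_model`.
#' @examples
#' beam <- beam_model(8.48, 1.6, 0.30, 1.0,
#'                    spatial_profile("gaussian", fwhm = 0.2),
#'                    temporal_profile(40))
#' photons_per_pulse(beam)
#' @export
beam_model <- function(photon_energy, pulse_energy, optics_transmission,
                       attenuation, spatial, temporal) {
  if (!.is_number(photon_energy) || photon_energy <= 0) .stopf("photon_energy must be > 0")
  if (!.is_number(pulse_energy) || pulse_energy <= 0) .stopf("pulse_energy must be > 0")
  if (!.is_number(optics_transmission) || optics_transmission <= 0 ||
      optics_transmission > 1) .stopf("optics_transmission must be in (0, 1]")
  if (!.is_number(attenuation) || attenuation <= 0 || attenuation > 1) {
    .stopf("attenuation must be in (0, 1]")
  }
  stopifnot(inherits(spatial, "spatial_profile"), inherits(temporal, "temporal_profile"))
  structure(list(photon_energy = photon_energy, pulse_energy = pulse_energy,
                 optics_transmission = optics_transmission,
                 attenuation = attenuation, spatial = spatial, temporal = temporal),
            class = "beam_model")
}

#' @export
print.beam_model <- function(x, ...) {
  cat(sprintf("<beam_model> %.3g keV, %.3g mJ, optics %.3g, attenuation %.4g\n",
              x$photon_energy, x$pulse_energy, x$optics_transmission, x$attenuation))
  cat(sprintf("  spatial: %s; temporal: flat-top %.3g fs\n",
              x$spatial$kind, x$temporal$duration))
  invisible(x)
}

#' Photons delivered per pulse at the interaction region
#'
#' `pulse_energy * attenuation * optics_transmission / photon_energy`.
#'
#' @param beam A [beam_model()].
#' @return Photon count per pulse.
#' @export
photons_per_pulse <- function(beam) {
  stopifnot(inherits(beam, "beam_model"))
  beam$pulse_energy * 1e-3 * beam$attenuation * beam$optics_transmission /
    (beam$photon_energy * .J_PER_KEV)
}

#' Peak fluence of a (double-)Gaussian focus
#'
#' For a 2-D Gaussian carrying `N` photons, the peak fluence is
#' `N / (2 pi sigma^2)` with `sigma = FWHM / sqrt(8 ln 2)`. For a
#' double Gaussian the component peaks add at the common centre.
#'
#' @param beam A [beam_model()], or a photon count when `spatial` is given.
#' @param spatial Optional [spatial_profile()] when `beam` is a photon count.
#' @return Peak fluence in photons um^-2.
#' @export
peak_fluence <- function(beam, spatial = NULL) {
  if (inherits(beam, "beam_model")) {
    n <- photons_per_pulse(beam)
    spatial <- beam$spatial
  } else {
    n <- beam
    if (is.null(spatial)) .stopf("supply a spatial_profile with a raw photon count")
  }
  if (!spatial$kind %in% c("gaussian", "double_gaussian")) {
    .stopf("peak_fluence is defined for Gaussian profiles only (got '%s')", spatial$kind)
  }
  sum(component_peak_fluences(n, spatial))
}

# Per-component peak fluences (photons um^-2) for a Gaussian mixture.
component_peak_fluences <- function(n_photons, spatial) {
  sig <- .fwhm_to_sigma(spatial$components$fwhm)
  n_photons * spatial$components$photon_fraction / (2 * pi * sig^2)
}

#' Photon-weighted fluence quadrature
#'
#' Discretizes the fluence distribution seen by the *photons* (equivalently,
#' by the scattering signal) of a focus. For a single 2-D Gaussian the
#' photon-weighted fluence is exactly uniform on `(0, F_peak]`; for a double
#' Gaussian it is the photon-fraction-weighted mixture of two such uniforms;
#' a `point` profile yields one node at the peak fluence.
#'
#' Nodes are midpoints of equal-probability slices, so weights are equal
#' within each component and sum to 1 overall.
#'
#' @param spatial A [spatial_profile()].
#' @param n_photons Photons per pulse feeding the profile.
#' @param n_nodes Number of nodes per component (>= 2 for distributed
#'   profiles).
#' @return List with `nodes` (fluences, photons um^-2) and `weights`
#'   (photon-weight fractions), class `fluence_quadrature`.
#' @export
fluence_quadrature <- function(spatial, n_photons, n_nodes = 32) {
  stopifnot(inherits(spatial, "spatial_profile"))
  if (spatial$kind == "point") {
    .stopf("a point profile has no fluence distribution; use the peak fluence directly")
  }
  if (spatial$kind == "uniform") {
    .stopf("uniform profiles carry a single effective fluence; no quadrature needed")
  }
  if (n_nodes < 2) .stopf("n_nodes must be >= 2 for a distributed profile")
  peaks <- component_peak_fluences(n_photons, spatial)
  fr <- spatial$components$photon_fraction
  nodes <- weights <- numeric(0)
  comp <- integer(0)
  for (i in seq_along(peaks)) {
    nodes <- c(nodes, (seq_len(n_nodes) - 0.5) / n_nodes * peaks[i])
    weights <- c(weights, rep(fr[i] / n_nodes, n_nodes))
    comp <- c(comp, rep(i, n_nodes))
  }
  structure(list(nodes = nodes, weights = weights, component = comp,
                 peaks = peaks), class = "fluence_quadrature")
}

#' Average absorbed dose estimate
#'
#' `dose = <fluence> * photon_energy * (mu_en / rho)`, converted to gray.
#' The averaging convention decides which fluence represents "the" dose of a
#' Gaussian focus when a *peak* fluence is supplied:
#'
#' * `"fwhm_disc"` (default): mean fluence over the disc of radius FWHM
#'   around the focus centre, i.e. `peak * 2 sigma^2 / R^2 * (1 - exp(-R^2 /
#'   (2 sigma^2)))` with `R = FWHM` (factor 0.3385);
#' * `"photon_mean"`: photon-weighted mean fluence, `peak / 2`;
#' * `"point"`: the supplied fluence as-is.
#'
#' The absolute scale is an estimate; only ratios between conditions are
#' convention-free (dose is linear in fluence).
#'
#' @param fluence Fluence in photons um^-2 (peak fluence under the disc and
#'   photon-mean conventions).
#' @param photon_energy keV.
#' @param medium Row name in the shipped mass-attenuation table
#'   (`"protein"`, `"water"`, `"Si"`), or a list with `mu_en_over_rho_cm2_g`.
#' @param convention Averaging convention, see Details.
#' @return Dose in Gy.
#' @export
average_dose <- function(fluence, photon_energy, medium = "protein",
                         convention = c("fwhm_disc", "photon_mean", "point")) {
  convention <- match.arg(convention)
  if (any(fluence < 0)) .stopf("fluence must be >= 0")
  mu_en <- if (is.list(medium)) {
    medium$mu_en_over_rho_cm2_g
  } else {
    .lookup_mu(medium, photon_energy)$mu_en_over_rho_cm2_g
  }
  if (is.null(mu_en) || is.na(mu_en)) .stopf("no mu_en/rho coefficient for this medium")
  factor <- switch(convention,
    fwhm_disc = {
      # mean of a 2-D Gaussian over the disc r <= FWHM, relative to the peak
      r2s2 <- .FWHM_PER_SIGMA^2 / 2            # R^2 / (2 sigma^2) at R = FWHM
      (1 - exp(-r2s2)) / r2s2
    },
    photon_mean = 0.5,
    point = 1)
  # photons/um^2 -> photons/m^2 (1e12); cm^2/g -> m^2/kg (1e-1)
  fluence * factor * 1e12 * photon_energy * .J_PER_KEV * mu_en * 1e-1
}

# Log-log interpolation of the shipped mu/rho table at a photon energy.
.lookup_mu <- function(medium, photon_energy) {
  path <- system.file("extdata", "mass_attenuation.csv", package = "hipxfel")
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  rows <- tab[tab$medium == medium, , drop = FALSE]
  if (nrow(rows) == 0L) .stopf("medium '%s' not in the mass-attenuation table", medium)
  if (photon_energy < min(rows$energy_keV) || photon_energy > max(rows$energy_keV)) {
    .stopf("photon energy %.3g keV outside the tabulated range for %s",
           photon_energy, medium)
  }
  interp <- function(y) {
    exp(approx(log(rows$energy_keV), log(y), xout = log(photon_energy))$y)
  }
  list(mu_over_rho_cm2_g = interp(rows$mu_over_rho_cm2_g),
       mu_en_over_rho_cm2_g = interp(rows$mu_en_over_rho_cm2_g),
       density_g_cm3 = rows$density_g_cm3[1])
}

#' Transmission of a flat attenuator behind the sample
#'
#' A flat slab normal to the direct beam intercepts scattered rays over a
#' path `thickness / cos(two_theta)`, so
#' `T = exp(-mu * thickness / cos(two_theta))`. The correction factor applied
#' to a measured intensity is `1 / T`.
#'
#' @param thickness Slab thickness in micrometres.
#' @param material Medium name in the shipped table (e.g. `"Si"`), or a list
#'   with `mu_over_rho_cm2_g` and `density_g_cm3`.
#' @param photon_energy keV (elastic scattering assumed).
#' @param two_theta Scattering angle in radians, in `[0, pi/2)`.
#' @return Transmission fraction in (0, 1].
#' @export
attenuator_transmission <- function(thickness, material = "Si",
                                    photon_energy = 8.48, two_theta = 0) {
  if (any(two_theta < 0 | two_theta >= pi / 2)) {
    .stopf("two_theta must lie in [0, pi/2) for a flat attenuator")
  }
  if (thickness < 0) .stopf("thickness must be >= 0")
  m <- if (is.list(material)) material else .lookup_mu(material, photon_energy)
  mu_per_um <- m$mu_over_rho_cm2_g * m$density_g_cm3 * 1e-4  # cm^-1 -> um^-1
  exp(-mu_per_um * thickness / cos(two_theta))
}

#' Ratio of a peak fluence to the saturation fluence
#'
#' @param peak Peak fluence, photons um^-2.
#' @param sat Saturation fluence, photons um^-2 (> 0).
#' @return Dimensionless fold ratio.
#' @export
fluence_ratio_to_saturation <- function(peak, sat) {
  if (any(sat <= 0)) .stopf("saturation fluence must be > 0")
  peak / sat
}
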