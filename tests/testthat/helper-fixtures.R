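# Shared fixtures: the reference beamline conditions and small helper atoms.

gd_atom <- function(...) load_atom_model(element = "Gd", ...)

ref_beam <- function(attenuation = 1,
                     spatial = spatial_profile("gaussian", fwhm = 0.2),
                     duration = 40) {
  beam_model(8.48, 1.6, 0.30, attenuation, spatial, temporal_profile(duration))
}

dg_profile <- function() {
  spatial_profile("double_gaussian",
                  components = data.frame(photon_fraction = c(0.5, 0.5),
                                          fwhm = c(0.2, 0.6)))
}

# Constant-cross-section, no-cascade atom: the absorption count is exactly
# Poisson with mean sigma_um2 * fluence. sigma = 1e4 barn = 1e-12 um^2, so
# fluence = n_mean * 1e12 gives mean n_mean.
poisson_atom <- function(Z = 40) {
  atom_model(element = "Xp", Z = Z,
             subshells = data.frame(label = "1s", occupancy = Z,
                                    binding_energy_keV = 1),
             sigma_total = 1e4, photon_energy = 8.48,
             q_floor = Inf, cascade_pmf = c("0" = 1))
}

poisson_fluence <- function(n_mean) n_mean * 1e12

# Minimal hand-built trajectory for form-factor unit tests.
fake_trajectory <- function(atom, times, populations) {
  structure(list(times = times, populations = populations, atom = atom,
                 fluence = NA_real_, temporal = temporal_profile(max(times)),
                 dt = diff(times)[1]),
            class = "charge_trajectory")
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
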