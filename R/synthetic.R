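# Seeded generators for every synthetic input the pipeline needs: SFX
# pattern-metadata streams with the qualitative correlation structure of
# real runs (bright patterns <-> high pulse energy <-> many peaks <-> better
# resolution), toy structures/maps with planted ionization contrast, and
# beam/atom fixture configurations.

#' Configuration for a synthetic SFX pattern-metadata stream
#'
#' Distributional choices emulate a SASE machine and jet-injected
#' microcrystals:
#' * pulse energy: gamma-distributed about 1.6 mJ (shape 100, ~10% relative
#'   jitter, typical SASE intensity fluctuation);
#' * on-crystal fluence: pulse energy times a lognormal coupling factor
#'   (`sdlog = 0.8`) absorbing pointing jitter and where the crystal sits in
#'   the focal profile — the dominant fluence spread;
#' * peak count: Poisson with mean rising and saturating in fluence;
#' * mean peak intensity: proportional to fluence times a lognormal
#'   crystal-size factor with multiplicative measurement noise;
#' * best resolution: improves (d shrinks) with peak count, with lognormal
#'   scatter.
#'
#' @param n_patterns Number of patterns.
#' @param seed Integer seed.
#' @param pulse_energy_mean_mj,pulse_energy_shape Gamma law of the monitor
#'   reading.
#' @param coupling_sdlog Lognormal sd of the fluence coupling factor.
#' @param peak_fluence_scale Hot-spot peak fluence (photons um^-2) an
#'   average pulse would deliver; default from the unattenuated reference
#'   beam.
#' @param n_peaks_base,n_peaks_max Peak-count law: mean = base +
#'   max * F / (F + median(F)).
#' @param intensity_scale,size_sdlog,intensity_shape Intensity law.
#' @param resolution_best_A,resolution_range_A,resolution_sdlog Resolution
#'   law: d = best + range * exp(-n_peaks / 60) * lognormal.
#' @param deterministic_counts Replace the Poisson peak-count draw by its
#'   rounded mean (used together with zero sdlogs and infinite shapes to
#'   express the fluctuation-free degenerate limit).
#' @return Object of class `stream_config`.
#' @export
stream_config <- function(n_patterns = 1e5, seed = 1,
                          pulse_energy_mean_mj = 1.6, pulse_energy_shape = 100,
                          coupling_sdlog = 0.8,
                          peak_fluence_scale = 7.8e12,
                          n_peaks_base = 15, n_peaks_max = 100,
                          intensity_scale = 1e-10, size_sdlog = 0.3,
                          intensity_shape = 50,
                          resolution_best_A = 1.8, resolution_range_A = 4,
                          resolution_sdlog = 0.1, deterministic_counts = FALSE) {
  cfg <- as.list(environment())
  # shape parameters may be Inf (degenerate, fluctuation-free limit)
  for (f in c("pulse_energy_shape", "intensity_shape")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0) {
      .stopf("%s must be a positive number (Inf allowed)", f)
    }
  }
  pos <- c("pulse_energy_mean_mj", "peak_fluence_scale",
           "n_peaks_max", "intensity_scale",
           "resolution_best_A", "resolution_range_A")
  for (f in pos) if (!.is_number(cfg[[f]]) || cfg[[f]] <= 0) {
    .stopf("%s must be a positive number", f)
  }
  nonneg <- c("coupling_sdlog", "size_sdlog", "resolution_sdlog", "n_peaks_base")
  for (f in nonneg) if (!.is_number(cfg[[f]]) || cfg[[f]] < 0) {
    .stopf("%s must be >= 0", f)
  }
  structure(cfg, class = "stream_config")
}

#' Generate a synthetic SFX pattern-metadata stream
#'
#' @param cfg A [stream_config()].
#' @return data.frame with columns `id`, `pulse_energy_reading` (mJ),
#'   `n_peaks`, `mean_peak_intensity`, `max_resolution` (A) and the ground
#'   truth `true_fluence` (photons um^-2). Deterministic in `(cfg, seed)`.
#' @examples
#' st <- generate_stream(stream_config(n_patterns = 1000, seed = 7))
#' cor(st$n_peaks, st$true_fluence, method = "spearman")
#' @export
generate_stream <- function(cfg = stream_config()) {
  stopifnot(inherits(cfg, "stream_config"))
  n <- as.integer(cfg$n_patterns)
  .with_seed(cfg$seed, {
    e <- if (is.infinite(cfg$pulse_energy_shape)) {
      rep(cfg$pulse_energy_mean_mj, n)
    } else {
      rgamma(n, shape = cfg$pulse_energy_shape,
             scale = cfg$pulse_energy_mean_mj / cfg$pulse_energy_shape)
    }
    coupling <- rlnorm(n, meanlog = -cfg$coupling_sdlog^2 / 2,
                       sdlog = cfg$coupling_sdlog)
    fl <- cfg$peak_fluence_scale * (e / cfg$pulse_energy_mean_mj) * coupling
    lam <- cfg$n_peaks_base + cfg$n_peaks_max * fl / (fl + median(fl))
    np <- if (cfg$deterministic_counts) round(lam) else rpois(n, lam)
    size <- rlnorm(n, -cfg$size_sdlog^2 / 2, cfg$size_sdlog)
    gain <- if (is.infinite(cfg$intensity_shape)) 1 else
      rgamma(n, shape = cfg$intensity_shape, rate = cfg$intensity_shape)
    inten <- cfg$intensity_scale * fl * size * gain
    res <- cfg$resolution_best_A + cfg$resolution_range_A * exp(-np / 60) *
      rlnorm(n, -cfg$resolution_sdlog^2 / 2, cfg$resolution_sdlog)
    data.frame(id = sprintf("p%07d", seq_len(n)),
               pulse_energy_reading = e, n_peaks = np,
               mean_peak_intensity = inten, max_resolution = res,
               true_fluence = fl, stringsAsFactors = FALSE)
  })
}

#' Configuration of a toy heavy-atom structure
#'
#' Two partially occupied heavy-atom sites whose effective electron counts
#' differ between a low-fluence and a high-fluence condition, plus an
#' eight-atom 48-electron reference group (a tryptophan-fragment stand-in)
#' that is identical in both conditions, and decoy light atoms that are part
#' of the model (hence absent from omit maps).
#'
#' @param heavy_positions 2 x 3 matrix of heavy-site coordinates (A).
#' @param heavy_occupancies Length-2 occupancies.
#' @param electrons_lf,electrons_hf Effective electrons per heavy site in
#'   the two conditions.
#' @param reference_center Centre of the reference group (A).
#' @param noise_sd Gaussian map-noise level, e-/A^3.
#' @param voxel Grid voxel (A).
#' @param b_factor Isotropic B for all atoms (A^2).
#' @param integration_radius Omit-sphere radius used downstream (A); site
#'   separation must exceed twice this.
#' @return Object of class `toy_structure_config`.
#' @export
toy_structure_config <- function(heavy_positions = rbind(c(8, 8, 8), c(16, 13, 9)),
                                 heavy_occupancies = c(1.0, 0.7),
                                 electrons_lf = 57, electrons_hf = 32,
                                 reference_center = c(10, 18, 14),
                                 noise_sd = 0.05, voxel = 0.3, b_factor = 15,
                                 integration_radius = 2.0) {
  if (!is.matrix(heavy_positions) || !all(dim(heavy_positions) == c(2, 3))) {
    .stopf("heavy_positions must be a 2 x 3 matrix")
  }
  sep <- sqrt(sum((heavy_positions[1, ] - heavy_positions[2, ])^2))
  if (sep <= 2 * integration_radius) {
    .stopf("heavy sites %.2f A apart; need > 2 x integration radius (%.2f A)",
           sep, 2 * integration_radius)
  }
  if (noise_sd < 0) .stopf("noise_sd must be >= 0")
  if (any(heavy_occupancies <= 0 | heavy_occupancies > 1)) {
    .stopf("occupancies must be in (0, 1]")
  }
  structure(as.list(environment())[
    c("heavy_positions", "heavy_occupancies", "electrons_lf", "electrons_hf",
      "reference_center", "noise_sd", "voxel", "b_factor", "integration_radius")],
    class = "toy_structure_config")
}

# Eight reference atoms (6 e- each, 48 e- total) on two fused rings, roughly
# an indole-fragment footprint ~3 A across.
.reference_positions <- function(center) {
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  ring1 <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  extra <- rbind(c(2.6, 0.8, 0), c(2.6, -0.8, 0))
  sweep(rbind(ring1, extra), 2, center, `+`)
}

#' Generate a matched pair of toy structures (and maps)
#'
#' Returns identical geometry for the two conditions; only the heavy-site
#' electron counts differ (planted ionization contrast). The rendered maps
#' emulate omit maps: they contain the omitted atoms only (heavy sites +
#' reference group), with optional Gaussian noise.
#'
#' @param cfg A [toy_structure_config()].
#' @param seed Integer seed for the map noise.
#' @param render Logical: also render and return the noisy maps?
#' @return List with `sites_lf`, `sites_hf` ([atom_sites()], including decoy
#'   light atoms flagged in the `omitted` attribute), `regions` (target and
#'   reference [omit_region()]s), and, when `render = TRUE`, `map_lf`,
#'   `map_hf`.
#' @export
generate_structure_pair <- function(cfg = toy_structure_config(), seed = 1,
                                    render = TRUE) {
  stopifnot(inherits(cfg, "toy_structure_config"))
  hp <- cfg$heavy_positions
  refs <- .reference_positions(cfg$reference_center)
  decoys <- rbind(c(4, 16, 6), c(18, 6, 14), c(6, 6, 16))
  build <- function(ne_heavy) {
    s <- atom_sites(
      x = c(hp[, 1], refs[, 1], decoys[, 1]),
      y = c(hp[, 2], refs[, 2], decoys[, 2]),
      z = c(hp[, 3], refs[, 3], decoys[, 3]),
      element = c("Gd", "Gd", rep("C", nrow(refs)), rep("O", nrow(decoys))),
      n_electrons = c(ne_heavy, ne_heavy, rep(6, nrow(refs)), rep(8, nrow(decoys))),
      occupancy = c(cfg$heavy_occupancies, rep(1, nrow(refs)), rep(1, nrow(decoys))),
      b_factor = cfg$b_factor)
    attr(s, "omitted") <- c(rep(TRUE, 2 + nrow(refs)), rep(FALSE, nrow(decoys)))
    s
  }
  sites_lf <- build(cfg$electrons_lf)
  sites_hf <- build(cfg$electrons_hf)
  regions <- list(
    targets = list(omit_region(hp[1, ], cfg$integration_radius),
                   omit_region(hp[2, ], cfg$integration_radius)),
    reference = lapply(seq_len(nrow(refs)),
                       function(i) omit_region(refs[i, ], cfg$integration_radius)))
  out <- list(sites_lf = sites_lf, sites_hf = sites_hf, regions = regions,
              config = cfg, seed = seed)
  if (render) {
    omit <- attr(sites_lf, "omitted")
    # common grid covering both conditions
    all_xyz <- sites_lf[omit, c("x", "y", "z")]
    fw <- .b_to_sigma(cfg$b_factor) * .FWHM_PER_SIGMA
    margin <- max(3.5 * fw, cfg$integration_radius + cfg$voxel)
    origin <- as.numeric(apply(all_xyz, 2, min)) - margin
    dims <- ceiling((as.numeric(apply(all_xyz, 2, max)) + margin - origin) /
                      cfg$voxel) + 1L
    rmap <- function(sites, sub_seed) {
      m <- render_map(sites[omit, ], origin = origin, voxel = cfg$voxel, dims = dims)
      if (cfg$noise_sd > 0) {
        m$values <- m$values + .with_seed(sub_seed,
          array(stats::rnorm(prod(dims), 0, cfg$noise_sd), dims))
      }
      m
    }
    out$map_lf <- rmap(sites_lf, seed)
    out$map_hf <- rmap(sites_hf, seed + 1)
  }
  out
}

#' Write the reference fixture configurations
#'
#' Emits the JSON beam/atom configurations used throughout the tests and
#' documentation: the reference beamline conditions (8.48 keV, 1.6 mJ, 30%
#' optics transmission, 40 fs flat-top), the attenuated low-fluence beam
#' (1.73%), the unattenuated high-fluence beam, the double-Gaussian focus
#' alternative (50% hot spot of 0.2 um FWHM, 50% pedestal of 0.6 um FWHM),
#' and the 20 fs high-fluence Bragg-termination gate.
#'
#' @param dir Directory to write into (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
fixture_configs <- function(dir = tempdir()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- list(
    atom = list(element = "Gd", table = NULL, q_floor = 33,
                cascade = list(min = 4, max = 12)),
    beam_lf = list(photon_energy_kev = 8.48, pulse_energy_mj = 1.6,
                   optics_transmission = 0.3, attenuation = 0.0173,
                   spatial = list(kind = "gaussian",
                                  components = list(list(photon_fraction = 1.0,
                                                         fwhm_um = 0.2))),
                   temporal = list(kind = "flat_top", duration_fs = 40)),
    beam_hf = list(photon_energy_kev = 8.48, pulse_energy_mj = 1.6,
                   optics_transmission = 0.3, attenuation = 1.0,
                   spatial = list(kind = "gaussian",
                                  components = list(list(photon_fraction = 1.0,
                                                         fwhm_um = 0.2))),
                   temporal = list(kind = "flat_top", duration_fs = 40)),
    spatial_alt = list(kind = "double_gaussian",
                       components = list(list(photon_fraction = 0.5, fwhm_um = 0.2),
                                         list(photon_fraction = 0.5, fwhm_um = 0.6))),
    gate_hf_fs = 20,
    std = list(n = 2000),
    seed = 1)
  path <- file.path(dir, "hip_reference.json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}
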