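test_that("stream generation is a pure function of (config, seed)", {
  cfg <- stream_config(n_patterns = 500, seed = 21)
  a <- generate_stream(cfg)
  b <- generate_stream(cfg)
  expect_identical(a, b)
  expect_false(identical(a, generate_stream(stream_config(500, seed = 22))))
  # ground truth is carried and positively coupled to every proxy
  expect_true(all(c("true_fluence", "n_peaks", "mean_peak_intensity",
                    "pulse_energy_reading") %in% names(a)))
  expect_gt(cor(a$n_peaks, a$true_fluence, method = "spearman"), 0.5)
  expect_gt(cor(a$mean_peak_intensity, a$true_fluence, method = "spearman"), 0.5)
})

test_that("the zero-fluctuation limit produces identical records", {
  cfg <- stream_config(n_patterns = 20, seed = 1,
                       pulse_energy_shape = Inf, coupling_sdlog = 0,
                       size_sdlog = 0, resolution_sdlog = 0,
                       intensity_shape = Inf, deterministic_counts = TRUE)
  st <- generate_stream(cfg)
  num <- st[, setdiff(names(st), "id")]
  expect_true(all(vapply(num, function(col) length(unique(col)) == 1, logical(1))))
})

test_that("structure pairs differ only at the heavy sites", {
  cfg <- toy_structure_config(noise_sd = 0)
  pr <- generate_structure_pair(cfg, seed = 2)
  # identical geometry; only n_electrons differs at the two heavy sites
  expect_equal(pr$sites_lf[, c("x", "y", "z", "occupancy", "b_factor")],
               pr$sites_hf[, c("x", "y", "z", "occupancy", "b_factor")])
  diff_ne <- pr$sites_lf$n_electrons != pr$sites_hf$n_electrons
  expect_equal(which(diff_ne), 1:2)
  # reference group integrates to 48 electrons (occupancy 1), in both maps
  for (m in list(pr$map_lf, pr$map_hf)) {
    expect_rel(integrate_positive(m, pr$regions$reference), 48, 0.01)
  }
  # zero planted contrast: maps identical without noise
  cfg0 <- toy_structure_config(electrons_lf = 40, electrons_hf = 40, noise_sd = 0)
  pr0 <- generate_structure_pair(cfg0, seed = 2)
  expect_equal(pr0$map_lf$values, pr0$map_hf$values)
  # separation invariant is enforced
  expect_error(toy_structure_config(
    heavy_positions = rbind(c(8, 8, 8), c(9, 8, 8))), "separation|apart")
})

test_that("noiseless end-to-end recovery of the planted contrast is tight", {
  cfg <- toy_structure_config(noise_sd = 0, voxel = 0.25)
  pr <- generate_structure_pair(cfg, seed = 3)
  est <- function(map, k) electrons_by_reference(
    map, pr$regions$targets[[k]], pr$regions$reference,
    target_occupancy = cfg$heavy_occupancies[k])$electrons
  for (k in 1:2) {
    contrast <- est(pr$map_lf, k) - est(pr$map_hf, k)
    expect_rel(contrast, cfg$electrons_lf - cfg$electrons_hf, 0.05)
  }
})

test_that("fixture configs round-trip through the parser and validator", {
  dir <- tempfile("fix")
  path <- fixture_configs(dir)
  expect_true(file.exists(path))
  cfg <- read_config(path)
  expect_length(validate_config(cfg), 0)
  expect_equal(cfg$beam_lf$attenuation, 0.0173)
  expect_equal(cfg$beam_hf$attenuation, 1.0)
  expect_equal(cfg$gate_hf_fs, 20)
  # writing the parsed config back yields the same structure
  p2 <- file.path(dir, "roundtrip.json")
  jsonlite::write_json(cfg, p2, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  expect_equal(read_config(p2), cfg)
  # the LF fixture reproduces the reference peak fluence
  b <- hipxfel:::.beam_from_config(cfg$beam_lf)
  expect_rel(peak_fluence(b), 1.35e11, 0.01)
})
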