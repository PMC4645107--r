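test_that("rendered Gaussians conserve occupancy-weighted electrons", {
  s <- atom_sites(x = 5, y = 5, z = 5, element = "Gd", n_electrons = 57,
                  occupancy = 0.8, b_factor = 15)
  m <- render_map(s, voxel = 0.25)
  expect_rel(sum(m$values) * m$voxel^3, 0.8 * 57, 0.005)
  # doubling occupancy doubles the integral
  s2 <- s; s2$occupancy <- 0.4
  m2 <- render_map(s2, origin = m$origin, voxel = 0.25, dims = m$dims)
  expect_equal(sum(m2$values), sum(m$values) / 2, tolerance = 1e-9)
  # superposition: two distant sites integrate independently
  pair <- atom_sites(x = c(5, 15), y = c(5, 5), z = c(5, 5),
                     n_electrons = c(10, 20), b_factor = 15)
  mp <- render_map(pair, voxel = 0.25)
  i1 <- integrate_positive(mp, omit_region(c(5, 5, 5), 2))
  i2 <- integrate_positive(mp, omit_region(c(15, 5, 5), 2))
  expect_rel(i1, 10, 0.01)
  expect_rel(i2, 20, 0.01)
  # a site too close to the grid edge is a coverage error
  expect_error(render_map(s, origin = c(4.5, 0, 0), voxel = 0.25,
                          dims = c(40, 60, 60)), "boundary")
})

test_that("difference maps are antisymmetric and show planted contrast", {
  s_lf <- atom_sites(5, 5, 5, "Gd", n_electrons = 57, occupancy = 0.9)
  s_hf <- atom_sites(5, 5, 5, "Gd", n_electrons = 32, occupancy = 0.9)
  a <- render_map(s_lf, voxel = 0.25)
  b <- render_map(s_hf, origin = a$origin, voxel = 0.25, dims = a$dims)
  d <- difference_map(a, b)
  expect_equal(difference_map(a, a)$values, array(0, a$dims))
  expect_equal(difference_map(b, a)$values, -d$values)
  expect_rel(integrate_positive(d, omit_region(c(5, 5, 5), 2)), 25 * 0.9, 0.01)
  shifted <- density_map(a$values, origin = a$origin + 1, voxel = a$voxel)
  expect_error(difference_map(a, shifted), "different grids")
})

test_that("positive-density integration respects region and threshold", {
  zero <- density_map(array(0, c(20, 20, 20)), voxel = 0.5)
  expect_equal(integrate_positive(zero, omit_region(c(5, 5, 5), 2)), 0)
  s <- atom_sites(5, 5, 5, "C", n_electrons = 6)
  m <- render_map(s, voxel = 0.25)
  expect_equal(integrate_positive(m, omit_region(c(5, 5, 5), 2),
                                  threshold = max(m$values) * 1.01), 0)
  expect_error(integrate_positive(m, omit_region(c(100, 5, 5), 2)), "outside")
})

test_that("the 48-electron reference calibrates electron counts", {
  # eight carbon-like atoms, 48 electrons total, at full occupancy
  ctr <- c(10, 10, 10)
  refs <- hipxfel:::.reference_positions(ctr)
  ref_sites <- atom_sites(refs[, 1], refs[, 2], refs[, 3], "C", n_electrons = 6)
  gd_site <- atom_sites(22, 10, 10, "Gd", n_electrons = 25, occupancy = 0.5)
  m <- render_map(rbind(ref_sites, gd_site), voxel = 0.25)
  ref_regions <- lapply(seq_len(nrow(refs)),
                        function(i) omit_region(refs[i, ], 2))
  expect_rel(integrate_positive(m, ref_regions), 48, 0.01)

  # target = reference recovers the reference electrons exactly
  same <- electrons_by_reference(m, ref_regions, ref_regions)
  expect_equal(same$electrons, 48)
  # occupancy-corrected recovery of the planted 25-electron site
  est <- electrons_by_reference(m, omit_region(c(22, 10, 10), 2), ref_regions,
                                target_occupancy = 0.5)
  expect_rel(est$electrons, 25, 0.02)
  # invariance under global multiplicative map scaling
  m3 <- density_map(m$values * 7.5, origin = m$origin, voxel = m$voxel)
  est3 <- electrons_by_reference(m3, omit_region(c(22, 10, 10), 2), ref_regions,
                                 target_occupancy = 0.5)
  expect_equal(est3$electrons, est$electrons, tolerance = 1e-12)
})

test_that("peak sigma levels rank sites by occupancy and ignore scale", {
  pr <- generate_structure_pair(toy_structure_config(noise_sd = 0.02), seed = 4)
  pos <- pr$config$heavy_positions
  sig <- peak_sigma_levels(pr$map_lf, pos)
  expect_gt(sig[1], sig[2])      # occupancy 1.0 site beats the 0.7 site
  scaled <- density_map(pr$map_lf$values * 3, origin = pr$map_lf$origin,
                        voxel = pr$map_lf$voxel)
  expect_equal(peak_sigma_levels(scaled, pos), sig, tolerance = 1e-9)
  flat <- density_map(array(1, c(8, 8, 8)), voxel = 1)
  expect_error(peak_sigma_levels(flat, c(2, 2, 2)), "degenerate")
  spike <- array(0, c(9, 9, 9)); spike[5, 5, 5] <- 10
  sm <- density_map(spike, voxel = 1)
  expect_equal(which.max(abs(sm$values)), 365L)
  expect_gt(peak_sigma_levels(sm, c(4, 4, 4)), 10)
})

test_that("CCP4 and PDB round-trips preserve the data", {
  s <- atom_sites(x = c(5, 9), y = c(5, 6), z = c(5, 7),
                  element = c("Gd", "C"), n_electrons = c(57, 6),
                  occupancy = c(0.7, 1), b_factor = c(15, 20))
  m <- render_map(s, voxel = 0.4)
  f <- tempfile(fileext = ".ccp4")
  write_ccp4(m, f)
  m2 <- read_ccp4(f)
  expect_equal(m2$dims, m$dims)
  expect_equal(m2$origin, m$origin, tolerance = 1e-6)
  expect_equal(m2$voxel, m$voxel, tolerance = 1e-6)
  expect_equal(m2$values, m$values, tolerance = 1e-6)

  p <- tempfile(fileext = ".pdb")
  write_pdb(s, p)
  s2 <- read_pdb(p, n_electrons = c(57, 6))
  expect_equal(s2$x, s$x)
  expect_equal(s2$occupancy, s$occupancy)
  expect_equal(s2$b_factor, s$b_factor)
  expect_equal(s2$element, s$element)
  expect_equal(s2$n_electrons, s$n_electrons)
})
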