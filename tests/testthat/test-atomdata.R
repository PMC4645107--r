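test_that("shipped atom models load, validate, and expose reference numbers", {
  gd <- gd_atom()
  expect_s3_class(gd, "atom_model")
  expect_identical(gd$Z, 64L)
  expect_equal(gd$sigma_total, 1.04e5)
  expect_equal(sum(gd$cascade_pmf), 1)
  expect_equal(as.integer(names(gd$cascade_pmf)), 4:12)

  # occupancies sum to Z for every shipped element
  tab_path <- system.file("extdata", "atomic_subshells.csv", package = "hipxfel")
  tab <- read.csv(tab_path, comment.char = "#")
  for (el in unique(tab$element)) {
    sub <- tab[tab$element == el & tab$subshell != "(total)", ]
    expect_equal(sum(sub$occupancy), sub$Z[1], info = el)
  }

  expect_error(load_atom_model(element = "Xx"), "not present")
  expect_error(load_atom_model(element = "Gd", photon_energy = 12.0),
               "reference energy")
})

test_that("photoelectron energies match the subshell ladder", {
  c_atom <- load_atom_model(element = "C")
  gd <- gd_atom()
  expect_lt(abs(photoelectron_energy(c_atom, "1s", 8.48) - 8.2), 0.05)
  expect_lt(abs(photoelectron_energy(gd, "LIII", 8.48) - 1.2), 0.05)
  # K shell of Gd (binding 50.2 keV) is inaccessible at 8.48 keV
  expect_null(photoelectron_energy(gd, "1s", 8.48))
  expect_null(photoelectron_energy(gd, "K", 8.48))
  expect_error(photoelectron_energy(gd, "Q9", 8.48), "unknown subshell")
  # energy + binding = photon energy whenever defined
  for (lab in c("LI", "LII", "LIII", "MI", "NI")) {
    b <- gd$subshells$binding_energy_keV[gd$subshells$label == lab]
    expect_equal(photoelectron_energy(gd, lab, 8.48) + b, 8.48)
  }
})

test_that("the charge ladder cross section is linear to zero at q_floor", {
  gd <- gd_atom()
  expect_equal(cross_section(gd, 0), 1.04e5)
  expect_equal(cross_section(gd, gd$q_floor), 0)
  expect_equal(cross_section(gd, gd$Z), 0)
  # halfway point (q_floor = 33 is odd; average the two straddling states)
  mid <- mean(cross_section(gd, c(16, 17)))
  expect_equal(mid, gd$sigma_total / 2)
  # nonincreasing over the whole ladder
  expect_true(all(diff(cross_section(gd, 0:gd$Z)) <= 0))
  expect_error(cross_section(gd, -1), "out of range")
  expect_error(cross_section(gd, 65), "out of range")
  # no-floor limit is constant
  expect_equal(cross_section(poisson_atom(), c(0, 5, 39)), rep(1e4, 3))
})

test_that("saturation fluence is the reciprocal cross section in um^2", {
  gd <- gd_atom()
  expect_rel(saturation_fluence(gd), 9.5e10, 0.02)
  # unit identity and reciprocal scaling
  one_barn <- atom_model("Xb", 2,
                         data.frame(label = "1s", occupancy = 2,
                                    binding_energy_keV = 1),
                         sigma_total = 1, photon_energy = 8.48,
                         q_floor = 2, cascade_pmf = c("0" = 1))
  expect_equal(saturation_fluence(one_barn), 1e16)
  two_barn <- atom_model("Xb", 2, one_barn$subshells, 2, 8.48, 2, c("0" = 1))
  expect_equal(saturation_fluence(two_barn), saturation_fluence(one_barn) / 2)
  expect_equal(saturation_fluence(gd) * gd$sigma_total * 1e-16, 1,
               tolerance = 1e-12)
})

test_that("atom model validation rejects inconsistent inputs", {
  sub <- data.frame(label = "1s", occupancy = 2, binding_energy_keV = 1)
  expect_error(atom_model("He", 3, sub, 1, 8.48, 2, c("0" = 1)), "sum to")
  expect_error(atom_model("He", 2, sub, -1, 8.48, 2, c("0" = 1)), "sigma_total")
  expect_error(atom_model("He", 2, sub, 1, 8.48, 5, c("0" = 1)), "q_floor")
  expect_error(atom_model("He", 2, sub, 1, 8.48, 2, c("0" = 0.5)), "sum to 1")
})
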