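test_that("dynamical form factors are population-weighted bound counts", {
  gd <- gd_atom()
  tp <- temporal_profile(40)
  tr0 <- evolve_populations(gd, 0, tp)
  ff <- dynamical_form_factor(gd, tr0)
  expect_true(all(Re(ff$values) == 64))
  expect_true(all(Im(ff$values) == 0))

  nq <- gd$Z + 1L
  # all population at q = 25
  P <- matrix(0, 2, nq); P[, 26] <- 1
  tr <- fake_trajectory(gd, c(0, 40), P)
  expect_equal(Re(dynamical_form_factor(gd, tr)$values), c(39, 39))
  # 50/50 mixture of q = 0 and q = 10
  P2 <- matrix(0, 2, nq); P2[, 1] <- 0.5; P2[, 11] <- 0.5
  tr2 <- fake_trajectory(gd, c(0, 40), P2)
  expect_equal(Re(dynamical_form_factor(gd, tr2)$values), c(59, 59))
})

test_that("a user scattering table overrides the default coefficients", {
  gd <- gd_atom()
  st <- data.frame(q = 0, f0 = 64, fprime = -2, fdprime = 3)
  gd2 <- atom_model("Gd", gd$Z, gd$subshells, gd$sigma_total, 8.48,
                    gd$q_floor, gd$cascade_pmf, scattering_table = st)
  tr0 <- evolve_populations(gd2, 0, temporal_profile(40))
  ff <- dynamical_form_factor(gd2, tr0)
  expect_equal(Re(ff$values[1]), 62)
  expect_equal(Im(ff$values[1]), 3)
})

test_that("effective scattering strength has the expected limits and monotonicity", {
  gd <- gd_atom()
  # zero-fluence limit: exactly Z (use a vanishing attenuation)
  tiny <- ref_beam(attenuation = 1e-12)
  expect_equal(effective_scattering_strength(gd, tiny)$f_eff, 64,
               tolerance = 1e-6)
  # strictly decreasing in peak fluence across the working range
  f_at <- function(att) effective_scattering_strength(gd, ref_beam(att))$f_eff
  # attenuations spanning peak fluences ~1e9 .. ~8e12 photons/um^2
  vals <- vapply(c(1.3e-4, 1.3e-3, 1.3e-2, 0.13, 1), f_at, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals >= 0 & vals <= 64))
})

test_that("gating restricts the average to the early pulse and never lowers f_eff", {
  gd <- gd_atom()
  hf <- ref_beam()
  gates <- c(5, 10, 20, 40)
  f <- vapply(gates, function(g)
    effective_scattering_strength(gd, hf, gate = g)$f_eff, numeric(1))
  expect_true(all(diff(f) < 0))   # longer gate, more accumulated ionization
  ungated <- effective_scattering_strength(gd, hf)
  expect_equal(f[length(f)], ungated$f_eff)
  # gate beyond the pulse duration clips with a warning
  expect_warning(clipped <- effective_scattering_strength(gd, hf, gate = 60),
                 "clipped")
  expect_equal(clipped$f_eff, ungated$f_eff)
})

test_that("spatial averaging includes weakly ionized wings", {
  gd <- gd_atom()
  for (att in c(0.0173, 1)) {
    b <- ref_beam(att)
    pt <- effective_scattering_strength(gd, b, mode = "point")$f_eff
    sp <- effective_scattering_strength(gd, b, mode = "spatial", n_nodes = 16)$f_eff
    expect_gt(sp, pt)
  }
  # quadrature convergence: doubling the node count moves f_eff < 0.1 e-
  b <- ref_beam()
  f16 <- effective_scattering_strength(gd, b, mode = "spatial", n_nodes = 16)$f_eff
  f32 <- effective_scattering_strength(gd, b, mode = "spatial", n_nodes = 32)$f_eff
  expect_lt(abs(f32 - f16), 0.1)
})

test_that("fluctuation estimates are seeded and consistent with the mean", {
  gd <- gd_atom()
  lf <- ref_beam(0.0173)
  s1 <- scattering_strength_std(gd, lf, n = 1500, seed = 11)
  s2 <- scattering_strength_std(gd, lf, n = 1500, seed = 11)
  expect_identical(s1$std, s2$std)
  # sample mean agrees with the deterministic f_eff within 3 standard errors
  f <- effective_scattering_strength(gd, lf, mode = "point")$f_eff
  expect_lt(abs(s1$mean - f), 3 * s1$std / sqrt(s1$n))
  # vanishing fluence: no ionization, no spread
  tiny <- ref_beam(attenuation = 1e-12)
  expect_lt(scattering_strength_std(gd, tiny, n = 200, seed = 3)$std, 1e-6)
  expect_error(scattering_strength_std(gd, lf, n = 50, seed = 1), ">= 100")
})

test_that("contrast operations enforce comparable conventions", {
  gd <- gd_atom()
  lf <- effective_scattering_strength(gd, ref_beam(0.0173))
  hf <- effective_scattering_strength(gd, ref_beam(1))
  expect_equal(ionization_contrast(lf, lf), 0)
  expect_gt(ionization_contrast(lf, hf), 0)
  sp <- effective_scattering_strength(gd, ref_beam(1), mode = "spatial",
                                      n_nodes = 16)
  expect_error(ionization_contrast(lf, sp), "modes")
  # gate equal to the pulse duration reduces to the ungated contrast
  expect_equal(gated_contrast(gd, ref_beam(0.0173), ref_beam(1), 40),
               ionization_contrast(lf, hf), tolerance = 1e-9)
})
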