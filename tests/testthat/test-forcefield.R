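test_that("debye_length matches the closed-form expression", {
  lam <- debye_length(0.150, 300, 78)
  eps0 <- 8.8541878128e-12; kB <- 1.380649e-23
  NAv <- 6.02214076e23; e <- 1.602176634e-19
  lam_ref <- sqrt(eps0 * 78 * kB * 300 /
                    (2 * 0.150 * 1000 * NAv * e^2)) * 1e10
  expect_equal(lam, lam_ref, tolerance = 1e-12)
  expect_gt(lam, 7.8); expect_lt(lam, 7.9)
  expect_gt(debye_length(0.05), lam)
  expect_error(debye_length(0), "positive")
})

test_that("electrostatic context derives its cutoff from the Debye length", {
  ctx <- electrostatic_context()
  expect_equal(ctx$lambda_D, debye_length())
  expect_equal(ctx$cutoff_elec, 5 * ctx$lambda_D)
  expect_equal(ctx$q_phos_dna, -0.6)
  expect_equal(ctx$q_phos_protein, -1.0)
})

test_that("screened Coulomb obeys Debye screening and the phosphate rule", {
  ctx <- electrostatic_context()
  u1 <- debye_huckel_energy(1, -1, 5, ctx)$energy
  u2 <- debye_huckel_energy(1, -1, 10, ctx)$energy
  expect_equal(u2 / u1, (5 / 10) * exp(-5 / ctx$lambda_D),
               tolerance = 1e-12)
  # pair-context phosphate charges override the nominal charge
  base <- debye_huckel_energy(1, 1, 6, ctx)$energy
  pp <- debye_huckel_energy(-123, -456, 6, ctx,
                            kind_i = "phosphate", kind_j = "phosphate")
  expect_equal(pp$energy, 0.6^2 * base, tolerance = 1e-12)
  pk <- debye_huckel_energy(0, 1, 6, ctx,
                            kind_i = "phosphate", kind_j = "protein")
  expect_equal(pk$energy, -1.0 * base, tolerance = 1e-12)
  # force is the negative radial derivative
  h <- 1e-6
  fd <- -(debye_huckel_energy(1, -1, 5 + h, ctx)$energy -
            debye_huckel_energy(1, -1, 5 - h, ctx)$energy) / (2 * h)
  expect_equal(debye_huckel_energy(1, -1, 5, ctx)$force, fd,
               tolerance = 1e-6)
  expect_error(debye_huckel_energy(1, 1, 0, ctx), "positive")
})

test_that("HPS pair energy is continuous and lambda-shaped", {
  sig <- 6.0; rc <- 2^(1 / 6) * sig
  for (lam in c(0, 0.5, 1)) {
    expect_equal(hps_pair_energy(rc - 1e-9, lam, sig),
                 hps_pair_energy(rc + 1e-9, lam, sig), tolerance = 1e-6)
  }
  # at r = sigma the LJ part vanishes: plateau value (1 - lambda) * eps
  expect_equal(hps_pair_energy(sig, 0.3, sig, eps = 0.2), 0.7 * 0.2,
               tolerance = 1e-12)
  # lambda = 1 reduces to plain Lennard-Jones
  r <- 7.5
  expect_equal(hps_pair_energy(r, 1, sig, 0.2),
               4 * 0.2 * ((sig / r)^12 - (sig / r)^6), tolerance = 1e-12)
  # lambda = 0 is purely repulsive
  expect_gte(hps_pair_energy(8, 0, sig), 0)
  expect_error(hps_pair_energy(-1, 0.5, sig), "positive")
})

test_that("12-10 contact and Morse wells have the stated minima", {
  expect_equal(go_contact_energy(5, 5, 0.3), -0.3, tolerance = 1e-12)
  h <- 1e-6
  d0 <- (go_contact_energy(5 + h, 5) - go_contact_energy(5 - h, 5)) / (2 * h)
  expect_lt(abs(d0), 1e-6)
  expect_lt(abs(go_contact_energy(50, 5)), 1e-8)

  expect_equal(base_pair_energy(5.5, 5.5, D = 4), -4, tolerance = 1e-12)
  expect_lt(abs(base_pair_energy(60, 5.5, D = 4)), 1e-6)
  expect_gt(base_pair_energy(3, 5.5), base_pair_energy(5.5, 5.5))
})

test_that("flexible-local tables interpolate exactly through constants", {
  tabs <- default_flexible_tables()
  expect_named(tabs, c("angle", "dihedral"))
  const <- rep(1.25, 30)
  for (x in c(0.3, 1.1, 2.9))
    expect_equal(flexible_local_energy(x, const), 1.25, tolerance = 1e-12)
  # dihedral tables are periodic
  tab <- sin(seq(-pi, pi, length.out = 37))[-37]
  for (x in c(-2.5, 0.4, 3.0)) {
    expect_equal(flexible_local_energy(x, tab, periodic = TRUE),
                 flexible_local_energy(x + 2 * pi, tab, periodic = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("ff_tables populates every interaction term for the composite", {
  topo <- composite_system()
  ff <- ff_tables(topo)
  for (w in ff_term_names) expect_gt(nrow(ff[[w]]), 0)
  expect_gt(length(ff$excl12_i), 0)
  expect_gt(length(ff$exclev_i), 0)
})

test_that("total forces are internal and energy translation-invariant", {
  topo <- composite_system()
  ff <- ff_tables(topo)
  pos <- jittered_positions(topo)
  ef <- total_energy_forces(pos, topo, ff = ff)
  expect_true(all(is.finite(ef$forces)))
  expect_lt(max(abs(colSums(ef$forces))), 1e-8)
  shifted <- sweep(pos, 2, c(13.2, -7.1, 4.4), "+")
  ef2 <- total_energy_forces(shifted, topo, ff = ff)
  expect_equal(ef2$energy[["total"]], ef$energy[["total"]],
               tolerance = 1e-10)
  expect_equal(ef$energy[["total"]],
               sum(ef$energy[names(ef$energy) != "total"]),
               tolerance = 1e-10)
})
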