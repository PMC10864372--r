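test_that("with no hyperfine coupling the yield reduces to the relaxation closed form", {
  p <- radical_pair(B = 50, a_A = 0, spin_A = 1 / 2, label = "no-hf")
  expect_equal(singlet_yield(p, kinetics(k = 3e6, r = 0)), 1, tolerance = 1e-12)
  for (kr in list(c(1e6, 1e6), c(2e6, 5e5), c(1e4, 1e7))) {
    expect_equal(
      singlet_yield(p, kinetics(kr[1], kr[2])),
      phi_no_hyperfine(kr[1], kr[2]),
      tolerance = 1e-12
    )
  }
})

test_that("the yield always lies in [1/4, 1]", {
  draws <- random_radical_pairs(20, seed = 11)
  for (i in seq_len(nrow(draws))) {
    pp <- row_to_pair(draws[i, ])
    phi <- singlet_yield(pp$params, pp$kin)
    expect_gte(phi, 0.25 - 1e-12)
    expect_lte(phi, 1 + 1e-12)
  }
})

test_that("time-domain propagation reproduces the closed form where resolvable", {
  # analytic limits first
  p0 <- radical_pair(B = 1, a_A = 0, spin_A = 1 / 2)
  h0 <- build_hamiltonian(p0)
  expect_equal(singlet_yield_timedomain(h0, kinetics(1e6, 0)), 1,
    tolerance = 1e-6
  )
  expect_equal(singlet_yield_timedomain(h0, kinetics(1e6, 1e6)), 0.625,
    tolerance = 1e-6
  )
  # gentle random systems: low field, fast kinetics keep the step count small
  draws <- random_radical_pairs(5,
    seed = 23, b_max = 5, a_max = 5,
    k_range = c(1e6, 1e8), r_range = c(1e6, 1e8)
  )
  for (i in seq_len(nrow(draws))) {
    pp <- row_to_pair(draws[i, ])
    h <- build_hamiltonian(pp$params)
    td <- singlet_yield_timedomain(h, pp$kin, max_steps = 3e5)
    cf <- singlet_yield(h, pp$kin)
    expect_equal(td, cf, tolerance = 1e-4)
  }
})

test_that("the time-domain integrator refuses under-resolved settings", {
  h <- build_hamiltonian(ser_radical_pair(B = 100))
  slow <- kinetics(k = 1e4, r = 1e4)
  expect_error(
    singlet_yield_timedomain(h, slow, max_steps = 1e4),
    "singlet_yield_liouville"
  )
  expect_error(
    singlet_yield_timedomain(h, kinetics(2e6, 1e6), n_steps = 10),
    "Insufficient time resolution"
  )
})

test_that("the Liouville resolvent solve matches the closed form to solver precision", {
  draws <- random_radical_pairs(5, seed = 31, dim_cap = 36)
  for (i in seq_len(nrow(draws))) {
    pp <- row_to_pair(draws[i, ])
    h <- build_hamiltonian(pp$params)
    expect_equal(
      singlet_yield_liouville(h, pp$kin),
      singlet_yield(h, pp$kin),
      tolerance = 1e-8
    )
  }
  h48 <- build_hamiltonian(radical_pair(
    B = 1, a_A = 1, spin_A = 1 / 2, a_B = 1, spin_B = 5 / 2
  ))
  expect_error(singlet_yield_liouville(h48, kinetics(1e6, 1e6), max_dim = 20), "max_dim")
})

test_that("isotope averaging is a weighted mean: reduction, duplication, permutation, linearity", {
  kin <- kinetics(2e6, 1e6)
  p <- ser_radical_pair(B = 30)
  one <- tibble::tibble(isotope = "only", weight = 1, spin = 0, a = 0)
  y1 <- isotope_averaged_yield(p, kin, isotopes = one)
  expect_equal(y1$phi_s, singlet_yield(p, kin), tolerance = 1e-12)

  twin <- tibble::tibble(
    isotope = c("a", "b"), weight = c(0.5, 0.5),
    spin = c(0, 0), a = c(0, 0)
  )
  expect_equal(isotope_averaged_yield(p, kin, isotopes = twin)$phi_s,
    y1$phi_s,
    tolerance = 1e-12
  )

  tab <- mg_isotope_table()
  fwd <- isotope_averaged_yield(p, kin, isotopes = tab)
  rev <- isotope_averaged_yield(p, kin, isotopes = tab[2:1, ])
  expect_equal(fwd$phi_s, rev$phi_s, tolerance = 1e-12)
  expect_equal(
    fwd$phi_s,
    sum(fwd$components$weight * fwd$components$phi_s),
    tolerance = 1e-12
  )

  bad <- tibble::tibble(isotope = "x", weight = 0.7, spin = 0, a = 0)
  expect_error(isotope_averaged_yield(p, kin, isotopes = bad), "sum to 1")
})

test_that("tidy and glance expose the yield structure", {
  y <- isotope_averaged_yield(ser_radical_pair(B = 100), kinetics(2e6, 1e6))
  td <- tidy(y)
  expect_equal(nrow(td), 3)
  expect_true("weighted" %in% td$isotope)
  g <- glance(y)
  expect_equal(g$pathway, "Ser")
  expect_equal(g$phi_s, y$phi_s)
})
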