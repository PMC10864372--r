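test_that("angular-momentum matrices satisfy the su(2) algebra for every supported spin", {
  for (s in c(0, 1 / 2, 1, 3 / 2, 2, 5 / 2)) {
    S <- spin_matrices(s)
    d <- 2 * s + 1
    expect_equal(dim(S$x), c(d, d))
    # Hermitian components
    for (c_ in S) expect_lt(max(Mod(c_ - Conj(t(c_)))), 1e-12)
    # commutator [Sx, Sy] = i Sz
    expect_lt(max(Mod(S$x %*% S$y - S$y %*% S$x - 1i * S$z)), 1e-12)
    # Casimir Sx^2 + Sy^2 + Sz^2 = s(s+1) I
    cas <- S$x %*% S$x + S$y %*% S$y + S$z %*% S$z
    expect_lt(max(Mod(cas - s * (s + 1) * diag(d))), 1e-12)
  }
  expect_equal(diag(Re(spin_matrices(1 / 2)$z)), c(1 / 2, -1 / 2))
  expect_equal(diag(Re(spin_matrices(5 / 2)$z)), seq(5 / 2, -5 / 2))
  # spin-1/2 x and y are half the Pauli matrices
  expect_equal(spin_matrices(1 / 2)$x, matrix(c(0, 0.5, 0.5, 0), 2) + 0i)
  expect_equal(
    spin_matrices(1 / 2)$y,
    matrix(c(0, -1i / 2, 1i / 2, 0), 2, byrow = TRUE)
  )
})

test_that("non-half-integer spins are rejected everywhere", {
  expect_error(spin_matrices(0.3), "half-integer")
  expect_error(spin_matrices(-0.5), "half-integer")
  expect_error(spin_system(nuclei_a = 0.7), "half-integer")
  expect_error(radical_pair(B = 1, a_A = 1, spin_A = 0.4), "half-integer")
})

test_that("composite system dimensions follow dim = 4 * prod(2I + 1)", {
  sys <- spin_system(nuclei_a = 1 / 2, nuclei_b = 5 / 2)
  expect_equal(sys$M_A, 2L)
  expect_equal(sys$M_B, 6L)
  expect_equal(sys$M, 12L)
  expect_equal(sys$dim, 48L)
  expect_equal(spin_system()$dim, 4L)
  # spin-0 nuclei contribute trivial factors
  expect_equal(spin_system(nuclei_a = c(0, 1))$dim, 12L)
})

test_that("embedding preserves identity, trace scaling, Hermiticity, and slot commutation", {
  sys <- spin_system(nuclei_a = 1 / 2, nuclei_b = 1)
  expect_equal(
    embed_operator(diag(2), 1, sys),
    diag(sys$dim) + 0i,
    ignore_attr = TRUE
  )
  op <- matrix(c(1, 2 + 1i, 2 - 1i, -3), 2, 2) # Hermitian
  emb <- embed_operator(op, 3, sys)
  expect_equal(
    sum(diag(emb)),
    sum(diag(op)) * (sys$dim / 2) + 0i
  )
  expect_lt(max(Mod(emb - Conj(t(emb)))), 1e-12)
  # operators embedded at different slots commute
  a <- embed_operator(spin_matrices(1 / 2)$x, 1, sys)
  b <- embed_operator(spin_matrices(1)$y, 4, sys)
  expect_lt(max(Mod(a %*% b - b %*% a)), 1e-12)
  expect_error(embed_operator(diag(3), 1, sys), "dimension")
  expect_error(embed_operator(diag(2), 9, sys), "slot")
})

test_that("the singlet projector is a Hermitian rank-M projector fixing singlet states", {
  for (nucs in list(list(a = numeric(), b = numeric()),
                    list(a = 1 / 2, b = numeric()),
                    list(a = 1 / 2, b = 5 / 2))) {
    sys <- spin_system(nuclei_a = nucs$a, nuclei_b = nucs$b)
    P <- singlet_projector(sys)
    expect_lt(max(Mod(P - Conj(t(P)))), 1e-12)
    expect_lt(max(Mod(P %*% P - P)), 1e-12)
    expect_equal(Re(sum(diag(P))), sys$M, tolerance = 1e-12)
    ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(abs(ev) < 1e-10 | abs(ev - 1) < 1e-10))
    expect_equal(sum(ev > 0.5), sys$M)
    # the singlet (x) nuclear basis state is an eigenvector with eigenvalue 1
    v <- singlet_state(sys, nuclear_index = sys$M)
    expect_lt(max(Mod(P %*% v - v)), 1e-12)
  }
})
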