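# Shared helpers: convert generator rows to parameter objects and provide
# small independent references.

row_to_pair <- function(row) {
  list(
    params = radical_pair(
      B = row$b, a_A = row$a_a, spin_A = row$spin_a,
      a_B = row$a_b, spin_B = row$spin_b, label = "synthetic"
    ),
    kin = kinetics(row$k, row$r)
  )
}

# Closed-form yield when both hyperfine couplings vanish: the singlet
# probability stays 1 under H, relaxes toward 1/4 at rate r, and is sampled
# at rate k.
phi_no_hyperfine <- function(k, r) 0.25 + 0.75 * k / (k + r)

# Frobenius-norm relative difference.
rel_mat_diff <- function(a, b) {
  max(Mod(a - b)) / max(1, max(Mod(a)))
}

# Two-electron singlet column vector tensored with a nuclear basis state.
singlet_state <- function(system, nuclear_index = 1) {
  s <- matrix(0 + 0i, 4, 1)
  s[2] <- 1 / sqrt(2) # |up down>
  s[3] <- -1 / sqrt(2) # |down up>
  nuc <- matrix(0 + 0i, system$M, 1)
  nuc[nuclear_index] <- 1
  s %x% nuc
}
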