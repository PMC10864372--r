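## Radical-pair parameter objects and the Zeeman + hyperfine Hamiltonian.

.constants_env <- new.env(parent = emptyenv())

#' Model constants for the NMDAR radical-pair system
#'
#' Reads the packaged constants bundle: free-electron g, the control and
#' exposure field strengths (0.15 and 100 mT), the dominant proton hyperfine
#' coupling of each oxyradical pathway (Ser 7.45 mT, Tyr 1.86 mT, both
#' spin 1/2), and the magnesium isotope table (90% spin-0, 10% spin-5/2
#' with a = -11.22 mT).
#'
#' @return A named list mirroring the JSON constants file.
#' @export
rp_constants <- function() {
  if (is.null(.constants_env$constants)) {
    path <- system.file("extdata", "radical_pair_constants.json",
      package = "radicalpair", mustWork = TRUE
    )
    .constants_env$constants <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  .constants_env$constants
}

#' Radical-pair physical parameters
#'
#' One spin-carrying nucleus per radical (the dominant-hyperfine
#' approximation): radical A is the oxyradical with its largest-coupling
#' proton, radical B the hydrated magnesium cation whose nucleus is spinful
#' only for the 25Mg isotopologue.
#'
#' @param B Magnetic flux density, mT (non-negative).
#' @param a_A Hyperfine coupling of the radical-A nucleus, mT (signed).
#' @param spin_A Spin quantum number of that nucleus (half-integer; 0 drops it).
#' @param a_B Hyperfine coupling of the radical-B nucleus, mT (signed).
#' @param spin_B Its spin quantum number (0 for 24/26Mg, 5/2 for 25Mg).
#' @param g Electron g-factor; both electrons share it.
#' @param label Pathway tag ("Ser", "Tyr", or free text).
#' @return An object of class `rp_params`.
#' @examples
#' ser_radical_pair(B = 100)
#' @export
radical_pair <- function(B, a_A, spin_A = 1 / 2, a_B = 0, spin_B = 0,
                         g = g_free_electron, label = "custom") {
  num1 <- function(x, nm, finite = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      abort(sprintf("`%s` must be a single finite number.", nm))
    }
    x
  }
  B <- num1(B, "B")
  if (B < 0) abort("`B` must be non-negative (mT).")
  g <- num1(g, "g")
  if (g <= 0) abort("`g` must be positive.")
  a_A <- num1(a_A, "a_A")
  a_B <- num1(a_B, "a_B")
  if (!is_half_integer(spin_A) || !is_half_integer(spin_B)) {
    abort("`spin_A` and `spin_B` must be non-negative half-integers.")
  }
  structure(
    list(
      B = B, g = g, a_A = a_A, spin_A = spin_A,
      a_B = a_B, spin_B = spin_B, label = as.character(label)
    ),
    class = "rp_params"
  )
}

#' @export
print.rp_params <- function(x, ...) {
  cat(sprintf(
    "<rp_params: %s>  B = %g mT, g = %g\n  a_A = %g mT (spin %g), a_B = %g mT (spin %g)\n",
    x$label, x$B, x$g, x$a_A, x$spin_A, x$a_B, x$spin_B
  ))
  invisible(x)
}

#' @rdname radical_pair
#' @export
ser_radical_pair <- function(B = rp_constants()$B0_mT) {
  cst <- rp_constants()
  radical_pair(
    B = B, a_A = cst$pathways$Ser$a_A_mT, spin_A = cst$pathways$Ser$spin_A,
    g = cst$g, label = "Ser"
  )
}

#' @rdname radical_pair
#' @export
tyr_radical_pair <- function(B = rp_constants()$B0_mT) {
  cst <- rp_constants()
  radical_pair(
    B = B, a_A = cst$pathways$Tyr$a_A_mT, spin_A = cst$pathways$Tyr$spin_A,
    g = cst$g, label = "Tyr"
  )
}

## Copy params with a different field / radical-B nucleus.
with_field <- function(params, B) {
  radical_pair(
    B = B, a_A = params$a_A, spin_A = params$spin_A,
    a_B = params$a_B, spin_B = params$spin_B, g = params$g, label = params$label
  )
}

with_isotope <- function(params, spin_B, a_B) {
  radical_pair(
    B = params$B, a_A = params$a_A, spin_A = params$spin_A,
    a_B = a_B, spin_B = spin_B, g = params$g, label = params$label
  )
}

#' Magnesium isotope table at natural abundance
#'
#' Spin-0 isotopes (24Mg and 26Mg) are lumped into one 90% component, since
#' spin-0 isotopologues are spectroscopically identical in this model; the
#' spinful 25Mg (spin 5/2, a = -11.22 mT) carries the remaining 10%.
#'
#' @return A tibble with columns `isotope`, `weight`, `spin`, `a` (mT).
#' @export
mg_isotope_table <- function() {
  iso <- rp_constants()$mg_isotopes
  tibble(
    isotope = iso$isotope, weight = iso$weight,
    spin = iso$spin, a = iso$a_mT
  )
}

#' Reaction and relaxation kinetics
#'
#' @param k Singlet/triplet recombination rate, s^-1 (positive; singlet and
#'   triplet channels are assumed to react at the same rate).
#' @param r Phenomenological spin relaxation rate, s^-1 (non-negative),
#'   mixing the electron pair toward the fully mixed state.
#' @return An object of class `rp_kinetics`.
#' @export
kinetics <- function(k, r) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    abort("`k` must be a single positive rate (s^-1).")
  }
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r < 0) {
    abort("`r` must be a single non-negative rate (s^-1).")
  }
  structure(list(k = k, r = r), class = "rp_kinetics")
}

#' @export
print.rp_kinetics <- function(x, ...) {
  cat(sprintf("<rp_kinetics>  k = %g s^-1, r = %g s^-1\n", x$k, x$r))
  invisible(x)
}

#' Zeeman + isotropic hyperfine Hamiltonian
#'
#' Builds `H = omega (S_Az + S_Bz) + a_A S_A . I_A + a_B S_B . I_B` in
#' angular-frequency units (rad/s), with `omega` the electron Larmor
#' frequency at field `B` and both hyperfine constants converted from mT by
#' the same gyromagnetic factor. Spin-0 nuclei contribute no term and no
#' tensor factor, so the Hilbert dimension is `4 * (2 spin_A + 1) *
#' (2 spin_B + 1)` over the spinful nuclei only. Nuclear Zeeman terms are
#' neglected (three orders of magnitude below the electron term).
#'
#' @param params An [radical_pair()] parameter set.
#' @param dim_cap Guard against accidentally huge synthetic spaces; the
#'   build refuses when `4 M` exceeds it.
#' @return An object of class `rp_hamiltonian`: list with the complex
#'   Hermitian `matrix` (rad/s), the [spin_system()] `system`, and the
#'   echoed `params`.
#' @examples
#' h <- build_hamiltonian(ser_radical_pair(B = 100))
#' dim(h$matrix) # 8 x 8: spin-0 Mg drops out
#' @export
build_hamiltonian <- function(params, dim_cap = 256) {
  stopifnot(inherits(params, "rp_params"))
  system <- spin_system(
    nuclei_a = if (params$spin_A > 0) params$spin_A else numeric(),
    nuclei_b = if (params$spin_B > 0) params$spin_B else numeric()
  )
  if (system$dim > dim_cap) {
    abort(sprintf(
      "Hilbert dimension %d exceeds dim_cap = %d.", system$dim, dim_cap
    ))
  }
  SA <- embedded_spin(1 / 2, 1L, system)
  SB <- embedded_spin(1 / 2, 2L, system)
  omega <- larmor_frequency(params$B, params$g)
  H <- omega * (SA$z + SB$z)
  slot <- 3L
  if (params$spin_A > 0) {
    IA <- embedded_spin(params$spin_A, slot, system)
    H <- H + mT_to_angular(params$a_A, params$g) *
      (SA$x %*% IA$x + SA$y %*% IA$y + SA$z %*% IA$z)
    slot <- slot + 1L
  }
  if (params$spin_B > 0) {
    IB <- embedded_spin(params$spin_B, slot, system)
    H <- H + mT_to_angular(params$a_B, params$g) *
      (SB$x %*% IB$x + SB$y %*% IB$y + SB$z %*% IB$z)
  }
  attr(H, "basis") <- system$basis
  structure(
    list(matrix = H, system = system, params = params),
    class = "rp_hamiltonian"
  )
}

#' @export
print.rp_hamiltonian <- function(x, ...) {
  cat(sprintf(
    "<rp_hamiltonian: %s>  dim %d, B = %g mT\n",
    x$params$label, x$system$dim, x$params$B
  ))
  invisible(x)
}

#' Eigensystem of a radical-pair Hamiltonian
#'
#' @param ham An [build_hamiltonian()] result.
#' @return An object of class `rp_eigensystem`: real eigenvalues `values`
#'   (angular frequencies, rad/s), the unitary `vectors` matrix whose columns
#'   are eigenstates, plus the `system` and `params`.
#' @export
eigensystem <- function(ham) {
  stopifnot(inherits(ham, "rp_hamiltonian"))
  es <- eigen(ham$matrix, symmetric = TRUE)
  structure(
    list(
      values = es$values, vectors = es$vectors,
      system = ham$system, params = ham$params
    ),
    class = "rp_eigensystem"
  )
}
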