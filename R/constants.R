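## CODATA 2018 values.
.mu_B <- 9.2740100783e-24 # Bohr magneton, J/T
.hbar <- 1.054571817e-34 # reduced Planck constant, J s

#' Free-electron g-factor used throughout the package
#'
#' Both radical electrons are assumed to carry the free-electron g-value,
#' a good approximation at the sub-tesla fields considered here.
#'
#' @export
g_free_electron <- 2.00232

#' Electron gyromagnetic ratio
#'
#' @param g Electron g-factor (dimensionless).
#' @return Gyromagnetic ratio in rad s^-1 T^-1.
#' @export
gyromagnetic_ratio <- function(g = g_free_electron) {
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g <= 0) {
    abort("`g` must be a single positive number.")
  }
  g * .mu_B / .hbar
}

#' Electron Larmor angular frequency
#'
#' Converts a magnetic flux density to the electron Larmor angular frequency
#' `omega = g * mu_B * B / hbar`. The same conversion factor is applied to
#' hyperfine coupling constants quoted in millitesla, so that every term of
#' the spin Hamiltonian lives in angular-frequency units and can be compared
#' directly with reaction and relaxation rates in s^-1.
#'
#' @param B Magnetic flux density in mT (non-negative).
#' @param g Electron g-factor.
#' @return Angular frequency in rad/s.
#' @examples
#' larmor_frequency(100) # ~1.76e10 rad/s
#' @export
larmor_frequency <- function(B, g = g_free_electron) {
  if (!is.numeric(B) || any(!is.finite(B)) || any(B < 0)) {
    abort("`B` must be non-negative and finite (mT).")
  }
  gyromagnetic_ratio(g) * B * 1e-3
}

## Signed mT -> rad/s conversion for hyperfine constants (sign preserved).
mT_to_angular <- function(a, g = g_free_electron) {
  gyromagnetic_ratio(g) * a * 1e-3
}
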