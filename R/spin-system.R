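## Composite-space bookkeeping and spin-operator algebra.
##
## Fixed tensor ordering everywhere: electron A, electron B, then the nuclei
## of radical A in list order, then the nuclei of radical B in list order.
## Every operator built here carries a `basis` attribute naming that ordering
## so that basis mismatches fail loudly rather than silently.

.basis_note <- function(system) {
  sprintf(
    "electron A (x) electron B (x) nuclei A [%s] (x) nuclei B [%s]",
    paste(format(system$nuclei_a), collapse = ", "),
    paste(format(system$nuclei_b), collapse = ", ")
  )
}

is_half_integer <- function(s, tol = 1e-9) {
  is.numeric(s) & is.finite(s) & s >= 0 & abs(2 * s - round(2 * s)) < tol
}

#' Composite spin system of a radical pair
#'
#' Describes the Hilbert space of two radical electrons (spin 1/2 each) plus
#' an arbitrary set of nuclear spins on each radical. The tensor-factor
#' ordering is fixed: electron A, electron B, nuclei of A (in list order),
#' nuclei of B (in list order). Spin-0 nuclei are retained in the record but
#' contribute trivial one-dimensional factors.
#'
#' @param nuclei_a,nuclei_b Numeric vectors of nuclear spin quantum numbers
#'   (non-negative half-integers) on radicals A and B.
#' @return An object of class `rp_spin_system` with fields `nuclei_a`,
#'   `nuclei_b`, the nuclear multiplicities `M_A`, `M_B`, `M` (products of
#'   `2I + 1`), the total Hilbert dimension `dim = 4 * M`, the per-factor
#'   dimensions `factor_dims`, and a `basis` note.
#' @examples
#' spin_system(nuclei_a = 1 / 2, nuclei_b = 5 / 2) # dim 48
#' @export
spin_system <- function(nuclei_a = numeric(), nuclei_b = numeric()) {
  nuclei_a <- as.numeric(nuclei_a)
  nuclei_b <- as.numeric(nuclei_b)
  if (!all(is_half_integer(nuclei_a)) || !all(is_half_integer(nuclei_b))) {
    abort("Every nuclear spin must be a non-negative half-integer (0, 1/2, 1, ...).")
  }
  M_A <- prod(2 * nuclei_a + 1)
  M_B <- prod(2 * nuclei_b + 1)
  M <- M_A * M_B
  sys <- structure(
    list(
      electron_count = 2L,
      nuclei_a = nuclei_a,
      nuclei_b = nuclei_b,
      M_A = as.integer(round(M_A)),
      M_B = as.integer(round(M_B)),
      M = as.integer(round(M)),
      dim = as.integer(round(4 * M)),
      factor_dims = as.integer(round(c(2, 2, 2 * nuclei_a + 1, 2 * nuclei_b + 1)))
    ),
    class = "rp_spin_system"
  )
  sys$basis <- .basis_note(sys)
  sys
}

#' @export
print.rp_spin_system <- function(x, ...) {
  cat("<rp_spin_system>\n")
  cat("  dim:", x$dim, " (4 x M, M =", x$M, ")\n")
  cat("  basis:", x$basis, "\n")
  invisible(x)
}

#' Angular-momentum matrices for an arbitrary spin
#'
#' Standard ladder-operator construction in the `|s, m>` basis ordered
#' `m = s, s - 1, ..., -s`. The z component is diagonal; x and y follow from
#' the raising/lowering operators, so `[Sx, Sy] = i Sz` and
#' `Sx^2 + Sy^2 + Sz^2 = s (s + 1) I` hold to machine precision.
#'
#' @param s Spin quantum number, a non-negative half-integer.
#' @return A list with complex `(2s+1) x (2s+1)` matrices `x`, `y`, `z`.
#' @examples
#' spin_matrices(1 / 2)$z # diag(1/2, -1/2)
#' @export
spin_matrices <- function(s) {
  if (length(s) != 1L || !is_half_integer(s)) {
    abort("`s` must be a single non-negative half-integer.")
  }
  m <- seq(s, -s, by = -1)
  if (s == 0) m <- 0
  d <- length(m)
  Sp <- matrix(0 + 0i, d, d)
  if (d > 1L) {
    for (i in seq_len(d - 1L)) {
      Sp[i, i + 1L] <- sqrt(s * (s + 1) - m[i + 1L] * (m[i + 1L] + 1))
    }
  }
  Sm <- Conj(t(Sp))
  list(
    x = (Sp + Sm) / 2,
    y = (Sp - Sm) / (2i),
    z = diag(m, d, d) + 0i
  )
}

#' Embed a single-factor operator into the composite space
#'
#' Forms `I (x) ... (x) op (x) ... (x) I` with `op` at the given tensor slot
#' of the system's fixed factor ordering (slot 1 = electron A, slot 2 =
#' electron B, then nuclei of A, then nuclei of B).
#'
#' @param op Square complex matrix acting on one factor.
#' @param slot Factor index (1-based) in the fixed ordering.
#' @param system An [spin_system()].
#' @return A `system$dim`-dimensional complex matrix with a `basis` attribute.
#' @export
embed_operator <- function(op, slot, system) {
  stopifnot(inherits(system, "rp_spin_system"))
  dims <- system$factor_dims
  if (!is.numeric(slot) || length(slot) != 1L || slot < 1 || slot > length(dims)) {
    abort(sprintf("`slot` must be in 1..%d.", length(dims)))
  }
  op <- as.matrix(op)
  if (nrow(op) != ncol(op) || nrow(op) != dims[slot]) {
    abort(sprintf(
      "Operator dimension %d does not match factor %d (dimension %d).",
      nrow(op), slot, dims[slot]
    ))
  }
  out <- matrix(1 + 0i, 1, 1)
  for (j in seq_along(dims)) {
    f <- if (j == slot) op + 0i else diag(dims[j]) + 0i
    out <- out %x% f
  }
  attr(out, "basis") <- system$basis
  out
}

## Embedded x/y/z components of one spin factor.
embedded_spin <- function(s, slot, system) {
  lapply(spin_matrices(s), embed_operator, slot = slot, system = system)
}

#' Singlet projection operator
#'
#' The projector onto the two-electron singlet subspace,
#' `P_S = 1/4 I - S_A . S_B`, acting as identity on every nuclear factor.
#' It is Hermitian, idempotent, and has rank `M` (one singlet level per
#' nuclear spin configuration).
#'
#' @param system An [spin_system()] with two electrons.
#' @return A `dim x dim` complex matrix with a `basis` attribute.
#' @export
singlet_projector <- function(system) {
  stopifnot(inherits(system, "rp_spin_system"))
  if (system$electron_count != 2L) {
    abort("The singlet projector is defined for exactly two electrons.")
  }
  SA <- embedded_spin(1 / 2, 1L, system)
  SB <- embedded_spin(1 / 2, 2L, system)
  P <- 0.25 * diag(system$dim) -
    (SA$x %*% SB$x + SA$y %*% SB$y + SA$z %*% SB$z)
  attr(P, "basis") <- system$basis
  P
}

## Total z angular momentum (electrons + all nuclei); conserved by the
## isotropic-hyperfine + z-Zeeman Hamiltonian.
total_jz <- function(system) {
  dims <- system$factor_dims
  spins <- c(1 / 2, 1 / 2, system$nuclei_a, system$nuclei_b)
  J <- matrix(0 + 0i, system$dim, system$dim)
  for (slot in seq_along(dims)) {
    J <- J + embed_operator(spin_matrices(spins[slot])$z, slot, system)
  }
  attr(J, "basis") <- system$basis
  J
}

is_hermitian <- function(m, tol = 1e-10) {
  max(Mod(m - Conj(t(m)))) <= tol * max(1, max(Mod(m)))
}
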