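## Field sweeps and k-r plane scans of the yield ratio.

#' Default magnetic-field grid for sweeps
#'
#' Log-spaced points across the scan range plus a linear refinement of the
#' weak-field window, where the low-field dip and the isotope spikes are
#' narrow features.
#'
#' @param b_min,b_max Field range, mT.
#' @param n_log Log-spaced point count across the full range.
#' @param refine_below Upper edge of the linearly refined weak-field
#'   window, mT.
#' @param n_refine Linear point count inside that window.
#' @return Sorted numeric vector of field strengths (mT).
#' @export
default_field_grid <- function(b_min = 0.15, b_max = 100, n_log = 400,
                               refine_below = 2, n_refine = 100) {
  stopifnot(b_min > 0, b_max > b_min)
  grid <- exp(seq(log(b_min), log(b_max), length.out = n_log))
  if (refine_below > b_min && n_refine > 0) {
    grid <- c(grid, seq(b_min, min(refine_below, b_max), length.out = n_refine))
  }
  sort(unique(grid))
}

## Eigen-cache entry for one (field, isotopologue): everything the closed
## form needs except the kinetics, so one diagonalisation serves every
## (k, r) cell.
.yield_cache_entry <- function(params, spin_B, a_B, B) {
  p <- with_field(with_isotope(params, spin_B, a_B), B)
  es <- eigensystem(build_hamiltonian(p))
  P <- singlet_projector(es$system)
  V <- es$vectors
  Pmn <- Conj(t(V)) %*% P %*% V
  list(
    W2 = Mod(Pmn)^2 / es$system$M,
    dw = outer(es$values, es$values, "-")
  )
}

.cached_phi <- function(entry, k, r) {
  kr <- k + r
  sum(entry$W2 * (k * kr) / (kr^2 + entry$dw^2)) - k / (4 * kr) + 0.25
}

#' Sweep the singlet yield over magnetic field strength
#'
#' Computes the isotope-averaged fractional singlet yield at each field in
#' `b_values`, returning the per-isotopologue curves alongside the
#' abundance-weighted one.
#'
#' @param params An [radical_pair()] parameter set (its `B` is ignored).
#' @param kin An [kinetics()] object.
#' @param b_values Strictly increasing field strengths, mT.
#' @param isotopes Isotope table, as in [isotope_averaged_yield()].
#' @return A tibble of class `rp_field_sweep` with columns `b` (mT),
#'   `component` (isotopologue name or `"weighted"`), and `phi_s`.
#'   Attributes carry the parameters and kinetics used.
#' @examples
#' field_sweep(ser_radical_pair(), kinetics(2e6, 1e6),
#'   b_values = c(0.15, 1, 10, 100)
#' )
#' @export
field_sweep <- function(params, kin, b_values = default_field_grid(),
                        isotopes = mg_isotope_table()) {
  stopifnot(inherits(params, "rp_params"), inherits(kin, "rp_kinetics"))
  if (is.unsorted(b_values, strictly = TRUE)) {
    abort("`b_values` must be strictly increasing.")
  }
  isotopes <- as_tibble(isotopes)
  rows <- purrr::map(b_values, function(b) {
    y <- isotope_averaged_yield(with_field(params, b), kin, isotopes)
    dplyr::bind_rows(
      y$components |> dplyr::transmute(
        b = b, component = .data$isotope, phi_s = .data$phi_s
      ),
      tibble(b = b, component = "weighted", phi_s = y$phi_s)
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(
    out,
    class = c("rp_field_sweep", class(out)),
    params = params, kinetics = kin, isotopes = isotopes
  )
}

#' Scan the yield ratio over the reaction/relaxation rate plane
#'
#' Evaluates `S = Phi_S(b_exp) / Phi_S(b_0)` (isotope-averaged) on a grid of
#' recombination rates `k` and relaxation rates `r`. The Hamiltonian does
#' not depend on the kinetics, so each of the four (field, isotopologue)
#' eigensystems is computed once and re-used across all grid cells; set
#' `cache = FALSE` to force the naive cell-by-cell route (used to verify
#' caching correctness).
#'
#' @param params An [radical_pair()] parameter set.
#' @param k_values,r_values Positive rate grids, s^-1; default 50 x 50
#'   log-spaced over `[1e5, 1e8]`, bracketing rates typical of radical-pair
#'   chemistry.
#' @param b_exp,b_0 Exposure and control fields, mT.
#' @param isotopes Isotope table.
#' @param cache Re-use eigensystems across cells (default) or not.
#' @return A tibble of class `rp_kr_scan` with columns `k`, `r`, `s`, plus
#'   grid and field attributes.
#' @export
kr_scan <- function(params,
                    k_values = 10^seq(5, 8, length.out = 50),
                    r_values = 10^seq(5, 8, length.out = 50),
                    b_exp = rp_constants()$Bexp_mT,
                    b_0 = rp_constants()$B0_mT,
                    isotopes = mg_isotope_table(),
                    cache = TRUE) {
  stopifnot(inherits(params, "rp_params"))
  if (length(k_values) < 1L || length(r_values) < 1L ||
    any(k_values <= 0) || any(r_values < 0)) {
    abort("Rate grids must be non-empty and positive.")
  }
  isotopes <- as_tibble(isotopes)
  cells <- tidyr::expand_grid(k = k_values, r = r_values)
  if (cache) {
    entries <- purrr::map(c(b_exp, b_0), function(b) {
      purrr::map2(
        isotopes$spin, isotopes$a,
        function(sp, a) .yield_cache_entry(params, sp, a, b)
      )
    })
    w <- isotopes$weight
    s_of <- function(k, r) {
      phi <- purrr::map_dbl(entries, function(ent) {
        sum(w * purrr::map_dbl(ent, .cached_phi, k = k, r = r))
      })
      phi[1L] / phi[2L]
    }
    cells$s <- purrr::map2_dbl(cells$k, cells$r, s_of)
  } else {
    cells$s <- purrr::map2_dbl(cells$k, cells$r, function(k, r) {
      yield_ratio(params, kinetics(k, r), b_exp = b_exp, b_0 = b_0,
        isotopes = isotopes
      )
    })
  }
  if (any(!is.finite(cells$s))) abort("Scan produced a non-finite cell.")
  structure(
    cells,
    class = c("rp_kr_scan", class(cells)),
    k_values = k_values, r_values = r_values,
    b_exp = b_exp, b_0 = b_0, params = params
  )
}

#' Contiguous above-threshold region of a k-r scan
#'
#' Thresholds the scan at `s >= threshold` and returns the 4-connected
#' component (in grid topology) containing the cell nearest to `(k0, r0)` in
#' log-rate space. Used to check that the quoted kinetics sit inside a
#' contiguous high-ratio region of the plane.
#'
#' @param scan An [kr_scan()] result.
#' @param threshold Ratio threshold.
#' @param k0,r0 Rates (s^-1) picking the seed cell.
#' @return A tibble of the cells in the component (possibly empty when the
#'   seed cell is below threshold), with a `seed` logical column.
#' @export
scan_component <- function(scan, threshold = 1.2, k0 = 2e6, r0 = 1e6) {
  stopifnot(inherits(scan, "rp_kr_scan"))
  kv <- attr(scan, "k_values")
  rv <- attr(scan, "r_values")
  S <- matrix(NA_real_, length(kv), length(rv))
  S[cbind(
    match(scan$k, kv),
    match(scan$r, rv)
  )] <- scan$s
  mask <- S >= threshold
  i0 <- which.min(abs(log(kv) - log(k0)))
  j0 <- which.min(abs(log(rv) - log(r0)))
  comp <- matrix(FALSE, length(kv), length(rv))
  if (isTRUE(mask[i0, j0])) {
    stack <- list(c(i0, j0))
    comp[i0, j0] <- TRUE
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ni <- cur[1] + d[1]
        nj <- cur[2] + d[2]
        if (ni >= 1 && ni <= nrow(comp) && nj >= 1 && nj <= ncol(comp) &&
          !comp[ni, nj] && isTRUE(mask[ni, nj])) {
          comp[ni, nj] <- TRUE
          stack[[length(stack) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  idx <- which(comp, arr.ind = TRUE)
  tibble(
    k = kv[idx[, 1]], r = rv[idx[, 2]],
    s = S[idx],
    seed = idx[, 1] == i0 & idx[, 2] == j0
  )
}
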