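## Synthetic inputs: randomized radical-pair configurations for property
## testing and Ca-uptake-shaped tables with a prescribed amplification.

#' Random radical-pair configurations
#'
#' Draws reproducible radical-pair parameter sets for property testing:
#' nuclear spins from `spin_choices` (one nucleus per radical), signed
#' hyperfine constants up to `a_max`, fields up to `b_max`, and log-uniform
#' kinetics. Spin combinations whose Hilbert dimension would exceed
#' `dim_cap` are rejected and redrawn.
#'
#' @param n Number of configurations.
#' @param seed Integer seed; identical seeds give identical draws.
#' @param spin_choices Candidate nuclear spin quantum numbers.
#' @param a_max Hyperfine magnitude bound, mT.
#' @param b_max Field bound, mT.
#' @param k_range,r_range Rate ranges (s^-1), sampled log-uniformly.
#' @param dim_cap Maximum Hilbert dimension.
#' @return A tibble with columns `id`, `spin_a`, `a_a`, `spin_b`, `a_b`,
#'   `b`, `k`, `r`, `dim`.
#' @export
random_radical_pairs <- function(n = 1, seed = 1,
                                 spin_choices = c(0, 1 / 2, 1, 3 / 2, 5 / 2),
                                 a_max = 20, b_max = 200,
                                 k_range = c(1e4, 1e8),
                                 r_range = c(1e4, 1e8),
                                 dim_cap = 48) {
  if (length(spin_choices) == 0L) abort("`spin_choices` must be non-empty.")
  if (!all(is_half_integer(spin_choices))) {
    abort("`spin_choices` must be non-negative half-integers.")
  }
  stopifnot(
    n >= 1, a_max > 0, b_max > 0,
    all(k_range > 0), all(r_range > 0), dim_cap >= 4
  )
  if (!any(4 * (2 * spin_choices + 1) %o% (2 * spin_choices + 1) <= dim_cap)) {
    abort("No spin combination fits within `dim_cap`.")
  }
  withr::with_seed(as.integer(seed), {
    draw_one <- function(id) {
      repeat {
        spin_a <- sample(spin_choices, 1)
        spin_b <- sample(spin_choices, 1)
        d <- 4 * (2 * spin_a + 1) * (2 * spin_b + 1)
        if (d <= dim_cap) break
      }
      tibble(
        id = id,
        spin_a = spin_a,
        a_a = runif(1, -a_max, a_max),
        spin_b = spin_b,
        a_b = runif(1, -a_max, a_max),
        b = runif(1, 0, b_max),
        k = exp(runif(1, log(k_range[1]), log(k_range[2]))),
        r = exp(runif(1, log(r_range[1]), log(r_range[2]))),
        dim = d
      )
    }
    dplyr::bind_rows(purrr::map(seq_len(n), draw_one))
  })
}

## Convenience: one drawn row -> (rp_params, rp_kinetics).
as_radical_pair <- function(row) {
  list(
    params = radical_pair(
      B = row$b, a_A = row$a_a, spin_A = row$spin_a,
      a_B = row$a_b, spin_B = row$spin_b, label = "synthetic"
    ),
    kinetics = kinetics(row$k, row$r)
  )
}

#' Synthetic calcium-uptake table
#'
#' Builds a table shaped like the experimental ones: a saturating
#' (Michaelis-Menten) control curve over NMDA concentration, and a field
#' column equal to control times a per-row ratio that declines linearly
#' with concentration rank, with the mean ratio pinned exactly to the
#' requested amplification factor. An optional seeded jitter perturbs the
#' control curve only, so the ratio structure is preserved.
#'
#' @param seed Integer seed for the jitter.
#' @param n_rows Number of concentration rows.
#' @param nmda_um NMDA concentrations (strictly increasing); default a
#'   log-like series of length `n_rows`.
#' @param amplification Requested mean field/control ratio (> 0).
#' @param ratio_spread Total decline of the ratio from first to last row.
#' @param control_max,control_km Saturation level (%) and half-saturation
#'   concentration of the control curve.
#' @param jitter_sd Relative s.d. of the multiplicative control jitter.
#' @return A tibble of class `rp_ca_table`.
#' @export
synthetic_ca_table <- function(seed = 1, n_rows = 5,
                               nmda_um = NULL,
                               amplification = 1.5,
                               ratio_spread = 0.6,
                               control_max = 30, control_km = 5,
                               jitter_sd = 0.02) {
  stopifnot(n_rows >= 1, amplification > 0, ratio_spread >= 0)
  nmda_um <- nmda_um %||% round(10^seq(0, 2, length.out = n_rows), 2)
  if (length(nmda_um) != n_rows || is.unsorted(nmda_um, strictly = TRUE)) {
    abort("`nmda_um` must be strictly increasing with length `n_rows`.")
  }
  offsets <- if (n_rows == 1L) {
    0
  } else {
    seq(ratio_spread / 2, -ratio_spread / 2, length.out = n_rows)
  }
  ratio <- amplification + offsets
  if (any(ratio <= 0)) {
    abort("`ratio_spread` too large for this amplification: ratios must stay positive.")
  }
  control <- withr::with_seed(as.integer(seed), {
    base <- control_max * nmda_um / (control_km + nmda_um)
    base * exp(stats::rnorm(n_rows, 0, jitter_sd))
  })
  field <- control * ratio
  if (any(c(control, field) <= 0) || any(c(control, field) > 100)) {
    abort("Generated percentages fall outside (0, 100]; adjust the control curve.")
  }
  structure(
    tibble(
      nmda_um = nmda_um,
      control_pct = control,
      field_pct = field
    ),
    class = c("rp_ca_table", class(tibble())),
    exposure = "synthetic"
  )
}
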