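## Qualitative features of the yield-vs-field curve: the low-field dip and
## the 25Mg level-crossing spikes.

## Classic peak prominence on a sampled curve: for each interior local
## maximum, walk outward until a strictly higher sample (or the edge),
## track the deepest valley on each side, and take peak - max(valleys).
.peak_prominences <- function(x) {
  n <- length(x)
  if (n < 3L) {
    return(tibble(index = integer(), prominence = numeric()))
  }
  idx <- which(diff(sign(diff(x))) < 0) + 1L
  prom <- purrr::map_dbl(idx, function(i) {
    left_min <- x[i]
    j <- i - 1L
    while (j >= 1L && x[j] <= x[i]) {
      left_min <- min(left_min, x[j])
      j <- j - 1L
    }
    right_min <- x[i]
    j <- i + 1L
    while (j <= n && x[j] <= x[i]) {
      right_min <- min(right_min, x[j])
      j <- j + 1L
    }
    x[i] - max(left_min, right_min)
  })
  tibble(index = idx, prominence = prom)
}

#' Detect the low-field dip of a yield sweep
#'
#' Searches the weighted yield curve for the drop at very weak field (the
#' low field effect: lifting of zero-field degeneracies among
#' hyperfine-coupled states transiently enhances singlet-triplet mixing).
#' The minimum of `Phi_S` inside the weak-field window is located and its
#' depth reported against two references, computed fresh from the sweep's
#' parameters: the exact zero-field yield and the yield at the control
#' field `b_0`. No dip is reported when the curve is flat or the minimum
#' sits at the window edge.
#'
#' @param sweep An [field_sweep()] result whose grid covers the sub-`window`
#'   region with at least `min_points` points.
#' @param window Upper edge of the weak-field search window, mT.
#' @param b_0 Control field (mT) for the second depth reference.
#' @param min_points Guard: minimum sweep points required below `window`.
#' @return A one-row tibble: `dip` (logical), `b_min`, `phi_min`,
#'   `phi_zero`, `phi_b0`, `depth_vs_zero`, `depth_vs_b0`.
#' @export
detect_low_field_dip <- function(sweep, window = 2,
                                 b_0 = rp_constants()$B0_mT,
                                 min_points = 20L) {
  stopifnot(inherits(sweep, "rp_field_sweep"))
  params <- attr(sweep, "params")
  kin <- attr(sweep, "kinetics")
  isotopes <- attr(sweep, "isotopes")
  wt <- sweep |> dplyr::filter(.data$component == "weighted")
  inside <- wt |> dplyr::filter(.data$b < window)
  if (nrow(inside) < min_points) {
    abort(sprintf(
      "Only %d sweep points below %g mT; >= %d needed to resolve the dip.",
      nrow(inside), window, min_points
    ))
  }
  phi_zero <- isotope_averaged_yield(with_field(params, 0), kin, isotopes)$phi_s
  phi_b0 <- isotope_averaged_yield(with_field(params, b_0), kin, isotopes)$phi_s
  i_min <- which.min(inside$phi_s)
  at_edge <- i_min == nrow(inside)
  depth_zero <- phi_zero - inside$phi_s[i_min]
  tibble(
    dip = !at_edge && depth_zero > 1e-12,
    b_min = inside$b[i_min],
    phi_min = inside$phi_s[i_min],
    phi_zero = phi_zero,
    phi_b0 = phi_b0,
    depth_vs_zero = depth_zero,
    depth_vs_b0 = phi_b0 - inside$phi_s[i_min]
  )
}

#' Detect level-crossing spikes in a single-isotopologue yield curve
#'
#' Sweeps `Phi_S(B)` for the radical pair exactly as parameterised (no
#' isotope averaging; pass the 25Mg parameters to probe the spikes the
#' spinful isotope introduces) and reports narrow local extrema whose
#' prominence exceeds a fraction of the curve's range. Each candidate is
#' cross-referenced against the spectrum: the minimum eigenvalue gap among
#' singlet-coupled state pairs (`|<m|P_S|n>|^2` above `coupling_threshold`,
#' distinct levels) is tracked across the grid, and a spike is flagged
#' `colocated` when that gap attains a local minimum within `match_window`
#' grid points — the energy-overlap signature the spikes arise from. The
#' weak-field window is excluded: the broad low-field dip is a separate
#' feature, reported by [detect_low_field_dip()].
#'
#' @param params An [radical_pair()] parameter set (single isotopologue).
#' @param kin An [kinetics()] object.
#' @param b_values Dense field grid, mT; default 400 log-spaced points over
#'   `[0.15, 100]`.
#' @param prominence_frac Prominence threshold as a fraction of the curve
#'   range.
#' @param coupling_threshold Threshold on `|<m|P_S|n>|^2` defining coupled
#'   state pairs.
#' @param search_above Lower field bound of the spike search, mT.
#' @param match_window Grid-point tolerance for gap/spike co-location.
#' @param min_points Guard: minimum grid size.
#' @return A tibble with one row per spike: `b`, `phi_s`, `prominence`,
#'   `type` (`"peak"`/`"trough"`), `gap_b` (field of the nearest coupled-gap
#'   local minimum), `colocated`.
#' @export
detect_spikes <- function(params, kin,
                          b_values = exp(seq(log(0.15), log(100),
                            length.out = 400
                          )),
                          prominence_frac = 0.01,
                          coupling_threshold = 1e-3,
                          search_above = 2,
                          match_window = 4L,
                          min_points = 100L) {
  stopifnot(inherits(params, "rp_params"), inherits(kin, "rp_kinetics"))
  if (length(b_values) < min_points) {
    abort(sprintf("Need >= %d field points to resolve spikes.", min_points))
  }
  b_values <- sort(b_values)
  per_b <- purrr::map(b_values, function(b) {
    es <- eigensystem(build_hamiltonian(with_field(params, b)))
    P <- singlet_projector(es$system)
    V <- es$vectors
    W2 <- Mod(Conj(t(V)) %*% P %*% V)^2
    phi <- singlet_yield(es, kin, projector = P)
    gap <- outer(es$values, es$values, "-")
    coupled <- W2 > coupling_threshold & row(W2) != col(W2)
    min_gap <- if (any(coupled)) min(abs(gap[coupled])) else NA_real_
    list(phi = phi, min_gap = min_gap)
  })
  phi <- purrr::map_dbl(per_b, "phi")
  min_gap <- purrr::map_dbl(per_b, "min_gap")
  rng <- diff(range(phi))
  if (rng <= 0) {
    return(tibble(
      b = numeric(), phi_s = numeric(), prominence = numeric(),
      type = character(), gap_b = numeric(), colocated = logical()
    ))
  }
  in_search <- b_values >= search_above
  gap_minima <- which(diff(sign(diff(min_gap))) > 0) + 1L
  spikes_of <- function(curve, type) {
    pk <- .peak_prominences(curve)
    pk |>
      dplyr::filter(
        .data$prominence >= prominence_frac * rng,
        in_search[.data$index]
      ) |>
      dplyr::mutate(type = type)
  }
  hits <- dplyr::bind_rows(
    spikes_of(phi, "peak"),
    spikes_of(-phi, "trough")
  )
  if (nrow(hits) == 0L) {
    return(tibble(
      b = numeric(), phi_s = numeric(), prominence = numeric(),
      type = character(), gap_b = numeric(), colocated = logical()
    ))
  }
  hits |>
    dplyr::transmute(
      b = b_values[.data$index],
      phi_s = phi[.data$index],
      prominence = .data$prominence,
      type = .data$type,
      gap_b = purrr::map_dbl(.data$index, function(i) {
        if (length(gap_minima) == 0L) {
          return(NA_real_)
        }
        b_values[gap_minima[which.min(abs(gap_minima - i))]]
      }),
      colocated = purrr::map_lgl(.data$index, function(i) {
        length(gap_minima) > 0L && min(abs(gap_minima - i)) <= match_window
      })
    ) |>
    dplyr::arrange(.data$b)
}
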