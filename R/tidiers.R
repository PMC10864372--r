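## broom-style tidiers for the result objects.

#' Tidy an isotope-averaged yield
#'
#' @param x An `rp_yield` object.
#' @param ... Unused.
#' @return Per-isotopologue rows plus a `"weighted"` row.
#' @export
tidy.rp_yield <- function(x, ...) {
  dplyr::bind_rows(
    x$components,
    tibble(
      isotope = "weighted", weight = 1,
      spin = NA_real_, a = NA_real_, phi_s = x$phi_s
    )
  )
}

#' @rdname tidy.rp_yield
#' @export
glance.rp_yield <- function(x, ...) {
  tibble(
    phi_s = x$phi_s, B = x$B,
    k = x$kinetics$k, r = x$kinetics$r,
    pathway = x$params$label,
    n_isotopologues = nrow(x$components)
  )
}

#' Tidy a field sweep
#'
#' @param x An `rp_field_sweep` object.
#' @param ... Unused.
#' @export
tidy.rp_field_sweep <- function(x, ...) {
  as_tibble(unclass(x)[c("b", "component", "phi_s")])
}

#' @rdname tidy.rp_field_sweep
#' @export
glance.rp_field_sweep <- function(x, ...) {
  wt <- tidy(x) |> dplyr::filter(.data$component == "weighted")
  kin <- attr(x, "kinetics")
  tibble(
    pathway = attr(x, "params")$label,
    k = kin$k, r = kin$r,
    n_fields = nrow(wt),
    b_min = min(wt$b), b_max = max(wt$b),
    phi_min = min(wt$phi_s), phi_max = max(wt$phi_s)
  )
}

#' Tidy a k-r scan
#'
#' @param x An `rp_kr_scan` object.
#' @param ... Unused.
#' @export
tidy.rp_kr_scan <- function(x, ...) {
  as_tibble(unclass(x)[c("k", "r", "s")])
}

#' @rdname tidy.rp_kr_scan
#' @export
glance.rp_kr_scan <- function(x, ...) {
  cells <- tidy(x)
  best <- cells[which.max(cells$s), ]
  tibble(
    pathway = attr(x, "params")$label,
    b_exp = attr(x, "b_exp"), b_0 = attr(x, "b_0"),
    n_cells = nrow(cells),
    s_max = best$s, k_at_max = best$k, r_at_max = best$r
  )
}

#' Tidy a model-vs-experiment comparison
#'
#' @param x An `rp_ca_comparison` object.
#' @param ... Unused.
#' @export
tidy.rp_ca_comparison <- function(x, ...) {
  x$ratios |>
    dplyr::mutate(s_model = x$s, s_minus_ratio = x$s - .data$ratio)
}

#' @rdname tidy.rp_ca_comparison
#' @export
glance.rp_ca_comparison <- function(x, ...) {
  tibble(
    exposure = x$exposure,
    s = x$s,
    mean_ratio = x$mean_ratio,
    s_over_mean = x$s_over_mean,
    within_range = x$within_range
  )
}
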