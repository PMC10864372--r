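kin_fig <- kinetics(k = 2e6, r = 1e6)

test_that("the yield ratio is exactly 1 at equal fields and consistent with direct yields", {
  p <- ser_radical_pair()
  expect_identical(yield_ratio(p, kin_fig, b_exp = 10, b_0 = 10), 1)
  s <- yield_ratio(p, kin_fig, b_exp = 50, b_0 = 0.5)
  hi <- isotope_averaged_yield(radicalpair:::with_field(p, 50), kin_fig)$phi_s
  lo <- isotope_averaged_yield(radicalpair:::with_field(p, 0.5), kin_fig)$phi_s
  expect_equal(s, hi / lo, tolerance = 1e-14)
})

test_that("field sweeps are flat without hyperfine coupling and match pointwise yields", {
  flat <- radical_pair(B = 0.15, a_A = 0, spin_A = 1 / 2, label = "no-hf")
  iso0 <- tibble::tibble(isotope = "none", weight = 1, spin = 0, a = 0)
  sw <- field_sweep(flat, kin_fig, b_values = c(0.15, 1, 10, 100), isotopes = iso0)
  wt <- tidy(sw) |> dplyr::filter(component == "weighted")
  expect_equal(wt$phi_s, rep(phi_no_hyperfine(2e6, 1e6), 4), tolerance = 1e-12)

  p <- tyr_radical_pair()
  sw2 <- field_sweep(p, kin_fig, b_values = c(0.15, 100))
  wt2 <- tidy(sw2) |> dplyr::filter(component == "weighted")
  ends <- purrr::map_dbl(c(0.15, 100), function(b) {
    isotope_averaged_yield(radicalpair:::with_field(p, b), kin_fig)$phi_s
  })
  expect_equal(wt2$phi_s, ends, tolerance = 1e-12)
  expect_error(field_sweep(p, kin_fig, b_values = c(1, 1, 2)), "increasing")
})

test_that("the single-proton yield increases monotonically well above the hyperfine scale", {
  p <- radical_pair(B = 1, a_A = 2, spin_A = 1 / 2, label = "proton")
  iso0 <- tibble::tibble(isotope = "none", weight = 1, spin = 0, a = 0)
  grid <- seq(20, 100, length.out = 40) # B >= 10 a_A
  sw <- field_sweep(p, kin_fig, b_values = grid, isotopes = iso0)
  wt <- tidy(sw) |> dplyr::filter(component == "weighted")
  expect_true(all(diff(wt$phi_s) > -1e-6))
})

test_that("the cached k-r scan equals naive cell-by-cell evaluation", {
  p <- ser_radical_pair()
  kv <- c(5e5, 2e6, 8e6)
  rv <- c(3e5, 1e6, 4e6)
  fast <- kr_scan(p, k_values = kv, r_values = rv)
  slow <- kr_scan(p, k_values = kv, r_values = rv, cache = FALSE)
  expect_equal(tidy(fast)$s, tidy(slow)$s, tolerance = 1e-12)
  # the quoted-kinetics cell agrees with yield_ratio
  cell <- tidy(fast) |> dplyr::filter(k == 2e6, r == 1e6)
  expect_equal(cell$s, yield_ratio(p, kin_fig), tolerance = 1e-12)
  # 1x1 grid consistency
  tiny <- kr_scan(p, k_values = 2e6, r_values = 1e6)
  expect_equal(tidy(tiny)$s, yield_ratio(p, kin_fig), tolerance = 1e-12)
})

test_that("the ratio surface collapses to 1 as hyperfine couplings vanish", {
  p <- radical_pair(B = 1, a_A = 0, spin_A = 1 / 2, label = "no-hf")
  iso0 <- tibble::tibble(isotope = "none", weight = 1, spin = 0, a = 0)
  sc <- kr_scan(p,
    k_values = c(1e5, 1e6, 1e7), r_values = c(1e5, 1e7),
    isotopes = iso0
  )
  expect_equal(tidy(sc)$s, rep(1, 6), tolerance = 1e-12)
})

test_that("scan_component returns the 4-connected region around the seed cell", {
  kv <- 10^seq(5, 7, length.out = 5)
  rv <- 10^seq(5, 7, length.out = 5)
  grid <- tidyr::expand_grid(k = kv, r = rv)
  # two islands above threshold: a 2x2 block containing the seed, and a
  # disconnected far corner cell
  s_mat <- matrix(1, 5, 5)
  s_mat[2:3, 2:3] <- 1.5
  s_mat[5, 5] <- 1.6
  grid$s <- purrr::map2_dbl(
    match(grid$k, kv), match(grid$r, rv),
    function(i, j) s_mat[i, j]
  )
  scan <- structure(grid,
    class = c("rp_kr_scan", class(grid)),
    k_values = kv, r_values = rv, b_exp = 100, b_0 = 0.15,
    params = ser_radical_pair()
  )
  comp <- scan_component(scan, threshold = 1.2, k0 = kv[2], r0 = rv[2])
  expect_equal(nrow(comp), 4) # the 2x2 island only, not the far corner
  expect_true(any(comp$seed))
  none <- scan_component(scan, threshold = 2, k0 = kv[2], r0 = rv[2])
  expect_equal(nrow(none), 0)
})

test_that("dip detection flags flat curves as dipless and guards sampling density", {
  flat <- radical_pair(B = 0.15, a_A = 0, spin_A = 1 / 2, label = "no-hf")
  iso0 <- tibble::tibble(isotope = "none", weight = 1, spin = 0, a = 0)
  sw <- field_sweep(flat, kin_fig,
    b_values = seq(0.05, 3, length.out = 60), isotopes = iso0
  )
  dip <- detect_low_field_dip(sw)
  expect_false(dip$dip)
  sparse <- field_sweep(flat, kin_fig,
    b_values = c(0.1, 0.5, 1, 1.5, 3), isotopes = iso0
  )
  expect_error(detect_low_field_dip(sparse), "points below")
})

test_that("spike detection returns nothing for a spin-0 isotopologue and guards its grid", {
  p24 <- radical_pair(B = 1, a_A = 7.45, spin_A = 1 / 2, spin_B = 0, label = "Ser-24Mg")
  grid <- exp(seq(log(0.15), log(100), length.out = 150))
  spikes <- detect_spikes(p24, kin_fig, b_values = grid)
  expect_equal(nrow(spikes), 0)
  expect_error(detect_spikes(p24, kin_fig, b_values = grid[1:20]), "field points")
})

test_that("spike count is stable once the field grid resolves the features", {
  p25 <- radical_pair(
    B = 1, a_A = 7.45, spin_A = 1 / 2,
    a_B = -11.22, spin_B = 5 / 2, label = "Ser-25Mg"
  )
  # the spikes are ~0.5 mT wide; uniform grids at 0.1 and 0.05 mT spacing
  # both resolve them, so halving the spacing must not change the census
  s1 <- detect_spikes(p25, kin_fig, b_values = seq(2, 100, by = 0.1))
  s2 <- detect_spikes(p25, kin_fig, b_values = seq(2, 100, by = 0.05))
  expect_gte(nrow(s1), 1)
  expect_equal(nrow(s1), nrow(s2))
  # matched spike locations agree within the coarser grid's resolution
  expect_equal(s1$b, s2$b, tolerance = 0.1 / min(s1$b))
})
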