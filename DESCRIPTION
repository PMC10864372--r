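Package: radicalpair
Title: Radical-Pair Spin Dynamics and Magnetic Field Effects on Singlet Yields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling static-magnetic-field effects on radical-pair
    reactions via the radical pair mechanism. Builds Zeeman plus isotropic
    hyperfine spin Hamiltonians for a pair of radical electrons each coupled to
    one nuclear spin, evaluates the fractional singlet yield of a singlet-born
    pair both in closed form over the Hamiltonian eigensystem and by
    independent Liouville-von Neumann integration, averages over magnesium
    isotopologues, scans the yield ratio across magnetic field strength and
    the reaction/relaxation rate plane, detects the low-field dip and
    isotope-related level-crossing spikes, and compares model yield ratios
    with tabulated calcium-uptake measurements from NMDA-receptor experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
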