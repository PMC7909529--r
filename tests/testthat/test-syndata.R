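# Synthetic cohort and spectrum generator.

test_that("cohort generation is deterministic under a fixed seed", {
  d <- cohort_design(n_control = 10, n_case = 10, seed = 42)
  c1 <- generate_cohort(d)
  c2 <- generate_cohort(d)
  expect_identical(c1$table$values, c2$table$values)
  expect_identical(c1$truth$concentrations, c2$truth$concentrations)
})

test_that("design validation rejects degenerate cohorts", {
  expect_error(cohort_design(n_control = 2), "at least 3")
  expect_error(cohort_design(metabolite_names = c("a", "a", "b")), "duplicate")
  expect_error(cohort_design(
    metabolite_names = c("a", "b"),
    effect = c(a = 0.5),
    latent_correlation = data.frame(a = "a", b = "b", r = 1.0)), "\\|r\\|")
  expect_error(cohort_design(effect = c(guanidinoacetate = 6)), "effect")
})

test_that("log-scale group effects converge to the design target", {
  d <- cohort_design(n_control = 5000, n_case = 5000,
                     effect = c(guanidinoacetate = 1.0),
                     latent_correlation = default_correlations()[0, ],
                     missing_rate = 0, seed = 11)
  co <- generate_cohort(d)
  lg <- log(co$table$values[, "guanidinoacetate"])
  is_case <- co$table$group == "case"
  expect_lt(abs(mean(lg[is_case]) - mean(lg[!is_case]) - 1.0), 0.05)
})

test_that("latent-factor correlations converge to the design target", {
  d <- cohort_design(n_control = 5000, n_case = 5000, effect = numeric(),
                     missing_rate = 0, seed = 12)
  co <- generate_cohort(d)
  lx <- log(co$table$values)
  expect_lt(abs(cor(lx[, "guanidinoacetate"], lx[, "phenylacetylglycine"]) - 0.93),
            0.05)
  expect_lt(abs(cor(lx[, "L-alanine"], lx[, "L-lactate"]) - 0.65), 0.05)
})

test_that("missingness injects zeros at roughly the requested rate", {
  d <- cohort_design(n_control = 500, n_case = 500, missing_rate = 0.1,
                     seed = 3)
  co <- generate_cohort(d)
  expect_lt(abs(mean(co$table$values == 0) - 0.1), 0.02)
  expect_true(all(co$truth$concentrations > 0))
})

test_that("lactate doublet resolves at J / spectrometer frequency", {
  s <- generate_spectrum(c("L-lactate" = 1), noise_sd = 0, n_points = 131072)
  win <- s$ppm > 1.30 & s$ppm < 1.36
  ii <- s$intensity[win]
  pp <- s$ppm[win]
  apex <- which(diff(sign(diff(ii))) == -2) + 1L
  expect_length(apex, 2L)
  grid <- diff(pp[1:2])
  expect_lt(abs(diff(pp[apex]) - 6.6 / nmr_frequency_mhz()), 2 * grid)
})

test_that("TSP singlet carries its nominal area", {
  s <- generate_spectrum(c(glycine = 0), noise_sd = 0, tsp_area = 1)
  got <- nmrbiomark:::trapz_between(s$ppm, s$intensity, -0.2, 0.2)
  # Lorentzian tails outside +/-0.2 ppm hold ~0.3% of the mass
  expect_lt(abs(got - 1), 0.01)
})

test_that("spectrum is linear in concentration", {
  s1 <- generate_spectrum(c(glycine = 1), noise_sd = 0, tsp_area = 0)
  s2 <- generate_spectrum(c(glycine = 2), noise_sd = 0, tsp_area = 0)
  a1 <- nmrbiomark:::trapz_between(s1$ppm, s1$intensity, 3.52, 3.62)
  a2 <- nmrbiomark:::trapz_between(s2$ppm, s2$intensity, 3.52, 3.62)
  expect_equal(a2, 2 * a1, tolerance = 1e-12)
})

test_that("noise-free total spectral area matches the analytic target", {
  conc <- c(glycine = 2, "L-lactate" = 1.5, guanidinoacetate = 0.7,
            taurine = 0.4)
  s <- generate_spectrum(conc, linewidth_hz = 2.5, noise_sd = 0,
                         n_points = 65536, tsp_area = 1)
  lib <- metabolite_library()
  expect_area <- 1 + sum(vapply(names(conc), function(m) {
    conc[[m]] * sum(lib$rel_area[lib$name == m])
  }, 0))
  got <- nmrbiomark:::trapz(s$ppm, s$intensity)
  expect_equal(got, expect_area, tolerance = 1e-6)
})

test_that("spectrum generation validates its inputs and is deterministic", {
  expect_error(generate_spectrum(c(unobtainium = 1)), "unknown metabolite")
  expect_error(generate_spectrum(c(glycine = -1)), "non-negative")
  s1 <- generate_spectrum(c(glycine = 1), noise_sd = 0.01, seed = 5)
  s2 <- generate_spectrum(c(glycine = 1), noise_sd = 0.01, seed = 5)
  expect_identical(s1$intensity, s2$intensity)
})

test_that("library invariants hold for the bundled multiplet table", {
  lib <- metabolite_library()
  expect_length(unique(lib$name), 20L)
  split_mult <- lib$multiplicity %in% c("d", "t", "q", "dt")
  expect_true(all(is.finite(lib$j_hz[split_mult])))
  expect_true(all(is.na(lib$j_hz[!split_mult])))
  expect_true(all(lib$rel_area > 0))
})
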