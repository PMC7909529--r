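# Spectrum I/O, TSP referencing, binning and window integration.

test_that("CSV spectra round-trip and re-sort a descending axis", {
  path <- withr::local_tempfile(fileext = ".csv")
  ppm <- seq(0, 9, length.out = 10)
  y <- sin(ppm)
  write_spectrum_csv(new_s <- nmrbiomark:::new_spectrum(ppm, y, "t"), path)
  s <- read_spectrum(path)
  expect_length(s$ppm, 10L)
  expect_equal(s$intensity, y, tolerance = 1e-12)

  # descending order on disk comes back ascending
  writeLines(c("ppm,intensity",
               paste(rev(ppm), rev(y), sep = ",")), path)
  s2 <- read_spectrum(path)
  expect_equal(s2$ppm, ppm)
  expect_equal(s2$intensity, y)
})

test_that("a malformed CSV row is reported with its line number", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ppm,intensity", "0.1,1", "0.2,oops", "0.3,3"), path)
  expect_error(read_spectrum(path), "line 3")
})

test_that("JCAMP-DX files round-trip through the writer and reader", {
  s <- generate_spectrum(c(glycine = 1), noise_sd = 0, n_points = 512)
  path <- withr::local_tempfile(fileext = ".jdx")
  write_spectrum_jcamp(s, path)
  s2 <- read_spectrum(path, format = "jcamp")
  expect_equal(s2$ppm, s$ppm, tolerance = 1e-9)
  # intensities quantized by the YFACTOR encoding
  expect_lt(max(abs(s2$intensity - s$intensity)), max(s$intensity) * 1e-4)
})

test_that("TSP referencing translates the apex to exactly 0 ppm", {
  s <- generate_spectrum(c(glycine = 1), noise_sd = 0)
  shifted <- s
  shifted$ppm <- shifted$ppm + 0.013
  ref <- reference_to_tsp(shifted)
  apex <- ref$ppm[which.max(ref$intensity[abs(ref$ppm) < 0.1])]
  inwin <- abs(ref$ppm) < 0.1
  expect_equal(ref$ppm[inwin][which.max(ref$intensity[inwin])], 0)
  expect_identical(ref$intensity, shifted$intensity)
  # already-referenced spectra are fixed points
  ref2 <- reference_to_tsp(ref)
  expect_equal(ref2$ppm, ref$ppm)
})

test_that("referencing a flat spectrum fails", {
  flat <- nmrbiomark:::new_spectrum(seq(-0.3, 9.8, length.out = 100),
                                    rep(1, 100))
  expect_error(reference_to_tsp(flat), "no reference peak")
})

test_that("the default scheme retains 350 of 439 buckets", {
  # oracle: explicit enumeration of the tiling
  edges <- 0.52 + 0.02 * (0:439)
  stopifnot(isTRUE(all.equal(edges[440], 9.30)))
  overlaps <- (pmin(edges[-1], 6.10) - pmax(edges[-440], 4.32)) > 1e-12
  expect_identical(sum(overlaps), 89L)

  s <- generate_spectrum(c(glycine = 1), noise_sd = 0)
  b <- bin_spectrum(s)
  expect_identical(b$n_total, 439L)
  expect_identical(b$n_excluded, 89L)
  expect_length(b$areas, 350L)
})

test_that("bucket count depends only on the scheme, not the intensities", {
  s1 <- generate_spectrum(c(glycine = 1), noise_sd = 0)
  s2 <- generate_spectrum(c("L-lactate" = 3, taurine = 1), noise_sd = 0.05,
                          seed = 2)
  expect_identical(length(bin_spectrum(s1)$areas), length(bin_spectrum(s2)$areas))
})

test_that("constant intensity yields bucket areas equal to the width", {
  s <- nmrbiomark:::new_spectrum(seq(0, 9.5, length.out = 4096), rep(1, 4096))
  b <- bin_spectrum(s)
  expect_true(all(abs(b$areas - 0.02) < 1e-9))
})

test_that("binning conserves the integral over the analysis range", {
  s <- generate_spectrum(c(glycine = 2, "L-lactate" = 1), noise_sd = 0.02,
                         seed = 9)
  b <- bin_spectrum(s)
  total <- nmrbiomark:::trapz_between(s$ppm, s$intensity, 0.52, 9.30)
  expect_equal(sum(b$areas) + sum(b$excluded_areas), total,
               tolerance = 1e-9)
})

test_that("referencing then binning equals binning the pre-shifted axis", {
  s <- reference_to_tsp(
    generate_spectrum(c(glycine = 1, guanidinoacetate = 2), noise_sd = 0))
  shifted <- s
  shifted$ppm <- shifted$ppm + 0.008
  b_ref <- bin_spectrum(reference_to_tsp(shifted))
  b_direct <- bin_spectrum(s)
  expect_equal(b_ref$areas, b_direct$areas, tolerance = 1e-9)
})

test_that("window integration recovers areas relative to TSP", {
  # guanidinoacetate at total area 2 (concentration x 2 protons); the wide
  # axis keeps Lorentzian edge-truncation effects out of the TSP reference
  s <- generate_spectrum(c(guanidinoacetate = 1), noise_sd = 0,
                         tsp_area = 1, n_points = 131072,
                         ppm_range = c(-1, 10))
  r <- suppressWarnings(integrate_metabolites(s))
  expect_lt(abs(r[["guanidinoacetate"]] - 2.0), 1e-3)
  # no signal at all -> integrals near zero
  s0 <- generate_spectrum(c(glycine = 0), noise_sd = 0, tsp_area = 1)
  r0 <- suppressWarnings(integrate_metabolites(s0))
  expect_true(all(abs(r0) < 0.02))
})

test_that("relative areas are invariant to a global concentration scale", {
  s1 <- generate_spectrum(c(guanidinoacetate = 1, glycine = 2), noise_sd = 0,
                          tsp_area = 1, n_points = 65536)
  s2 <- generate_spectrum(c(guanidinoacetate = 2, glycine = 4), noise_sd = 0,
                          tsp_area = 2, n_points = 65536)
  r1 <- suppressWarnings(integrate_metabolites(s1))
  r2 <- suppressWarnings(integrate_metabolites(s2))
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("overlapping windows of different metabolites warn once", {
  s <- generate_spectrum(c(taurine = 1, betaine = 1), noise_sd = 0)
  expect_warning(integrate_metabolites(s), "taurine \\(3.27\\) / betaine \\(3.27\\)")
})
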