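# Bundled reference data: the 20-metabolite urinary assignment library
# (chemical shifts, multiplicities, J-couplings, proton weights) and the
# published model-selection lists from the prostate-cancer urine cohort this
# pipeline re-implements. Shifts are ppm relative to TSP at 0; J in Hz.

#' Spectrometer frequency used to convert J-couplings to ppm
#'
#' The acquisition frequency of the reference instrument (600 MHz magnet,
#' nominal proton frequency 600.13 MHz). A coupling of J Hz corresponds to a
#' ppm spacing of `J / nmr_frequency_mhz()`.
#'
#' @return the proton frequency in MHz
#' @export
nmr_frequency_mhz <- function() 600.13

#' Reference library of 20 urinary metabolites
#'
#' One row per resolved multiplet: metabolite name, HMDB accession, multiplet
#' center (ppm to TSP), multiplicity (`s`, `d`, `t`, `q` or `m` for an
#' unresolved broad signal), scalar coupling J (Hz; `NA` for singlets and
#' unresolved multiplets) and the relative area of the multiplet in proton
#' units. The `vip` column carries the published OPLS-DA variable-importance
#' values for the same 20 metabolites (repeated across a metabolite's rows),
#' used by [select_consensus()] worked examples and the acceptance checks.
#'
#' Taurine's triplet couplings are not stated in the source table; a typical
#' 6.6 Hz is filled in. The two unresolved aromatic N-methylnicotinamide
#' signals are encoded as `m`.
#'
#' @return a data.frame with columns `name`, `hmdb_id`, `shift_ppm`,
#'   `multiplicity`, `j_hz`, `rel_area`, `vip`
#' @export
metabolite_library <- function() {
  rows <- list(
    #            name                    hmdb            ppm   mult  J     H    vip
    list("L-lactate",            "HMDB0000190", 1.33, "d", 6.6, 3, 1.43),
    list("L-lactate",            "HMDB0000190", 4.13, "q", 4.8, 1, 1.43),
    list("L-alanine",            "HMDB0000161", 1.48, "d", 7.2, 3, 1.76),
    list("acetate",              "HMDB0000042", 1.92, "s", NA,  3, 1.45),
    list("succinate",            "HMDB0000254", 2.41, "s", NA,  4, 0.06),
    list("citrate",              "HMDB0000094", 2.54, "d", 16.2, 2, 0.42),
    list("citrate",              "HMDB0000094", 2.70, "d", 15.6, 2, 0.42),
    list("dimethylglycine",      "HMDB0000092", 2.92, "s", NA,  6, 1.06),
    list("dimethylglycine",      "HMDB0000092", 3.72, "s", NA,  2, 1.06),
    list("formate",              "HMDB0000142", 8.46, "s", NA,  1, 0.99),
    list("dimethylamine",        "HMDB0000087", 2.73, "s", NA,  6, 0.82),
    list("methylguanidine",      "HMDB0001522", 2.85, "s", NA,  3, 0.17),
    list("trimethylamine",       "HMDB0000906", 2.88, "s", NA,  9, 0.89),
    list("creatinine",           "HMDB0000562", 3.04, "s", NA,  3, 0.45),
    list("creatinine",           "HMDB0000562", 4.06, "s", NA,  2, 0.45),
    list("taurine",              "HMDB0000251", 3.27, "t", 6.6, 2, 0.29),
    list("taurine",              "HMDB0000251", 3.42, "t", 6.6, 2, 0.29),
    list("betaine",              "HMDB0000043", 3.27, "s", NA,  9, 0.09),
    list("betaine",              "HMDB0000043", 3.90, "s", NA,  2, 0.09),
    list("guanidinoacetate",     "HMDB0000128", 3.80, "s", NA,  2, 1.94),
    list("hippurate",            "HMDB0000714", 3.97, "d", 6.0, 2, 0.02),
    list("hippurate",            "HMDB0000714", 7.55, "t", 7.8, 2, 0.02),
    list("hippurate",            "HMDB0000714", 7.64, "t", 7.8, 1, 0.02),
    list("hippurate",            "HMDB0000714", 7.84, "d", 7.2, 2, 0.02),
    list("N-methylnicotinamide", "HMDB0003152", 9.29, "s", NA,  1, 0.55),
    list("N-methylnicotinamide", "HMDB0003152", 8.97, "d", 6.0, 1, 0.55),
    list("N-methylnicotinamide", "HMDB0003152", 8.91, "m", NA,  1, 0.55),
    list("N-methylnicotinamide", "HMDB0003152", 8.19, "m", NA,  1, 0.55),
    list("N-methylnicotinamide", "HMDB0003152", 4.48, "s", NA,  3, 0.55),
    list("2-hydroxyisobutyrate", "HMDB0000729", 1.36, "s", NA,  6, 0.36),
    list("glycine",              "HMDB0000123", 3.57, "s", NA,  2, 1.36),
    list("fumarate",             "HMDB0000134", 6.56, "s", NA,  2, 0.32),
    list("phenylacetylglycine",  "HMDB0000821", 3.68, "s", NA,  2, 1.59),
    list("phenylacetylglycine",  "HMDB0000821", 7.37, "m", NA,  2, 1.59),
    list("phenylacetylglycine",  "HMDB0000821", 7.43, "m", NA,  3, 1.59)
  )
  out <- data.frame(
    name         = vapply(rows, `[[`, "", 1L),
    hmdb_id      = vapply(rows, `[[`, "", 2L),
    shift_ppm    = vapply(rows, function(r) as.numeric(r[[3L]]), 0),
    multiplicity = vapply(rows, `[[`, "", 4L),
    j_hz         = vapply(rows, function(r) as.numeric(r[[5L]]), 0),
    rel_area     = vapply(rows, function(r) as.numeric(r[[6L]]), 0),
    vip          = vapply(rows, function(r) as.numeric(r[[7L]]), 0),
    stringsAsFactors = FALSE
  )
  validate_metabolite_library(out)
  out
}

validate_metabolite_library <- function(lib) {
  stop_if_not(all(lib$shift_ppm >= -0.5 & lib$shift_ppm <= 10.0),
              "multiplet centers must lie in [-0.5, 10] ppm")
  stop_if_not(all(lib$rel_area > 0), "relative areas must be positive")
  split_mult <- lib$multiplicity %in% c("d", "t", "q", "dt")
  stop_if_not(all(is.finite(lib$j_hz[split_mult])),
              "J coupling required for multiplicities d/t/q/dt")
  stop_if_not(!any(is.finite(lib$j_hz[!split_mult])),
              "J coupling only allowed for multiplicities d/t/q/dt")
  invisible(lib)
}

#' Per-metabolite published VIP values
#'
#' @param lib a metabolite library data.frame, see [metabolite_library()]
#' @return named numeric vector, one entry per metabolite
#' @export
reference_vip <- function(lib = metabolite_library()) {
  first <- !duplicated(lib$name)
  stats::setNames(lib$vip[first], lib$name[first])
}

#' Published per-model selection lists from the reference urine cohort
#'
#' The feature sets each latent-variable model selected in the original
#' analysis of the 50 vs 50 prostate-cancer urine cohort: PCA top-7 by
#' first-component contribution, PLS-DA and OPLS-DA by |loading| > 0.2 on the
#' predictive component, plus the set of metabolites with Bonferroni-adjusted
#' Wilcoxon p < 0.01. These printed lists are inputs to the consensus worked
#' example; they are not recomputed here because the cohort's per-sample data
#' were never deposited.
#'
#' @return a list with character vectors `pca`, `plsda`, `oplsda`,
#'   `wilcoxon_p01`
#' @export
reference_model_selections <- function() {
  list(
    pca = c("guanidinoacetate", "betaine", "phenylacetylglycine", "taurine",
            "dimethylglycine", "L-alanine", "L-lactate"),
    plsda = c("guanidinoacetate", "L-alanine", "phenylacetylglycine",
              "L-lactate", "glycine", "acetate", "dimethylglycine", "formate"),
    oplsda = c("guanidinoacetate", "L-alanine", "phenylacetylglycine",
               "acetate", "L-lactate", "glycine", "dimethylglycine",
               "formate", "trimethylamine"),
    wilcoxon_p01 = c("guanidinoacetate", "phenylacetylglycine", "glycine",
                     "L-lactate", "L-alanine")
  )
}
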