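# Synthetic cohort and spectrum generation.
#
# The generator reproduces the statistical structure the downstream analysis
# assumes: a two-group urinary cohort (default 50 control / 50 case), 20
# metabolites with log-normal concentrations, case-vs-control shifts applied
# on the log scale (guanidinoacetate, phenylacetylglycine and glycine up;
# L-lactate and L-alanine down), strong pairwise log-scale correlations
# induced through shared Gaussian latent factors, and MCAR missingness.

#' Default study conditions of the synthetic cohort
#'
#' `default_log_means()` gives per-metabolite control-group means of log
#' concentration (arbitrary units spanning the orders of magnitude typical of
#' urinary profiles); `default_effects()` the planted log-scale case shifts
#' (guanidinoacetate, phenylacetylglycine, glycine up; L-lactate, L-alanine
#' down); `default_correlations()` the target log-scale Pearson correlations
#' between marker pairs.
#'
#' @return named numeric vector, or a data.frame with columns `a`, `b`, `r`
#' @name default_design
NULL

#' @rdname default_design
#' @export
default_log_means <- function() {
  c("L-lactate" = 1.0, "L-alanine" = 0.5, "acetate" = 0.7, "succinate" = 0.2,
    "citrate" = 2.0, "dimethylglycine" = 0.4, "formate" = 0.3,
    "dimethylamine" = 1.2, "methylguanidine" = -0.5, "trimethylamine" = 0.2,
    "creatinine" = 3.0, "taurine" = 1.0, "betaine" = 0.8,
    "guanidinoacetate" = 0.8, "hippurate" = 2.2, "N-methylnicotinamide" = 0.0,
    "2-hydroxyisobutyrate" = -0.2, "glycine" = 1.5, "fumarate" = -0.8,
    "phenylacetylglycine" = 0.9)
}

#' @rdname default_design
#' @export
default_effects <- function() {
  c("guanidinoacetate" = 1.2, "phenylacetylglycine" = 1.0, "glycine" = 0.8,
    "L-lactate" = -0.9, "L-alanine" = -1.0)
}

#' @rdname default_design
#' @export
default_correlations <- function() {
  data.frame(
    a = c("guanidinoacetate", "guanidinoacetate", "phenylacetylglycine",
          "L-alanine"),
    b = c("phenylacetylglycine", "glycine", "glycine", "L-lactate"),
    r = c(0.93, 0.67, 0.64, 0.65),
    stringsAsFactors = FALSE
  )
}

#' Specify a synthetic two-group cohort
#'
#' @param n_control,n_case group sizes (each >= 3; defaults 50/50)
#' @param metabolite_names feature names; defaults to the 20-metabolite
#'   reference library
#' @param log_mean_control named per-metabolite mean of log concentration in
#'   the control group
#' @param effect named log-scale case-minus-control shifts; metabolites not
#'   named get effect 0. `|effect| < 5`.
#' @param latent_correlation data.frame with columns `a`, `b`, `r`: target
#'   Pearson correlations between log concentrations, `|r| < 1`
#' @param noise_sd log-scale standard deviation common to all metabolites
#' @param missing_rate fraction of entries zeroed out completely at random
#' @param seed integer RNG seed
#' @return an object of class `cohort_design`
#' @export
cohort_design <- function(n_control = 50, n_case = 50,
                          metabolite_names = unique(metabolite_library()$name),
                          log_mean_control = default_log_means(),
                          effect = default_effects(),
                          latent_correlation = default_correlations(),
                          noise_sd = 1, missing_rate = 0.02, seed = 1L) {
  stop_if_not(n_control >= 3 && n_case >= 3, "need at least 3 samples per group")
  stop_if_not(!anyDuplicated(metabolite_names), "duplicate metabolite names")
  stop_if_not(all(abs(effect) < 5), "|effect| must be < 5")
  stop_if_not(all(abs(latent_correlation$r) < 1), "target |r| must be < 1")
  stop_if_not(noise_sd > 0, "noise_sd must be positive")
  stop_if_not(missing_rate >= 0 && missing_rate < 1, "missing_rate in [0, 1)")
  stop_if_not(all(names(effect) %in% metabolite_names),
              "effect names must be metabolite names")
  stop_if_not(all(c(latent_correlation$a, latent_correlation$b) %in%
                    metabolite_names),
              "correlation pair names must be metabolite names")
  mu <- rep(0, length(metabolite_names))
  names(mu) <- metabolite_names
  mu[names(log_mean_control)[names(log_mean_control) %in% metabolite_names]] <-
    log_mean_control[names(log_mean_control) %in% metabolite_names]
  eff <- rep(0, length(metabolite_names))
  names(eff) <- metabolite_names
  eff[names(effect)] <- effect
  structure(
    list(n_control = n_control, n_case = n_case,
         metabolite_names = metabolite_names,
         log_mean_control = mu, effect = eff,
         latent_correlation = latent_correlation,
         noise_sd = noise_sd, missing_rate = missing_rate,
         seed = as.integer(seed)),
    class = "cohort_design"
  )
}

# Target correlation matrix from the pairwise list; Cholesky factor acts as
# the loading matrix of shared latent factors.
design_correlation_chol <- function(design) {
  p <- length(design$metabolite_names)
  R <- diag(p)
  dimnames(R) <- list(design$metabolite_names, design$metabolite_names)
  lc <- design$latent_correlation
  for (i in seq_len(nrow(lc))) {
    R[lc$a[i], lc$b[i]] <- lc$r[i]
    R[lc$b[i], lc$a[i]] <- lc$r[i]
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  stop_if_not(min(ev) > 1e-10,
              "target correlations are jointly infeasible (matrix not positive definite)")
  chol(R)
}

#' Generate a synthetic cohort concentration table
#'
#' Draws log-normal metabolite concentrations with the design's group shifts
#' and latent-factor correlation structure, applies MCAR missingness (entries
#' set to zero), and attaches case subgroup annotations (Gleason-score and
#' PSA strata) for the subgroup analyses.
#'
#' @param design a [cohort_design()]
#' @return a list with elements `table` (a [feature_table()]) and `truth`
#'   (true markers, noise-free concentrations, design echo and seed)
#' @export
generate_cohort <- function(design) {
  stop_if_not(inherits(design, "cohort_design"), "design must be a cohort_design")
  set.seed(design$seed)
  n <- design$n_control + design$n_case
  p <- length(design$metabolite_names)
  group <- factor(rep(c("control", "case"), c(design$n_control, design$n_case)),
                  levels = c("control", "case"))
  L <- design_correlation_chol(design)
  z <- matrix(stats::rnorm(n * p), n, p) %*% L
  log_conc <- matrix(design$log_mean_control, n, p, byrow = TRUE) +
    outer(as.numeric(group == "case"), design$effect) +
    design$noise_sd * z
  conc <- exp(log_conc)
  dimnames(conc) <- list(sprintf("sample_%03d", seq_len(n)),
                         design$metabolite_names)
  values <- conc
  if (design$missing_rate > 0) {
    drop <- stats::runif(n * p) < design$missing_rate
    values[drop] <- 0
  }
  gs <- psa <- rep(NA_character_, n)
  is_case <- group == "case"
  gs[is_case] <- sample(c("GS<=6", "GS>=7"), sum(is_case), replace = TRUE,
                        prob = c(0.3, 0.7))
  psa[is_case] <- sample(c("PSA<=10", "PSA10-20", "PSA>20"), sum(is_case),
                         replace = TRUE, prob = c(14, 14, 22) / 50)
  tab <- feature_table(values, group,
                       subgroups = data.frame(gs = gs, psa = psa,
                                              stringsAsFactors = FALSE))
  truth <- list(
    true_markers = names(design$effect)[design$effect != 0],
    concentrations = conc,
    design = design,
    seed = design$seed
  )
  list(table = tab, truth = truth)
}

# Line positions (ppm offsets from the multiplet center) and binomial weights
# for one multiplet. Unresolved 'm' signals are a single broad line handled
# by the caller.
multiplet_lines <- function(multiplicity, j_hz, freq_mhz = nmr_frequency_mhz()) {
  n <- switch(multiplicity, s = 1L, d = 2L, t = 3L, q = 4L, m = 1L,
              stop("unknown multiplicity: ", multiplicity))
  if (n == 1L) return(list(offsets = 0, weights = 1))
  j_ppm <- j_hz / freq_mhz
  k <- seq_len(n) - 1L
  list(offsets = (k - (n - 1L) / 2) * j_ppm,
       weights = choose(n - 1L, k) / 2^(n - 1L))
}

#' Simulate a 1H-NMR urine spectrum
#'
#' Renders every multiplet in the library as a sum of Lorentzian lines with
#' binomial intensity ratios (doublet 1:1, triplet 1:2:1, quartet 1:3:3:1);
#' unresolved `m` signals become one broad line (4x linewidth). Each line is
#' normalized so that its integral over the simulated axis equals its target
#' area, hence total noise-free spectral area equals
#' `tsp_area + sum(concentration * rel_area)`. A TSP reference singlet of
#' area `tsp_area` sits at 0.00 ppm. Optional broad water (4.70 ppm) and urea
#' (5.80 ppm) signals give the exclusion logic something to exclude.
#'
#' @param concentrations named non-negative concentrations; names must exist
#'   in `library`
#' @param library multiplet library, see [metabolite_library()]
#' @param linewidth_hz Lorentzian full width at half maximum in Hz
#' @param noise_sd additive Gaussian noise standard deviation (0 = none)
#' @param tsp_area area of the TSP reference singlet
#' @param seed RNG seed for the noise draw (ignored when `noise_sd = 0`)
#' @param ppm_range simulated axis limits; extends below 0 so the TSP signal
#'   is on-grid
#' @param n_points number of uniformly spaced axis points
#' @param water,urea inject broad solvent/urea humps
#' @param sample_id,group metadata attached to the spectrum
#' @return a `spectrum` object (fields `ppm`, `intensity`, `sample_id`, `group`)
#' @export
generate_spectrum <- function(concentrations, library = metabolite_library(),
                              linewidth_hz = 1.2, noise_sd = 0, tsp_area = 1,
                              seed = NULL, ppm_range = c(-0.3, 9.8),
                              n_points = 16384, water = FALSE, urea = FALSE,
                              sample_id = "synthetic", group = NA_character_) {
  stop_if_not(all(concentrations >= 0), "concentrations must be non-negative")
  stop_if_not(linewidth_hz > 0, "linewidth must be positive")
  unknown <- setdiff(names(concentrations), library$name)
  stop_if_not(length(unknown) == 0L,
              "unknown metabolite(s): %s", paste(unknown, collapse = ", "))
  ppm <- seq(ppm_range[1L], ppm_range[2L], length.out = n_points)
  intensity <- numeric(n_points)
  hw <- (linewidth_hz / nmr_frequency_mhz()) / 2   # Lorentzian HWHM in ppm

  # area-exact truncated Lorentzian: integral over [min, max] equals `area`
  add_line <- function(center, area, half_width) {
    norm <- (atan((ppm_range[2L] - center) / half_width) -
               atan((ppm_range[1L] - center) / half_width)) / pi
    intensity <<- intensity + area / norm *
      (half_width / pi) / ((ppm - center)^2 + half_width^2)
  }

  for (met in names(concentrations)) {
    conc <- concentrations[[met]]
    if (conc == 0) next
    rows <- library[library$name == met, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      mult <- rows$multiplicity[i]
      area <- conc * rows$rel_area[i]
      if (mult == "m") {
        add_line(rows$shift_ppm[i], area, hw * 4)
      } else {
        ml <- multiplet_lines(mult, rows$j_hz[i])
        for (k in seq_along(ml$offsets))
          add_line(rows$shift_ppm[i] + ml$offsets[k], area * ml$weights[k], hw)
      }
    }
  }
  if (tsp_area > 0) add_line(0, tsp_area, hw)
  if (water) add_line(4.70, 50 * max(1, tsp_area), 40 / nmr_frequency_mhz() / 2)
  if (urea) add_line(5.80, 10 * max(1, tsp_area), 10 / nmr_frequency_mhz() / 2)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    intensity <- intensity + stats::rnorm(n_points, sd = noise_sd)
  }
  new_spectrum(ppm, intensity, sample_id = sample_id, group = group)
}

#' Generate synthetic spectra for a whole cohort
#'
#' @param cohort result of [generate_cohort()]
#' @param ... forwarded to [generate_spectrum()]
#' @return a list of `spectrum` objects, one per sample (noise seeds derived
#'   from the design seed)
#' @export
generate_cohort_spectra <- function(cohort, ...) {
  vals <- cohort$table$values
  grp <- as.character(cohort$table$group)
  args <- list(...)
  lapply(seq_len(nrow(vals)), function(i) {
    a <- args
    a$concentrations <- vals[i, ]
    a$sample_id <- rownames(vals)[i]
    a$group <- grp[i]
    if (is.null(a$seed) && !is.null(a$noise_sd) && a$noise_sd > 0)
      a$seed <- cohort$truth$seed * 1000L + i
    do.call(generate_spectrum, a)
  })
}
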