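#' Analyte (biomarker) configuration
#'
#' Bundles the assay characteristics of one urinary PAH metabolite (limit of
#' detection, between-day analytical imprecision) with the generative
#' toxicokinetic truth used by [simulate_study()]: a constant background
#' excretion rate plus an exposure pulse absorbed and eliminated by first-order
#' kinetics.
#'
#' @param name Analyte code, one of `"DHN"` (1,2-dihydroxynaphthalene),
#'   `"NAP1"` (1-hydroxynaphthalene), `"NAP2"` (2-hydroxynaphthalene),
#'   `"PYR1"` (1-hydroxypyrene).
#' @param lod Limit of detection (ug/L), > 0.
#' @param assay_cv Assay coefficient of variation (fraction, >= 0), applied as
#'   multiplicative lognormal measurement noise.
#' @param baseline_rate Background urinary excretion rate (ug/h) at the cohort
#'   median; multiplied per subject by a lognormal factor (see
#'   [study_design()]).
#' @param dose_mean Mean metabolite-equivalent absorbed dose per training
#'   session (ug).
#' @param dose_cv Between-session lognormal coefficient of variation of the
#'   absorbed dose (fraction).
#' @param ka First-order absorption rate constant (1/h).
#' @param ke First-order (terminal) elimination rate constant (1/h); must
#'   satisfy `ka > ke > 0`, so the terminal log-slope of the excretion pulse
#'   equals `-ke` and the elimination half-life is `log(2)/ke`.
#' @param fe Fraction of the absorbed dose excreted as this metabolite,
#'   in (0, 1].
#'
#' @return An object of class `analyte_config` (a named list).
#' @seealso [paper_analytes()] for the packaged study defaults.
#' @export
analyte_config <- function(name, lod, assay_cv, baseline_rate,
                           dose_mean, dose_cv, ka, ke, fe = 1) {
  name <- match.arg(name, c("DHN", "NAP1", "NAP2", "PYR1"))
  stopifnot(
    is.numeric(lod), length(lod) == 1L, lod > 0,
    is.numeric(assay_cv), length(assay_cv) == 1L, assay_cv >= 0,
    is.numeric(baseline_rate), baseline_rate >= 0,
    is.numeric(dose_mean), dose_mean >= 0,
    is.numeric(dose_cv), dose_cv >= 0,
    is.numeric(ka), is.numeric(ke), ke > 0, ka > ke,
    is.numeric(fe), fe > 0, fe <= 1
  )
  structure(
    list(name = name, lod = lod, assay_cv = assay_cv,
         baseline_rate = baseline_rate, dose_mean = dose_mean,
         dose_cv = dose_cv, ka = ka, ke = ke, fe = fe),
    class = "analyte_config"
  )
}

#' @export
print.analyte_config <- function(x, ...) {
  cat(sprintf(
    "<analyte_config> %s: LOD %g ug/L, assay CV %.1f%%, t1/2 %.2f h (ke %.4f/h, ka %.2f/h)\n",
    x$name, x$lod, 100 * x$assay_cv, log(2) / x$ke, x$ke, x$ka))
  cat(sprintf("  baseline %g ug/h, dose %g ug (CV %.0f%%), fe %g\n",
              x$baseline_rate, x$dose_mean, 100 * x$dose_cv, x$fe))
  invisible(x)
}

#' Scheduled sampling windows of the 24-h spot-urine protocol
#'
#' Nine predefined sampling times bracketing one training session: two
#' pre-exposure samples (morning urine, immediately before training) and seven
#' post-exposure samples up to the next morning. Times are hours relative to
#' exposure onset; each window is the observed range over which that scheduled
#' void actually occurred.
#'
#' @return A tibble with columns `window_index`, `t_min`, `t_max`, `t_mean`.
#' @export
sampling_windows <- function() {
  tibble::tibble(
    window_index = 1:9,
    t_min  = c(-5.3, -1.0, 1.5, 2.5, 4.5, 7.4,  9.6, 11.6, 18.2),
    t_max  = c(-2.3, -0.1, 2.4, 3.6, 5.6, 8.6, 12.8, 14.1, 21.8),
    t_mean = c(-4.2, -0.4, 2.0, 3.0, 5.2, 8.1, 11.2, 12.7, 20.1)
  )
}

#' Study design for the synthetic spot-urine generator
#'
#' Describes the repeated-measures sampling protocol (subjects x sessions x
#' nine scheduled samplings) plus the physiological nuisance processes that a
#' spot-urine study drags along: urine flow, creatinine excretion (with
#' between-subject and per-void lognormal variability), unscheduled voiding,
#' and between-subject variability of background metabolite excretion.
#'
#' @param n_subjects Number of participants (default 6).
#' @param n_sessions Training sessions per participant (default 5).
#' @param windows Sampling-window tibble as from [sampling_windows()]
#'   (exactly 9 rows, ordered).
#' @param exposure_duration Duration of smoke exposure (h); the absorbed dose
#'   enters the kinetic depot as a bolus at its midpoint.
#' @param unscheduled_void_rate Poisson rate (voids/h) of additional
#'   urinations between the first and last scheduled sampling.
#' @param urine_flow_mean Mean urine production (L/h).
#' @param urine_flow_cv Per-void lognormal CV of void volume.
#' @param creatinine_rate_mean Mean creatinine excretion rate (g/h);
#'   1.5 g/day at the default.
#' @param creatinine_subject_cv Between-subject lognormal CV of the creatinine
#'   excretion rate.
#' @param creatinine_void_cv Per-void lognormal CV of excreted creatinine mass.
#' @param baseline_subject_cv Between-subject lognormal CV of background
#'   metabolite excretion rates.
#' @param overnight_gap Assumed time (h) between the last void of the previous
#'   day and the first morning sample, setting its accumulation interval.
#'
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_subjects = 6,
                         n_sessions = 5,
                         windows = sampling_windows(),
                         exposure_duration = 0.75,
                         unscheduled_void_rate = 0.10,
                         urine_flow_mean = 0.06,
                         urine_flow_cv = 0.5,
                         creatinine_rate_mean = 1.5 / 24,
                         creatinine_subject_cv = 0.2,
                         creatinine_void_cv = 0.3,
                         baseline_subject_cv = 0.4,
                         overnight_gap = 8) {
  stopifnot(
    n_subjects >= 1, n_sessions >= 1,
    is.data.frame(windows), nrow(windows) == 9L,
    all(c("window_index", "t_min", "t_max") %in% names(windows)),
    all(windows$t_min < windows$t_max),
    !is.unsorted(rowMeans(windows[, c("t_min", "t_max")]), strictly = TRUE),
    exposure_duration > 0, unscheduled_void_rate >= 0,
    urine_flow_mean > 0, urine_flow_cv >= 0,
    creatinine_rate_mean > 0, creatinine_subject_cv >= 0,
    creatinine_void_cv >= 0, baseline_subject_cv >= 0, overnight_gap > 0
  )
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_sessions = as.integer(n_sessions),
         windows = tibble::as_tibble(windows),
         exposure_duration = exposure_duration,
         unscheduled_void_rate = unscheduled_void_rate,
         urine_flow_mean = urine_flow_mean,
         urine_flow_cv = urine_flow_cv,
         creatinine_rate_mean = creatinine_rate_mean,
         creatinine_subject_cv = creatinine_subject_cv,
         creatinine_void_cv = creatinine_void_cv,
         baseline_subject_cv = baseline_subject_cv,
         overnight_gap = overnight_gap),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> %d subjects x %d sessions x %d samplings\n",
              x$n_subjects, x$n_sessions, nrow(x$windows)))
  invisible(x)
}

#' Packaged study-default analyte configurations
#'
#' The four urinary biomarkers monitored in the firefighting-instructor live
#' fire training study: DHN, 1-NAP, 2-NAP (naphthalene metabolites) and 1-PYR
#' (pyrene metabolite). LODs and assay CVs follow the reported analytical
#' method; elimination rate constants are set from the reported mean
#' elimination half-lives (6.6, 6.2, 5.2, 7.7 h); absorption constants and
#' doses are chosen so that the noise-free peak of the creatinine-adjusted
#' concentration falls in sampling window 4 (window 5 for 1-PYR) at roughly
#' the reported peak medians, and baseline rates reproduce the order of the
#' reported pre-exposure medians.
#'
#' @return A named list of [analyte_config()] objects.
#' @export
paper_analytes <- function() {
  list(
    DHN  = analyte_config("DHN",  lod = 0.3,  assay_cv = 0.094,
                          baseline_rate = 0.19,   dose_mean = 100,  dose_cv = 0.5,
                          ka = 1.2,  ke = log(2) / 6.6, fe = 1),
    NAP1 = analyte_config("NAP1", lod = 0.1,  assay_cv = 0.128,
                          baseline_rate = 0.031,  dose_mean = 8.3,  dose_cv = 0.5,
                          ka = 1.2,  ke = log(2) / 6.2, fe = 1),
    NAP2 = analyte_config("NAP2", lod = 0.1,  assay_cv = 0.142,
                          baseline_rate = 0.125,  dose_mean = 6.1,  dose_cv = 0.5,
                          ka = 1.2,  ke = log(2) / 5.2, fe = 1),
    PYR1 = analyte_config("PYR1", lod = 0.02, assay_cv = 0.156,
                          baseline_rate = 0.0031, dose_mean = 0.37, dose_cv = 0.5,
                          ka = 0.40, ke = log(2) / 7.7, fe = 1)
  )
}

#' Read a run configuration from YAML
#'
#' Parses a configuration file mirroring [study_design()] and
#' [analyte_config()] field names (see the packaged
#' `system.file("extdata", "params.paper.yaml", package = "pahkin")`).
#' Fields not present fall back to the packaged defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `design` (a `study_design`), `analytes`
#'   (named list of `analyte_config`), and `options` (seed, baseline window,
#'   AR(1) convention, percentile convention, paths; whatever the file
#'   carries).
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  des_args <- raw$design %||% list()
  if (!is.null(des_args$windows)) {
    des_args$windows <- tibble::as_tibble(
      purrr::map_dfr(des_args$windows, tibble::as_tibble))
  }
  design <- do.call(study_design, des_args)
  analytes <- paper_analytes()
  if (!is.null(raw$analytes)) {
    analytes <- purrr::imap(raw$analytes, function(a, nm) {
      a$name <- a$name %||% nm
      do.call(analyte_config, a)
    })
    names(analytes) <- purrr::map_chr(analytes, "name")
  }
  list(design = design, analytes = analytes,
       options = raw$options %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
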