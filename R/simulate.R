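#' One-compartment body burden after a bolus into a first-order depot
#'
#' Bateman amount profile: a dose enters an absorption depot at `t = 0` and is
#' absorbed with rate constant `ka` into a central compartment eliminated with
#' rate constant `ke`. The terminal log-slope equals `-ke`, so elimination
#' half-life is `log(2)/ke`; the unique maximum is at
#' `t_max = log(ka/ke)/(ka - ke)`.
#'
#' @param t Time since start of absorption (h); values `< 0` return 0.
#' @param dose Absorbed dose (ug).
#' @param ka,ke Absorption and elimination rate constants (1/h), `ka != ke`.
#' @return Amount in the body (ug), same length as `t`.
#' @export
body_burden <- function(t, dose, ka, ke) {
  stopifnot(ka > 0, ke > 0)
  if (isTRUE(all.equal(ka, ke))) {
    stop("degenerate kinetics: ka == ke has no two-exponential form ",
         "(reparameterise one constant slightly)")
  }
  tt <- pmax(t, 0)
  dose * ka / (ka - ke) * (exp(-ke * tt) - exp(-ka * tt))
}

## closed-form integral of body_burden over [u0, u1], times >= 0
bateman_integral <- function(u0, u1, dose, ka, ke) {
  u0 <- pmax(u0, 0)
  u1 <- pmax(u1, 0)
  dose * ka / (ka - ke) *
    ((exp(-ke * u0) - exp(-ke * u1)) / ke -
       (exp(-ka * u0) - exp(-ka * u1)) / ka)
}

#' Metabolite mass excreted into urine over a collection interval
#'
#' Renal excretion is the elimination flux `fe * ke * X(u)` of the
#' [body_burden()] profile, integrated in closed form over the interval,
#' plus constant background excretion `baseline_rate * (t1 - t0)`.
#' Additive over adjacent intervals.
#'
#' @param t0,t1 Interval bounds (h) since start of absorption, `t0 < t1`;
#'   portions before `t = 0` contribute background only.
#' @param analyte An [analyte_config()].
#' @param dose Absorbed dose for this session (ug).
#' @param baseline_rate Background excretion rate (ug/h); defaults to the
#'   analyte's configured rate (override for subject-level variability).
#' @return Excreted mass (ug).
#' @export
excreted_amount <- function(t0, t1, analyte, dose,
                            baseline_rate = analyte$baseline_rate) {
  stopifnot(t0 < t1)
  pulse <- analyte$fe * analyte$ke *
    bateman_integral(t0, t1, dose, analyte$ka, analyte$ke)
  pulse + baseline_rate * (t1 - t0)
}

#' Apply the analytical assay to a true concentration
#'
#' Multiplicative lognormal measurement noise with coefficient of variation
#' `analyte$assay_cv` (mean-one noise), followed by comparison against the
#' limit of detection. The raw noisy value is retained even when flagged
#' below the LOD; censoring substitution happens in preprocessing.
#'
#' @param true_conc True concentration(s), ug/L, `>= 0`.
#' @param analyte An [analyte_config()].
#' @return A tibble with columns `measured` (ug/L) and `below_lod` (logical).
#'   Uses the current R random number stream.
#' @export
apply_assay <- function(true_conc, analyte) {
  stopifnot(all(true_conc >= 0))
  if (analyte$assay_cv > 0) {
    sdlog <- sqrt(log1p(analyte$assay_cv^2))
    noise <- stats::rlnorm(length(true_conc), -sdlog^2 / 2, sdlog)
  } else {
    noise <- rep(1, length(true_conc))
  }
  measured <- true_conc * noise
  tibble::tibble(measured = measured, below_lod = measured < analyte$lod)
}

## mean-one lognormal draws with given CV
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, -sdlog^2 / 2, sdlog)
}

## deterministic substream seed; small enough for 32-bit R integers
substream_seed <- function(seed, subject, session = 0L) {
  as.integer((as.double(seed) + 100019 * subject + 1009 * session) %%
               2147483629)
}

#' Simulate a void-level spot-urine biomonitoring study
#'
#' Generates every urination event for each subject x training session: nine
#' scheduled voids at times drawn uniformly within the protocol's sampling
#' windows (kept strictly increasing), plus unscheduled voids from a Poisson
#' process between the first and last scheduled sampling. Each void's analyte
#' concentration is the mass excreted since the previous void (background plus
#' first-order absorption/elimination pulse from a bolus at the exposure
#' midpoint) divided by the void volume; creatinine mass accrues at a
#' subject-specific rate with per-void noise. Assay noise and LOD flagging are
#' applied per analyte.
#'
#' Reproducibility: one master seed; subject- and session-level substreams are
#' derived from it, so enlarging the cohort does not perturb existing
#' subjects' data.
#'
#' @param design A [study_design()].
#' @param analytes Named list of [analyte_config()] objects.
#' @param seed Integer master seed.
#' @return A tibble, one row per void, with columns `subject_id`,
#'   `session_id`, `time_h`, `volume_L`, `creatinine_g_per_L`, `scheduled`
#'   (0/1), `window_index` (NA for unscheduled voids), and per analyte
#'   `<name>_true_ug_per_L`, `<name>_meas_ug_per_L`, `<name>_below_lod`.
#' @export
simulate_study <- function(design, analytes = paper_analytes(), seed) {
  stopifnot(inherits(design, "study_design"), length(analytes) >= 1,
            is.numeric(seed), length(seed) == 1L)
  stopifnot(all(vapply(analytes, inherits, logical(1), "analyte_config")))
  names(analytes) <- vapply(analytes, `[[`, character(1), "name")
  bolus_time <- design$exposure_duration / 2
  w <- design$windows

  subj_rows <- lapply(seq_len(design$n_subjects), function(i) {
    ## subject-level multipliers (own substream: stable under added sessions)
    set.seed(substream_seed(seed, i))
    crea_mult <- rlnorm_cv(1, design$creatinine_subject_cv)
    base_mult <- rlnorm_cv(length(analytes), design$baseline_subject_cv)
    names(base_mult) <- names(analytes)

    ses_rows <- lapply(seq_len(design$n_sessions), function(j) {
      set.seed(substream_seed(seed, i, j))
      doses <- vapply(analytes, function(a) {
        a$dose_mean * rlnorm_cv(1, a$dose_cv)
      }, numeric(1))

      ## scheduled times: uniform within windows, forced strictly increasing
      t_sched <- numeric(nrow(w))
      prev <- -Inf
      for (k in seq_len(nrow(w))) {
        lo <- max(w$t_min[k], prev + 0.01)
        t_sched[k] <- stats::runif(1, min(lo, w$t_max[k]), w$t_max[k])
        prev <- t_sched[k]
      }
      span <- t_sched[length(t_sched)] - t_sched[1]
      n_uns <- stats::rpois(1, design$unscheduled_void_rate * span)
      t_uns <- sort(stats::runif(n_uns, t_sched[1] + 1e-3,
                                 t_sched[length(t_sched)] - 1e-3))
      times <- c(t_sched, t_uns)
      sched <- c(rep(TRUE, length(t_sched)), rep(FALSE, length(t_uns)))
      widx <- c(w$window_index, rep(NA_integer_, length(t_uns)))
      ord <- order(times)
      times <- times[ord]; sched <- sched[ord]; widx <- widx[ord]

      prev_t <- c(times[1] - design$overnight_gap, times[-length(times)])
      dt <- times - prev_t
      volume <- design$urine_flow_mean * dt *
        rlnorm_cv(length(dt), design$urine_flow_cv)
      crea_mass <- design$creatinine_rate_mean * crea_mult * dt *
        rlnorm_cv(length(dt), design$creatinine_void_cv)

      out <- tibble::tibble(
        subject_id = sprintf("S%02d", i),
        session_id = sprintf("T%d", j),
        time_h = times,
        volume_L = volume,
        creatinine_g_per_L = crea_mass / volume,
        scheduled = as.integer(sched),
        window_index = widx
      )
      for (nm in names(analytes)) {
        a <- analytes[[nm]]
        mass <- mapply(function(t0, t1) {
          excreted_amount(t0 - bolus_time, t1 - bolus_time, a, doses[[nm]],
                          baseline_rate = a$baseline_rate * base_mult[[nm]])
        }, prev_t, times)
        true_conc <- mass / volume
        meas <- apply_assay(true_conc, a)
        out[[paste0(nm, "_true_ug_per_L")]] <- true_conc
        out[[paste0(nm, "_meas_ug_per_L")]] <- meas$measured
        out[[paste0(nm, "_below_lod")]] <- meas$below_lod
      }
      out
    })
    dplyr::bind_rows(ses_rows)
  })
  dplyr::bind_rows(subj_rows)
}

#' Write / read a void-level table as CSV
#'
#' Plain UTF-8 CSV with a mandatory header row; an optional metadata block is
#' written as leading `#` comment lines and skipped on read.
#'
#' @param voids A void tibble as from [simulate_study()].
#' @param path File path.
#' @param metadata Optional named list written as `# key: value` lines.
#' @return `write_voids()` returns `path` invisibly; `read_voids()` returns
#'   the tibble.
#' @export
write_voids <- function(voids, path, metadata = NULL) {
  write_csv_meta(voids, path, metadata)
}

#' @rdname write_voids
#' @export
read_voids <- function(path) {
  x <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  lodc <- grep("_below_lod$", names(x), value = TRUE)
  x[lodc] <- lapply(x[lodc], as.logical)
  x
}

write_csv_meta <- function(x, path, metadata = NULL) {
  lines <- character(0)
  if (!is.null(metadata)) {
    lines <- sprintf("# %s: %s", names(metadata),
                     vapply(metadata, function(v) paste(format(v), collapse = " "),
                            character(1)))
  }
  readr::write_lines(lines, path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}
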