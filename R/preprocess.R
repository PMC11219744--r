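#' Pool unscheduled voids into the next scheduled sample
#'
#' Emulates the physical pooling of the collection protocol: every unscheduled
#' urination is combined with the next scheduled void, so concentrations mix
#' by volume, `c_pool = sum(c_i * V_i) / sum(V_i)`, for creatinine and every
#' analyte column (`*_ug_per_L`). Below-LOD flags are re-evaluated against the
#' pooled measured concentration, since in the study the assay was run on the
#' pooled physical sample. Unscheduled voids after the last scheduled sampling
#' cannot be pooled forward and are dropped with a warning.
#'
#' @param voids Void-level tibble (schema of [simulate_study()]), any number
#'   of subject-sessions; must contain at least one scheduled void per
#'   subject-session present.
#' @param analytes Named list of [analyte_config()]; used for the LOD
#'   re-evaluation of `<name>_meas_ug_per_L` columns.
#' @return A sample-level tibble: identity columns, `window_index`, `time_h`
#'   (time of the scheduled anchor void), `volume_L` (summed), pooled
#'   creatinine and analyte concentrations, `n_pooled`.
#' @export
pool_voids <- function(voids, analytes = paper_analytes()) {
  if (nrow(voids) == 0) return(voids[0, , drop = FALSE])
  if (!any(voids$scheduled == 1)) stop("no scheduled voids to pool into")
  names(analytes) <- vapply(analytes, `[[`, character(1), "name")

  conc_cols <- grep("_ug_per_L$", names(voids), value = TRUE)
  pooled <- voids |>
    dplyr::group_by(.data$subject_id, .data$session_id) |>
    dplyr::group_modify(function(d, key) {
      if (!any(d$scheduled == 1)) {
        stop("subject-session without any scheduled void")
      }
      d <- dplyr::arrange(d, .data$time_h)
      sched_pos <- which(d$scheduled == 1)
      ## anchor = first scheduled void at or after each row
      anchor <- vapply(seq_len(nrow(d)), function(r) {
        nxt <- sched_pos[sched_pos >= r]
        if (length(nxt) == 0) NA_integer_ else nxt[1]
      }, integer(1))
      n_trailing <- sum(is.na(anchor))
      if (n_trailing > 0) {
        warning(sprintf("dropping %d trailing unscheduled void(s)", n_trailing))
        d <- d[!is.na(anchor), , drop = FALSE]
        anchor <- anchor[!is.na(anchor)]
      }
      out <- lapply(split(seq_len(nrow(d)), anchor), function(rows) {
        blk <- d[rows, , drop = FALSE]
        anchor_row <- blk[blk$scheduled == 1, , drop = FALSE]
        V <- sum(blk$volume_L)
        smp <- tibble::tibble(
          window_index = anchor_row$window_index,
          time_h = anchor_row$time_h,
          volume_L = V,
          creatinine_g_per_L = sum(blk$creatinine_g_per_L * blk$volume_L) / V,
          n_pooled = nrow(blk)
        )
        for (cc in conc_cols) {
          smp[[cc]] <- sum(blk[[cc]] * blk$volume_L) / V
        }
        smp
      })
      dplyr::bind_rows(out)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$subject_id, .data$session_id, .data$time_h)

  ## re-evaluate censoring on the pooled measured concentration
  for (nm in names(analytes)) {
    mc <- paste0(nm, "_meas_ug_per_L")
    if (mc %in% names(pooled)) {
      pooled[[paste0(nm, "_below_lod")]] <- pooled[[mc]] < analytes[[nm]]$lod
    }
  }
  pooled
}

#' Substitute censored concentrations by half the detection limit
#'
#' Values flagged below the LOD are replaced by `lod / 2`; others pass
#' through unchanged. Idempotent.
#'
#' @param measured Measured concentration(s), ug/L.
#' @param below_lod Logical censoring flag(s).
#' @param lod Limit of detection (ug/L), > 0.
#' @return Numeric vector of substituted concentrations.
#' @export
substitute_lod <- function(measured, below_lod, lod) {
  stopifnot(lod > 0)
  ifelse(below_lod, lod / 2, measured)
}

#' Creatinine adjustment of a urinary concentration
#'
#' Expresses an analyte concentration per gram of creatinine to correct spot
#' samples for hydration-driven dilution: `ug/L / (g/L) = ug/g`.
#'
#' @param conc Analyte concentration(s), ug/L.
#' @param creatinine Creatinine concentration(s), g/L, > 0.
#' @return Adjusted concentration(s), ug/g creatinine.
#' @export
adjust_creatinine <- function(conc, creatinine) {
  if (any(creatinine <= 0)) stop("creatinine concentration must be > 0")
  conc / creatinine
}

#' Apply the creatinine-range inclusion rule and account for samples
#'
#' Samples are included when their creatinine concentration lies in
#' `[lower, upper]` g/L (bounds inclusive, per WHO convention). Excluded
#' samples are retained with `included = FALSE` so the accounting stays
#' auditable.
#'
#' @param samples Sample-level tibble with a `creatinine_g_per_L` column.
#' @param lower,upper Inclusion bounds in g/L (defaults 0.3 and 3.0).
#' @param expected Number of samples the protocol scheduled (for the
#'   accounting report); defaults to `nrow(samples)`.
#' @return A list: `samples` (input plus logical `included`) and `accounting`
#'   (list with `expected`, `collected`, `included`, `excluded_creatinine`,
#'   `missing`).
#' @export
apply_inclusion <- function(samples, lower = 0.3, upper = 3.0,
                            expected = nrow(samples)) {
  stopifnot(lower < upper, expected >= nrow(samples))
  samples$included <- samples$creatinine_g_per_L >= lower &
    samples$creatinine_g_per_L <= upper
  acc <- list(
    expected = as.integer(expected),
    collected = nrow(samples),
    included = sum(samples$included),
    excluded_creatinine = sum(!samples$included),
    missing = as.integer(expected) - nrow(samples)
  )
  list(samples = samples, accounting = acc)
}

#' Full void-to-sample preprocessing stage
#'
#' Chains [pool_voids()], [substitute_lod()] (on the pooled measured
#' concentrations), [adjust_creatinine()] and [apply_inclusion()] to produce
#' the analysis-ready creatinine-adjusted sample table.
#'
#' @param voids Void-level tibble (schema of [simulate_study()]).
#' @param analytes Named list of [analyte_config()].
#' @param lower,upper Creatinine inclusion bounds (g/L).
#' @param expected Scheduled sample count for accounting; default
#'   `NULL` takes the number of pooled samples.
#' @return A list: `samples` (one row per scheduled sampling with
#'   `<name>_ug_per_L` post-substitution, `<name>_ug_per_g`,
#'   `<name>_below_lod`, `included`) and `accounting`.
#' @export
preprocess_voids <- function(voids, analytes = paper_analytes(),
                             lower = 0.3, upper = 3.0, expected = NULL) {
  names(analytes) <- vapply(analytes, `[[`, character(1), "name")
  analytes <- analytes[paste0(names(analytes), "_meas_ug_per_L") %in%
                         names(voids)]
  if (length(analytes) == 0) stop("no analyte measurement columns found")
  pooled <- pool_voids(voids, analytes)
  ## accumulation-interval midpoint: pooling merges unscheduled voids forward,
  ## so sample k collects urine produced over (t[k-1], t[k]]; a concentration
  ## is the interval average and is best anchored at the midpoint for
  ## kinetics. First sample of a set (unknown interval start) keeps its void
  ## time.
  pooled <- pooled |>
    dplyr::group_by(.data$subject_id, .data$session_id) |>
    dplyr::arrange(.data$time_h, .by_group = TRUE) |>
    dplyr::mutate(t_mid_h = ifelse(is.na(dplyr::lag(.data$time_h)),
                                   .data$time_h,
                                   (dplyr::lag(.data$time_h) + .data$time_h) / 2)) |>
    dplyr::ungroup()
  out <- tibble::tibble(
    subject_id = pooled$subject_id,
    session_id = pooled$session_id,
    window_index = pooled$window_index,
    time_h = pooled$time_h,
    t_mid_h = pooled$t_mid_h,
    volume_L = pooled$volume_L,
    creatinine_g_per_L = pooled$creatinine_g_per_L,
    n_pooled = pooled$n_pooled
  )
  for (nm in names(analytes)) {
    a <- analytes[[nm]]
    meas <- pooled[[paste0(nm, "_meas_ug_per_L")]]
    flag <- pooled[[paste0(nm, "_below_lod")]]
    subst <- substitute_lod(meas, flag, a$lod)
    out[[paste0(nm, "_ug_per_L")]] <- subst
    out[[paste0(nm, "_ug_per_g")]] <- adjust_creatinine(
      subst, pooled$creatinine_g_per_L)
    out[[paste0(nm, "_below_lod")]] <- flag
  }
  apply_inclusion(out, lower = lower, upper = upper,
                  expected = expected %||% nrow(out))
}

#' Write / read the processed sample table and its accounting report
#'
#' @param samples Sample-level tibble (element `samples` of
#'   [preprocess_voids()]).
#' @param path CSV file path (samples) or JSON path (accounting).
#' @param metadata Optional named list written as `#` comment lines.
#' @param accounting Accounting list as produced by [apply_inclusion()].
#' @return Writers return `path` invisibly; readers the parsed object.
#' @export
write_samples <- function(samples, path, metadata = NULL) {
  write_csv_meta(samples, path, metadata)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  x <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  for (cc in grep("_below_lod$|^included$", names(x), value = TRUE)) {
    x[[cc]] <- as.logical(x[[cc]])
  }
  x
}

#' @rdname write_samples
#' @export
write_accounting <- function(accounting, path, metadata = NULL) {
  jsonlite::write_json(c(accounting, list(metadata = metadata)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
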