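#' Locate the post-exposure peak concentration per sample set
#'
#' For each subject x session sample set, finds the maximum creatinine-adjusted
#' concentration of one biomarker among included post-exposure samples
#' (windows 3-9 by default) and its time since exposure onset. Ties are broken
#' by the earlier time. Sets without any eligible sample are omitted (their
#' count is in the `n_excluded_sets` attribute).
#'
#' @param samples Sample-level tibble from [preprocess_voids()].
#' @param analyte Analyte name (e.g. `"DHN"`).
#' @param peak_windows Window indices eligible for the peak search.
#' @return A tibble `subject_id`, `session_id`, `biomarker`, `t_peak` (h),
#'   `c_peak` (ug/g), with attribute `n_excluded_sets`.
#' @export
locate_peak <- function(samples, analyte, peak_windows = 3:9) {
  col <- paste0(analyte, "_ug_per_g")
  stopifnot(col %in% names(samples))
  if ("included" %in% names(samples)) {
    samples <- samples[samples$included, , drop = FALSE]
  }
  n_sets_all <- nrow(dplyr::distinct(samples, .data$subject_id,
                                     .data$session_id))
  eligible <- samples[samples$window_index %in% peak_windows &
                        !is.na(samples[[col]]), , drop = FALSE]
  peaks <- eligible |>
    dplyr::group_by(.data$subject_id, .data$session_id) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) == 0) {
        return(tibble::tibble(biomarker = character(0), t_peak = numeric(0),
                              c_peak = numeric(0)))
      }
      best <- which(d[[col]] == max(d[[col]]))
      best <- best[which.min(d$time_h[best])]
      tibble::tibble(biomarker = analyte,
                     t_peak = d$time_h[best], c_peak = d[[col]][best])
    }) |>
    dplyr::ungroup()
  attr(peaks, "n_excluded_sets") <- n_sets_all - nrow(peaks)
  peaks
}

#' Build post-peak decay records for the exponential-decay fit
#'
#' For each sample set and biomarker, the baseline `C0` is the adjusted
#' concentration of the pre-training sample (window 2, falling back to
#' window 1 when window 2 is missing or excluded). Every included sample at or
#' after the located peak with `C > C0` becomes one record with
#' `t` = time since the peak and `y = ln(C - C0)`; records with `C <= C0`
#' are dropped (counted), and sets without a usable baseline or peak are
#' excluded (counted).
#'
#' @param samples Sample-level tibble from [preprocess_voids()].
#' @param analytes Character vector of biomarker names.
#' @param baseline_window,fallback_window Window indices supplying `C0`.
#' @param peak_windows Windows eligible for the peak search and the decay
#'   records.
#' @return A tibble `subject_id`, `session_id`, `biomarker`, `t`, `y`, `C`,
#'   `C0`, with attributes `n_dropped_le_c0` and `n_sets_excluded`.
#' @export
build_decay_records <- function(samples, analytes,
                                baseline_window = 2, fallback_window = 1,
                                peak_windows = 3:9) {
  if ("included" %in% names(samples)) {
    samples <- samples[samples$included, , drop = FALSE]
  }
  n_dropped <- 0L
  n_sets_excluded <- 0L
  recs <- lapply(analytes, function(b) {
    col <- paste0(b, "_ug_per_g")
    peaks <- locate_peak(samples, b, peak_windows)
    sets <- dplyr::group_split(samples, .data$subject_id, .data$session_id)
    out <- lapply(sets, function(d) {
      pk <- peaks[peaks$subject_id == d$subject_id[1] &
                    peaks$session_id == d$session_id[1], , drop = FALSE]
      c0 <- d[[col]][d$window_index == baseline_window]
      if (length(c0) == 0) c0 <- d[[col]][d$window_index == fallback_window]
      if (nrow(pk) == 0 || length(c0) == 0 || is.na(c0[1])) {
        n_sets_excluded <<- n_sets_excluded + 1L
        return(NULL)
      }
      c0 <- c0[1]
      post <- d[d$window_index %in% peak_windows &
                  d$time_h >= pk$t_peak & !is.na(d[[col]]), , drop = FALSE]
      keep <- post[[col]] > c0
      n_dropped <<- n_dropped + sum(!keep)
      post <- post[keep, , drop = FALSE]
      if (nrow(post) == 0) {
        n_sets_excluded <<- n_sets_excluded + 1L
        return(NULL)
      }
      ## kinetic time axis: accumulation-interval midpoints when available
      ## (a spot sample averages excretion over its interval), else void
      ## times
      tcol <- if ("t_mid_h" %in% names(post)) "t_mid_h" else "time_h"
      t_anchor <- if ("t_mid_h" %in% names(d)) {
        d$t_mid_h[d$time_h == pk$t_peak][1]
      } else pk$t_peak
      tibble::tibble(subject_id = post$subject_id,
                     session_id = post$session_id,
                     biomarker = b,
                     t = post[[tcol]] - t_anchor,
                     C = post[[col]], C0 = c0,
                     y = log(post[[col]] - c0))
    })
    dplyr::bind_rows(out)
  })
  recs <- dplyr::bind_rows(recs)
  attr(recs, "n_dropped_le_c0") <- n_dropped
  attr(recs, "n_sets_excluded") <- n_sets_excluded
  recs
}

#' Elimination half-lives from a fitted decay model
#'
#' Converts each biomarker's fitted elimination slope `lambda` (1/h, negative
#' for decay) into a half-life `log(2) / (-lambda)` (h), applying the same
#' monotone transform to the confidence-interval endpoints. Slopes `>= 0`
#' yield an undefined (NA) half-life and are flagged.
#'
#' @param fit An `eq1_fit` object from [fit_eq1_mixed()].
#' @return A tibble `biomarker`, `lambda`, `se`, `lambda_lower`,
#'   `lambda_upper`, `half_life`, `hl_lower`, `hl_upper`, `half_life_defined`.
#' @export
derive_half_lives <- function(fit) {
  stopifnot(inherits(fit, "eq1_fit"))
  b <- fit$biomarkers
  hl <- function(l) ifelse(l < 0, log(2) / (-l), NA_real_)
  tibble::tibble(
    biomarker = b$biomarker,
    lambda = b$lambda, se = b$se,
    lambda_lower = b$lambda_lower, lambda_upper = b$lambda_upper,
    half_life = hl(b$lambda),
    hl_lower = hl(b$lambda_lower),
    hl_upper = ifelse(b$lambda_upper < 0, log(2) / (-b$lambda_upper), Inf),
    half_life_defined = b$lambda < 0
  )
}

#' Time needed to decay from peak back to baseline
#'
#' Under monophasic first-order elimination, the number of halvings from the
#' peak to the baseline concentration is `log2(c_peak / c_base)`; the time
#' required is that number times the half-life. The rounded-halvings
#' convenience product (`round(n) * half_life`) is also reported, matching the
#' usual "about n half-lives" phrasing.
#'
#' @param c_peak,c_base Peak and baseline adjusted concentrations (ug/g),
#'   `c_peak >= c_base > 0`.
#' @param half_life Elimination half-life (h), > 0.
#' @return A list: `n_halvings`, `hours`, `hours_rounded_n`.
#' @export
time_to_baseline <- function(c_peak, c_base, half_life) {
  stopifnot(c_base > 0, c_peak >= c_base, half_life > 0)
  n <- log2(c_peak / c_base)
  list(n_halvings = n, hours = n * half_life,
       hours_rounded_n = round(n) * half_life)
}

#' Summarise time to peak per biomarker
#'
#' Median and range of the per-set time to peak (h since exposure onset).
#'
#' @param peaks A tibble of per-set peaks with a `biomarker` column, e.g.
#'   row-bound results of [locate_peak()] over several biomarkers.
#' @return A tibble `biomarker`, `n_sets`, `median_t_peak`, `min_t_peak`,
#'   `max_t_peak`.
#' @export
summarize_time_to_peak <- function(peaks) {
  stopifnot(nrow(peaks) >= 1)
  peaks |>
    dplyr::group_by(.data$biomarker) |>
    dplyr::summarise(n_sets = dplyr::n(),
                     median_t_peak = stats::median(.data$t_peak),
                     min_t_peak = min(.data$t_peak),
                     max_t_peak = max(.data$t_peak),
                     .groups = "drop")
}
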