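#' Per-window descriptive statistics of adjusted concentrations
#'
#' One row per sampling window and analyte with the sample count, median,
#' quartiles and range of the creatinine-adjusted concentration over all
#' included samples, in the layout of a stratified concentration table.
#'
#' @param samples Sample-level tibble from [preprocess_voids()]; only rows
#'   with `included == TRUE` enter the statistics (rows without the column
#'   are all used).
#' @param analytes Character vector of analyte names; default: all
#'   `*_ug_per_g` columns found.
#' @param convention Percentile convention: `"linear"` (interpolation of
#'   order statistics, `h = (n-1)p + 1`; R type 7, the default) or
#'   `"weighted"` (weighted-average convention, R type 6, as used by some
#'   commercial packages). Medians agree between the two; quartiles can
#'   differ in the last decimal.
#' @return A tibble with columns `window_index`, `analyte`, `n`, `median`,
#'   `p25`, `p75`, `min`, `max` (ug/g creatinine; `NA` where `n = 0`).
#' @export
summarize_by_window <- function(samples, analytes = NULL,
                                convention = c("linear", "weighted")) {
  convention <- match.arg(convention)
  qtype <- if (convention == "linear") 7 else 6
  if (is.null(analytes)) {
    analytes <- sub("_ug_per_g$", "",
                    grep("_ug_per_g$", names(samples), value = TRUE))
  }
  if ("included" %in% names(samples)) {
    samples <- samples[samples$included, , drop = FALSE]
  }
  grid <- tidyr::expand_grid(
    window_index = sort(unique(sampling_windows()$window_index)),
    analyte = analytes
  )
  purrr::pmap_dfr(grid, function(window_index, analyte) {
    v <- samples[[paste0(analyte, "_ug_per_g")]][
      samples$window_index == window_index]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      return(tibble::tibble(window_index = window_index, analyte = analyte,
                            n = 0L, median = NA_real_, p25 = NA_real_,
                            p75 = NA_real_, min = NA_real_, max = NA_real_))
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = qtype, names = FALSE)
    tibble::tibble(window_index = window_index, analyte = analyte,
                   n = length(v), median = q[2], p25 = q[1], p75 = q[3],
                   min = min(v), max = max(v))
  })
}

#' Relative concentration change between two samplings
#'
#' For each subject-session sample set where both windows are present and
#' included, the ratio `c_to / c_from` of creatinine-adjusted concentrations
#' (e.g. peak over pre-exposure baseline); the aggregate is the median ratio
#' over the sets.
#'
#' @param samples Sample-level tibble from [preprocess_voids()].
#' @param analyte Analyte name (e.g. `"DHN"`).
#' @param from_window,to_window Sampling-window indices (1..9).
#' @return A list: `ratios` (tibble with per-set `ratio`), `median_ratio`,
#'   and `n_skipped` (sets missing either window).
#' @export
relative_change <- function(samples, analyte, from_window = 2, to_window = 4) {
  col <- paste0(analyte, "_ug_per_g")
  stopifnot(col %in% names(samples))
  if ("included" %in% names(samples)) {
    samples <- samples[samples$included, , drop = FALSE]
  }
  sets <- samples |>
    dplyr::filter(.data$window_index %in% c(from_window, to_window)) |>
    dplyr::select("subject_id", "session_id", "window_index",
                  value = dplyr::all_of(col)) |>
    tidyr::pivot_wider(names_from = "window_index", values_from = "value",
                       names_prefix = "w")
  fw <- paste0("w", from_window); tw <- paste0("w", to_window)
  for (cc in c(fw, tw)) if (!cc %in% names(sets)) sets[[cc]] <- NA_real_
  complete <- !is.na(sets[[fw]]) & !is.na(sets[[tw]])
  ratios <- sets[complete, c("subject_id", "session_id")]
  ratios$ratio <- sets[[tw]][complete] / sets[[fw]][complete]
  list(ratios = ratios,
       median_ratio = if (nrow(ratios)) stats::median(ratios$ratio) else NA_real_,
       n_skipped = sum(!complete))
}

#' Per-window shares of the naphthalene metabolites
#'
#' Expresses each metabolite's median concentration as a percentage of the
#' summed medians of the three naphthalene metabolites (DHN, 1-NAP, 2-NAP)
#' in the same sampling window.
#'
#' @param medians A tibble with columns `window_index`, `analyte`, `median`
#'   (e.g. from [summarize_by_window()]), restricted to the metabolites whose
#'   shares are wanted; all medians must be `>= 0` and each window's sum
#'   `> 0`.
#' @return A tibble `window_index`, `analyte`, `share_pct` (exact, summing to
#'   100 per window) and `share_pct_rounded` (nearest integer, the reporting
#'   granularity).
#' @export
metabolite_proportions <- function(medians) {
  stopifnot(all(c("window_index", "analyte", "median") %in% names(medians)),
            all(medians$median >= 0))
  medians |>
    dplyr::group_by(.data$window_index) |>
    dplyr::group_modify(function(d, key) {
      tot <- sum(d$median)
      if (tot <= 0) stop("zero metabolite sum in window ", key$window_index)
      tibble::tibble(analyte = d$analyte,
                     share_pct = 100 * d$median / tot,
                     share_pct_rounded = round(100 * d$median / tot))
    }) |>
    dplyr::ungroup()
}

#' Pearson correlation of log concentrations between two analytes
#'
#' Correlation of the natural-log creatinine-adjusted concentrations across
#' all included samples (pooling subjects, sessions and windows), with the
#' two-sided p-value from the t transform on `n - 2` degrees of freedom.
#'
#' @param samples Sample-level tibble from [preprocess_voids()].
#' @param pair Character vector of two analyte names.
#' @return A tibble: `analyte_a`, `analyte_b`, `n`, `r`, `p`.
#' @export
log_pearson <- function(samples, pair) {
  stopifnot(length(pair) == 2)
  if ("included" %in% names(samples)) {
    samples <- samples[samples$included, , drop = FALSE]
  }
  x <- samples[[paste0(pair[1], "_ug_per_g")]]
  y <- samples[[paste0(pair[2], "_ug_per_g")]]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (any(x <= 0) || any(y <= 0)) stop("log correlation needs positive values")
  if (stats::sd(log(x)) == 0 || stats::sd(log(y)) == 0) {
    stop("zero variance in log concentrations")
  }
  ct <- stats::cor.test(log(x), log(y), method = "pearson",
                        alternative = "two.sided")
  tibble::tibble(analyte_a = pair[1], analyte_b = pair[2],
                 n = length(x), r = unname(ct$estimate), p = ct$p.value)
}

#' Concentration-time plot of the biomonitoring data
#'
#' Individual included samples as points over median lines per analyte, log
#' concentration axis. Requires ggplot2.
#'
#' @param samples Sample-level tibble from [preprocess_voids()].
#' @param analytes Analyte names to show; default all.
#' @return A ggplot object.
#' @export
plot_concentration_time <- function(samples, analytes = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  if (is.null(analytes)) {
    analytes <- sub("_ug_per_g$", "",
                    grep("_ug_per_g$", names(samples), value = TRUE))
  }
  if ("included" %in% names(samples)) {
    samples <- samples[samples$included, , drop = FALSE]
  }
  long <- samples |>
    dplyr::select("subject_id", "session_id", "window_index", "time_h",
                  dplyr::all_of(paste0(analytes, "_ug_per_g"))) |>
    tidyr::pivot_longer(dplyr::all_of(paste0(analytes, "_ug_per_g")),
                        names_to = "analyte", values_to = "conc") |>
    dplyr::mutate(analyte = sub("_ug_per_g$", "", .data$analyte))
  med <- long |>
    dplyr::group_by(.data$analyte, .data$window_index) |>
    dplyr::summarise(time_h = stats::median(.data$time_h),
                     conc = stats::median(.data$conc), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_h, y = .data$conc,
                                     colour = .data$analyte)) +
    ggplot2::geom_point(alpha = 0.4, size = 1) +
    ggplot2::geom_line(data = med, linewidth = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time since exposure onset (h)",
                  y = "Concentration (ug/g creatinine, log scale)",
                  colour = "Biomarker")
}
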