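## Independent oracles and small fixtures shared across test files.

## Dense multivariate-normal log-likelihood of decay records: builds the full
## covariance matrix entry by entry from the variance components, without any
## of the package's block assembly.
dense_loglik <- function(records, beta, components, ar1 = "order") {
  records <- records[order(records$subject_id, records$session_id,
                           records$biomarker, records$t), ]
  n <- nrow(records)
  lev <- sort(unique(as.character(records$biomarker)))
  X <- matrix(0, n, 2 * length(lev))
  colnames(X) <- c(paste0("biomarker", lev), paste0("biomarker", lev, ":t"))
  for (l in lev) {
    sel <- records$biomarker == l
    X[sel, paste0("biomarker", l)] <- 1
    X[sel, paste0("biomarker", l, ":t")] <- records$t[sel]
  }
  mu <- drop(X %*% beta[colnames(X)])

  series <- paste(records$subject_id, records$session_id, records$biomarker)
  rank_in_series <- stats::ave(records$t, series, FUN = rank)
  V <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (records$subject_id[i] != records$subject_id[j]) next
      v <- 0
      for (trm in components$terms) {
        same_unit <- if (trm$level == "participant") TRUE else
          records$session_id[i] == records$session_id[j]
        if (!same_unit) next
        G <- trm$cov
        v <- v + if (trm$with_slope) {
          G[1, 1] + G[1, 2] * (records$t[i] + records$t[j]) +
            G[2, 2] * records$t[i] * records$t[j]
        } else G[1, 1]
      }
      if (series[i] == series[j]) {
        d <- if (ar1 == "continuous") abs(records$t[i] - records$t[j])
             else abs(rank_in_series[i] - rank_in_series[j])
        v <- v + components$sigma2 * components$phi^d
      }
      V[i, j] <- v
    }
  }
  r <- records$y - mu
  as.numeric(-0.5 * (n * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       t(r) %*% solve(V, r)))
}

## deterministic small decay-record tables for fitter tests
make_tiny_records <- function(seed, n_subj = 2, n_ses = 2, n_bio = 2,
                              times = c(0, 2, 5), lambda = -0.11,
                              sigma = 0.3) {
  set.seed(seed)
  bio <- c("A", "B")[seq_len(n_bio)]
  grid <- expand.grid(subject_id = sprintf("S%d", seq_len(n_subj)),
                      session_id = sprintf("T%d", seq_len(n_ses)),
                      biomarker = bio, t = times,
                      stringsAsFactors = FALSE)
  u <- stats::rnorm(n_subj, 0, 0.2)
  grid$y <- 4 + as.numeric(factor(grid$biomarker)) * 0.3 +
    lambda * grid$t + stats::rnorm(nrow(grid), 0, sigma) +
    u[as.integer(factor(grid$subject_id))]
  tibble::as_tibble(grid)
}

## small hand-built sample table (already "preprocessed") for kinetics tests
make_sample_set <- function(conc, times = c(-4.2, -0.4, 2.0, 3.0, 5.2, 8.1,
                                            11.2, 12.7, 20.1),
                            subject = "S01", session = "T1",
                            analyte = "DHN", creatinine = 1) {
  stopifnot(length(conc) == length(times))
  out <- tibble::tibble(
    subject_id = subject, session_id = session,
    window_index = seq_along(times), time_h = times,
    volume_L = 0.2, creatinine_g_per_L = creatinine, n_pooled = 1L,
    included = TRUE)
  out[[paste0(analyte, "_ug_per_L")]] <- conc * creatinine
  out[[paste0(analyte, "_ug_per_g")]] <- conc
  out[[paste0(analyte, "_below_lod")]] <- FALSE
  out
}

## noise-free design for kinetic-fidelity checks
noise_free_design <- function(unscheduled_void_rate = 0, ...) {
  study_design(urine_flow_cv = 0, creatinine_subject_cv = 0,
               creatinine_void_cv = 0, baseline_subject_cv = 0,
               unscheduled_void_rate = unscheduled_void_rate, ...)
}

quiet_analyte <- function(name = "DHN", ke = log(2) / 6.6, ka = 1.2,
                          baseline_rate = 0, dose_mean = 100, lod = 1e-9,
                          assay_cv = 0, dose_cv = 0, fe = 1) {
  analyte_config(name, lod = lod, assay_cv = assay_cv,
                 baseline_rate = baseline_rate, dose_mean = dose_mean,
                 dose_cv = dose_cv, ka = ka, ke = ke, fe = fe)
}
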