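one_analyte <- list(DHN = analyte_config("DHN", lod = 0.3, assay_cv = 0,
                                         baseline_rate = 0.2, dose_mean = 0,
                                         dose_cv = 0, ka = 1.2,
                                         ke = log(2) / 6.6))

make_voids <- function(times, volumes, conc, crea = 1, scheduled,
                       window_index) {
  tibble::tibble(
    subject_id = "S01", session_id = "T1", time_h = times,
    volume_L = volumes, creatinine_g_per_L = crea,
    scheduled = scheduled, window_index = window_index,
    DHN_true_ug_per_L = conc, DHN_meas_ug_per_L = conc,
    DHN_below_lod = conc < 0.3)
}

test_that("pooling mixes voids by volume and conserves mass", {
  v <- make_voids(times = c(1, 2), volumes = c(0.2, 0.3), conc = c(100, 50),
                  scheduled = c(0L, 1L), window_index = c(NA, 3L))
  s <- pool_voids(v, one_analyte)
  expect_equal(nrow(s), 1L)
  expect_equal(s$volume_L, 0.5)
  expect_equal(s$DHN_meas_ug_per_L, 70)   # (20 + 15) ug / 0.5 L
  expect_equal(s$n_pooled, 2L)
  expect_equal(s$time_h, 2)

  ## identity when nothing is unscheduled
  v2 <- make_voids(times = 1:3, volumes = rep(0.2, 3), conc = c(5, 6, 7),
                   scheduled = rep(1L, 3), window_index = 1:3)
  s2 <- pool_voids(v2, one_analyte)
  expect_equal(s2$DHN_meas_ug_per_L, c(5, 6, 7))
  expect_equal(s2$n_pooled, rep(1L, 3))

  ## associativity: pooling pairwise equals pooling all at once
  V <- c(0.1, 0.25, 0.3); C <- c(80, 20, 45)
  pair <- sum(C[1:2] * V[1:2]) / sum(V[1:2])
  seq_pool <- (pair * sum(V[1:2]) + C[3] * V[3]) / sum(V)
  all_pool <- sum(C * V) / sum(V)
  expect_equal(seq_pool, all_pool)
  v3 <- make_voids(times = 1:3, volumes = V, conc = C,
                   scheduled = c(0L, 0L, 1L), window_index = c(NA, NA, 3L))
  expect_equal(pool_voids(v3, one_analyte)$DHN_meas_ug_per_L, all_pool)

  ## trailing unscheduled voids are dropped with a warning
  v4 <- make_voids(times = c(1, 2), volumes = c(0.2, 0.2), conc = c(5, 5),
                   scheduled = c(1L, 0L), window_index = c(3L, NA))
  expect_warning(s4 <- pool_voids(v4, one_analyte), "trailing")
  expect_equal(nrow(s4), 1L)
  expect_error(pool_voids(make_voids(1, 0.2, 5, scheduled = 0L,
                                     window_index = NA), one_analyte),
               "scheduled")
})

test_that("pooling re-evaluates the censoring flag on the pooled sample", {
  ## below-LOD void pooled into a high scheduled void: pooled value > LOD
  v <- make_voids(times = c(1, 2), volumes = c(0.1, 0.4), conc = c(0.1, 10),
                  scheduled = c(0L, 1L), window_index = c(NA, 3L))
  s <- pool_voids(v, one_analyte)
  expect_false(s$DHN_below_lod)
  expect_equal(s$DHN_meas_ug_per_L, (0.01 + 4) / 0.5)
})

test_that("LOD substitution uses half the detection limit and is idempotent", {
  expect_equal(substitute_lod(0.12, TRUE, 0.3), 0.15)
  expect_equal(substitute_lod(5.0, FALSE, 0.3), 5.0)
  expect_equal(substitute_lod(0.005, TRUE, 0.02), 0.01)
  x <- c(0.05, 2, 0.2); f <- c(TRUE, FALSE, TRUE)
  once <- substitute_lod(x, f, 0.3)
  expect_equal(substitute_lod(once, f, 0.3), once)
})

test_that("creatinine adjustment divides by the creatinine concentration", {
  expect_equal(adjust_creatinine(10, 1.0), 10)
  expect_equal(adjust_creatinine(5, 2.0), 2.5)
  expect_equal(adjust_creatinine(0.15, 0.5), 0.3)
  expect_error(adjust_creatinine(1, 0), "creatinine")
})

test_that("inclusion bounds are inclusive and the accounting balances", {
  s <- tibble::tibble(creatinine_g_per_L = c(0.29, 0.30, 1.0, 3.00, 3.01))
  r <- apply_inclusion(s)
  expect_equal(r$samples$included, c(FALSE, TRUE, TRUE, TRUE, FALSE))

  ## all-compliant protocol-sized table
  r2 <- apply_inclusion(tibble::tibble(creatinine_g_per_L = rep(1, 270)))
  expect_equal(r2$accounting$included, 270)
  expect_equal(r2$accounting$excluded_creatinine, 0)

  ## the published accounting arithmetic: 2 missing, 31 out of range
  crea <- c(rep(1, 237), rep(0.1, 31))
  r3 <- apply_inclusion(tibble::tibble(creatinine_g_per_L = crea),
                        expected = 270)
  a <- r3$accounting
  expect_equal(a$collected, 268)
  expect_equal(a$missing, 2)
  expect_equal(a$included, 237)
  expect_equal(a$collected, a$expected - a$missing)
  expect_equal(a$included + a$excluded_creatinine, a$collected)
})

test_that("inclusion flags are per-sample (adding rows changes nothing)", {
  s <- tibble::tibble(creatinine_g_per_L = c(0.5, 2.9, 0.2))
  f1 <- apply_inclusion(s)$samples$included
  f2 <- apply_inclusion(dplyr::bind_rows(
    s, tibble::tibble(creatinine_g_per_L = 5)))$samples$included
  expect_equal(f2[1:3], f1)
})

test_that("processed samples round-trip through CSV", {
  v <- simulate_study(study_design(n_subjects = 2, n_sessions = 1),
                      paper_analytes(), seed = 21)
  prep <- preprocess_voids(v)
  path <- withr::local_tempfile(fileext = ".csv")
  write_samples(prep$samples, path, metadata = list(seed = 21))
  back <- read_samples(path)
  expect_equal(as.data.frame(back), as.data.frame(prep$samples),
               tolerance = 1e-9)

  vpath <- withr::local_tempfile(fileext = ".csv")
  write_voids(v, vpath, metadata = list(seed = 21))
  expect_equal(as.data.frame(read_voids(vpath)), as.data.frame(v),
               tolerance = 1e-9)
})

test_that("full preprocessing produces adjusted, flagged, accounted samples", {
  v <- simulate_study(study_design(), paper_analytes(), seed = 12)
  prep <- preprocess_voids(v, expected = 270)
  s <- prep$samples
  expect_equal(nrow(s), 270)
  expect_true(all(s$DHN_ug_per_g == s$DHN_ug_per_L / s$creatinine_g_per_L))
  expect_equal(prep$accounting$included + prep$accounting$excluded_creatinine,
               270)
  ## substituted values never sit below half the LOD
  expect_true(all(s$DHN_ug_per_L[s$DHN_below_lod] == 0.15))
  ## one sample per window per set, strictly increasing times
  per_set <- split(s, paste(s$subject_id, s$session_id))
  expect_true(all(vapply(per_set, function(d) {
    !anyDuplicated(d$window_index) && all(diff(d$time_h) > 0)
  }, logical(1))))
})
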