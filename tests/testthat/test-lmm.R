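test_that("perfect exponential data is fitted exactly", {
  ## noise-free ln(C - C0) is a straight line; OLS limit of the model
  t <- seq(0, 12, by = 2)
  recs <- tibble::tibble(subject_id = "S1", session_id = "T1",
                         biomarker = "DHN", t = t, y = log(100) - 0.1 * t)
  fit <- fit_eq1_mixed(recs, eq1_spec(random = "none", ar1 = "none"))
  expect_equal(fit$biomarkers$lambda, -0.1, tolerance = 1e-8)
  expect_equal(fit$biomarkers$intercept, log(100), tolerance = 1e-8)
  expect_equal(fit$biomarkers$half_life, log(2) / 0.1, tolerance = 1e-6)

  ## two perfect subjects under the full model: slope still exact, and the
  ## variance components collapse towards zero
  recs2 <- dplyr::bind_rows(recs, dplyr::mutate(recs, subject_id = "S2"))
  fit2 <- fit_eq1_mixed(recs2)
  expect_equal(fit2$biomarkers$lambda, -0.1, tolerance = 1e-6)
  expect_lt(fit2$components$sigma2, 1e-6)
  expect_true(fit2$boundary)
})

test_that("with no random effects and no AR(1), the fit is exactly OLS", {
  recs <- make_tiny_records(seed = 101, n_subj = 3, n_ses = 2, n_bio = 2,
                            times = c(0, 1.5, 4, 7))
  fit <- fit_eq1_mixed(recs, eq1_spec(random = "none", ar1 = "none"))
  ols <- lm(y ~ 0 + biomarker + biomarker:t, data = recs)
  co <- coef(ols)
  expect_equal(fit$biomarkers$lambda,
               unname(co[paste0("biomarker", c("A", "B"), ":t")]),
               tolerance = 1e-8)
  expect_equal(fit$biomarkers$intercept,
               unname(co[paste0("biomarker", c("A", "B"))]),
               tolerance = 1e-8)
})

test_that("a fixed AR(1) with no random effects matches closed-form GLS", {
  recs <- make_tiny_records(seed = 7, n_subj = 2, n_ses = 2, n_bio = 1,
                            times = c(0, 2, 4, 6))
  phi <- 0.5
  fit <- fit_eq1_mixed(recs, eq1_spec(random = "none", ar1 = "order",
                                      fix_phi = phi))
  ## closed form: beta = (X' R^-1 X)^-1 X' R^-1 y with R block AR(1)
  recs_o <- recs[order(recs$subject_id, recs$session_id, recs$biomarker,
                       recs$t), ]
  n <- nrow(recs_o)
  X <- cbind(1, recs_o$t)
  series <- paste(recs_o$subject_id, recs_o$session_id)
  pos <- stats::ave(seq_len(n), series, FUN = seq_along)
  R <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (series[i] == series[j]) R[i, j] <- phi^abs(pos[i] - pos[j])
  }
  beta <- solve(t(X) %*% solve(R, X), t(X) %*% solve(R, recs_o$y))
  expect_equal(fit$biomarkers$lambda, beta[2, 1], tolerance = 1e-8)
  expect_equal(fit$biomarkers$intercept, beta[1, 1], tolerance = 1e-8)
  expect_equal(fit$components$phi, phi)
})

test_that("the structured likelihood equals a dense MVN construction", {
  ## arbitrary (not fitted) components, several random tiny instances
  for (seed in 1:5) {
    recs <- make_tiny_records(seed = seed, n_subj = sample(2:3, 1),
                              n_ses = 2, n_bio = 2, times = c(0, 2, 5))
    spec <- eq1_spec()
    components <- list(
      terms = list(
        list(level = "participant", with_slope = TRUE,
             cov = matrix(c(0.05, 0.012, 0.012, 0.004), 2)),
        list(level = "session", with_slope = FALSE,
             cov = matrix(0.03, 1, 1))),
      sigma2 = 0.09, phi = 0.4)
    beta <- c(4.1, 4.5, -0.09, -0.12)
    names(beta) <- c("biomarkerA", "biomarkerB",
                     "biomarkerA:t", "biomarkerB:t")
    ll_pkg <- eq1_loglik(recs, spec, beta, components)
    ll_oracle <- dense_loglik(recs, beta, components)
    expect_equal(ll_pkg, ll_oracle, tolerance = 1e-6)
  }

  ## and at fitted parameters on one instance
  recs <- make_tiny_records(seed = 31, n_subj = 3, n_ses = 2, n_bio = 1,
                            times = c(0, 2, 5, 9))
  fit <- fit_eq1_mixed(recs)
  ll_pkg <- eq1_loglik(recs, fit$spec, fit$beta, fit$components)
  ll_oracle <- dense_loglik(recs, fit$beta, fit$components)
  expect_equal(ll_pkg, ll_oracle, tolerance = 1e-6)
})

test_that("random intercepts with phi = 0 reproduce a compound-symmetry fit", {
  skip_if_not_installed("nlme")
  ## strong subject intercepts so the intraclass correlation is clearly
  ## positive (a random intercept cannot represent a negative ICC, while
  ## corCompSymm can)
  set.seed(170)
  recs <- make_tiny_records(seed = 17, n_subj = 4, n_ses = 2, n_bio = 1,
                            times = c(0, 2, 4, 8), sigma = 0.2)
  u <- rnorm(4, 0, 0.6)
  recs$y <- recs$y + u[as.integer(factor(recs$subject_id))]
  fit <- fit_eq1_mixed(recs, eq1_spec(random = "intercepts",
                                      session_intercept = FALSE,
                                      ar1 = "none", method = "ML"))
  g <- nlme::gls(y ~ t, data = recs,
                 correlation = nlme::corCompSymm(form = ~ 1 | subject_id),
                 method = "ML")
  expect_equal(fit$biomarkers$lambda, unname(coef(g)["t"]), tolerance = 1e-4)
  expect_equal(fit$biomarkers$intercept, unname(coef(g)["(Intercept)"]),
               tolerance = 1e-4)
  expect_equal(as.numeric(fit$logLik), as.numeric(logLik(g)),
               tolerance = 1e-6)
})

test_that("the full model agrees with an independent mixed-model fitter", {
  skip_if_not_installed("nlme")
  set.seed(505)
  ## one biomarker, 5 subjects x 3 sessions x 6 times, AR(1) noise
  grid <- expand.grid(subject_id = sprintf("S%d", 1:5),
                      session_id = sprintf("T%d", 1:3),
                      t = c(0, 2, 4, 7, 10, 17), stringsAsFactors = FALSE)
  grid <- grid[order(grid$subject_id, grid$session_id, grid$t), ]
  u0 <- rnorm(5, 0, 0.3); u1 <- rnorm(5, 0, 0.015)
  w <- rnorm(15, 0, 0.2)
  phi <- 0.5
  grid$y <- NA_real_
  for (s in 1:5) for (k in 1:3) {
    idx <- grid$subject_id == sprintf("S%d", s) &
      grid$session_id == sprintf("T%d", k)
    e <- as.numeric(arima.sim(list(ar = phi), n = sum(idx), sd = 0.25))
    grid$y[idx] <- 4.5 + u0[s] + (-0.105 + u1[s]) * grid$t[idx] +
      w[(s - 1) * 3 + k] + e
  }
  recs <- tibble::as_tibble(cbind(grid, biomarker = "DHN"))
  fit <- fit_eq1_mixed(recs)
  lme_fit <- nlme::lme(
    y ~ t, data = recs,
    random = list(subject_id = ~ t, session_id = ~ 1),
    correlation = nlme::corAR1(form = ~ 1 | subject_id / session_id),
    method = "REML", control = nlme::lmeControl(opt = "optim"))
  expect_equal(fit$biomarkers$lambda, unname(nlme::fixef(lme_fit)["t"]),
               tolerance = 1e-3)
  expect_equal(fit$components$phi,
               as.numeric(coef(lme_fit$modelStruct$corStruct,
                               unconstrained = FALSE)),
               tolerance = 0.05)
})

test_that("rescaling concentrations shifts intercepts, not slopes", {
  recs <- make_tiny_records(seed = 23, n_subj = 3, n_ses = 2, n_bio = 2,
                            times = c(0, 2, 5, 9))
  fit1 <- fit_eq1_mixed(recs)
  recs2 <- dplyr::mutate(recs, y = y + log(7.3))  # C and C0 scaled by 7.3
  fit2 <- fit_eq1_mixed(recs2)
  expect_equal(fit2$biomarkers$lambda, fit1$biomarkers$lambda,
               tolerance = 1e-6)
  expect_equal(fit2$biomarkers$intercept - fit1$biomarkers$intercept,
               rep(log(7.3), 2), tolerance = 1e-5)
})

test_that("degenerate inputs are rejected with clear errors", {
  recs <- make_tiny_records(seed = 1, n_subj = 2, n_ses = 1, n_bio = 1,
                            times = c(0, 3))
  recs$t <- 0
  expect_error(fit_eq1_mixed(recs), "distinct times")
  one_sub <- make_tiny_records(seed = 1, n_subj = 1, n_ses = 2, n_bio = 1,
                               times = c(0, 2, 4))
  expect_warning(fit_eq1_mixed(one_sub), "fewer than 2 participants")
})
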