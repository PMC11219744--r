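#' Specification of the exponential-decay mixed model
#'
#' Controls the structure and estimation of the linear mixed model for
#' post-peak log concentration differences `y = ln(C - C0)`: fixed effects are
#' a per-biomarker intercept (`ln B_b`) and slope (`lambda_b`, the elimination
#' rate); random effects and the residual correlation capture the
#' repeated-measures structure of participants completing several training
#' sessions.
#'
#' @param random Random-effects structure: `"slopes"` (default; random
#'   intercept and correlated random `t`-slope at the level chosen by
#'   `slope_level`, plus a session-within-participant random intercept),
#'   `"intercepts"` (random intercepts only), or `"none"`.
#' @param slope_level Level carrying the random slope when
#'   `random = "slopes"`: `"participant"` (default) or `"session"` (the
#'   session-within-participant level; the participant level then keeps a
#'   random intercept).
#' @param session_intercept Keep the session-within-participant random
#'   intercept (ignored when `random = "none"`).
#' @param ar1 Residual correlation within each time-ordered
#'   subject-session-biomarker series: `"order"` (default; correlation
#'   `phi^|i-j|` of observation ranks), `"continuous"` (`phi^|t_i-t_j|`,
#'   `phi` in (0,1)), or `"none"`.
#' @param fix_phi Optional fixed value for the AR(1) parameter (e.g. 0);
#'   `NULL` estimates it.
#' @param method `"REML"` (default) or `"ML"`.
#' @param ci Interval type for fixed effects: `"t"` (default; t quantile with
#'   `n_participants - 2` degrees of freedom, a conservative small-sample
#'   choice) or `"normal"` (Wald).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `eq1_spec`.
#' @export
eq1_spec <- function(random = c("slopes", "intercepts", "none"),
                     slope_level = c("participant", "session"),
                     session_intercept = TRUE,
                     ar1 = c("order", "continuous", "none"),
                     fix_phi = NULL,
                     method = c("REML", "ML"),
                     ci = c("t", "normal"),
                     conf_level = 0.95) {
  structure(
    list(random = match.arg(random),
         slope_level = match.arg(slope_level),
         session_intercept = isTRUE(session_intercept),
         ar1 = match.arg(ar1),
         fix_phi = fix_phi,
         method = match.arg(method),
         ci = match.arg(ci),
         conf_level = conf_level),
    class = "eq1_spec")
}

## ---- internal model assembly -------------------------------------------

## random-effect term list: each term = list(level, with_slope)
re_terms <- function(spec) {
  if (spec$random == "none") return(list())
  terms <- list()
  if (spec$random == "slopes" && spec$slope_level == "participant") {
    terms <- c(terms, list(list(level = "participant", with_slope = TRUE)))
    if (spec$session_intercept) {
      terms <- c(terms, list(list(level = "session", with_slope = FALSE)))
    }
  } else if (spec$random == "slopes") {
    terms <- c(terms, list(list(level = "participant", with_slope = FALSE)))
    terms <- c(terms, list(list(level = "session", with_slope = TRUE)))
  } else {
    terms <- c(terms, list(list(level = "participant", with_slope = FALSE)))
    if (spec$session_intercept) {
      terms <- c(terms, list(list(level = "session", with_slope = FALSE)))
    }
  }
  terms
}

## per-participant fixed/random design and AR(1) series layout
build_blocks <- function(records, spec) {
  stopifnot(all(c("subject_id", "session_id", "biomarker", "t", "y")
                %in% names(records)))
  records$biomarker <- factor(records$biomarker)
  ord <- order(records$subject_id, records$session_id,
               records$biomarker, records$t)
  records <- records[ord, , drop = FALSE]
  ## cell-means coding of biomarker + biomarker:t (robust to 1 level)
  lev <- levels(records$biomarker)
  Xint <- vapply(lev, function(l) as.numeric(records$biomarker == l),
                 numeric(nrow(records)))
  Xslp <- Xint * records$t
  X <- cbind(Xint, Xslp)
  colnames(X) <- c(paste0("biomarker", lev), paste0("biomarker", lev, ":t"))
  terms <- re_terms(spec)
  split_idx <- split(seq_len(nrow(records)), records$subject_id)
  blocks <- lapply(split_idx, function(idx) {
    d <- records[idx, , drop = FALSE]
    ## each term: Z with columns grouped per level unit (intercept[, slope]),
    ## marginal covariance kronecker(I_groups, cov)
    Zs <- lapply(terms, function(trm) {
      if (trm$level == "participant") {
        Z <- if (trm$with_slope) cbind(1, d$t) else cbind(rep(1, nrow(d)))
        list(Z = Z, groups = 1L)
      } else {
        f <- factor(d$session_id)
        cols <- lapply(levels(f), function(l) {
          ind <- as.numeric(d$session_id == l)
          if (trm$with_slope) cbind(ind, ind * d$t) else cbind(ind)
        })
        list(Z = do.call(cbind, cols), groups = nlevels(f))
      }
    })
    series <- interaction(d$session_id, d$biomarker, drop = TRUE)
    ser <- lapply(split(seq_len(nrow(d)), series), function(s) {
      D <- if (spec$ar1 == "continuous") abs(outer(d$t[s], d$t[s], "-"))
           else abs(outer(seq_along(s), seq_along(s), "-"))
      list(idx = s, D = D)
    })
    list(X = X[idx, , drop = FALSE], y = d$y, Zs = Zs, series = ser,
         n = length(idx))
  })
  list(blocks = blocks, X = X, records = records, terms = terms,
       coef_names = colnames(X),
       n_participants = length(blocks), n = nrow(records))
}

## theta layout: per term 3 params (log-Cholesky) or 1 (log sd); log sigma;
## optional transformed phi
theta_layout <- function(spec) {
  terms <- re_terms(spec)
  sizes <- vapply(terms, function(trm) if (trm$with_slope) 3L else 1L,
                  integer(1))
  n_phi <- if (spec$ar1 != "none" && is.null(spec$fix_phi)) 1L else 0L
  list(sizes = sizes, n_theta = sum(sizes) + 1L + n_phi, n_phi = n_phi)
}

## decode theta -> list of covariance matrices, sigma2, phi
decode_theta <- function(theta, spec) {
  lay <- theta_layout(spec)
  covs <- list()
  pos <- 1L
  for (sz in lay$sizes) {
    if (sz == 3L) {
      L <- matrix(c(exp(theta[pos]), theta[pos + 1], 0, exp(theta[pos + 2])),
                  2, 2)
      covs <- c(covs, list(L %*% t(L)))
    } else {
      covs <- c(covs, list(matrix(exp(2 * theta[pos]), 1, 1)))
    }
    pos <- pos + sz
  }
  sigma2 <- exp(2 * theta[pos]); pos <- pos + 1L
  phi <- if (lay$n_phi == 1L) {
    if (spec$ar1 == "continuous") stats::plogis(theta[pos]) else tanh(theta[pos])
  } else if (spec$ar1 != "none") spec$fix_phi else 0
  list(covs = covs, sigma2 = sigma2, phi = phi)
}

## marginal covariance of one participant block
block_cov <- function(blk, comp) {
  V <- matrix(0, blk$n, blk$n)
  for (k in seq_along(blk$Zs)) {
    Z <- blk$Zs[[k]]$Z
    G <- diag(blk$Zs[[k]]$groups) %x% comp$covs[[k]]
    V <- V + Z %*% G %*% t(Z)
  }
  for (s in blk$series) {
    V[s$idx, s$idx] <- V[s$idx, s$idx] + comp$sigma2 * comp$phi^s$D
  }
  V
}

## profile -2 log likelihood (ML or REML) over theta; beta profiled by GLS
neg2ll <- function(theta, bl, spec) {
  comp <- decode_theta(theta, spec)
  p <- ncol(bl$blocks[[1]]$X)
  XtVX <- matrix(0, p, p); XtVy <- numeric(p)
  yVy <- 0; logdet <- 0
  for (blk in bl$blocks) {
    V <- block_cov(blk, comp)
    U <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(U)) return(1e10)
    Qx <- backsolve(U, blk$X, transpose = TRUE)
    Qy <- backsolve(U, blk$y, transpose = TRUE)
    XtVX <- XtVX + crossprod(Qx)
    XtVy <- XtVy + drop(crossprod(Qx, Qy))
    yVy <- yVy + sum(Qy^2)
    logdet <- logdet + 2 * sum(log(diag(U)))
  }
  beta <- tryCatch(solve(XtVX, XtVy), error = function(e) NULL)
  if (is.null(beta)) return(1e10)
  quad <- yVy - sum(beta * XtVy)
  N <- bl$n
  out <- if (spec$method == "REML") {
    (N - p) * log(2 * pi) + logdet + determinant(XtVX)$modulus + quad
  } else {
    N * log(2 * pi) + logdet + quad
  }
  as.numeric(out)
}

## beta, vcov and components at a given theta
gls_at <- function(theta, bl, spec) {
  comp <- decode_theta(theta, spec)
  p <- ncol(bl$blocks[[1]]$X)
  XtVX <- matrix(0, p, p); XtVy <- numeric(p)
  for (blk in bl$blocks) {
    V <- block_cov(blk, comp)
    U <- chol(V)
    Qx <- backsolve(U, blk$X, transpose = TRUE)
    Qy <- backsolve(U, blk$y, transpose = TRUE)
    XtVX <- XtVX + crossprod(Qx)
    XtVy <- XtVy + drop(crossprod(Qx, Qy))
  }
  beta <- solve(XtVX, XtVy)
  vcov_beta <- solve(XtVX)
  names(beta) <- bl$coef_names
  dimnames(vcov_beta) <- list(bl$coef_names, bl$coef_names)
  list(beta = beta, vcov_beta = vcov_beta, components = comp)
}

## deterministic starting values: a generic spread-based start plus a
## method-of-moments start from per-series OLS lines (within-series residual
## sd -> sigma, lag-1 residual autocorrelation -> phi, dispersion of series
## intercepts/slopes across units -> variance starts)
theta_start <- function(bl, spec) {
  X <- do.call(rbind, lapply(bl$blocks, `[[`, "X"))
  y <- unlist(lapply(bl$blocks, `[[`, "y"))
  s <- sqrt(max(stats::deviance(stats::lm.fit(X, y)) /
                  max(1, length(y) - ncol(X)), 1e-4))
  lay <- theta_layout(spec)
  phi_t <- function(p) if (spec$ar1 == "continuous") stats::qlogis(p) else atanh(p)

  generic <- numeric(0)
  for (sz in lay$sizes) {
    generic <- c(generic,
                 if (sz == 3L) c(log(s / 2), 0, log(s / 20)) else log(s / 2))
  }
  generic <- c(generic, log(0.7 * s))
  if (lay$n_phi == 1L) generic <- c(generic, phi_t(0.2))

  ## method-of-moments start from per-series lines
  rec <- bl$records
  series <- interaction(rec$subject_id, rec$session_id, rec$biomarker,
                        drop = TRUE)
  ints <- slps <- numeric(0); subj <- character(0)
  resids <- list()
  for (sid in levels(series)) {
    d <- rec[series == sid, , drop = FALSE]
    if (nrow(d) >= 3 && length(unique(d$t)) >= 2) {
      cf <- stats::coef(f <- stats::lm.fit(cbind(1, d$t), d$y))
      ints <- c(ints, cf[1]); slps <- c(slps, cf[2])
      subj <- c(subj, as.character(d$subject_id[1]))
      resids <- c(resids, list(f$residuals))
    }
  }
  mom <- generic
  if (length(ints) >= 3) {
    e <- unlist(resids)
    sigma0 <- max(stats::sd(e), s / 10, 1e-3)
    lag1 <- unlist(lapply(resids, function(r) {
      if (length(r) >= 3) r[-1] * r[-length(r)] else numeric(0)
    }))
    phi0 <- min(max(sum(lag1) / sum(e^2), 0.05), 0.8)
    sd_int <- max(stats::sd(tapply(ints, subj, mean)), sigma0 / 10)
    sd_slp <- max(stats::sd(tapply(slps, subj, mean)), sigma0 / 100)
    sd_ses <- max(sqrt(max(stats::var(ints) -
                             sd_int^2, 0)), sigma0 / 10)
    per_level <- function(sz) {
      if (sz == 3L) c(log(sd_int), 0, log(sd_slp)) else log(sd_ses)
    }
    mom <- numeric(0)
    for (sz in lay$sizes) mom <- c(mom, per_level(sz))
    mom <- c(mom, log(sigma0))
    if (lay$n_phi == 1L) mom <- c(mom, phi_t(phi0))
  }
  unique(list(mom, generic))
}

#' Fit the exponential-decay linear mixed model
#'
#' Fits `y = ln(C - C0)` against time since peak with per-biomarker fixed
#' intercepts and slopes, random effects per [eq1_spec()], and AR(1)
#' residual correlation, by maximising the restricted (or full) marginal
#' Gaussian likelihood. The marginal covariance of each participant's record
#' vector is assembled from the random-effect design blocks plus an
#' AR(1)-structured residual block within each time-ordered
#' subject-session-biomarker series; fixed effects are profiled out by
#' generalised least squares. Optimisation uses `nlminb` over transformed
#' parameters (log-Cholesky factors for covariance blocks, log sigma, atanh
#' or logistic phi) from fixed, documented starting values, so the fit is
#' deterministic given the input records.
#'
#' @param records Decay-record tibble from [build_decay_records()] (columns
#'   `subject_id`, `session_id`, `biomarker`, `t`, `y`).
#' @param spec An [eq1_spec()].
#' @param control Passed to [stats::nlminb()]'s `control` (defaults:
#'   `iter.max = 500`, `eval.max = 800`, `rel.tol = 1e-10`).
#' @return An object of class `eq1_fit`: per-biomarker slope table
#'   (`$biomarkers`), fixed effects (`$beta`, `$vcov_beta`), variance
#'   components (`$components`: covariance matrix per random term, `sigma2`,
#'   `phi`), `$logLik`, `$converged`, bookkeeping counts, and the spec.
#' @export
fit_eq1_mixed <- function(records, spec = eq1_spec(), control = list()) {
  stopifnot(inherits(spec, "eq1_spec"))
  records <- tibble::as_tibble(records)
  if (length(unique(records$subject_id)) < 2 && spec$random != "none") {
    warning("fewer than 2 participants; random-effect variances are weakly ",
            "identified")
  }
  for (b in unique(records$biomarker)) {
    if (length(unique(records$t[records$biomarker == b])) < 2) {
      stop("biomarker ", b, " has fewer than 2 distinct times since peak")
    }
  }
  bl <- build_blocks(records, spec)
  ctl <- utils::modifyList(list(iter.max = 500, eval.max = 800,
                                rel.tol = 1e-10), control)
  starts <- theta_start(bl, spec)
  opt <- NULL
  for (start in starts) {
    cand <- stats::nlminb(start, neg2ll, bl = bl, spec = spec,
                          lower = rep(-15, length(start)),
                          upper = rep(15, length(start)), control = ctl)
    if (cand$convergence != 0) {
      ## one deterministic restart from the terminating point;
      ## boundary-bound variance components often trip "false convergence"
      cand2 <- stats::nlminb(cand$par, neg2ll, bl = bl, spec = spec,
                             lower = rep(-15, length(cand$par)),
                             upper = rep(15, length(cand$par)),
                             control = ctl)
      if (cand2$objective <= cand$objective) cand <- cand2
    }
    if (is.null(opt) || cand$objective < opt$objective) opt <- cand
  }
  sol <- gls_at(opt$par, bl, spec)
  converged <- opt$convergence == 0 && is.finite(opt$objective)

  ## per-biomarker slope table
  lev <- levels(bl$records$biomarker)
  slope_names <- paste0("biomarker", lev, ":t")
  int_names <- paste0("biomarker", lev)
  q <- if (spec$ci == "t") {
    stats::qt(1 - (1 - spec$conf_level) / 2, df = max(1, bl$n_participants - 2))
  } else {
    stats::qnorm(1 - (1 - spec$conf_level) / 2)
  }
  lambda <- sol$beta[slope_names]
  se <- sqrt(diag(sol$vcov_beta)[slope_names])
  biomarkers <- tibble::tibble(
    biomarker = lev,
    n_records = as.integer(table(bl$records$biomarker)[lev]),
    intercept = unname(sol$beta[int_names]),
    lambda = unname(lambda), se = unname(se),
    lambda_lower = unname(lambda - q * se),
    lambda_upper = unname(lambda + q * se)
  )
  hl <- derive_half_lives_table(biomarkers)
  biomarkers <- dplyr::left_join(
    biomarkers, hl[, c("biomarker", "half_life", "hl_lower", "hl_upper")],
    by = "biomarker")

  ## flag variance components pinned at the lower boundary
  pinned <- any(abs(opt$par - (-15)) < 1e-6)
  structure(
    list(biomarkers = biomarkers, beta = sol$beta,
         vcov_beta = sol$vcov_beta,
         components = list(
           terms = lapply(seq_along(bl$terms), function(k) {
             list(level = bl$terms[[k]]$level,
                  with_slope = bl$terms[[k]]$with_slope,
                  cov = sol$components$covs[[k]])
           }),
           sigma2 = sol$components$sigma2,
           phi = sol$components$phi),
         logLik = -0.5 * opt$objective,
         objective = opt$objective,
         method = spec$method,
         converged = converged,
         boundary = pinned,
         message = opt$message,
         theta = opt$par,
         n_records = bl$n, n_participants = bl$n_participants,
         spec = spec),
    class = "eq1_fit")
}

## half-life transform used both internally and by derive_half_lives()
derive_half_lives_table <- function(b) {
  hl <- function(l) ifelse(l < 0, log(2) / (-l), NA_real_)
  tibble::tibble(
    biomarker = b$biomarker,
    half_life = hl(b$lambda),
    hl_lower = hl(b$lambda_lower),
    hl_upper = ifelse(b$lambda_upper < 0, log(2) / (-b$lambda_upper), Inf))
}

#' Marginal Gaussian log-likelihood of the decay model
#'
#' Evaluates the (unprofiled) multivariate-normal log-likelihood of the
#' records under given fixed effects and variance components, assembling the
#' per-participant covariance blocks exactly as the fitter does. Mainly a
#' verification surface: an independent dense construction of the full
#' covariance matrix must reproduce this value.
#'
#' @param records Decay-record tibble (see [fit_eq1_mixed()]).
#' @param spec An [eq1_spec()].
#' @param beta Named fixed-effect vector (as `fit$beta`).
#' @param components Variance components (as `fit$components`).
#' @return The log-likelihood (a scalar).
#' @export
eq1_loglik <- function(records, spec, beta, components) {
  bl <- build_blocks(records, spec)
  comp <- list(covs = lapply(components$terms, `[[`, "cov"),
               sigma2 = components$sigma2, phi = components$phi)
  ll <- 0
  for (blk in bl$blocks) {
    V <- block_cov(blk, comp)
    U <- chol(V)
    r <- blk$y - drop(blk$X %*% beta[bl$coef_names])
    Qr <- backsolve(U, r, transpose = TRUE)
    ll <- ll - 0.5 * (blk$n * log(2 * pi) + 2 * sum(log(diag(U))) +
                        sum(Qr^2))
  }
  ll
}

#' @export
print.eq1_fit <- function(x, ...) {
  cat(sprintf("<eq1_fit> %s, %d records, %d participants, %s\n",
              x$method, x$n_records, x$n_participants,
              if (x$converged) "converged" else "NOT CONVERGED"))
  cat(sprintf("  sigma = %.4g, phi = %.3f, logLik = %.3f\n",
              sqrt(x$components$sigma2), x$components$phi, x$logLik))
  b <- x$biomarkers
  for (i in seq_len(nrow(b))) {
    cat(sprintf("  %-5s lambda %8.5f (se %.5f)  t1/2 %5.2f h [%.2f, %.2f]\n",
                b$biomarker[i], b$lambda[i], b$se[i], b$half_life[i],
                b$hl_lower[i], b$hl_upper[i]))
  }
  invisible(x)
}
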