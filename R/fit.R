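#' @importFrom generics tidy glance
NULL

# negative FIML log-likelihood and its analytic gradient via the RAM
# chain rule. Non-PD implied covariances are treated as infeasible.
make_objective <- function(sk, pats) {
  nlab <- length(sk$labels)
  BIG <- 1e12
  obj <- function(theta) {
    st <- tryCatch(ram_structure(sk, theta), error = function(e) NULL)
    if (is.null(st)) return(BIG)
    ll <- mvn_fiml_loglik(st$mu, st$Sigma, pats)
    if (!is.finite(ll)) return(BIG)
    -ll
  }
  grad <- function(theta) {
    st <- tryCatch(ram_structure(sk, theta), error = function(e) NULL)
    if (is.null(st)) return(numeric(nlab))
    blocks <- mvn_fiml_score_blocks(st$mu, st$Sigma, pats)
    if (is.null(blocks)) return(numeric(nlab))
    E <- st$E
    Cobs <- st$C[sk$obs, , drop = FALSE]
    WA <- crossprod(E, blocks$Gs %*% Cobs)     # nv x nv
    WS <- crossprod(E, blocks$Gs %*% E)        # nv x nv
    u <- drop(crossprod(E, blocks$gm))         # nv
    g <- numeric(nlab)
    for (k in seq_len(nlab)) {
      tot <- 0
      e <- sk$a_entries[[k]]
      if (!is.null(e)) for (r in seq_len(nrow(e))) {
        i <- e[r, 1]; j <- e[r, 2]
        tot <- tot + 2 * WA[i, j] + u[i] * st$m[j]
      }
      e <- sk$s_entries[[k]]
      if (!is.null(e)) for (r in seq_len(nrow(e))) {
        i <- e[r, 1]; j <- e[r, 2]
        tot <- tot + if (i == j) WS[i, i] else WS[i, j] + WS[j, i]
      }
      e <- sk$m_entries[[k]]
      if (!is.null(e)) for (r in seq_len(nrow(e))) tot <- tot + u[e[r, 1]]
      g[k] <- tot
    }
    -g
  }
  list(obj = obj, grad = grad)
}

fd_hessian <- function(grad, theta, h = 1e-5) {
  k <- length(theta)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    hj <- h * (1 + abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + hj
    tm <- theta; tm[j] <- tm[j] - hj
    H[, j] <- (grad(tp) - grad(tm)) / (2 * hj)
  }
  (H + t(H)) / 2
}

#' Fit a latent change score model by maximum likelihood (FIML)
#'
#' Estimates the free parameters of a specification from wide panel
#' data by full-information maximum likelihood: each row contributes
#' the Gaussian log-density of its observed cells, so incomplete rows
#' are retained. Optimization uses analytic gradients with
#' quasi-Newton iterations and seeded multi-start restarts; standard
#' errors come from the observed information at the optimum. The
#' chi-square statistic compares the fitted model to the saturated
#' model (estimated by EM when cells are missing), and fit indices use
#' the independence-with-free-means baseline.
#'
#' @param data Wide data frame; columns must cover the spec's observed
#'   roster (`item_w1`, ... convention). Missing cells are `NA`.
#' @param spec An `lcs_spec`.
#' @param start Optional named starting values (defaults to
#'   scale-informed package starts).
#' @param restarts Maximum number of perturbed restarts after a failed
#'   or unconverged solve (default 5).
#' @param seed Seed controlling the restart jitter.
#' @param se Compute standard errors (default `TRUE`); skipping them
#'   saves a Hessian evaluation in large models.
#' @param grad_tol Gradient-norm tolerance used to declare convergence.
#' @return An object of class `lcs_fit`; see [tidy.lcs_fit()] and
#'   [glance.lcs_fit()] for tabular views.
#' @export
fit_lcs <- function(data, spec, start = NULL, restarts = 5, seed = 1,
                    se = TRUE, grad_tol = 1e-4) {
  vars <- observed_vars(spec)
  missing_cols <- setdiff(vars, colnames(data))
  if (length(missing_cols)) {
    stop("data lacks observed columns: ",
         paste(utils::head(missing_cols, 5), collapse = ", "), call. = FALSE)
  }
  pats <- fiml_patterns(data, vars)
  sk <- ram_skeleton(spec)
  k <- length(sk$labels)
  theta0 <- start_values(spec, data)
  if (!is.null(start)) theta0[names(start)] <- start
  theta0 <- theta0[sk$labels]
  fo <- make_objective(sk, pats)

  best <- NULL
  rng <- make_rng(seed)
  for (attempt in seq_len(restarts + 1)) {
    th_init <- if (attempt == 1) theta0 else
      theta0 + rng$rnorm(k, sd = 0.1 * (1 + abs(theta0)))
    res <- tryCatch(
      stats::nlminb(th_init, fo$obj, fo$grad,
                    control = list(iter.max = 2000, eval.max = 4000,
                                   rel.tol = 1e-11, x.tol = 1e-9)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) next
    # gradient norm per observation: scale-free convergence check.
    # nlminb may report "singular convergence" at a flat optimum (common
    # with many free change-score covariances); the gradient criterion
    # is the arbiter, the solver code is recorded as a diagnostic.
    gn <- sqrt(sum(fo$grad(res$par)^2)) / max(1, pats$n_used)
    ok <- gn < grad_tol
    cand <- list(res = res, grad_norm = gn, converged = ok, attempt = attempt)
    if (is.null(best) || res$objective < best$res$objective - 1e-8 ||
        (!best$converged && ok)) best <- cand
    if (ok) break
  }
  if (is.null(best)) {
    stop("non-convergence: no restart produced a finite objective", call. = FALSE)
  }
  theta <- stats::setNames(best$res$par, sk$labels)
  ll <- -best$res$objective

  sat <- em_saturated(pats)
  base <- baseline_independence(pats)
  N <- pats$n_used
  p <- length(vars)
  cfp <- count_free_parameters(spec, p)
  chi2 <- max(2 * (sat$loglik - ll), 0)
  chi2_b <- max(2 * (sat$loglik - base$loglik), 0)

  vc <- NULL; ses <- rep(NA_real_, k); hess_kappa <- NA_real_
  if (se) {
    H <- fd_hessian(fo$grad, best$res$par)
    vc <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vc)) {
      dg <- diag(vc)
      ses <- ifelse(dg > 0, sqrt(dg), NA_real_)
      hess_kappa <- kappa(H, exact = FALSE)
    }
  }

  betas <- standardize_theta(spec, sk, theta)
  estimates <- tibble::tibble(
    label = sk$labels,
    b = as.numeric(theta),
    se = ses,
    beta = unname(betas[sk$labels]),
    z = .data_safe_div(as.numeric(theta), ses)
  )
  estimates$p.value <- 2 * stats::pnorm(-abs(estimates$z))

  ic <- information_criteria(ll, cfp$free, N)
  indices <- compute_fit_indices(chi2, cfp$df, chi2_b, base$df, N,
                                 sat = sat, spec = spec, theta = theta, vars = vars)

  structure(list(
    estimates = estimates, theta = theta, loglik = ll,
    chisq = chi2, df = cfp$df, n_free = cfp$free, N = N,
    p.value = if (cfp$df > 0)
      stats::pchisq(chi2, cfp$df, lower.tail = FALSE) else NA_real_,
    baseline = list(chisq = chi2_b, df = base$df, loglik = base$loglik),
    saturated_loglik = sat$loglik,
    indices = indices, aic = ic$aic, bic = ic$bic,
    convergence = list(converged = best$converged, attempts = best$attempt,
                       grad_norm = best$grad_norm, code = best$res$convergence,
                       message = best$res$message,
                       em_iterations = sat$iterations,
                       hessian_condition = hess_kappa,
                       n_dropped = pats$n_dropped),
    vcov = vc, spec = spec
  ), class = "lcs_fit")
}

.data_safe_div <- function(a, b) ifelse(is.na(b) | b == 0, NA_real_, a / b)

# standardized coefficients from the implied moments:
# regressions  beta = b * sd(predictor) / sd(outcome)
# covariances  beta = b / (sd1 * sd2); variances b / var; means b / sd
standardize_theta <- function(spec, sk, theta) {
  st <- ram_structure(sk, theta_for(sk, theta))
  sd_all <- sqrt(pmax(diag(st$C), 0))
  out <- stats::setNames(rep(NA_real_, length(sk$labels)), sk$labels)
  for (kk in seq_along(sk$labels)) {
    v <- theta[[sk$labels[kk]]]
    e <- sk$a_entries[[kk]]
    if (!is.null(e)) {
      i <- e[1, 1]; j <- e[1, 2]
      out[kk] <- if (sd_all[i] > 0) v * sd_all[j] / sd_all[i] else NA_real_
      next
    }
    e <- sk$s_entries[[kk]]
    if (!is.null(e)) {
      i <- e[1, 1]; j <- e[1, 2]
      den <- sd_all[i] * sd_all[j]
      out[kk] <- if (den > 0) v / den else NA_real_
      next
    }
    e <- sk$m_entries[[kk]]
    if (!is.null(e)) {
      i <- e[1, 1]
      out[kk] <- if (sd_all[i] > 0) v / sd_all[i] else NA_real_
    }
  }
  out
}

#' Standardized coefficients of a fitted model
#'
#' Returns the estimates with standardized coefficients computed from
#' the model-implied standard deviations (latent change-factor SDs come
#' from the implied structure). Under equality constraints the implied
#' SDs of the first constrained entry are used.
#'
#' @param fit An `lcs_fit`.
#' @return A tibble `label`, `b`, `beta`.
#' @export
standardize <- function(fit) {
  fit$estimates[, c("label", "b", "beta")]
}

compute_fit_indices <- function(chi2, df, chi2_b, df_b, N, sat, spec, theta, vars) {
  rmsea <- if (df > 0) sqrt(max(chi2 - df, 0) / (df * N)) else 0
  ci <- rmsea_ci(chi2, df, N)
  num <- max(chi2 - df, 0)
  den <- max(chi2_b - df_b, chi2 - df, 0)
  cfi <- if (den > 0) 1 - num / den else 1
  # SRMR over standardized residual covariances and means, saturated
  # (sample) moments vs implied
  im <- implied_moments(spec, theta)
  S <- sat$cov; m <- sat$mean
  sds <- sqrt(pmax(diag(S), .Machine$double.eps))
  Dres <- (S - im$Sigma[vars, vars]) / tcrossprod(sds)
  mres <- (m - im$mu[vars]) / sds
  p <- length(vars)
  srmr <- sqrt((sum(Dres[upper.tri(Dres, diag = TRUE)]^2) + sum(mres^2)) /
                 (p * (p + 1) / 2 + p))
  list(rmsea = rmsea, rmsea.ci.lower = ci[1], rmsea.ci.upper = ci[2],
       rmsea.undefined = df <= 0, cfi = cfi, srmr = srmr)
}

# 90% CI for RMSEA by inverting the noncentral chi-square distribution
rmsea_ci <- function(chi2, df, N, level = 0.90) {
  if (df <= 0 || N <= 0) return(c(0, 0))
  a <- (1 - level) / 2
  upper_p <- 1 - a  # pchisq(chi2, df, ncp = lo) = 1 - a
  lo <- 0
  if (stats::pchisq(chi2, df) > upper_p) {
    lo <- stats::uniroot(function(nc) stats::pchisq(chi2, df, ncp = nc) - upper_p,
                         lower = 0, upper = max(chi2 * 2, 10),
                         extendInt = "downX")$root
  }
  hi <- 0
  if (stats::pchisq(chi2, df) > a) {
    hi <- stats::uniroot(function(nc) stats::pchisq(chi2, df, ncp = nc) - a,
                         lower = 0, upper = max(chi2 * 3, 10),
                         extendInt = "downX")$root
  }
  c(sqrt(lo / (df * N)), sqrt(hi / (df * N)))
}

#' Model fit indices of a fitted model
#'
#' RMSEA with its 90% confidence interval (noncentral chi-square
#' inversion), CFI against the independence-with-free-means baseline,
#' and SRMR over standardized residual means and covariances. A custom
#' baseline fit (fitted to the same data) may be supplied, in which case
#' CFI is recomputed against it.
#'
#' @param fit An `lcs_fit`.
#' @param baseline Optional `lcs_fit` to use as the baseline model
#'   instead of the built-in independence model.
#' @return A one-row tibble of indices.
#' @export
fit_indices <- function(fit, baseline = NULL) {
  cfi <- fit$indices$cfi
  if (!is.null(baseline)) {
    if (baseline$N != fit$N) {
      stop("baseline was fitted to different data", call. = FALSE)
    }
    num <- max(fit$chisq - fit$df, 0)
    den <- max(baseline$chisq - baseline$df, fit$chisq - fit$df, 0)
    cfi <- if (den > 0) 1 - num / den else 1
  }
  tibble::tibble(
    chisq = fit$chisq, df = fit$df, p.value = fit$p.value,
    rmsea = fit$indices$rmsea,
    rmsea.ci.lower = fit$indices$rmsea.ci.lower,
    rmsea.ci.upper = fit$indices$rmsea.ci.upper,
    cfi = cfi, srmr = fit$indices$srmr,
    aic = fit$aic, bic = fit$bic, N = fit$N
  )
}

#' @export
print.lcs_fit <- function(x, ...) {
  cat("<lcs_fit> ", x$spec$meta$model %||% "custom",
      "  (", x$n_free, " free, df ", x$df, ", N ", x$N, ")\n", sep = "")
  cat(sprintf("  chi-square %.3f on %d df;  logLik %.3f\n", x$chisq, x$df, x$loglik))
  cat(sprintf("  RMSEA %.3f [%.3f, %.3f]  CFI %.3f  SRMR %.3f\n",
              x$indices$rmsea, x$indices$rmsea.ci.lower, x$indices$rmsea.ci.upper,
              x$indices$cfi, x$indices$srmr))
  cat(sprintf("  AIC %.3f  BIC %.3f  converged: %s\n", x$aic, x$bic,
              x$convergence$converged))
  invisible(x)
}

#' Tidy the parameter estimates of a fitted model
#'
#' @param x An `lcs_fit`.
#' @param ... Unused.
#' @return A tibble with one row per free parameter label: `label`, `b`,
#'   `se`, `beta`, `z`, `p.value`.
#' @method tidy lcs_fit
#' @export
tidy.lcs_fit <- function(x, ...) x$estimates

#' One-row model summary of a fitted model
#'
#' @param x An `lcs_fit`.
#' @param ... Unused.
#' @return A one-row tibble: model label, log-likelihood, chi-square,
#'   df, fit indices, information criteria, N, convergence flag.
#' @method glance lcs_fit
#' @export
glance.lcs_fit <- function(x, ...) {
  tibble::tibble(
    model = x$spec$meta$model %||% "custom",
    logLik = x$loglik, chisq = x$chisq, df = x$df, p.value = x$p.value,
    rmsea = x$indices$rmsea, cfi = x$indices$cfi, srmr = x$indices$srmr,
    aic = x$aic, bic = x$bic, n_free = x$n_free, N = x$N,
    converged = x$convergence$converged
  )
}

#' Serialize a fitted model to JSON
#'
#' Writes the estimates table (label, b, SE, beta, z), the fit block
#' (chi-square, df, p, RMSEA with CI, CFI, SRMR, AIC, BIC, N) and the
#' convergence block.
#'
#' @param fit An `lcs_fit`.
#' @param path Optional output file.
#' @return The JSON string, invisibly when written to a file.
#' @export
fit_to_json <- function(fit, path = NULL) {
  payload <- list(
    model = fit$spec$meta$model %||% "custom",
    estimates = fit$estimates,
    fit = list(chisq = fit$chisq, df = fit$df, p = fit$p.value,
               rmsea = c(fit$indices$rmsea.ci.lower, fit$indices$rmsea.ci.upper),
               rmsea.point = fit$indices$rmsea,
               cfi = fit$indices$cfi, srmr = fit$indices$srmr,
               aic = fit$aic, bic = fit$bic, N = fit$N),
    convergence = fit$convergence
  )
  json <- jsonlite::toJSON(payload, dataframe = "columns", auto_unbox = TRUE,
                           digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

# deterministic local RNG that does not disturb the global stream
make_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    st <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
    st
  }
  draw <- function(f, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- f(...)
    env$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
    out
  }
  list(rnorm = function(n, mean = 0, sd = 1) draw(stats::rnorm, n, mean, sd),
       runif = function(n, min = 0, max = 1) draw(stats::runif, n, min, max))
}
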