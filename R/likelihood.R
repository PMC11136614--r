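# Gaussian likelihood machinery: complete-data ML, pattern-wise FIML,
# the EM-estimated saturated model under missingness, and the closed-form
# independence baseline.

LOG2PI <- log(2 * pi)

#' Sample moment summary of a panel
#'
#' Sample mean vector and maximum-likelihood covariance matrix (divisor
#' `N`) of complete wide data, in the column order given.
#'
#' @param data A data frame or matrix of complete observations.
#' @param vars Columns to use (default: all).
#' @return A list with `mean`, `cov`, `n`, `vars`.
#' @export
moment_summary <- function(data, vars = colnames(data)) {
  X <- as.matrix(data[, vars, drop = FALSE])
  if (anyNA(X)) stop("moment_summary requires complete data", call. = FALSE)
  n <- nrow(X)
  mu <- colMeans(X)
  S <- crossprod(sweep(X, 2, mu)) / n
  list(mean = mu, cov = S, n = n, vars = vars)
}

# Group rows by missingness pattern; store per-pattern count, observed
# column index, mean, and scatter about the pattern mean. Rows with no
# observed cell are dropped with a logged count.
fiml_patterns <- function(data, vars) {
  X <- as.matrix(data[, vars, drop = FALSE])
  storage.mode(X) <- "double"
  obs <- !is.na(X)
  key <- apply(obs, 1, function(z) paste(as.integer(z), collapse = ""))
  empty <- rowSums(obs) == 0
  n_dropped <- sum(empty)
  keep <- which(!empty)
  pats <- split(keep, key[keep])
  patterns <- lapply(pats, function(rows) {
    o <- which(obs[rows[1], ])
    Xo <- X[rows, o, drop = FALSE]
    ng <- nrow(Xo)
    mo <- colMeans(Xo)
    W <- crossprod(sweep(Xo, 2, mo))
    list(rows = rows, o = o, n = ng, mean = mo, W = W)
  })
  structure(list(patterns = unname(patterns), n_used = length(keep),
                 n_dropped = n_dropped, p = length(vars), vars = vars,
                 X = X, obs = obs),
            class = "fiml_patterns")
}

# log-likelihood of MVN(mu, Sigma) over the observed cells of each row,
# computed pattern-wise from sufficient statistics.
mvn_fiml_loglik <- function(mu, Sigma, pats) {
  ll <- 0
  for (g in pats$patterns) {
    o <- g$o
    So <- Sigma[o, o, drop = FALSE]
    ch <- tryCatch(chol(So), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    logdet <- 2 * sum(log(diag(ch)))
    Si <- chol2inv(ch)
    d <- g$mean - mu[o]
    ll <- ll - 0.5 * (g$n * (length(o) * LOG2PI + logdet) +
                        sum(Si * g$W) + g$n * drop(crossprod(d, Si %*% d)))
  }
  ll
}

# Accumulate dll/dSigma (full p x p, symmetric) and dll/dmu over patterns.
mvn_fiml_score_blocks <- function(mu, Sigma, pats) {
  p <- pats$p
  Gs <- matrix(0, p, p); gm <- numeric(p)
  for (g in pats$patterns) {
    o <- g$o
    So <- Sigma[o, o, drop = FALSE]
    ch <- tryCatch(chol(So), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Si <- chol2inv(ch)
    d <- g$mean - mu[o]
    Sid <- Si %*% d
    Gs[o, o] <- Gs[o, o] +
      0.5 * (Si %*% (g$W + g$n * tcrossprod(d)) %*% Si - g$n * Si)
    gm[o] <- gm[o] + g$n * drop(Sid)
  }
  list(Gs = Gs, gm = gm)
}

#' Complete-data Gaussian log-likelihood of a model
#'
#' Evaluates the casewise Gaussian log-likelihood of a specification at
#' given parameter values against a complete-data moment summary. Equals
#' the sum of casewise log-densities; maximal (chi-square 0) when the
#' implied moments equal the sample moments.
#'
#' @param spec An `lcs_spec`.
#' @param theta Named parameter values.
#' @param moments A [moment_summary()].
#' @return The log-likelihood (scalar).
#' @export
loglik_complete <- function(spec, theta, moments) {
  im <- implied_moments(spec, theta)
  vars <- moments$vars
  Sigma <- im$Sigma[vars, vars]
  mu <- im$mu[vars]
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) stop("implied covariance is not positive definite", call. = FALSE)
  p <- length(vars); n <- moments$n
  logdet <- 2 * sum(log(diag(ch)))
  Si <- chol2inv(ch)
  d <- moments$mean - mu
  -0.5 * n * (p * LOG2PI + logdet + sum(Si * moments$cov) +
                drop(crossprod(d, Si %*% d)))
}

#' Full-information (FIML) log-likelihood of a model
#'
#' Casewise Gaussian log-likelihood over each row's observed subset;
#' with no missing cells this equals [loglik_complete()] exactly. Rows
#' with no observed cell are excluded (their count is attached as the
#' `"n_dropped"` attribute).
#'
#' @param spec An `lcs_spec`.
#' @param theta Named parameter values.
#' @param data Wide data frame with missing cells as `NA`.
#' @return The log-likelihood, with attributes `n_used` and `n_dropped`.
#' @export
loglik_fiml <- function(spec, theta, data) {
  vars <- observed_vars(spec)
  pats <- fiml_patterns(data, vars)
  im <- implied_moments(spec, theta)
  ll <- mvn_fiml_loglik(im$mu[vars], im$Sigma[vars, vars], pats)
  attr(ll, "n_used") <- pats$n_used
  attr(ll, "n_dropped") <- pats$n_dropped
  ll
}

# Saturated (unstructured MVN) estimates under missingness by EM.
# Complete data short-circuits to the sample moments.
em_saturated <- function(pats, tol = 1e-8, maxit = 500) {
  p <- pats$p
  complete <- length(pats$patterns) == 1 && length(pats$patterns[[1]]$o) == p
  if (complete) {
    g <- pats$patterns[[1]]
    mu <- g$mean; Sigma <- g$W / g$n
    return(list(mean = mu, cov = Sigma,
                loglik = mvn_fiml_loglik(mu, Sigma, pats),
                iterations = 0L, converged = TRUE))
  }
  # init: available-case means and variances, zero covariances
  mu <- colMeans(pats$X, na.rm = TRUE)
  v <- apply(pats$X, 2, stats::var, na.rm = TRUE)
  v[!is.finite(v) | v <= 0] <- 1
  Sigma <- diag(v, p)
  ll_old <- -Inf; converged <- FALSE; it <- 0L
  n <- pats$n_used
  for (it in seq_len(maxit)) {
    sum_x <- numeric(p); sum_xx <- matrix(0, p, p)
    for (g in pats$patterns) {
      o <- g$o; m <- setdiff(seq_len(p), o)
      So <- Sigma[o, o, drop = FALSE]
      Si <- chol2inv(chol(So))
      s_o <- g$n * g$mean
      S_oo_raw <- g$W + g$n * tcrossprod(g$mean)
      sum_x[o] <- sum_x[o] + s_o
      sum_xx[o, o] <- sum_xx[o, o] + S_oo_raw
      if (length(m)) {
        K <- Sigma[m, o, drop = FALSE] %*% Si
        c1 <- s_o - g$n * mu[o]
        C2 <- S_oo_raw - tcrossprod(s_o, mu[o]) - tcrossprod(mu[o], s_o) +
          g$n * tcrossprod(mu[o])
        mm_sum <- g$n * mu[m] + drop(K %*% c1)
        sum_x[m] <- sum_x[m] + mm_sum
        V <- Sigma[m, m, drop = FALSE] - K %*% Sigma[o, m, drop = FALSE]
        Sxm <- tcrossprod(s_o, mu[m]) + (S_oo_raw - tcrossprod(s_o, mu[o])) %*% t(K)
        Smm <- g$n * tcrossprod(mu[m]) + tcrossprod(mu[m], drop(K %*% c1)) +
          tcrossprod(drop(K %*% c1), mu[m]) + K %*% C2 %*% t(K) + g$n * V
        sum_xx[o, m] <- sum_xx[o, m] + Sxm
        sum_xx[m, o] <- sum_xx[m, o] + t(Sxm)
        sum_xx[m, m] <- sum_xx[m, m] + Smm
      }
    }
    mu <- sum_x / n
    Sigma <- sum_xx / n - tcrossprod(mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    ll <- mvn_fiml_loglik(mu, Sigma, pats)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE; break
    }
    ll_old <- ll
  }
  list(mean = mu, cov = Sigma, loglik = mvn_fiml_loglik(mu, Sigma, pats),
       iterations = it, converged = converged)
}

# Independence baseline (free means and variances, zero covariances).
# Under MCAR the likelihood factors per column, so the ML solution is the
# per-column observed-cell mean and ML variance; closed form.
baseline_independence <- function(pats) {
  X <- pats$X
  ll <- 0; k <- 0L
  for (j in seq_len(ncol(X))) {
    x <- X[, j]; x <- x[!is.na(x)]
    nj <- length(x)
    if (nj == 0) next
    mj <- mean(x); vj <- mean((x - mj)^2)
    vj <- max(vj, .Machine$double.eps)
    ll <- ll - 0.5 * nj * (LOG2PI + log(vj) + 1)
    k <- k + 2L
  }
  p <- ncol(X)
  list(loglik = ll, k = k, df = p * (p + 3) / 2 - k)
}
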