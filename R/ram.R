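# RAM representation: directed paths in A (A[to, from]), covariances in S,
# intercepts/means in M. Implied moments over the full roster:
#   C  = (I - A)^-1 S (I - A)^-T,   m = (I - A)^-1 M
# and the observed filter picks out rows/columns of the observed roster.

ram_skeleton <- function(spec) {
  vars <- spec$variables$name
  nv <- length(vars)
  idx <- stats::setNames(seq_len(nv), vars)
  labs <- free_labels(spec)
  lab_id <- stats::setNames(seq_along(labs), labs)

  A0 <- matrix(0, nv, nv, dimnames = list(vars, vars))
  S0 <- matrix(0, nv, nv, dimnames = list(vars, vars))
  M0 <- stats::setNames(numeric(nv), vars)

  # assignment lists: for each free label, the entries it fills
  a_entries <- vector("list", length(labs))
  s_entries <- vector("list", length(labs))
  m_entries <- vector("list", length(labs))

  for (r in seq_len(nrow(spec$paths))) {
    i <- idx[[spec$paths$to[r]]]; j <- idx[[spec$paths$from[r]]]
    if (spec$paths$free[r]) {
      k <- lab_id[[spec$paths$label[r]]]
      a_entries[[k]] <- rbind(a_entries[[k]], c(i, j))
    } else A0[i, j] <- spec$paths$value[r]
  }
  for (r in seq_len(nrow(spec$covs))) {
    i <- idx[[spec$covs$v1[r]]]; j <- idx[[spec$covs$v2[r]]]
    if (spec$covs$free[r]) {
      k <- lab_id[[spec$covs$label[r]]]
      s_entries[[k]] <- rbind(s_entries[[k]], c(i, j))
    } else {
      S0[i, j] <- spec$covs$value[r]; S0[j, i] <- spec$covs$value[r]
    }
  }
  for (r in seq_len(nrow(spec$means))) {
    i <- idx[[spec$means$var[r]]]
    if (spec$means$free[r]) {
      k <- lab_id[[spec$means$label[r]]]
      m_entries[[k]] <- rbind(m_entries[[k]], i)
    } else M0[i] <- spec$means$value[r]
  }

  list(vars = vars, nv = nv, labels = labs,
       obs = match(observed_vars(spec), vars),
       A0 = A0, S0 = S0, M0 = M0,
       a_entries = a_entries, s_entries = s_entries, m_entries = m_entries)
}

ram_fill <- function(sk, theta) {
  A <- sk$A0; S <- sk$S0; M <- sk$M0
  for (k in seq_along(sk$labels)) {
    v <- theta[[k]]
    e <- sk$a_entries[[k]]
    if (!is.null(e)) for (r in seq_len(nrow(e))) A[e[r, 1], e[r, 2]] <- v
    e <- sk$s_entries[[k]]
    if (!is.null(e)) for (r in seq_len(nrow(e))) {
      S[e[r, 1], e[r, 2]] <- v; S[e[r, 2], e[r, 1]] <- v
    }
    e <- sk$m_entries[[k]]
    if (!is.null(e)) for (r in seq_len(nrow(e))) M[e[r, 1]] <- v
  }
  list(A = A, S = S, M = M)
}

# Full-roster implied structure at theta. B = (I - A)^-1 solved once.
ram_structure <- function(sk, theta) {
  mats <- ram_fill(sk, theta)
  ImA <- diag(sk$nv) - mats$A
  B <- tryCatch(solve(ImA), error = function(e)
    stop("non-recursive-model: path system is singular", call. = FALSE))
  C <- B %*% mats$S %*% t(B)
  m <- drop(B %*% mats$M)
  E <- B[sk$obs, , drop = FALSE]
  list(A = mats$A, S = mats$S, M = mats$M, B = B, C = C, m = m, E = E,
       Sigma = C[sk$obs, sk$obs, drop = FALSE], mu = m[sk$obs])
}

#' Model-implied mean vector and covariance matrix
#'
#' Solves the path system at the supplied parameter values and returns
#' the implied mean vector and covariance matrix over the observed
#' variables. Wherever the change-score algebra fixes unit paths, the
#' implied means obey `E[y_t] = E[y_{t-1}] + E[dy_t]` exactly.
#'
#' @param spec An `lcs_spec`.
#' @param theta Named numeric vector of free-parameter values; names must
#'   cover every free label of `spec`.
#' @return A list with `mu` (named mean vector), `Sigma` (covariance
#'   matrix), both over the observed roster, plus `latent_sd` (implied
#'   standard deviations of the full roster, used for standardization).
#' @export
implied_moments <- function(spec, theta) {
  sk <- ram_skeleton(spec)
  th <- theta_for(sk, theta)
  st <- ram_structure(sk, th)
  mu <- stats::setNames(st$mu, sk$vars[sk$obs])
  dimnames(st$Sigma) <- list(sk$vars[sk$obs], sk$vars[sk$obs])
  list(mu = mu, Sigma = st$Sigma,
       latent_sd = stats::setNames(sqrt(pmax(diag(st$C), 0)), sk$vars))
}

theta_for <- function(sk, theta) {
  miss <- setdiff(sk$labels, names(theta))
  if (length(miss)) stop("missing parameter values for: ",
                         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  as.numeric(theta[sk$labels])
}

# Starting values: unit loadings, zero regressions, variances at the scale
# of their observed analogues, means/intercepts at observed analogues.
start_values <- function(spec, data = NULL) {
  labs <- free_labels(spec)
  th <- stats::setNames(numeric(length(labs)), labs)
  var_scale <- 1; mean_scale <- 0
  col_var <- NULL; col_mean <- NULL
  if (!is.null(data)) {
    obs <- intersect(observed_vars(spec), colnames(data))
    X <- as.matrix(data[, obs, drop = FALSE])
    col_var <- apply(X, 2, stats::var, na.rm = TRUE)
    col_mean <- colMeans(X, na.rm = TRUE)
    var_scale <- stats::median(col_var, na.rm = TRUE)
    mean_scale <- stats::median(col_mean, na.rm = TRUE)
  }
  for (lab in labs) {
    th[lab] <- if (grepl("^lam", lab)) 1
    else if (grepl("^(eps_|dist_)", lab)) 0.5 * var_scale
    else if (grepl("^(psi1_|zeta_|var_)", lab)) {
      # variance label: own-variance vs covariance distinguished downstream
      0.5 * var_scale
    } else if (grepl("^(epsc_|zcov_)", lab)) 0
    else if (grepl("^(phi_|gamma_|b_)", lab)) 0
    else if (grepl("^(tau|mu1_|mu_)", lab)) mean_scale
    else 0
  }
  # covariance-typed psi1 labels (two base names) start at 0
  covlabs <- spec$covs$label[spec$covs$free & spec$covs$v1 != spec$covs$v2]
  th[names(th) %in% covlabs & grepl("^psi1_", names(th))] <- 0.1 * var_scale
  if (!is.null(col_var)) {
    # residual variances at half the matching column's variance
    for (lab in grep("^eps_", labs, value = TRUE)) {
      cn <- sub("^eps_", "", lab)
      if (cn %in% names(col_var)) th[lab] <- 0.5 * col_var[[cn]]
    }
    for (lab in grep("^(mu1_|psi1_)", labs, value = TRUE)) {
      base <- sub("^(mu1_|psi1_)", "", lab)
      # marker column of the chain head, if directly observed
      cand <- grep(paste0("^", base, "_w"), names(col_mean), value = TRUE)
      if (length(cand)) {
        if (grepl("^mu1_", lab)) th[lab] <- col_mean[[cand[1]]]
        else if (!lab %in% covlabs) th[lab] <- col_var[[cand[1]]]
      }
    }
    # change-score means/variances start at the observed wave-to-wave
    # differences of the matching series (when directly observed)
    for (lab in grep("^(alpha_|zeta_)", labs, value = TRUE)) {
      m <- regmatches(lab, regexec("^(alpha|zeta)_(.+)_w([0-9]+)$", lab))[[1]]
      if (!length(m)) next
      base <- m[3]; w <- as.integer(m[4])
      c2 <- paste0(base, "_w", w); c1 <- paste0(base, "_w", w - 1)
      if (all(c(c1, c2) %in% names(col_mean))) {
        if (m[2] == "alpha") th[lab] <- col_mean[[c2]] - col_mean[[c1]]
        else th[lab] <- 0.5 * (col_var[[c2]] + col_var[[c1]])
      }
    }
    th[grepl("^mu_age", names(th))] <- if ("age" %in% names(col_mean)) col_mean[["age"]] else 0
    th[grepl("^var_age", names(th))] <- if ("age" %in% names(col_var)) col_var[["age"]] else 1
    if ("gender" %in% names(col_mean)) {
      th[grepl("^mu_gender", names(th))] <- col_mean[["gender"]]
      th[grepl("^var_gender", names(th))] <- col_var[["gender"]]
    }
  }
  th
}
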