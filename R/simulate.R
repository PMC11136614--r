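# Synthetic-cohort generator: latent change score trajectories from either
# generative world (common cause vs mutualism), item emission (continuous
# Likert-like or binary symptoms), parceling, and MCAR masking.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# draw n rows from MVN(0, V) allowing V to be merely PSD
rmvn0 <- function(n, V) {
  p <- ncol(V)
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  L <- ev$vectors %*% diag(sqrt(lam), p)
  matrix(stats::rnorm(n * p), n, p) %*% t(L)
}

check_psd <- function(V, what) {
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop(what, " must be positive semidefinite", call. = FALSE)
  }
}

#' Population dynamics of a latent change score process
#'
#' Bundles the generative dynamics: self-feedback `phi` and coupling
#' `gamma` per interval, change-score means `alpha`, the full covariance
#' of the change residuals across all (domain, interval) pairs, the
#' baseline (wave 1) latent moments, and optional covariate slopes on
#' the baseline factors.
#'
#' @param domains Character vector of domain names (length `k`).
#' @param n_waves Number of waves `W` (so `W - 1` intervals).
#' @param phi Self-feedback; scalar, length-`k` vector, or `k x (W-1)`
#'   matrix.
#' @param gamma Coupling; scalar (applied to every ordered pair), or a
#'   `k x k x (W-1)` array with zero diagonal; must be 0/absent for a
#'   single domain.
#' @param alpha Change-score means; scalar, vector, or `k x (W-1)` matrix.
#' @param zeta_var Change-residual variances; scalar, vector, or matrix
#'   as `alpha`.
#' @param zeta_cor Correlation among change residuals across all
#'   (domain, interval) pairs; scalar exchangeable correlation or a full
#'   `k(W-1) x k(W-1)` correlation matrix.
#' @param t1_mean,t1_var Baseline latent means and variances (scalar or
#'   length `k`).
#' @param t1_cor Baseline inter-domain correlation (scalar or `k x k`).
#' @param covariate_slopes Named list, e.g. `list(age = c(0.01, -0.01))`,
#'   of per-unit effects of a covariate on the baseline latents.
#' @return An object of class `lcs_params`.
#' @export
trajectory_params <- function(domains, n_waves,
                              phi = -0.2, gamma = 0, alpha = 0.2,
                              zeta_var = 0.5, zeta_cor = 0,
                              t1_mean = 0, t1_var = 1, t1_cor = 0.3,
                              covariate_slopes = NULL) {
  k <- length(domains); W <- n_waves; ni <- W - 1
  stopifnot(W >= 2, k >= 1)
  expand_km <- function(x, what) {
    if (is.matrix(x)) { stopifnot(nrow(x) == k, ncol(x) == ni); x }
    else matrix(x, k, ni, dimnames = list(domains, NULL))
  }
  phi <- expand_km(phi); alpha <- expand_km(alpha); zv <- expand_km(zeta_var)
  if (any(zv < 0)) stop("zeta_var must be >= 0", call. = FALSE)
  if (is.array(gamma) && length(dim(gamma)) == 3) {
    stopifnot(all(dim(gamma) == c(k, k, ni)))
    G <- gamma
  } else {
    G <- array(gamma, c(k, k, ni))
  }
  if (k == 1 && any(G != 0)) stop("gamma must be empty for a single domain",
                                  call. = FALSE)
  for (t in seq_len(ni)) for (j in seq_len(k)) G[j, j, t] <- 0
  dimnames(G) <- list(domains, domains, NULL)

  dnames <- as.vector(vapply(2:W, function(w) paste0(domains, "_w", w),
                             character(k)))
  m <- k * ni
  sdv <- sqrt(as.vector(zv))  # domain-major within interval
  R <- if (is.matrix(zeta_cor)) zeta_cor else {
    Rm <- matrix(zeta_cor, m, m); diag(Rm) <- 1; Rm
  }
  stopifnot(all(dim(R) == c(m, m)))
  zeta_cov <- R * tcrossprod(sdv)
  dimnames(zeta_cov) <- list(dnames, dnames)
  check_psd(zeta_cov, "change-residual covariance")

  t1_mean <- rep_len(t1_mean, k); t1_sd <- sqrt(rep_len(t1_var, k))
  Rt <- if (is.matrix(t1_cor)) t1_cor else {
    Rm <- matrix(t1_cor, k, k); diag(Rm) <- 1; Rm
  }
  t1_cov <- Rt * tcrossprod(t1_sd)
  dimnames(t1_cov) <- list(domains, domains)
  check_psd(t1_cov, "baseline covariance")

  structure(list(domains = domains, n_waves = W, phi = phi, gamma = G,
                 alpha = alpha, zeta_cov = zeta_cov,
                 t1_mean = stats::setNames(t1_mean, domains), t1_cov = t1_cov,
                 covariate_slopes = covariate_slopes),
            class = "lcs_params")
}

#' Simulate latent change score trajectories
#'
#' Draws wave-1 latent scores from the baseline Gaussian and builds
#' later waves by the change-score recursion
#' `dy_t = alpha + phi * y_{t-1} + sum_src gamma * y_src,{t-1} + zeta_t`,
#' `y_t = y_{t-1} + dy_t`, with the change residuals `zeta` drawn
#' jointly across all (domain, interval) pairs from their stated
#' covariance. The accounting identity `y_t = y_{t-1} + dy_t` holds
#' exactly for every simulated record.
#'
#' @param params An [trajectory_params()].
#' @param n Number of persons.
#' @param seed Seed; mandatory for reproducibility.
#' @param covariates Optional data frame (`n` rows) of covariate values
#'   acting through `params$covariate_slopes`.
#' @return An object of class `lcs_latent_panel`: arrays `y`
#'   (`n x k x W`) and `dy` (`n x k x (W-1)`), plus the inputs.
#' @export
simulate_lcs_trajectories <- function(params, n, seed, covariates = NULL) {
  stopifnot(inherits(params, "lcs_params"))
  k <- length(params$domains); W <- params$n_waves
  with_seed(seed, {
    y <- array(NA_real_, c(n, k, W),
               dimnames = list(NULL, params$domains, paste0("w", seq_len(W))))
    mu1 <- matrix(params$t1_mean, n, k, byrow = TRUE)
    if (!is.null(params$covariate_slopes) && !is.null(covariates)) {
      for (cv in names(params$covariate_slopes)) {
        if (!cv %in% names(covariates)) next
        sl <- rep_len(params$covariate_slopes[[cv]], k)
        mu1 <- mu1 + outer(covariates[[cv]], sl)
      }
    }
    y[, , 1] <- mu1 + rmvn0(n, params$t1_cov)
    zeta <- rmvn0(n, params$zeta_cov)   # columns: domain-major within interval
    dy <- array(NA_real_, c(n, k, W - 1),
                dimnames = list(NULL, params$domains, paste0("w", 2:W)))
    for (t in 2:W) {
      it <- t - 1
      prev <- y[, , t - 1, drop = FALSE][, , 1, drop = FALSE]
      prev <- matrix(prev, n, k)
      d <- matrix(params$alpha[, it], n, k, byrow = TRUE) +
        prev * matrix(params$phi[, it], n, k, byrow = TRUE) +
        prev %*% params$gamma[, , it] +      # [src, tgt]: y_src * gamma -> tgt
        zeta[, (it - 1) * k + seq_len(k), drop = FALSE]
      dy[, , it] <- d
      y[, , t] <- y[, , t - 1] + d
    }
    structure(list(y = y, dy = dy, params = params, n = n,
                   covariates = covariates),
              class = "lcs_latent_panel")
  })
}

#' @export
print.lcs_latent_panel <- function(x, ...) {
  cat("<lcs_latent_panel> ", x$n, " persons x ", length(x$params$domains),
      " domains x ", x$params$n_waves, " waves\n", sep = "")
  invisible(x)
}

#' Long tibble view of a latent panel
#' @param x An `lcs_latent_panel`.
#' @param ... Unused.
#' @return Tibble with `person`, `domain`, `wave`, `y`, `dy` (`NA` at
#'   wave 1).
#' @method as_tibble lcs_latent_panel
#' @export
as_tibble.lcs_latent_panel <- function(x, ...) {
  k <- length(x$params$domains); W <- x$params$n_waves
  out <- tidyr::expand_grid(person = seq_len(x$n),
                            domain = x$params$domains,
                            wave = seq_len(W))
  out$y <- mapply(function(p, d, w) x$y[p, d, w], out$person, out$domain, out$wave)
  out$dy <- mapply(function(p, d, w) if (w == 1) NA_real_ else x$dy[p, d, w - 1],
                   out$person, out$domain, out$wave)
  out
}

#' Default measurement generating values for a design
#'
#' Item loadings drawn once (seeded) from U(0.4, 0.8), intercepts at the
#' scale midpoint for Likert-like items (3) and 0 otherwise, residual SD
#' 0.6, and target marginal prevalences for binary symptoms spread over
#' 0.10-0.40 (rarer symptoms later in the roster).
#'
#' @param design An `lcs_design`.
#' @param seed Seed for the loading draw.
#' @return Tibble `item`, `domain`, `loading`, `intercept`, `resid_sd`,
#'   `prevalence`.
#' @export
default_measurement <- function(design, seed = 20230501) {
  n <- nrow(design$items)
  with_seed(seed, {
    tibble::tibble(
      item = design$items$item,
      domain = design$items$domain,
      loading = stats::runif(n, 0.4, 0.8),
      intercept = if (design$scale_type == "continuous-likert") 3 else 0,
      resid_sd = 0.6,
      prevalence = if (design$scale_type == "binary-symptom")
        seq(0.40, 0.10, length.out = n) else NA_real_
    )
  })
}

#' Emit observed items from latent trajectories
#'
#' Continuous items are `intercept + loading * y + residual`. With
#' `discretize = "likert-5"` the continuous value is rounded and clipped
#' to 1-5. With `discretize = "binary"` each item is Bernoulli with
#' probability `pnorm(loading * y + c)`, the offset `c` solved so the
#' wave-1 marginal prevalence matches the item's target.
#'
#' @param latents An `lcs_latent_panel`.
#' @param design An `lcs_design`. Item domains must exist in the panel;
#'   for a common-cause world pass the expanded panel (see
#'   [expand_common_cause()]).
#' @param measurement Tibble as from [default_measurement()].
#' @param seed Seed for residual/Bernoulli draws.
#' @param discretize `"none"`, `"likert-5"` or `"binary"`.
#' @return Wide tibble of `item_wave` columns (`<item>_w<t>`).
#' @export
emit_items <- function(latents, design, measurement = default_measurement(design),
                       seed = 1, discretize = c("none", "likert-5", "binary")) {
  discretize <- match.arg(discretize)
  stopifnot(inherits(latents, "lcs_latent_panel"))
  if (!all(measurement$domain %in% dimnames(latents$y)[[2]])) {
    stop("invalid-design: measurement refers to domains absent from the panel",
         call. = FALSE)
  }
  if (discretize == "binary" &&
      any(!is.finite(measurement$prevalence) |
            measurement$prevalence <= 0 | measurement$prevalence >= 1)) {
    stop("target prevalence must lie in (0, 1)", call. = FALSE)
  }
  n <- latents$n; W <- latents$params$n_waves
  out <- list()
  with_seed(seed, {
    for (r in seq_len(nrow(measurement))) {
      it <- measurement$item[r]; d <- measurement$domain[r]
      lam <- measurement$loading[r]
      for (w in seq_len(W)) {
        yv <- latents$y[, d, w]
        col <- paste0(it, "_w", w)
        if (discretize == "binary") {
          # offset solved from the wave-1 latent moments:
          # P(x = 1) = pnorm((lam*mu1 + c) / sqrt(1 + lam^2 s1^2)) = prevalence
          mu1 <- latents$params$t1_mean[[d]]
          s1sq <- latents$params$t1_cov[d, d]
          cc <- stats::qnorm(measurement$prevalence[r]) * sqrt(1 + lam^2 * s1sq) -
            lam * mu1
          out[[col]] <- stats::rbinom(n, 1, stats::pnorm(lam * yv + cc))
        } else {
          x <- measurement$intercept[r] + lam * yv +
            stats::rnorm(n, 0, measurement$resid_sd[r])
          if (discretize == "likert-5") x <- pmin(5, pmax(1, round(x)))
          out[[col]] <- x
        }
      }
    }
  })
  tibble::as_tibble(out)
}

#' Expand a single-liability panel into domain latents
#'
#' In the common-cause world the single latent (p, or depression) drives
#' the domains: each domain latent at each wave is
#' `intercept + loading * liability + disturbance`. Returns a panel over
#' the domains whose items can then be emitted as usual. `dy` of the
#' expanded domains is the implied difference, so the change identity is
#' preserved.
#'
#' @param latents A 1-domain `lcs_latent_panel` (the liability chain).
#' @param domains Target domain names.
#' @param loadings,intercepts Second-order loadings/intercepts (recycled).
#' @param dist_sd Disturbance SD per domain (recycled).
#' @param seed Seed for the disturbance draws (wave-specific
#'   disturbances, independent over waves).
#' @return An `lcs_latent_panel` over `domains`.
#' @export
expand_common_cause <- function(latents, domains, loadings = 1, intercepts = 0,
                                dist_sd = sqrt(0.5), seed = 1) {
  stopifnot(length(dimnames(latents$y)[[2]]) == 1)
  k <- length(domains); W <- latents$params$n_waves; n <- latents$n
  loadings <- rep_len(loadings, k); intercepts <- rep_len(intercepts, k)
  dist_sd <- rep_len(dist_sd, k)
  y <- array(NA_real_, c(n, k, W),
             dimnames = list(NULL, domains, paste0("w", seq_len(W))))
  with_seed(seed, {
    for (j in seq_len(k)) {
      for (w in seq_len(W)) {
        y[, j, w] <- intercepts[j] + loadings[j] * latents$y[, 1, w] +
          stats::rnorm(n, 0, dist_sd[j])
      }
    }
  })
  dy <- array(NA_real_, c(n, k, W - 1),
              dimnames = list(NULL, domains, paste0("w", 2:W)))
  for (t in 2:W) dy[, , t - 1] <- y[, , t] - y[, , t - 1]
  p2 <- latents$params
  p2$domains <- domains
  # implied wave-1 moments of the expanded domains (used by the binary
  # threshold solver): loading^2 * liability variance + disturbance
  mu_l <- latents$params$t1_mean[[1]]; v_l <- latents$params$t1_cov[1, 1]
  p2$t1_mean <- stats::setNames(intercepts + loadings * mu_l, domains)
  p2$t1_cov <- v_l * tcrossprod(loadings) + diag(dist_sd^2, k)
  dimnames(p2$t1_cov) <- list(domains, domains)
  structure(list(y = y, dy = dy, params = p2, n = n,
                 covariates = latents$covariates),
            class = "lcs_latent_panel")
}

#' Parcel sum scores from binary symptom items
#'
#' Sums each parcel's member items per person and wave. Items must be
#' coded so 1 indicates symptom presence; an 8-item parcel therefore
#' ranges 0-8 and a 4-item parcel 0-4.
#'
#' @param items_wide Wide tibble of binary `<item>_w<t>` columns.
#' @param parcel_map Named list parcel -> member items.
#' @param waves Wave labels present in the columns.
#' @return Wide tibble of `<parcel>_w<t>` columns.
#' @export
parcel_scores <- function(items_wide, parcel_map, waves) {
  out <- list()
  for (w in waves) {
    for (pc in names(parcel_map)) {
      cols <- paste0(parcel_map[[pc]], "_w", w)
      missing_cols <- setdiff(cols, colnames(items_wide))
      if (length(missing_cols)) {
        stop("invalid-design: parcel member columns absent: ",
             paste(missing_cols, collapse = ", "), call. = FALSE)
      }
      out[[paste0(pc, "_w", w)]] <- rowSums(items_wide[, cols, drop = FALSE])
    }
  }
  tibble::as_tibble(out)
}

#' Mask cells completely at random
#'
#' Masks each data cell independently with probability `rate` (MCAR).
#' Rows losing every cell are dropped; their count is attached as the
#' `"n_dropped"` attribute and reported via a message.
#'
#' @param panel Wide tibble.
#' @param rate Missing probability in `[0, 1)`.
#' @param seed Seed.
#' @param exclude Columns never masked (ids, covariates).
#' @return The masked tibble (possibly fewer rows).
#' @export
apply_missingness <- function(panel, rate, seed, exclude = c("person", "age", "gender")) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) {
    attr(panel, "n_dropped") <- 0L
    return(panel)
  }
  cols <- setdiff(colnames(panel), exclude)
  X <- as.matrix(panel[, cols])
  with_seed(seed, {
    mask <- matrix(stats::runif(length(X)) < rate, nrow(X), ncol(X))
    X[mask] <- NA
  })
  panel[, cols] <- tibble::as_tibble(as.data.frame(X))
  all_missing <- rowSums(!is.na(panel[, cols])) == 0
  n_dropped <- sum(all_missing)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) with no observed cell dropped")
    panel <- panel[!all_missing, , drop = FALSE]
  }
  attr(panel, "n_dropped") <- n_dropped
  panel
}

# ---------------------------------------------------------------------------
# Cohort-level configuration and presets ------------------------------------

#' Simulation configuration for a synthetic cohort
#'
#' Collects everything that defines a simulated study: the measurement
#' design, the generating world (`"common-cause"` or `"mutualism"`),
#' the trajectory dynamics, measurement values, MCAR missing rate,
#' discretization, sample size and seed. [config_zproso()] and
#' [config_share()] provide the two cohort-like presets with their
#' study-scale defaults.
#'
#' @param design An `lcs_design`.
#' @param world Generating world.
#' @param n Persons.
#' @param params An `lcs_params` over the design's domains (mutualism
#'   world) or over the single liability (common-cause world).
#' @param measurement Measurement values tibble.
#' @param second_order For the common-cause world, a list with
#'   `loadings`, `intercepts`, `dist_sd` expanding the liability into
#'   the design's domains.
#' @param missing_rate MCAR rate in `[0, 1)`.
#' @param discretize `"none"`, `"likert-5"` or `"binary"`.
#' @param age_mean,age_sd Covariate distribution when the design carries
#'   an age covariate.
#' @param seed Mandatory seed.
#' @return An object of class `lcs_sim_config`.
#' @export
sim_config <- function(design, world = c("mutualism", "common-cause"),
                       n, params, measurement = default_measurement(design),
                       second_order = NULL,
                       missing_rate = 0, discretize = "none",
                       age_mean = 61.5, age_sd = 8.3, seed = 1) {
  world <- match.arg(world)
  stopifnot(missing_rate >= 0, missing_rate < 1)
  if (discretize == "binary" && design$scale_type != "binary-symptom") {
    stop("binary thresholds require a binary-symptom design", call. = FALSE)
  }
  structure(list(design = design, world = world, n = n, params = params,
                 measurement = measurement, second_order = second_order,
                 missing_rate = missing_rate, discretize = discretize,
                 age_mean = age_mean, age_sd = age_sd, seed = seed),
            class = "lcs_sim_config")
}

#' @export
print.lcs_sim_config <- function(x, ...) {
  cat("<lcs_sim_config> ", x$world, " world, n = ", x$n, ", ",
      length(x$design$waves), " waves, missing ", 100 * x$missing_rate,
      "%, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Adolescent-cohort simulation preset
#'
#' Study-scale defaults: n = 1,482 persons, 42 Likert-like items over 4
#' domains and 4 waves, about 11% MCAR missingness. Dynamics: baseline
#' variances 1 with inter-domain correlations 0.3, self-feedback -0.2,
#' coupling +0.2 in the mutualism world and a single p-factor chain in
#' the common-cause world.
#'
#' @param n Persons.
#' @param world Generating world.
#' @param missing_rate MCAR rate.
#' @param discretize `"none"` (items treated as continuous) or
#'   `"likert-5"`.
#' @param seed Seed.
#' @param waves Number of waves (default 4; smaller values give reduced
#'   designs for quick experiments).
#' @return An `lcs_sim_config`.
#' @export
config_zproso <- function(n = 1482, world = c("mutualism", "common-cause"),
                          missing_rate = 0.11, discretize = "none", seed = 1,
                          waves = 4) {
  world <- match.arg(world)
  design <- design_zproso()
  if (waves != 4) design$waves <- seq_len(waves)
  domains <- unique(design$items$domain)
  params <- if (world == "mutualism") {
    trajectory_params(domains, waves, phi = -0.2, gamma = 0.2)
  } else {
    trajectory_params("p", waves, phi = -0.2, gamma = 0)
  }
  sim_config(design, world, n, params,
             second_order = if (world == "common-cause")
               list(loadings = c(1, 0.8, 0.6, 0.7), intercepts = 0,
                    dist_sd = sqrt(0.5)),
             missing_rate = missing_rate, discretize = discretize, seed = seed)
}

#' Older-adult cohort simulation preset
#'
#' Study-scale defaults: n = 6,443 persons, 12 binary symptoms over 5
#' waves parceled into affective suffering (8 items) and motivation (4
#' items), about 5.31% MCAR missingness on the parcel scores, and a
#' baseline age covariate distributed N(61.5, 8.3^2) with a small
#' positive slope on the baseline latents.
#'
#' @inheritParams config_zproso
#' @param waves Number of waves (default 5).
#' @return An `lcs_sim_config`.
#' @export
config_share <- function(n = 6443, world = c("mutualism", "common-cause"),
                         missing_rate = 0.0531, seed = 1, waves = 5) {
  world <- match.arg(world)
  design <- design_share()
  if (waves != 5) design$waves <- seq_len(waves)
  domains <- unique(design$items$domain)
  params <- if (world == "mutualism") {
    trajectory_params(domains, waves, phi = -0.2, gamma = 0.2,
                      covariate_slopes = list(age = 0.012))
  } else {
    trajectory_params("dep", waves, phi = -0.2, gamma = 0,
                      covariate_slopes = list(age = 0.012))
  }
  sim_config(design, world, n, params,
             second_order = if (world == "common-cause")
               list(loadings = c(1, 0.8), intercepts = 0, dist_sd = sqrt(0.5)),
             missing_rate = missing_rate, discretize = "binary", seed = seed)
}

#' Simulate a full synthetic cohort
#'
#' Runs the generator end to end for a configuration: latent
#' trajectories in the stated world, item emission, parceling for
#' binary-symptom designs, covariate draws, and MCAR masking. The
#' returned data are in the wide `<item>_w<t>` (or `<parcel>_w<t>`)
#' convention ready for [fit_lcs()]. Identical configurations (same
#' seed) reproduce identical output.
#'
#' @param config An `lcs_sim_config`.
#' @param seed Overrides the config seed when supplied.
#' @return A list of class `lcs_cohort`: `data` (wide tibble with
#'   `person` id), `items` (pre-parcel item data for binary designs),
#'   `latents`, `design`, `config`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "lcs_sim_config"))
  design <- config$design
  n <- config$n
  # distinct sub-seeds per stage, derived from the master seed
  s <- function(off) (seed * 7L + off) %% .Machine$integer.max
  covariates <- NULL
  if ("age" %in% design$covariates) {
    covariates <- with_seed(s(1), tibble::tibble(
      age = stats::rnorm(n, config$age_mean, config$age_sd)))
  }
  lat <- simulate_lcs_trajectories(config$params, n, seed = s(2),
                                   covariates = covariates)
  if (config$world == "common-cause") {
    so <- config$second_order
    domains <- unique(design$items$domain)
    lat_d <- expand_common_cause(lat, domains, so$loadings, so$intercepts,
                                 so$dist_sd, seed = s(3))
  } else {
    lat_d <- lat
  }
  items <- emit_items(lat_d, design, config$measurement, seed = s(4),
                      discretize = config$discretize)
  if (!is.null(design$parcel_map)) {
    data <- parcel_scores(items, design$parcel_map, design$waves)
  } else {
    data <- items
  }
  if (!is.null(covariates)) data <- dplyr::bind_cols(data, covariates)
  data <- dplyr::bind_cols(tibble::tibble(person = seq_len(n)), data)
  data <- apply_missingness(data, config$missing_rate, seed = s(5))
  structure(list(data = data, items = items, latents = lat_d,
                 liability = if (config$world == "common-cause") lat else NULL,
                 design = design, config = config),
            class = "lcs_cohort")
}

#' @export
print.lcs_cohort <- function(x, ...) {
  cat("<lcs_cohort> ", nrow(x$data), " persons, ",
      ncol(x$data) - 1, " columns (", x$config$world, " world)\n", sep = "")
  invisible(x)
}

#' Write a simulated cohort to CSV with a JSON sidecar
#'
#' The CSV uses the wide `item<i>_w<t>` header convention with blank
#' cells for missing values; the sidecar records the full simulation
#' configuration for audit.
#'
#' @param cohort An `lcs_cohort`.
#' @param path CSV output path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(cohort, path) {
  utils::write.csv(cohort$data, path, row.names = FALSE, na = "")
  cfg <- cohort$config
  side <- list(
    world = cfg$world, n = cfg$n, waves = length(cfg$design$waves),
    missing_rate = cfg$missing_rate, discretize = cfg$discretize,
    seed = cfg$seed,
    domains = cfg$params$domains,
    phi = cfg$params$phi, gamma = cfg$params$gamma, alpha = cfg$params$alpha,
    zeta_cov = cfg$params$zeta_cov, t1_mean = cfg$params$t1_mean,
    t1_cov = cfg$params$t1_cov,
    measurement = cfg$measurement,
    reverse_coded = cfg$design$reverse_coded
  )
  writeLines(jsonlite::toJSON(side, dataframe = "columns", auto_unbox = TRUE,
                              digits = NA, null = "null"),
             paste0(path, ".json"))
  invisible(path)
}

# map an lcs_params object onto the chain-parameter labels of a spec
# (direct-score chains; optionally a one-factor chain via the f_ prefix)
trajectory_theta <- function(spec, params, age_mean = NULL, age_var = NULL,
                             extra = NULL, partial = FALSE) {
  labs <- free_labels(spec)
  th <- stats::setNames(rep(NA_real_, length(labs)), labs)
  doms <- params$domains
  strip <- function(x) sub("^f_", "", x)
  zc <- params$zeta_cov
  find_dom <- function(b) {
    b <- strip(b)
    if (b %in% doms) b else NA_character_
  }
  for (lab in labs) {
    if (grepl("^mu1_", lab)) {
      d <- find_dom(sub("^mu1_", "", lab))
      if (!is.na(d)) th[lab] <- params$t1_mean[[d]]
    } else if (grepl("^psi1_", lab)) {
      rest <- strip(sub("^psi1_", "", lab))
      if (rest %in% doms) th[lab] <- params$t1_cov[rest, rest]
      else {
        for (d1 in doms) {
          pre <- paste0(d1, "_")
          if (startsWith(rest, pre) || startsWith(rest, paste0(d1, "_f_"))) {
            d2 <- strip(sub(paste0("^", d1, "_"), "", rest))
            if (d2 %in% doms) { th[lab] <- params$t1_cov[d1, d2]; break }
          }
        }
      }
    } else if (grepl("^alpha_", lab)) {
      m <- regmatches(lab, regexec("^alpha_(.+)_w([0-9]+)$", lab))[[1]]
      d <- find_dom(m[2]); t <- as.integer(m[3])
      if (!is.na(d)) th[lab] <- params$alpha[d, t - 1]
    } else if (grepl("^zeta_", lab)) {
      m <- regmatches(lab, regexec("^zeta_(.+)_w([0-9]+)$", lab))[[1]]
      d <- find_dom(m[2]); key <- paste0(d, "_w", m[3])
      if (!is.na(d) && key %in% rownames(zc)) th[lab] <- zc[key, key]
    } else if (grepl("^zcov_", lab)) {
      m <- regmatches(lab, regexec("^zcov_(.+)_w([0-9]+)_(.+)_w([0-9]+)$", lab))[[1]]
      d1 <- find_dom(m[2]); d2 <- find_dom(m[4])
      k1 <- paste0(d1, "_w", m[3]); k2 <- paste0(d2, "_w", m[5])
      if (!is.na(d1) && !is.na(d2) && all(c(k1, k2) %in% rownames(zc))) {
        th[lab] <- zc[k1, k2]
      }
    } else if (grepl("^phi_", lab)) {
      m <- regmatches(lab, regexec("^phi_(.+)_w([0-9]+)$", lab))[[1]]
      d <- find_dom(m[2]); t <- as.integer(m[3])
      if (!is.na(d)) th[lab] <- params$phi[d, t - 1]
    } else if (grepl("^gamma_", lab)) {
      m <- regmatches(lab, regexec("^gamma_(.+)_w([0-9]+)$", lab))[[1]]
      t <- as.integer(m[3]); rest <- m[2]
      for (src in doms) {
        for (pref in c(paste0(src, "_"), paste0("f_", src, "_"))) {
          if (startsWith(rest, pref)) {
            tgt <- find_dom(sub(paste0("^", pref), "", rest))
            if (!is.na(tgt)) { th[lab] <- params$gamma[src, tgt, t - 1]; break }
          }
        }
        if (!is.na(th[lab])) break
      }
    } else if (lab == "mu_age" && !is.null(age_mean)) th[lab] <- age_mean
    else if (lab == "var_age" && !is.null(age_var)) th[lab] <- age_var
    else if (grepl("^b_age_", lab) && !is.null(params$covariate_slopes$age)) {
      tgt <- find_dom(sub("_w[0-9]+$", "", sub("^b_age_", "", lab)))
      sl <- rep_len(params$covariate_slopes$age, length(doms))
      names(sl) <- doms
      if (!is.na(tgt)) th[lab] <- sl[[tgt]]
    }
  }
  if (!is.null(extra)) th[names(extra)] <- extra
  if (partial) return(th)
  if (anyNA(th)) {
    stop("trajectory_theta could not map labels: ",
         paste(utils::head(names(th)[is.na(th)], 5), collapse = ", "), call. = FALSE)
  }
  th
}
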