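test_that("implied moments obey the change-score identities", {
  design <- toy_design_2x2()
  spec <- build_mutualism_multivariate(design)
  sk <- lcscomp:::ram_skeleton(spec)
  th <- lcscomp:::start_values(spec)
  th[grep("^(phi_|gamma_)", names(th))] <- c(-0.3, 0.2, 0.1, -0.1)
  th[grep("^alpha_", names(th))] <- c(0.4, -0.2)
  th[grep("^mu1_", names(th))] <- c(1, 0.5)
  im_full <- lcscomp:::ram_structure(sk, lcscomp:::theta_for(sk, th))
  m <- stats::setNames(im_full$m, sk$vars)
  # E[y_t] - E[y_{t-1}] - E[dy_t] = 0 exactly, forced by the unit paths
  for (d in c("f_A", "f_B")) {
    expect_equal(m[[paste0(d, "_w2")]],
                 m[[paste0(d, "_w1")]] + m[[paste0("d_", d, "_w2")]])
  }
})

test_that("perfect-stability limit gives constant moments across waves", {
  # univariate chain, direct scores: alpha = 0, phi = 0, zeta = 0
  design <- measurement_design(
    tibble::tibble(item = c("a", "b"), domain = c("A", "B")),
    waves = 1:3, parcel_map = list(a = "a", b = "b"))
  spec <- build_mutualism_bivariate(design)
  th <- lcscomp:::start_values(spec)
  th[grep("^(alpha_|phi_|gamma_|zeta_|zcov_)", names(th))] <- 0
  th[grep("^mu1_", names(th))] <- 2
  th[grep("^psi1_a$|^psi1_b$", names(th))] <- 1.5
  th[grep("^psi1_a_b$", names(th))] <- 0.4
  im <- implied_moments(spec, th)
  expect_equal(unname(im$mu), rep(2, 6))
  # all cross-wave covariances of a series equal its wave-1 variance
  acols <- paste0("a_w", 1:3)
  expect_true(all(abs(im$Sigma[acols, acols] - 1.5) < 1e-12))
})

test_that("complete-data log-likelihood matches closed forms", {
  # one observed variable fitted to its own sample moments
  x <- c(1.2, 0.8, 2.1, 1.4, 0.3)
  n <- length(x); m <- mean(x); v <- mean((x - m)^2)
  vars <- "v1"
  spec <- lcscomp:::new_model_spec(
    variables = tibble::tibble(name = vars, latent = FALSE),
    paths = tibble::tibble(from = character(), to = character(),
                           label = character(), value = double(), free = logical()),
    covs = tibble::tibble(v1 = "v1", v2 = "v1", label = "s", value = NA_real_,
                          free = TRUE),
    means = tibble::tibble(var = "v1", label = "m", value = NA_real_, free = TRUE))
  ms <- moment_summary(data.frame(v1 = x))
  ll <- loglik_complete(spec, c(s = v, m = m), ms)
  expect_equal(ll, sum(stats::dnorm(x, m, sqrt(v), log = TRUE)))
})

test_that("chi-square is zero at the saturated point", {
  ch <- base_cohort()
  spec <- build_mutualism_bivariate(ch$design)
  # df 0 here: the direct-score mutualism spec saturates 6 variables
  expect_equal(count_free_parameters(spec)$df, 0)
  f <- base_fit()
  expect_lt(f$chisq, 1e-4)
  expect_equal(f$df, 0)
  expect_true(f$indices$rmsea.undefined)
  expect_equal(f$indices$rmsea, 0)
})

test_that("FIML equals complete-data likelihood when nothing is missing", {
  ch <- base_cohort()
  spec <- build_mutualism_bivariate(ch$design)
  th <- lcscomp:::start_values(spec, ch$data)
  ms <- moment_summary(ch$data[, observed_vars(spec)])
  ll_c <- loglik_complete(spec, th, ms)
  ll_f <- loglik_fiml(spec, th, ch$data)
  expect_equal(as.numeric(ll_f), ll_c, tolerance = 1e-10)
})

test_that("FIML of a single row with one observed cell is the univariate density", {
  ch <- base_cohort()
  spec <- build_mutualism_bivariate(ch$design)
  th <- lcscomp:::start_values(spec, ch$data)
  row <- ch$data[1, ]
  keep <- "aff_w1"
  for (cn in setdiff(observed_vars(spec), keep)) row[[cn]] <- NA
  ll <- loglik_fiml(spec, th, row)
  im <- implied_moments(spec, th)
  expect_equal(as.numeric(ll),
               stats::dnorm(row[[keep]], im$mu[keep],
                            sqrt(im$Sigma[keep, keep]), log = TRUE))
})

test_that("rows with no observed cell are excluded and counted", {
  ch <- base_cohort()
  spec <- build_mutualism_bivariate(ch$design)
  th <- lcscomp:::start_values(spec, ch$data)
  d2 <- ch$data
  for (cn in observed_vars(spec)) d2[[cn]][3] <- NA
  ll <- loglik_fiml(spec, th, d2)
  expect_equal(attr(ll, "n_dropped"), 1L)
  expect_equal(attr(ll, "n_used"), nrow(d2) - 1L)
})

test_that("the analytic gradient matches central finite differences", {
  ch <- direct_cohort(n = 150, waves = 3, seed = 31, missing_rate = 0.15)
  spec <- build_mutualism_bivariate(ch$design)
  sk <- lcscomp:::ram_skeleton(spec)
  pats <- lcscomp:::fiml_patterns(ch$data, observed_vars(spec))
  fo <- lcscomp:::make_objective(sk, pats)
  th <- lcscomp:::start_values(spec, ch$data)[sk$labels]
  set.seed(8)
  th <- th + stats::rnorm(length(th), 0, 0.05)
  ga <- fo$grad(th)
  gn <- vapply(seq_along(th), function(j) {
    h <- 1e-6 * (1 + abs(th[j]))
    tp <- th; tp[j] <- tp[j] + h
    tm <- th; tm[j] <- tm[j] - h
    (fo$obj(tp) - fo$obj(tm)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(ga - gn) / (1 + abs(gn))), 1e-5)
})

test_that("the optimum has a small gradient and the same solution from random starts", {
  ch <- base_cohort()
  f1 <- base_fit()
  expect_true(f1$convergence$converged)
  expect_lt(f1$convergence$grad_norm, 1e-4)
  # refit from jittered starts: same optimum
  spec <- build_mutualism_bivariate(ch$design)
  th0 <- lcscomp:::start_values(spec, ch$data)
  set.seed(99)
  jit <- stats::rnorm(length(th0), 0, 0.15)
  f2 <- fit_lcs(ch$data, spec, start = th0 + jit, seed = 12)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-6)
  expect_equal(unname(f2$theta), unname(f1$theta), tolerance = 1e-3)
})

test_that("nested models never beat their nesting model on chi-square", {
  ch <- direct_cohort(n = 300, waves = 3, seed = 41, missing_rate = 0.05)
  full <- fit_lcs(ch$data, build_mutualism_bivariate(ch$design), seed = 2,
                  se = FALSE)
  restricted <- fit_lcs(ch$data,
                        build_mutualism_bivariate(ch$design,
                                                  "fixed-change-covariances"),
                        seed = 2, se = FALSE)
  expect_gte(restricted$chisq, full$chisq - 1e-6)
})

test_that("standardized coefficients follow the implied-moment algebra", {
  f <- base_fit()
  spec <- f$spec
  sk <- lcscomp:::ram_skeleton(spec)
  st <- lcscomp:::ram_structure(sk, lcscomp:::theta_for(sk, f$theta))
  sds <- stats::setNames(sqrt(diag(st$C)), sk$vars)
  est <- tidy(f)
  # brute-force check for one phi and one gamma label
  for (lab in c("phi_aff_w2", "gamma_mot_aff_w2")) {
    row <- spec$paths[!is.na(spec$paths$label) & spec$paths$label == lab, ]
    manual <- est$b[est$label == lab] * sds[[row$from]] / sds[[row$to]]
    expect_equal(est$beta[est$label == lab], manual)
  }
  # b = 0 implies beta = 0
  th0 <- f$theta; th0["gamma_mot_aff_w2"] <- 0
  b0 <- lcscomp:::standardize_theta(spec, sk, th0)
  expect_equal(unname(b0["gamma_mot_aff_w2"]), 0)
})

test_that("fit indices hit their analytic endpoints", {
  # chi2 == df gives RMSEA 0
  ci <- lcscomp:::rmsea_ci(10, 10, 500)
  expect_equal(sqrt(max(10 - 10, 0) / (10 * 500)), 0)
  expect_lte(ci[1], ci[2])
  # CFI endpoints: fitted = baseline -> 0; fitted = saturated -> 1
  cfi <- function(chi2, df, chi2_b, df_b) {
    num <- max(chi2 - df, 0); den <- max(chi2_b - df_b, chi2 - df, 0)
    if (den > 0) 1 - num / den else 1
  }
  expect_equal(cfi(250, 20, 250, 20), 0)
  expect_equal(cfi(0, 0, 250, 20), 1)
  # RMSEA CI brackets the point estimate on a real fit
  ch <- direct_cohort(n = 300, waves = 3, seed = 43)
  f <- fit_lcs(ch$data,
               build_mutualism_bivariate(ch$design, "fixed-change-covariances"),
               seed = 2, se = FALSE)
  expect_gte(f$indices$rmsea, f$indices$rmsea.ci.lower - 1e-10)
  expect_lte(f$indices$rmsea, f$indices$rmsea.ci.upper + 1e-10)
  # the tabular view matches the stored indices; using the model itself
  # as its own baseline drives CFI to the lower endpoint
  tab <- fit_indices(f)
  expect_equal(tab$cfi, f$indices$cfi)
  expect_equal(fit_indices(f, baseline = f)$cfi, 0)
})

test_that("EM saturated solution matches closed-form moments when data are complete", {
  ch <- base_cohort()
  vars <- observed_vars(build_mutualism_bivariate(ch$design))
  pats <- lcscomp:::fiml_patterns(ch$data, vars)
  sat <- lcscomp:::em_saturated(pats)
  ms <- moment_summary(ch$data[, vars])
  expect_equal(sat$mean, ms$mean)
  expect_equal(sat$cov, ms$cov)
})

test_that("EM saturated likelihood dominates any structured model under missingness", {
  ch <- direct_cohort(n = 250, waves = 3, seed = 47, missing_rate = 0.12)
  spec <- build_mutualism_bivariate(ch$design)
  f <- fit_lcs(ch$data, spec, seed = 2, se = FALSE)
  expect_gte(f$saturated_loglik, f$loglik - 1e-6)
  expect_gte(f$loglik, f$baseline$loglik - 1e-6)
})
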