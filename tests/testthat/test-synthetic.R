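test_that("zero dynamics give constant trajectories", {
  params <- trajectory_params(c("a", "b"), 3, phi = 0, gamma = 0, alpha = 0,
                              zeta_var = 0)
  lat <- simulate_lcs_trajectories(params, 50, seed = 1)
  expect_equal(lat$y[, , 2], lat$y[, , 1])
  expect_equal(lat$y[, , 3], lat$y[, , 1])
  expect_true(all(lat$dy == 0))
})

test_that("one-step change means follow the hand recursion", {
  # E[dy1 at wave 2] = alpha1 + phi1 E[y1] + gamma(2->1) E[y2]
  #                  = 0.2 - 0.3 * 1.0 + 0.1 * 0.5 = -0.05
  G <- array(0, c(2, 2, 1), dimnames = list(c("a", "b"), c("a", "b"), NULL))
  G["b", "a", 1] <- 0.1
  params <- trajectory_params(
    c("a", "b"), 2, phi = matrix(c(-0.3, 0), 2, 1),
    gamma = G, alpha = matrix(c(0.2, 0), 2, 1),
    zeta_var = 0.2, t1_mean = c(1.0, 0.5), t1_var = 1, t1_cor = 0)
  lat <- simulate_lcs_trajectories(params, 200000, seed = 2)
  expect_equal(mean(lat$dy[, "a", 1]), -0.05, tolerance = 0.01)
})

test_that("the level/change accounting identity holds exactly", {
  params <- trajectory_params(c("a", "b"), 4)
  lat <- simulate_lcs_trajectories(params, 100, seed = 3)
  for (t in 2:4) {
    expect_identical(lat$y[, , t], lat$y[, , t - 1] + lat$dy[, , t - 1])
  }
})

test_that("identical configurations reproduce identical cohorts", {
  cfg <- config_share(n = 60, waves = 3, seed = 9)
  c1 <- suppressMessages(simulate_cohort(cfg))
  c2 <- suppressMessages(simulate_cohort(cfg))
  expect_identical(c1$data, c2$data)
  expect_identical(c1$items, c2$items)
  # a different seed changes the draw
  c3 <- suppressMessages(simulate_cohort(config_share(n = 60, waves = 3, seed = 10)))
  expect_false(identical(c1$data, c2$data) && identical(c1$data, c3$data))
})

test_that("identity emission reproduces latents exactly", {
  cfg <- config_bivariate_direct(n = 40, waves = 3, seed = 5)
  ch <- simulate_cohort(cfg)
  expect_equal(ch$data$aff_w2, unname(ch$latents$y[, "aff", 2]))
  expect_equal(ch$data$mot_w3, unname(ch$latents$y[, "mot", 3]))
})

test_that("binary thresholds hit their target prevalences", {
  design <- design_share()
  params <- trajectory_params(c("aff", "mot"), 5)
  lat <- simulate_lcs_trajectories(params, 10000, seed = 11)
  meas <- default_measurement(design)
  meas$prevalence <- rep(c(0.3, 0.1), length.out = nrow(meas))
  items <- emit_items(lat, design, meas, seed = 12, discretize = "binary")
  for (r in c(1, 2)) {
    it <- meas$item[r]
    prev <- mean(items[[paste0(it, "_w1")]])
    se <- sqrt(meas$prevalence[r] * (1 - meas$prevalence[r]) / 10000)
    expect_lt(abs(prev - meas$prevalence[r]), 3 * se + 0.01)
  }
  expect_error(
    emit_items(lat, design,
               dplyr::mutate(meas, prevalence = 1.2), seed = 1,
               discretize = "binary"),
    "prevalence")
})

test_that("a latent-median threshold yields prevalence one half", {
  design <- design_share()
  params <- trajectory_params(c("aff", "mot"), 5, t1_mean = 0)
  lat <- simulate_lcs_trajectories(params, 10000, seed = 13)
  meas <- default_measurement(design)
  meas$prevalence <- 0.5
  items <- emit_items(lat, design, meas, seed = 14, discretize = "binary")
  prev <- mean(items$sadness_w1)
  expect_lt(abs(prev - 0.5), 3 * sqrt(0.25 / 10000) + 0.01)
})

test_that("parcel scores are member sums with the documented ranges", {
  design <- design_share()
  n <- 30
  items <- tibble::as_tibble(
    stats::setNames(as.data.frame(matrix(1L, n, 12)),
                    paste0(design$items$item, "_w1")))
  sc <- parcel_scores(items, design$parcel_map, waves = 1)
  expect_equal(sc$aff_w1, rep(8, n))
  expect_equal(sc$mot_w1, rep(4, n))
  items0 <- tibble::as_tibble(
    stats::setNames(as.data.frame(matrix(0L, n, 12)),
                    paste0(design$items$item, "_w1")))
  sc0 <- parcel_scores(items0, design$parcel_map, waves = 1)
  expect_equal(sc0$aff_w1, rep(0, n))
  expect_error(parcel_scores(items[, -1], design$parcel_map, waves = 1),
               "invalid-design")
})

test_that("MCAR masking matches its nominal rate and rate 0 is the identity", {
  cfg <- config_zproso(n = 200, seed = 21, missing_rate = 0)
  ch <- simulate_cohort(cfg)
  masked <- apply_missingness(ch$data, 0.11, seed = 22)
  cols <- setdiff(colnames(masked), "person")
  frac <- mean(is.na(as.matrix(masked[, cols])))
  ncell <- length(cols) * nrow(masked)
  expect_lt(abs(frac - 0.11), 3 * sqrt(0.11 * 0.89 / ncell))
  same <- apply_missingness(ch$data, 0, seed = 22)
  expect_identical(as.data.frame(same), as.data.frame(ch$data))
})

test_that("non-PSD generating covariances are rejected before sampling", {
  R <- matrix(c(1, 2, 2, 1), 2, 2)  # correlation > 1: not PSD
  expect_error(trajectory_params(c("a", "b"), 2, zeta_cor = R),
               "positive semidefinite")
  expect_error(trajectory_params("a", 3, gamma = 0.2), "single domain")
})

test_that("simulated moments converge to the implied moments of the matching spec", {
  cfg <- config_bivariate_direct(n = 120000, waves = 3, seed = 77)
  ch <- simulate_cohort(cfg)
  spec <- build_mutualism_bivariate(ch$design)
  th <- lcscomp:::trajectory_theta(spec, cfg$params)
  im <- implied_moments(spec, th)
  v <- observed_vars(spec)
  X <- as.matrix(ch$data[, v])
  n <- nrow(X)
  mu_hat <- colMeans(X); S_hat <- stats::cov(X)
  sd_mu <- sqrt(diag(im$Sigma)[v] / n)
  expect_true(all(abs(mu_hat - im$mu[v]) < 4 * sd_mu))
  # covariance entries: MC error ~ sqrt((s_ii s_jj + s_ij^2)/n)
  for (i in seq_along(v)) for (j in seq_along(v)) {
    mc <- sqrt((im$Sigma[i, i] * im$Sigma[j, j] + im$Sigma[i, j]^2) / n)
    expect_lt(abs(S_hat[v[i], v[j]] - im$Sigma[v[i], v[j]]), 4 * mc)
  }
})

test_that("cohorts round-trip through CSV with config sidecar", {
  cfg <- config_zproso(n = 25, waves = 3, seed = 31, missing_rate = 0.1)
  ch <- suppressMessages(simulate_cohort(cfg))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_panel_csv(ch, tmp)
  expect_true(file.exists(paste0(tmp, ".json")))
  back <- read_panel_csv(tmp, ch$design)
  expect_equal(as.data.frame(back[, colnames(ch$data)]),
               as.data.frame(ch$data), tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(is.na(back$item01_w2), is.na(ch$data$item01_w2))
  side <- jsonlite::fromJSON(paste0(tmp, ".json"))
  expect_equal(side$seed, 31)
  expect_equal(side$missing_rate, 0.1)
})
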