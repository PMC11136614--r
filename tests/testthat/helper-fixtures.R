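# Shared fixtures: tiny designs and memoized fits so expensive objects
# are built once per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .cache)) assign(key, force(expr), .cache)
  get(key, .cache)
}

# two-domain, two-wave toy design (one interval, one pair)
toy_design_2x2 <- function() {
  measurement_design(
    tibble::tibble(item = c("a1", "a2", "b1", "b2"),
                   domain = c("A", "A", "B", "B")),
    waves = 1:2)
}

# single-construct design: 6 continuous items, 3 waves (for invariance)
inv_design <- function() {
  measurement_design(
    tibble::tibble(item = paste0("x", 1:6), domain = "dep"),
    waves = 1:3)
}

# direct bivariate cohort (identity emission): the generator and the
# direct-score models share one scale, so truth is recoverable
direct_cohort <- function(n = 500, waves = 3, seed = 101, missing_rate = 0,
                          world = "mutualism", ...) {
  simulate_cohort(config_bivariate_direct(n = n, waves = waves, world = world,
                                          missing_rate = missing_rate,
                                          seed = seed, ...))
}

fit_direct_mut <- function(cohort, ...) {
  fit_lcs(cohort$data, build_mutualism_bivariate(cohort$design), ...)
}

# a small complete-data bivariate cohort and its mutualism fit, reused
# across engine tests
base_cohort <- function() cached("base_cohort", direct_cohort(n = 400, seed = 77))

base_fit <- function() cached("base_fit", fit_direct_mut(base_cohort(), seed = 3))

# synthetic invariance cohort: liability chain -> 6 items; optionally a
# planted intercept drift on chosen items at chosen waves
inv_cohort <- function(n = 600, seed = 55, drift = NULL) {
  design <- inv_design()
  params <- trajectory_params("dep", 3, phi = -0.2, gamma = 0)
  lat <- simulate_lcs_trajectories(params, n, seed = seed)
  meas <- tibble::tibble(item = paste0("x", 1:6), domain = "dep",
                         loading = c(1, 0.8, 0.7, 0.6, 0.5, 0.9),
                         intercept = 0, resid_sd = 0.5, prevalence = NA_real_)
  data <- emit_items(lat, design, meas, seed = seed + 2)
  if (!is.null(drift)) {
    for (d in drift) {
      cn <- paste0(d$item, "_w", d$wave)
      data[[cn]] <- data[[cn]] + d$delta
    }
  }
  list(data = data, design = design)
}
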