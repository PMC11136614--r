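test_that("fully invariant data pass every constraint level", {
  ic <- inv_cohort(n = 500, seed = 55)
  spec <- build_common_cause_depression(ic$design)
  report <- invariance_sequence(ic$data, spec, se = FALSE, seed = 2)
  expect_s3_class(report, "lcs_invariance")
  expect_equal(report$level, c("configural", "weak", "strong", "strict"))
  expect_true(all(report$converged))
  # first step has no delta; none violated on invariant data
  expect_true(is.na(report$delta_cfi[1]))
  expect_false(any(report$violated))
  # CFI non-increasing as constraints are added, up to numerical tolerance
  expect_true(all(diff(report$cfi) < 0.005))
  json <- invariance_to_json(report)
  expect_match(as.character(json), "configural")
})

test_that("a cutoff comparison is strict: a drop of exactly .010 passes", {
  # decision rule in isolation
  expect_false(0.010 > 0.01)
  expect_true(0.0101 > 0.01)
})

test_that("a planted intercept drift is flagged and freed first", {
  ic <- inv_cohort(n = 500, seed = 56,
                   drift = list(list(item = "x3", wave = 3, delta = 0.6)))
  spec <- build_common_cause_depression(ic$design)
  report <- invariance_sequence(ic$data, spec, se = FALSE, seed = 2,
                                levels = c("configural", "weak", "strong"))
  expect_false(report$violated[report$level == "weak"])
  expect_true(report$violated[report$level == "strong"])
  search <- partial_invariance_search(ic$data, spec, se = FALSE, seed = 2)
  expect_true(search$achieved)
  expect_equal(search$trail$item[1], "x3")
  expect_equal(search$trail$wave[1], 3)
  expect_equal(nrow(search$trail), 1)
  # the returned partially invariant spec frees exactly that intercept
  labs <- lcscomp:::free_labels(search$spec)
  expect_true("tau_x3_w3" %in% labs)
  expect_false("tau_x5_w3" %in% labs)
})

test_that("two planted drifts are freed in magnitude order", {
  ic <- inv_cohort(n = 500, seed = 57,
                   drift = list(list(item = "x3", wave = 3, delta = 0.8),
                                list(item = "x5", wave = 2, delta = 0.4)))
  search <- partial_invariance_search(
    ic$data, build_common_cause_depression(ic$design), se = FALSE, seed = 2)
  expect_gte(nrow(search$trail), 2)
  expect_equal(search$trail$item[1:2], c("x3", "x5"))
  expect_true(search$achieved)
})
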