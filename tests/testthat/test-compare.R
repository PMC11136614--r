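test_that("information criteria follow their closed forms", {
  ic <- information_criteria(-100, 10, 100)
  expect_equal(ic$aic, 220)
  expect_equal(ic$bic, 200 + 10 * log(100))
  ic0 <- information_criteria(-57.3, 0, 42)
  expect_equal(ic0$aic, 114.6)
  expect_equal(ic0$bic, 114.6)
})

test_that("criterion weights normalize, symmetrize, and shift-invariate", {
  expect_equal(unname(akaike_weights(c(5, 5))), c(0.5, 0.5))
  w <- akaike_weights(c(0, 2))
  expect_equal(unname(round(w, 3)), c(0.731, 0.269))
  expect_equal(sum(w), 1)
  # invariant to adding a constant
  expect_equal(akaike_weights(c(0, 2) + 1e6), w)
  # numerically safe for huge separations
  wbig <- akaike_weights(c(1e6, 1e6 + 5000))
  expect_equal(unname(wbig), c(1, 0), tolerance = 1e-12)
  expect_error(akaike_weights(3), "finite")
  expect_error(akaike_weights(c(1, Inf)), "finite")
})

test_that("likelihood-ratio tests handle identical, nested, and non-nested fits", {
  ch <- direct_cohort(n = 250, waves = 3, seed = 61)
  full <- fit_lcs(ch$data, build_mutualism_bivariate(ch$design), seed = 2,
                  se = FALSE)
  restricted <- fit_lcs(
    ch$data, build_mutualism_bivariate(ch$design, "fixed-change-covariances"),
    seed = 2, se = FALSE)
  out <- lrt(restricted, full)
  expect_equal(out$delta_df, choose(4, 2))
  expect_gte(out$delta_chisq, 0)
  # identical fits: delta 0, p 1
  same <- lrt(full, full)
  expect_equal(same$delta_chisq, 0)
  expect_equal(same$delta_df, 0)
  expect_equal(same$p.value, 1)
  # a common-cause fit is not label-nested in the mutualism fit
  cc <- fit_lcs(ch$data, build_common_cause_depression(ch$design), seed = 2,
                se = FALSE)
  expect_error(lrt(cc, full), "not nested")
})

test_that("comparison tables carry weights that sum to one", {
  ch <- direct_cohort(n = 250, waves = 3, seed = 62)
  f_mut <- fit_lcs(ch$data, build_mutualism_bivariate(ch$design), seed = 2,
                   se = FALSE)
  f_cc <- fit_lcs(ch$data, build_common_cause_depression(ch$design), seed = 2,
                  se = FALSE)
  tab <- compare_models(common_cause = f_cc, mutualism = f_mut)
  expect_s3_class(tab, "lcs_comparison")
  expect_equal(sum(tab$akaike_weight), 1)
  expect_equal(sum(tab$schwarz_weight), 1)
  md <- comparison_markdown(tab)
  expect_length(md, 2 + nrow(tab))
  expect_match(md[1], "Akaike")
  p <- autoplot(tab)
  expect_s3_class(p, "ggplot")
})
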