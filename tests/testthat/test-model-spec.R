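test_that("measurement designs validate their structure", {
  expect_s3_class(design_zproso(), "lcs_design")
  expect_equal(nrow(design_zproso()$items), 42)
  expect_length(unique(design_zproso()$items$domain), 4)
  expect_length(design_zproso()$waves, 4)
  d <- design_share()
  expect_equal(lengths(d$parcel_map), c(aff = 8L, mot = 4L))
  expect_length(d$waves, 5)
  expect_error(
    measurement_design(tibble::tibble(item = "a", domain = "x"), waves = 1),
    "unsupported-design")
  expect_error(
    measurement_design(tibble::tibble(item = "a", domain = NA_character_),
                       waves = 1:2),
    "invalid-design")
  expect_error(
    measurement_design(tibble::tibble(item = c("a", "b"), domain = "x"),
                       waves = 1:2,
                       parcel_map = list(p1 = c("a", "b"), p2 = "b")),
    "disjoint")
})

test_that("builders reject unsupported designs", {
  one_dom <- measurement_design(
    tibble::tibble(item = c("a", "b"), domain = "x"), waves = 1:2)
  expect_error(build_common_cause_pfactor(one_dom), "invalid-design")
  expect_error(build_mutualism_multivariate(one_dom), "invalid-design")
  three_series <- measurement_design(
    tibble::tibble(item = c("a", "b", "c"), domain = c("x", "y", "z")),
    waves = 1:2, parcel_map = list(p1 = "a", p2 = "b", p3 = "c"))
  expect_error(build_mutualism_bivariate(three_series), "unsupported-design")
  expect_error(
    build_mutualism_bivariate(
      measurement_design(tibble::tibble(item = c("a", "b"),
                                        domain = c("x", "y")),
                         waves = 1:2, parcel_map = list(p1 = "a", p2 = "b")),
      variant = "age-on-change"),
    "age covariate")
})

test_that("a 2-wave design yields one change factor, one phi, no change covariances", {
  spec <- build_common_cause_pfactor(toy_design_2x2())
  labs <- lcscomp:::free_labels(spec)
  expect_length(grep("^phi_", labs), 1)
  expect_length(grep("^alpha_", labs), 1)
  expect_length(grep("^zeta_", labs), 1)
  expect_length(grep("^zcov_", labs), 0)
  # freeing change covariances adds nothing with a single change factor
  spec2 <- apply_variant(spec, "free-change-covariances")
  expect_equal(count_free_parameters(spec2)$free, count_free_parameters(spec)$free)
})

test_that("a 2-domain 2-wave mutualism model has 2 couplings and 1 change covariance", {
  spec <- build_mutualism_bivariate(
    measurement_design(tibble::tibble(item = c("a", "b"), domain = c("x", "y")),
                       waves = 1:2, parcel_map = list(pa = "a", pb = "b")))
  labs <- lcscomp:::free_labels(spec)
  expect_length(grep("^gamma_", labs), 2)
  expect_length(grep("^zcov_", labs), 1)
})

test_that("coupling parameters enumerate over (source, target, interval)", {
  # enumeration oracle: ordered domain pairs x intervals
  spec <- lcs_model("zproso_mut")
  doms <- c("int", "ext", "pro", "adhd")
  expected <- nrow(expand.grid(src = doms, tgt = doms, t = 2:4)) -
    length(doms) * 3  # drop src == tgt
  expect_equal(expected, 36)
  expect_length(grep("^gamma_", lcscomp:::free_labels(spec)), expected)
})

test_that("every builder fixes exactly 2 unit paths per chain interval", {
  count_unit <- function(spec) {
    audit <- lcs_symbol_audit(spec)
    sum(audit$count[audit$symbol %in% c("beta_unit_auto", "beta_unit_loading")])
  }
  # zproso_cc: 1 chain x 3 intervals x 2; share_mut: 2 chains x 4 x 2
  expect_equal(count_unit(lcs_model("zproso_cc")), 6)
  expect_equal(count_unit(lcs_model("zproso_mut")), 24)
  expect_equal(count_unit(lcs_model("share_cc")), 8)
  expect_equal(count_unit(lcs_model("share_mut")), 16)
})

test_that("symbol audit maps each change-score symbol to one entry class", {
  audit <- lcs_symbol_audit(lcs_model("share_mut"))
  expect_setequal(audit$symbol,
                  c("y", "delta", "beta_unit_auto", "beta_unit_loading",
                    "phi", "gamma", "zeta"))
  expect_equal(audit$count[audit$symbol == "delta"], 8)
  expect_equal(audit$count[audit$symbol == "phi"], 8)
  expect_equal(audit$count[audit$symbol == "gamma"], 8)
  expect_equal(audit$count[audit$symbol == "zeta"], 8)
  expect_true(all(audit$count > 0))
})

test_that("variant application is idempotent and reversible", {
  base <- lcs_model("share_cc")
  freed <- apply_variant(base, "free-change-covariances")
  freed2 <- apply_variant(freed, "free-change-covariances")
  expect_equal(count_free_parameters(freed2), count_free_parameters(freed))
  refixed <- apply_variant(freed, "fixed-change-covariances")
  expect_equal(count_free_parameters(refixed)$free,
               count_free_parameters(base)$free)
  expect_error(lcs_model("share_cc",
                         c("free-change-covariances", "fixed-change-covariances")),
               "incompatible")
  expect_error(lcs_model("share_cc", c("weak", "strong")), "incompatible")
})

test_that("freeing change covariances shifts df by choose(k, 2)", {
  cases <- list(
    list(spec = lcs_model("zproso_cc"), k = 3),
    list(spec = lcs_model("share_cc"), k = 4))
  for (cs in cases) {
    df0 <- count_free_parameters(cs$spec)$df
    df1 <- count_free_parameters(
      apply_variant(cs$spec, "free-change-covariances"))$df
    expect_equal(df0 - df1, choose(cs$k, 2))
  }
  # and in reverse for the bivariate model with 8 change factors
  df_full <- count_free_parameters(lcs_model("share_mut"))$df
  df_fixed <- count_free_parameters(
    lcs_model("share_mut", "fixed-change-covariances"))$df
  expect_equal(df_fixed - df_full, choose(8, 2))
})

test_that("a fully saturated spec has df 0", {
  vars <- c("v1", "v2", "v3")
  pairs <- utils::combn(vars, 2)
  spec <- lcscomp:::new_model_spec(
    variables = tibble::tibble(name = vars, latent = FALSE),
    paths = tibble::tibble(from = character(), to = character(),
                           label = character(), value = double(),
                           free = logical()),
    covs = dplyr::bind_rows(
      tibble::tibble(v1 = vars, v2 = vars, label = paste0("v_", vars),
                     value = NA_real_, free = TRUE),
      tibble::tibble(v1 = pairs[1, ], v2 = pairs[2, ],
                     label = paste0("c_", pairs[1, ], pairs[2, ]),
                     value = NA_real_, free = TRUE)),
    means = tibble::tibble(var = vars, label = paste0("m_", vars),
                           value = NA_real_, free = TRUE))
  expect_equal(count_free_parameters(spec)$df, 0)
})

test_that("specifications round-trip through JSON", {
  spec <- lcs_model("share_mut", "age-on-change")
  json <- spec_to_json(spec)
  back <- spec_from_json(json)
  expect_equal(back$paths, spec$paths)
  expect_equal(back$covs, spec$covs)
  expect_equal(back$means, spec$means)
  expect_equal(count_free_parameters(back), count_free_parameters(spec))
})

test_that("residual-covariance scope is all wave pairs for the item cohort and equality for parcels", {
  sp_z <- lcs_model("zproso_cc")
  # 42 items x choose(4, 2) = 252 distinct labels
  expect_length(grep("^epsc_", lcscomp:::free_labels(sp_z)), 252)
  sp_s <- lcs_model("share_cc")
  expect_length(grep("^epsc_", lcscomp:::free_labels(sp_s)), 2)
  # ... yet each parcel's label appears at every one of the 10 wave pairs
  epsc_rows <- sp_s$covs[grepl("^epsc_aff$", sp_s$covs$label), ]
  expect_equal(nrow(epsc_rows), choose(5, 2))
})
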