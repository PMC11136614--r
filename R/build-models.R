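#' @keywords internal
# ---------------------------------------------------------------------------
# Variant handling -----------------------------------------------------------

.known_variants <- c("preregistered", "free-change-covariances",
                     "fixed-change-covariances", "age-on-change",
                     "age-on-change-free", "gender-baseline-covariate",
                     "configural", "weak", "strong", "strict", "partial")

parse_variants <- function(variant, freed_intercepts = list()) {
  variant <- unique(variant)
  bad <- setdiff(variant, .known_variants)
  if (length(bad)) stop("unknown variant tag(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  lev <- intersect(variant, c("configural", "weak", "strong", "strict", "partial"))
  if (length(lev) > 1) stop("incompatible variants: multiple invariance levels",
                            call. = FALSE)
  if (all(c("free-change-covariances", "fixed-change-covariances") %in% variant)) {
    stop("incompatible variants: change-score covariances cannot be both free and fixed",
         call. = FALSE)
  }
  if (all(c("age-on-change", "age-on-change-free") %in% variant)) {
    stop("incompatible variants: pick one age-on-change reading", call. = FALSE)
  }
  if (length(lev) && lev == "partial" && !length(freed_intercepts)) {
    stop("partial invariance requires `freed_intercepts`", call. = FALSE)
  }
  list(
    tags = sort(setdiff(variant, "preregistered")),
    change_cov = if ("free-change-covariances" %in% variant) "free"
                 else if ("fixed-change-covariances" %in% variant) "fixed"
                 else "default",
    age_on_change = if ("age-on-change" %in% variant) "constrained"
                    else if ("age-on-change-free" %in% variant) "free"
                    else "none",
    gender = "gender-baseline-covariate" %in% variant,
    invariance = if (length(lev)) lev else "strong",
    freed_intercepts = freed_intercepts
  )
}

# ---------------------------------------------------------------------------
# Assembly blocks ------------------------------------------------------------

# Measurement layer: items loading on one factor per (domain, wave).
# The first item of each domain is the marker: loading fixed to 1 and
# intercept fixed to 0 at every wave, so factor variances and T1 factor
# means are estimable. Invariance level controls which measurement
# parameters are equality-constrained over waves.
measurement_block <- function(items, waves, invariance = "strong",
                              freed_intercepts = list(),
                              resid_cov = c("all-pairs", "equal", "lag1", "none"),
                              factor_prefix = "f_") {
  resid_cov <- match.arg(resid_cov)
  domains <- unique(items$domain)
  paths <- list(); covs <- list(); means <- list()
  obs <- character()
  freed_key <- vapply(freed_intercepts, function(fi)
    paste0(fi$item, "_w", fi$wave), character(1))

  for (d in domains) {
    dom_items <- items$item[items$domain == d]
    marker <- dom_items[1]
    for (w in waves) {
      fac <- paste0(factor_prefix, d, "_w", w)
      for (it in dom_items) {
        ov <- paste0(it, "_w", w)
        obs <- c(obs, ov)
        # loading
        if (it == marker) {
          paths[[length(paths) + 1]] <- path_row(fac, ov, value = 1)
        } else if (invariance == "configural") {
          paths[[length(paths) + 1]] <- path_row(fac, ov,
                                                 label = paste0("lam_", it, "_w", w))
        } else {
          paths[[length(paths) + 1]] <- path_row(fac, ov, label = paste0("lam_", it))
        }
        # intercept
        if (it == marker) {
          means[[length(means) + 1]] <- mean_row(ov, value = 0)
        } else if (invariance %in% c("configural", "weak")) {
          means[[length(means) + 1]] <- mean_row(ov, label = paste0("tau_", it, "_w", w))
        } else if (invariance == "partial" && paste0(it, "_w", w) %in% freed_key) {
          means[[length(means) + 1]] <- mean_row(ov, label = paste0("tau_", it, "_w", w))
        } else {
          means[[length(means) + 1]] <- mean_row(ov, label = paste0("tau_", it))
        }
        # residual variance
        if (invariance == "strict") {
          covs[[length(covs) + 1]] <- cov_row(ov, ov, label = paste0("eps_", it))
        } else {
          covs[[length(covs) + 1]] <- cov_row(ov, ov, label = paste0("eps_", it, "_w", w))
        }
      }
    }
    # indicator-specific residual covariances across waves
    if (resid_cov != "none") {
      for (it in dom_items) {
        wp <- utils::combn(seq_along(waves), 2)
        for (j in seq_len(ncol(wp))) {
          w1 <- waves[wp[1, j]]; w2 <- waves[wp[2, j]]
          if (resid_cov == "lag1" && wp[2, j] - wp[1, j] != 1) next
          lab <- if (resid_cov == "equal") paste0("epsc_", it)
                 else paste0("epsc_", it, "_w", w1, "_w", w2)
          covs[[length(covs) + 1]] <- cov_row(paste0(it, "_w", w1),
                                              paste0(it, "_w", w2), label = lab)
        }
      }
    }
  }
  list(observed = unique(obs),
       paths = dplyr::bind_rows(paths), covs = dplyr::bind_rows(covs),
       means = dplyr::bind_rows(means))
}

# Latent-change-score chains over `bases` (variable base names; the wave-w
# realisation is "<base>_w<w>"). For each base: unit-fixed autoregression
# between successive waves, a change factor d_<base>_w<w> with unit-fixed
# loading, free change mean and variance per interval, self-feedback phi
# per interval, and (optionally) coupling gamma from every other base's
# previous level. Residual variance of each chain variable at waves >= 2
# is fixed to 0 so all residual variance is carried by the change factor.
chain_block <- function(bases, waves, coupling = FALSE,
                        change_cov = c("none", "all"),
                        t1_cov = TRUE) {
  change_cov <- match.arg(change_cov)
  paths <- list(); covs <- list(); means <- list()
  latents <- character()
  dvars <- character()
  W <- length(waves)
  for (b in bases) {
    # T1 moments
    head <- paste0(b, "_w", waves[1])
    means[[length(means) + 1]] <- mean_row(head, label = paste0("mu1_", b))
    covs[[length(covs) + 1]] <- cov_row(head, head, label = paste0("psi1_", b))
    for (k in 2:W) {
      w <- waves[k]; wprev <- waves[k - 1]
      cur <- paste0(b, "_w", w); prev <- paste0(b, "_w", wprev)
      dv <- paste0("d_", b, "_w", w)
      latents <- c(latents, dv)
      dvars <- c(dvars, dv)
      paths[[length(paths) + 1]] <- path_row(prev, cur, value = 1)
      paths[[length(paths) + 1]] <- path_row(dv, cur, value = 1)
      covs[[length(covs) + 1]] <- cov_row(cur, cur, value = 0)  # all residual variance on d
      means[[length(means) + 1]] <- mean_row(dv, label = paste0("alpha_", b, "_w", w))
      covs[[length(covs) + 1]] <- cov_row(dv, dv, label = paste0("zeta_", b, "_w", w))
      paths[[length(paths) + 1]] <- path_row(prev, dv, label = paste0("phi_", b, "_w", w))
      if (coupling) {
        for (src in setdiff(bases, b)) {
          paths[[length(paths) + 1]] <- path_row(
            paste0(src, "_w", wprev), dv,
            label = paste0("gamma_", src, "_", b, "_w", w))
        }
      }
    }
  }
  if (t1_cov && length(bases) > 1) {
    pr <- utils::combn(bases, 2)
    for (j in seq_len(ncol(pr))) {
      covs[[length(covs) + 1]] <- cov_row(
        paste0(pr[1, j], "_w", waves[1]), paste0(pr[2, j], "_w", waves[1]),
        label = paste0("psi1_", pr[1, j], "_", pr[2, j]))
    }
  }
  if (change_cov == "all" && length(dvars) > 1) {
    pr <- utils::combn(dvars, 2)
    for (j in seq_len(ncol(pr))) {
      covs[[length(covs) + 1]] <- cov_row(
        pr[1, j], pr[2, j],
        label = paste0("zcov_", sub("^d_", "", pr[1, j]), "_", sub("^d_", "", pr[2, j])))
    }
  }
  list(latents = latents, change_factors = dvars,
       paths = dplyr::bind_rows(paths), covs = dplyr::bind_rows(covs),
       means = dplyr::bind_rows(means))
}

covariate_block <- function(name, targets, slope_prefix = "b_") {
  list(
    observed = name,
    paths = dplyr::bind_rows(lapply(targets, function(tg)
      path_row(name, tg, label = paste0(slope_prefix, name, "_", tg)))),
    covs = cov_row(name, name, label = paste0("var_", name)),
    means = mean_row(name, label = paste0("mu_", name))
  )
}

assemble_spec <- function(observed, latents, blocks, meta) {
  variables <- tibble::tibble(
    name = c(observed, latents),
    latent = c(rep(FALSE, length(observed)), rep(TRUE, length(latents)))
  )
  new_model_spec(
    variables = variables,
    paths = dplyr::bind_rows(lapply(blocks, `[[`, "paths")),
    covs = dplyr::bind_rows(lapply(blocks, `[[`, "covs")),
    means = dplyr::bind_rows(lapply(blocks, `[[`, "means")),
    meta = meta
  )
}

# ---------------------------------------------------------------------------
# Builders -------------------------------------------------------------------

#' Common-cause model with a higher-order p factor
#'
#' Builds the common-cause specification for a multi-domain item design:
#' four (or more) correlated first-order factors per wave, a
#' second-order p factor per wave, and a univariate latent-change-score
#' chain on p. Change means, variances and self-feedback are free per
#' interval; change-score covariances are fixed to zero unless the
#' `free-change-covariances` variant is applied. Measurement is strongly
#' invariant by default (equal loadings and intercepts over waves,
#' residual variances free per wave) with indicator-specific residual
#' covariances across all wave pairs.
#'
#' @param design An [measurement_design()] with at least 2 waves and
#'   items in at least 2 domains.
#' @param variant Character vector of variant tags; see Details.
#' @param freed_intercepts For the `partial` invariance level, a list of
#'   `list(item =, wave =)` pairs whose intercept equality is released.
#' @param resid_cov Scope of the indicator-specific residual
#'   covariances: `"all-pairs"` (default), `"equal"`, `"lag1"`, `"none"`.
#'
#' @details Supported variant tags: `preregistered` (no-op),
#'   `free-change-covariances`, `fixed-change-covariances`,
#'   `age-on-change`, `age-on-change-free`, `gender-baseline-covariate`,
#'   and one invariance level among `configural`, `weak`, `strong`,
#'   `strict`, `partial`. Variant application is idempotent.
#'
#' @return An `lcs_spec`.
#' @export
build_common_cause_pfactor <- function(design, variant = "preregistered",
                                       freed_intercepts = list(),
                                       resid_cov = "all-pairs") {
  v <- parse_variants(variant, freed_intercepts)
  if (length(design$waves) < 2) stop("unsupported-design: need >= 2 waves", call. = FALSE)
  domains <- unique(design$items$domain)
  if (length(domains) < 2) {
    stop("invalid-design: p-factor model needs >= 2 first-order domains; ",
         "use build_common_cause_depression for a single construct", call. = FALSE)
  }
  waves <- design$waves
  mb <- measurement_block(design$items, waves, v$invariance, v$freed_intercepts,
                          resid_cov = resid_cov)
  # second-order layer: first-order factors load on p at each wave
  marker_dom <- domains[1]
  so <- list(paths = list(), covs = list(), means = list())
  first_order <- character()
  for (w in waves) {
    pfac <- paste0("f_p_w", w)
    for (d in domains) {
      fac <- paste0("f_", d, "_w", w)
      first_order <- c(first_order, fac)
      if (d == marker_dom) {
        so$paths[[length(so$paths) + 1]] <- path_row(pfac, fac, value = 1)
        so$means[[length(so$means) + 1]] <- mean_row(fac, value = 0)
      } else {
        so$paths[[length(so$paths) + 1]] <- path_row(pfac, fac, label = paste0("lam2_", d))
        so$means[[length(so$means) + 1]] <- mean_row(fac, label = paste0("tau2_", d))
      }
      so$covs[[length(so$covs) + 1]] <- cov_row(fac, fac, label = paste0("dist_", d, "_w", w))
    }
  }
  so <- lapply(so, dplyr::bind_rows)
  cb <- chain_block("f_p", waves, coupling = FALSE,
                    change_cov = if (v$change_cov == "free") "all" else "none")
  blocks <- list(mb, so, cb)
  latents <- c(first_order, paste0("f_p_w", waves), cb$change_factors)
  observed <- mb$observed
  if (v$gender) {
    gb <- covariate_block("gender", paste0("f_p_w", waves[1]))
    blocks <- c(blocks, list(gb)); observed <- c(observed, "gender")
  }
  assemble_spec(observed, latents, blocks, meta = list(
    model = design_model_name(design, "cc"),
    builder = "build_common_cause_pfactor",
    design = design, variants = v$tags, freed_intercepts = v$freed_intercepts,
    resid_cov = resid_cov
  ))
}

#' Dynamic-mutualism model with coupled domain chains
#'
#' Builds the mutualism specification for a multi-domain item design:
#' correlated first-order factors per wave (no second-order factor), one
#' latent-change-score chain per domain, self-feedback per (domain,
#' interval), coupling from every other domain's previous level per
#' (ordered pair, interval), and all pairwise covariances among all
#' change factors free.
#'
#' @inheritParams build_common_cause_pfactor
#' @return An `lcs_spec`.
#' @export
build_mutualism_multivariate <- function(design, variant = "preregistered",
                                         freed_intercepts = list(),
                                         resid_cov = "all-pairs") {
  v <- parse_variants(variant, freed_intercepts)
  if (length(design$waves) < 2) stop("unsupported-design: need >= 2 waves", call. = FALSE)
  domains <- unique(design$items$domain)
  if (length(domains) < 2) {
    stop("invalid-design: mutualism needs >= 2 domains; use the common-cause builder",
         call. = FALSE)
  }
  waves <- design$waves
  mb <- measurement_block(design$items, waves, v$invariance, v$freed_intercepts,
                          resid_cov = resid_cov)
  bases <- paste0("f_", domains)
  cb <- chain_block(bases, waves, coupling = TRUE,
                    change_cov = if (v$change_cov == "fixed") "none" else "all")
  blocks <- list(mb, cb)
  observed <- mb$observed
  latents <- c(as.vector(outer(bases, waves, function(b, w) paste0(b, "_w", w))),
               cb$change_factors)
  if (v$gender) {
    gb <- covariate_block("gender", paste0(bases, "_w", waves[1]))
    blocks <- c(blocks, list(gb)); observed <- c(observed, "gender")
  }
  assemble_spec(observed, latents, blocks, meta = list(
    model = design_model_name(design, "mut"),
    builder = "build_mutualism_multivariate",
    design = design, variants = v$tags, freed_intercepts = v$freed_intercepts,
    resid_cov = resid_cov
  ))
}

#' Common-cause model for a single construct measured by parcels
#'
#' Builds the one-factor common-cause specification: a depression (or
#' other single-construct) factor per wave measured by the design's
#' parcels (or by its items when no parcel map is present), a univariate
#' latent-change-score chain, and baseline age as an exogenous covariate
#' regressed onto the wave-1 factor when the design carries an `age`
#' covariate. The indicator-specific residual covariance of each parcel
#' is equality-constrained across all wave pairs by default.
#'
#' @inheritParams build_common_cause_pfactor
#' @param resid_cov Scope of the indicator-specific residual covariances;
#'   defaults to `"equal"` (one parameter per indicator shared across
#'   wave pairs).
#' @return An `lcs_spec`.
#' @export
build_common_cause_depression <- function(design, variant = "preregistered",
                                          freed_intercepts = list(),
                                          resid_cov = "equal") {
  v <- parse_variants(variant, freed_intercepts)
  if (length(design$waves) < 2) stop("unsupported-design: need >= 2 waves", call. = FALSE)
  indicators <- share_indicators(design)
  if (length(indicators) < 2) {
    stop("invalid-design: need >= 2 indicators per wave", call. = FALSE)
  }
  waves <- design$waves
  ind_items <- tibble::tibble(item = indicators, domain = "dep")
  mb <- measurement_block(ind_items, waves, v$invariance, v$freed_intercepts,
                          resid_cov = resid_cov)
  cb <- chain_block("f_dep", waves, coupling = FALSE,
                    change_cov = if (v$change_cov == "free") "all" else "none")
  blocks <- list(mb, cb)
  observed <- mb$observed
  latents <- c(paste0("f_dep_w", waves), cb$change_factors)
  has_age <- "age" %in% design$covariates
  if (!has_age && v$age_on_change != "none") {
    stop("invalid-design: age-on-change requested but the design has no age covariate",
         call. = FALSE)
  }
  if (has_age) {
    ab <- covariate_block("age", paste0("f_dep_w", waves[1]))
    # for the univariate chain both readings free one slope per change factor
    if (v$age_on_change != "none") {
      extra <- dplyr::bind_rows(lapply(cb$change_factors, function(dv)
        path_row("age", dv, label = paste0("b_age_", dv))))
      ab$paths <- dplyr::bind_rows(ab$paths, extra)
    }
    blocks <- c(blocks, list(ab)); observed <- c(observed, "age")
  }
  if (v$gender) {
    gb <- covariate_block("gender", paste0("f_dep_w", waves[1]))
    blocks <- c(blocks, list(gb)); observed <- c(observed, "gender")
  }
  assemble_spec(observed, latents, blocks, meta = list(
    model = design_model_name(design, "cc"),
    builder = "build_common_cause_depression",
    design = design, variants = v$tags, freed_intercepts = v$freed_intercepts,
    resid_cov = resid_cov
  ))
}

# Note: for the univariate chain the published age-on-change step frees
# one slope per change factor (df 4 over 5 waves), while the bivariate
# step adds two (one per domain, equal across intervals, df 2). Both
# readings are exposed on each builder; reports flag which was used.

#' Bivariate dynamic-mutualism model on parcel scores
#'
#' Builds the coupled bivariate latent-change-score specification in
#' which the two parcel series are modeled directly as construct scores
#' (no measurement layer): per interval, self-feedback for each parcel
#' and coupling from the other parcel's previous level; all pairwise
#' covariances among the change factors free; baseline age regressed
#' onto both wave-1 scores when present. The `age-on-change` variant
#' adds one age slope per domain, equality-constrained across intervals
#' (two parameters); `age-on-change-free` frees one slope per change
#' factor.
#'
#' @inheritParams build_common_cause_pfactor
#' @return An `lcs_spec`.
#' @export
build_mutualism_bivariate <- function(design, variant = "preregistered",
                                      freed_intercepts = list()) {
  v <- parse_variants(variant, freed_intercepts)
  if (length(design$waves) < 2) stop("unsupported-design: need >= 2 waves", call. = FALSE)
  indicators <- share_indicators(design)
  if (length(indicators) != 2) {
    stop("unsupported-design: the bivariate builder needs exactly 2 parcel series",
         call. = FALSE)
  }
  waves <- design$waves
  cb <- chain_block(indicators, waves, coupling = TRUE,
                    change_cov = if (v$change_cov == "fixed") "none" else "all")
  blocks <- list(cb)
  observed <- unlist(lapply(waves, function(w) paste0(indicators, "_w", w)))
  latents <- cb$change_factors
  has_age <- "age" %in% design$covariates
  if (!has_age && v$age_on_change != "none") {
    stop("invalid-design: age-on-change requested but the design has no age covariate",
         call. = FALSE)
  }
  if (has_age) {
    ab <- covariate_block("age", paste0(indicators, "_w", waves[1]))
    if (v$age_on_change == "constrained") {
      extra <- dplyr::bind_rows(lapply(cb$change_factors, function(dv) {
        base <- sub("_w[0-9]+$", "", sub("^d_", "", dv))
        path_row("age", dv, label = paste0("b_age_d_", base))
      }))
      ab$paths <- dplyr::bind_rows(ab$paths, extra)
    } else if (v$age_on_change == "free") {
      extra <- dplyr::bind_rows(lapply(cb$change_factors, function(dv)
        path_row("age", dv, label = paste0("b_age_", dv))))
      ab$paths <- dplyr::bind_rows(ab$paths, extra)
    }
    blocks <- c(blocks, list(ab)); observed <- c(observed, "age")
  }
  if (v$gender) {
    gb <- covariate_block("gender", paste0(indicators, "_w", waves[1]))
    blocks <- c(blocks, list(gb)); observed <- c(observed, "gender")
  }
  assemble_spec(observed, latents, blocks, meta = list(
    model = design_model_name(design, "mut"),
    builder = "build_mutualism_bivariate",
    design = design, variants = v$tags, freed_intercepts = v$freed_intercepts
  ))
}

share_indicators <- function(design) {
  if (!is.null(design$parcel_map)) names(design$parcel_map) else design$items$item
}

design_model_name <- function(design, kind) {
  n <- nrow(design$items)
  if (n == 42 && length(design$waves) == 4) paste0("zproso_", kind)
  else if (!is.null(design$parcel_map) && length(design$parcel_map) == 2 &&
           length(design$waves) == 5) paste0("share_", kind)
  else paste0("custom_", kind)
}

#' Build a preset model by name
#'
#' Dispatches the four study models: `zproso_cc` (higher-order p-factor
#' common cause), `zproso_mut` (four-domain mutualism), `share_cc`
#' (one-factor depression common cause with age covariate), `share_mut`
#' (bivariate parcel mutualism with age covariate).
#'
#' @param preset One of `"zproso_cc"`, `"zproso_mut"`, `"share_cc"`,
#'   `"share_mut"`.
#' @param variant Character vector of variant tags.
#' @param ... Passed to the underlying builder.
#' @return An `lcs_spec`.
#' @examples
#' spec <- lcs_model("share_mut")
#' count_free_parameters(spec)
#' @export
lcs_model <- function(preset = c("zproso_cc", "zproso_mut", "share_cc", "share_mut"),
                      variant = "preregistered", ...) {
  preset <- match.arg(preset)
  switch(preset,
    zproso_cc = build_common_cause_pfactor(design_zproso(), variant, ...),
    zproso_mut = build_mutualism_multivariate(design_zproso(), variant, ...),
    share_cc = build_common_cause_depression(design_share(), variant, ...),
    share_mut = build_mutualism_bivariate(design_share(), variant, ...)
  )
}

#' Re-apply or change variants on a built specification
#'
#' Rebuilds the specification from its stored design with the merged
#' variant set, so applying a tag twice is a no-op and freeing then
#' re-fixing the change-score covariances restores the original
#' free-parameter count.
#'
#' @param spec An `lcs_spec` produced by one of the builders.
#' @param variant Tags to add (or replace; see `replace`).
#' @param replace When `TRUE`, `variant` replaces the stored tags
#'   instead of being merged with them.
#' @return An `lcs_spec`.
#' @export
apply_variant <- function(spec, variant, replace = FALSE) {
  meta <- spec$meta
  if (is.null(meta$builder)) stop("spec has no stored builder; rebuild manually",
                                  call. = FALSE)
  tags <- if (replace) variant else unique(c(meta$variants, variant))
  # adding "fixed" removes a previous "free" and vice versa
  if ("fixed-change-covariances" %in% variant) {
    tags <- setdiff(tags, "free-change-covariances")
  }
  if ("free-change-covariances" %in% variant) {
    tags <- setdiff(tags, "fixed-change-covariances")
  }
  lev <- intersect(variant, c("configural", "weak", "strong", "strict", "partial"))
  if (length(lev)) {
    tags <- setdiff(tags, setdiff(c("configural", "weak", "strong", "strict", "partial"), lev))
  }
  args <- list(meta$design, variant = if (length(tags)) tags else "preregistered",
               freed_intercepts = meta$freed_intercepts %||% list())
  if (!is.null(meta$resid_cov) &&
      meta$builder != "build_mutualism_bivariate") {
    args$resid_cov <- meta$resid_cov
  }
  do.call(meta$builder, args)
}
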