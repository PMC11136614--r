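# Information-criterion arbitration: AIC/BIC, Akaike and Schwarz weights,
# and likelihood-ratio tests for nested pairs.

#' Information criteria from a log-likelihood
#'
#' `AIC = -2 ll + 2k`, `BIC = -2 ll + k log N`, with `k` the number of
#' free parameters after equality merging and `N` the rows used in the
#' likelihood.
#'
#' @param loglik Log-likelihood at the optimum.
#' @param k Free-parameter count.
#' @param n Sample size.
#' @return A list with `aic` and `bic`.
#' @export
information_criteria <- function(loglik, k, n) {
  stopifnot(n >= 1, k >= 0)
  list(aic = -2 * loglik + 2 * k, bic = -2 * loglik + k * log(n))
}

#' Akaike (or Schwarz) weights from criterion values
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = IC_i - min(IC)`. Computed on the differences so very large
#' criterion values stay numerically safe. Applied to AIC values these
#' are Akaike weights; applied to BIC values, Schwarz weights. A weight
#' is read as the conditional probability that the model is the best of
#' the compared set.
#'
#' @param ic Numeric vector of criterion values (at least 2, all finite).
#' @return Numeric vector of weights summing to 1, named like `ic`.
#' @examples
#' akaike_weights(c(cc = 504085.954, mut = 499782.029))
#' @export
akaike_weights <- function(ic) {
  if (length(ic) < 2 || !all(is.finite(ic))) {
    stop("akaike_weights needs >= 2 finite criterion values", call. = FALSE)
  }
  d <- ic - min(ic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Likelihood-ratio test of two nested fitted models
#'
#' Verifies nesting by label-set inclusion (the restricted model's free
#' labels, net of variant-specific additions, must not exceed the full
#' model's), then computes `Delta chi2 = 2 (ll_full - ll_restricted)`,
#' `Delta df = k_full - k_restricted`, and a central chi-square p-value.
#'
#' @param fit_restricted,fit_full `lcs_fit` objects fitted to the same
#'   data.
#' @param check_nesting Set `FALSE` to skip the label-inclusion check
#'   (for reparameterized but analytically nested pairs).
#' @return A one-row tibble: `delta_chisq`, `delta_df`, `p.value`.
#' @export
lrt <- function(fit_restricted, fit_full, check_nesting = TRUE) {
  if (fit_restricted$N != fit_full$N) {
    stop("models were fitted to different numbers of rows", call. = FALSE)
  }
  k_r <- fit_restricted$n_free; k_f <- fit_full$n_free
  if (check_nesting) {
    lr <- free_labels(fit_restricted$spec); lf <- free_labels(fit_full$spec)
    if (!all(lr %in% lf)) {
      stop("models are not nested by label-set inclusion", call. = FALSE)
    }
  }
  dchi <- 2 * (fit_full$loglik - fit_restricted$loglik)
  if (dchi < -1e-6 * max(1, abs(fit_full$loglik))) {
    stop("refit-required: restricted model attained a higher likelihood ",
         "than the full model (a local optimum)", call. = FALSE)
  }
  dchi <- max(dchi, 0)
  ddf <- k_f - k_r
  tibble::tibble(
    delta_chisq = dchi, delta_df = ddf,
    p.value = if (ddf > 0) stats::pchisq(dchi, ddf, lower.tail = FALSE)
              else if (dchi == 0) 1 else NA_real_
  )
}

#' Compare fitted models on fit indices, information criteria and weights
#'
#' Assembles the head-to-head comparison table: per model the chi-square
#' test, RMSEA with 90% CI, CFI, SRMR, AIC, BIC, and the Akaike and
#' Schwarz weights over the compared set.
#'
#' @param ... Named `lcs_fit` objects (or a single named list of them).
#' @return A tibble of class `lcs_comparison`, one row per model.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(config_share(n = 300, waves = 3), seed = 7)
#' f1 <- fit_lcs(cohort$data, build_common_cause_depression(cohort$design))
#' f2 <- fit_lcs(cohort$data, build_mutualism_bivariate(cohort$design))
#' compare_models(common_cause = f1, mutualism = f2)
#' }
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !inherits(fits[[1]], "lcs_fit")) {
    fits <- fits[[1]]
  }
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$spec$meta$model %||% "model",
                          character(1))
  }
  tab <- dplyr::bind_rows(lapply(fits, glance))
  tab$model <- names(fits)
  tab$rmsea.ci.lower <- vapply(fits, function(f) f$indices$rmsea.ci.lower, 0)
  tab$rmsea.ci.upper <- vapply(fits, function(f) f$indices$rmsea.ci.upper, 0)
  tab$akaike_weight <- akaike_weights(tab$aic)
  tab$schwarz_weight <- akaike_weights(tab$bic)
  tab <- tab[, c("model", "chisq", "df", "p.value", "rmsea",
                 "rmsea.ci.lower", "rmsea.ci.upper", "cfi", "srmr",
                 "aic", "bic", "akaike_weight", "schwarz_weight",
                 "logLik", "n_free", "N", "converged")]
  class(tab) <- c("lcs_comparison", class(tab))
  tab
}

#' Render a comparison table as markdown
#'
#' Columns follow the order chi-square, df, RMSEA \[CI\], CFI, SRMR, AIC,
#' BIC, plus the normalized weight block.
#'
#' @param tab An `lcs_comparison`.
#' @param digits Rounding for display.
#' @return A character vector of markdown lines.
#' @export
comparison_markdown <- function(tab, digits = 3) {
  f <- function(x, d = digits) formatC(x, digits = d, format = "f", big.mark = ",")
  lines <- c(
    "| Model | chi2 | df | RMSEA [90% CI] | CFI | SRMR | AIC | BIC | Akaike w | Schwarz w |",
    "|---|---|---|---|---|---|---|---|---|---|",
    vapply(seq_len(nrow(tab)), function(i) {
      paste0("| ", tab$model[i], " | ", f(tab$chisq[i]), " | ", tab$df[i], " | ",
             f(tab$rmsea[i]), " [", f(tab$rmsea.ci.lower[i]), ", ",
             f(tab$rmsea.ci.upper[i]), "] | ", f(tab$cfi[i]), " | ",
             f(tab$srmr[i]), " | ", f(tab$aic[i]), " | ", f(tab$bic[i]), " | ",
             f(tab$akaike_weight[i], 4), " | ", f(tab$schwarz_weight[i], 4), " |")
    }, character(1))
  )
  lines
}

#' Plot normalized model probabilities
#'
#' Bar chart of Akaike and Schwarz weights per model — the normalized
#' probability that each model is the best of the compared set.
#'
#' @param object An `lcs_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lcs_comparison
#' @export
autoplot.lcs_comparison <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object[, c("model", "akaike_weight", "schwarz_weight")],
    cols = c("akaike_weight", "schwarz_weight"),
    names_to = "criterion", values_to = "weight")
  d$criterion <- ifelse(d$criterion == "akaike_weight",
                        "Akaike weight (AIC)", "Schwarz weight (BIC)")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$model, y = .data$weight,
                                  fill = .data$model)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~criterion) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "Normalized probability") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
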