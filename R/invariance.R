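# Longitudinal measurement invariance: the configural -> weak -> strong
# -> strict sequence with the delta-CFI decision rule, and the sequential
# partial-invariance search that frees intercepts one at a time.

#' Longitudinal measurement-invariance sequence
#'
#' Fits the same model at the four constraint levels (configural: free
#' loadings and intercepts per wave; weak: equal loadings; strong: plus
#' equal intercepts; strict: plus equal residual variances), computes
#' `delta CFI = CFI(previous) - CFI(current)` at each step, and flags a
#' violation when the drop strictly exceeds the cutoff — so a drop of
#' exactly .010 passes under the default cutoff.
#'
#' @param data Wide panel data.
#' @param spec A built `lcs_spec` whose stored builder supports
#'   invariance levels (any of the measurement-layer builders).
#' @param cutoff Strict decision cutoff on the CFI drop (default .01).
#' @param levels Constraint levels to fit, in order.
#' @param ... Passed to [fit_lcs()].
#' @return An object of class `lcs_invariance`: a tibble with one row
#'   per step (`level`, `cfi`, `delta_cfi`, `violated`, `converged`,
#'   fit statistics) carrying the fitted objects as an attribute.
#' @export
invariance_sequence <- function(data, spec, cutoff = 0.01,
                                levels = c("configural", "weak", "strong", "strict"),
                                ...) {
  fits <- list()
  rows <- list()
  prev_cfi <- NA_real_
  for (lev in levels) {
    sp <- apply_variant(spec, lev)
    ft <- tryCatch(fit_lcs(data, sp, ...), error = function(e) e)
    if (inherits(ft, "error")) {
      rows[[lev]] <- tibble::tibble(
        level = lev, chisq = NA_real_, df = NA_real_, cfi = NA_real_,
        delta_cfi = NA_real_, violated = NA, converged = FALSE,
        note = conditionMessage(ft))
      next
    }
    fits[[lev]] <- ft
    dcfi <- if (is.na(prev_cfi)) NA_real_ else prev_cfi - ft$indices$cfi
    rows[[lev]] <- tibble::tibble(
      level = lev, chisq = ft$chisq, df = ft$df, cfi = ft$indices$cfi,
      delta_cfi = dcfi,
      violated = if (is.na(dcfi)) FALSE else dcfi > cutoff,
      converged = ft$convergence$converged, note = NA_character_)
    if (ft$convergence$converged) prev_cfi <- ft$indices$cfi
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "fits") <- fits
  attr(out, "cutoff") <- cutoff
  class(out) <- c("lcs_invariance", class(out))
  out
}

#' Sequential partial-invariance search over intercepts
#'
#' Starting from the strong (equal-intercept) model, repeatedly releases
#' the single intercept equality whose release most improves the fit
#' (selected by exhaustive one-at-a-time refitting, the largest
#' chi-square drop), until the CFI drop of the partially constrained
#' model relative to the weak (equal-loadings) model no longer exceeds
#' the cutoff. Marker intercepts stay fixed.
#'
#' @param data Wide panel data.
#' @param spec A built `lcs_spec` with a measurement layer.
#' @param cutoff Strict delta-CFI cutoff (default .01).
#' @param max_free Safety cap on the number of released intercepts.
#' @param ... Passed to [fit_lcs()].
#' @return A list of class `lcs_partial_invariance`: `spec` (the
#'   partially invariant specification), `trail` (tibble of freed
#'   intercepts in release order with fit improvement), `achieved`
#'   (logical), `exhausted` (logical).
#' @export
partial_invariance_search <- function(data, spec, cutoff = 0.01,
                                      max_free = Inf, ...) {
  weak <- fit_lcs(data, apply_variant(spec, "weak"), ...)
  design <- spec$meta$design
  waves <- design$waves
  # candidate intercepts: non-marker items at waves >= 2 (wave-1 intercept
  # retains the shared label so the release is identified)
  if (spec$meta$builder == "build_common_cause_depression") {
    items <- share_indicators(design)
    markers <- items[1]
  } else {
    items <- design$items$item
    markers <- vapply(split(design$items$item, design$items$domain),
                      `[`, character(1), 1)
  }
  candidates <- expand.grid(item = setdiff(items, markers), wave = waves[-1],
                            stringsAsFactors = FALSE)
  freed <- list()
  trail <- list()
  achieved <- FALSE; exhausted <- FALSE
  current <- fit_lcs(data, apply_variant(spec, "strong"), ...)
  repeat {
    dcfi <- weak$indices$cfi - current$indices$cfi
    if (dcfi <= cutoff) { achieved <- TRUE; break }
    if (nrow(candidates) == 0 || length(freed) >= max_free) {
      exhausted <- TRUE; break
    }
    # exhaustive one-at-a-time refits; pick the largest chi-square drop
    drops <- rep(NA_real_, nrow(candidates))
    cand_fits <- vector("list", nrow(candidates))
    for (i in seq_len(nrow(candidates))) {
      fi <- c(freed, list(list(item = candidates$item[i],
                               wave = candidates$wave[i])))
      sp_i <- rebuild_partial(spec, fi)
      ft <- tryCatch(fit_lcs(data, sp_i, ...), error = function(e) NULL)
      if (!is.null(ft)) { drops[i] <- current$chisq - ft$chisq; cand_fits[[i]] <- ft }
    }
    if (all(is.na(drops))) { exhausted <- TRUE; break }
    best <- which.max(drops)
    freed <- c(freed, list(list(item = candidates$item[best],
                                wave = candidates$wave[best])))
    trail[[length(trail) + 1]] <- tibble::tibble(
      item = candidates$item[best], wave = candidates$wave[best],
      chisq_drop = drops[best], cfi_after = cand_fits[[best]]$indices$cfi)
    current <- cand_fits[[best]]
    candidates <- candidates[-best, , drop = FALSE]
  }
  structure(list(
    spec = if (length(freed)) rebuild_partial(spec, freed)
           else apply_variant(spec, "strong"),
    fit = current,
    trail = if (length(trail)) dplyr::bind_rows(trail) else
      tibble::tibble(item = character(), wave = integer(),
                     chisq_drop = double(), cfi_after = double()),
    achieved = achieved, exhausted = exhausted,
    weak_cfi = weak$indices$cfi
  ), class = "lcs_partial_invariance")
}

rebuild_partial <- function(spec, freed) {
  meta <- spec$meta
  tags <- unique(c(setdiff(meta$variants,
                           c("configural", "weak", "strong", "strict", "partial")),
                   "partial"))
  args <- list(meta$design, variant = tags, freed_intercepts = freed)
  if (!is.null(meta$resid_cov) && meta$builder != "build_mutualism_bivariate") {
    args$resid_cov <- meta$resid_cov
  }
  do.call(meta$builder, args)
}

#' @export
print.lcs_invariance <- function(x, ...) {
  cat("<lcs_invariance> cutoff", attr(x, "cutoff"), "\n")
  print(tibble::as_tibble(x))
  invisible(x)
}

#' Serialize an invariance report to JSON
#' @param report An `lcs_invariance`.
#' @param path Optional output file.
#' @return The JSON string, invisibly when written to a file.
#' @export
invariance_to_json <- function(report, path = NULL) {
  json <- jsonlite::toJSON(list(cutoff = attr(report, "cutoff"),
                                steps = tibble::as_tibble(report)),
                           dataframe = "columns", auto_unbox = TRUE,
                           digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
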