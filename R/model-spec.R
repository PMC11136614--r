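#' @importFrom dplyr %>% mutate filter select bind_rows distinct arrange group_by summarise ungroup n left_join
#' @importFrom rlang .data
NULL

# A model specification is a declarative matrix-form SEM description:
#   variables: tibble(name, latent)
#   paths:     tibble(from, to, label, value, free)   directed effects
#   covs:      tibble(v1, v2, label, value, free)     (co)variances, v1 == v2 for variances
#   means:     tibble(var, label, value, free)        intercepts / means
# Free entries carry a label; entries sharing a label are constrained
# equal. Fixed entries carry the fixed value and label NA.
new_model_spec <- function(variables, paths, covs, means, meta = list()) {
  spec <- structure(
    list(variables = variables, paths = paths, covs = covs, means = means,
         meta = meta),
    class = "lcs_spec"
  )
  validate_model_spec(spec)
}

validate_model_spec <- function(spec) {
  vars <- spec$variables$name
  stopifnot(!anyDuplicated(vars))
  ref <- unique(c(spec$paths$from, spec$paths$to, spec$covs$v1, spec$covs$v2,
                  spec$means$var))
  if (!all(ref %in% vars)) {
    stop("invalid-spec: entries reference unknown variables: ",
         paste(setdiff(ref, vars), collapse = ", "), call. = FALSE)
  }
  bad <- (spec$paths$free & is.na(spec$paths$label)) |
    (!spec$paths$free & is.na(spec$paths$value))
  if (any(bad)) stop("invalid-spec: path needs a label (free) or a value (fixed)",
                     call. = FALSE)
  # canonical order of covariance pairs so duplicates are detectable
  key <- paste(pmin(spec$covs$v1, spec$covs$v2), pmax(spec$covs$v1, spec$covs$v2))
  if (anyDuplicated(key)) stop("invalid-spec: duplicated covariance entry", call. = FALSE)
  if (anyDuplicated(paste(spec$paths$from, spec$paths$to))) {
    stop("invalid-spec: duplicated path entry", call. = FALSE)
  }
  if (anyDuplicated(spec$means$var)) stop("invalid-spec: duplicated mean entry", call. = FALSE)
  spec
}

path_row <- function(from, to, label = NA_character_, value = NA_real_,
                     free = is.na(value)) {
  tibble::tibble(from = from, to = to, label = label, value = value, free = free)
}

cov_row <- function(v1, v2, label = NA_character_, value = NA_real_,
                    free = is.na(value)) {
  tibble::tibble(v1 = v1, v2 = v2, label = label, value = value, free = free)
}

mean_row <- function(var, label = NA_character_, value = NA_real_,
                     free = is.na(value)) {
  tibble::tibble(var = var, label = label, value = value, free = free)
}

#' Observed-variable names of a model specification
#' @param spec An `lcs_spec`.
#' @return Character vector in roster order.
#' @export
observed_vars <- function(spec) {
  spec$variables$name[!spec$variables$latent]
}

#' Free parameters and model degrees of freedom
#'
#' Counts the distinct free parameter labels of a specification after
#' merging equality sets (entries sharing a label count once) and
#' derives the model degrees of freedom against the saturated mean and
#' covariance structure of `p` observed variables, which carries
#' `p(p+3)/2` moments. Negative df are returned as-is and flagged.
#'
#' @param spec An `lcs_spec`.
#' @param p Number of observed variables; defaults to the spec's own
#'   observed roster.
#' @return A tibble with columns `free`, `p`, `moments`, `df`,
#'   `identified_df` (FALSE when df < 0).
#' @export
count_free_parameters <- function(spec, p = length(observed_vars(spec))) {
  labs <- free_labels(spec)
  k <- length(labs)
  moments <- p * (p + 3) / 2
  tibble::tibble(free = k, p = p, moments = moments, df = moments - k,
                 identified_df = moments - k >= 0)
}

free_labels <- function(spec) {
  unique(stats::na.omit(c(
    spec$paths$label[spec$paths$free],
    spec$covs$label[spec$covs$free],
    spec$means$label[spec$means$free]
  )))
}

#' @export
print.lcs_spec <- function(x, ...) {
  cfp <- count_free_parameters(x)
  cat("<lcs_spec> ", x$meta$model %||% "custom",
      if (!is.null(x$meta$variants) && length(x$meta$variants))
        paste0(" [", paste(x$meta$variants, collapse = ", "), "]") else "",
      "\n", sep = "")
  cat("  variables: ", sum(!x$variables$latent), " observed + ",
      sum(x$variables$latent), " latent\n", sep = "")
  cat("  free parameters: ", cfp$free, "  df: ", cfp$df, "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a model specification to JSON (and back)
#'
#' The JSON form records the variable roster, every path, covariance and
#' mean entry with its label / fixed value, and the meta block, so a
#' specification can be audited or rebuilt outside R.
#'
#' @param spec An `lcs_spec`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `spec_to_json`: the JSON string (invisibly when written to a
#'   file). `spec_from_json`: the rebuilt `lcs_spec`.
#' @export
spec_to_json <- function(spec, path = NULL) {
  meta <- spec$meta
  if (!is.null(meta$design)) meta$design <- unclass(meta$design)
  payload <- list(
    variables = spec$variables, paths = spec$paths, covs = spec$covs,
    means = spec$means, meta = meta
  )
  json <- jsonlite::toJSON(payload, dataframe = "columns", auto_unbox = TRUE,
                           digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' @rdname spec_to_json
#' @param json A JSON string or file path produced by [spec_to_json()].
#' @export
spec_from_json <- function(json) {
  payload <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  as_tb <- function(d, chr, dbl, lgl) {
    d <- tibble::as_tibble(d)
    for (cc in chr) d[[cc]] <- as.character(d[[cc]])
    for (cc in dbl) d[[cc]] <- as.numeric(d[[cc]])
    for (cc in lgl) d[[cc]] <- as.logical(d[[cc]])
    d
  }
  meta <- payload$meta
  if (!is.null(meta$design)) {
    d <- meta$design
    meta$design <- measurement_design(
      items = tibble::as_tibble(d$items), waves = d$waves,
      scale_type = d$scale_type,
      reverse_coded = as.character(d$reverse_coded %||% character()),
      parcel_map = if (length(d$parcel_map)) lapply(d$parcel_map, as.character),
      covariates = as.character(d$covariates %||% character()))
  }
  new_model_spec(
    variables = as_tb(payload$variables, "name", character(), "latent"),
    paths = as_tb(payload$paths, c("from", "to", "label"), "value", "free"),
    covs = as_tb(payload$covs, c("v1", "v2", "label"), "value", "free"),
    means = as_tb(payload$means, c("var", "label"), "value", "free"),
    meta = meta
  )
}

#' Audit the change-score algebra of a specification
#'
#' Maps each symbol of the latent-change-score algebra to the entry
#' class that realizes it and counts the realizations: levels `y`
#' (latent or observed chain variables), change factors `delta`
#' (variables named `d_*`), the unit-fixed autoregressive paths and
#' unit-fixed change-factor loadings (`beta = 1`), self-feedback `phi`,
#' coupling `gamma`, and change residual variances `zeta`.
#'
#' @param spec An `lcs_spec`.
#' @return A tibble with columns `symbol`, `entry_class`, `count`.
#' @export
lcs_symbol_audit <- function(spec) {
  is_delta <- grepl("^d_", spec$variables$name)
  unit <- spec$paths[!spec$paths$free & !is.na(spec$paths$value) &
                       spec$paths$value == 1, , drop = FALSE]
  auto <- unit[!grepl("^d_", unit$from) & unit$to %in% chain_targets(spec), ]
  dload <- unit[grepl("^d_", unit$from), ]
  tibble::tibble(
    symbol = c("y", "delta", "beta_unit_auto", "beta_unit_loading",
               "phi", "gamma", "zeta"),
    entry_class = c("variable(level)", "variable(change factor)",
                    "path(fixed 1, level on previous level)",
                    "path(fixed 1, level on change factor)",
                    "path(free, change on own previous level)",
                    "path(free, change on other previous level)",
                    "covariance(change-factor variance)"),
    count = c(
      sum(spec$variables$name %in% chain_vars(spec)),
      sum(is_delta),
      nrow(auto),
      nrow(dload),
      sum(grepl("^phi_", spec$paths$label) & spec$paths$free, na.rm = TRUE),
      sum(grepl("^gamma_", spec$paths$label) & spec$paths$free, na.rm = TRUE),
      sum(grepl("^zeta_", spec$covs$label) & spec$covs$free & spec$covs$v1 == spec$covs$v2,
          na.rm = TRUE)
    )
  )
}

# chain variables: those receiving a unit-fixed path from a change factor,
# plus their wave-1 ancestors (sources of unit autoregressions)
chain_targets <- function(spec) {
  unit <- spec$paths[!spec$paths$free & !is.na(spec$paths$value) &
                       spec$paths$value == 1, , drop = FALSE]
  unique(unit$to[grepl("^d_", unit$from)])
}

chain_vars <- function(spec) {
  unit <- spec$paths[!spec$paths$free & !is.na(spec$paths$value) &
                       spec$paths$value == 1, , drop = FALSE]
  tg <- chain_targets(spec)
  unique(c(tg, unit$from[unit$to %in% tg & !grepl("^d_", unit$from)]))
}
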