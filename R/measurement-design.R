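#' Describe a longitudinal measurement design
#'
#' A measurement design records which items are administered, which
#' symptom domain each item indicates, the ordered assessment waves, the
#' response scale, any reverse-coded items, and (for binary symptom
#' scales) an optional parcel map that groups items into sum-score
#' parcels.
#'
#' @param items A data frame with columns `item` and `domain`, one row
#'   per item. Every item must map to exactly one domain.
#' @param waves Ordered wave labels (integer or character); at least two.
#' @param scale_type `"continuous-likert"` or `"binary-symptom"`.
#' @param reverse_coded Character vector of item ids whose scores are
#'   reversed upstream so that higher always means more pathology.
#' @param parcel_map Optional named list mapping parcel id to a character
#'   vector of member items. Parcels must be disjoint.
#' @param covariates Character vector of observed covariate columns
#'   (for example `"age"`) available alongside the items.
#'
#' @return An object of class `lcs_design`.
#' @seealso [design_zproso()], [design_share()] for the two built-in
#'   cohort-like presets.
#' @export
measurement_design <- function(items, waves,
                               scale_type = c("continuous-likert", "binary-symptom"),
                               reverse_coded = character(),
                               parcel_map = NULL,
                               covariates = character()) {
  scale_type <- match.arg(scale_type)
  items <- tibble::as_tibble(items)
  if (!all(c("item", "domain") %in% names(items))) {
    stop("invalid-design: `items` needs columns `item` and `domain`", call. = FALSE)
  }
  if (anyDuplicated(items$item)) {
    stop("invalid-design: duplicated item ids", call. = FALSE)
  }
  if (any(is.na(items$domain))) {
    stop("invalid-design: item with no domain", call. = FALSE)
  }
  if (length(waves) < 2) {
    stop("unsupported-design: at least 2 waves are required", call. = FALSE)
  }
  if (!is.null(parcel_map)) {
    members <- unlist(parcel_map, use.names = FALSE)
    if (anyDuplicated(members)) {
      stop("invalid-design: parcels must be disjoint", call. = FALSE)
    }
    if (!all(members %in% items$item)) {
      stop("invalid-design: parcel member not among items", call. = FALSE)
    }
  }
  if (!all(reverse_coded %in% items$item)) {
    stop("invalid-design: reverse-coded item not among items", call. = FALSE)
  }
  structure(
    list(
      items = items,
      waves = waves,
      scale_type = scale_type,
      reverse_coded = reverse_coded,
      parcel_map = parcel_map,
      covariates = covariates
    ),
    class = "lcs_design"
  )
}

#' @export
print.lcs_design <- function(x, ...) {
  cat("<lcs_design> ", nrow(x$items), " items, ",
      length(unique(x$items$domain)), " domains, ",
      length(x$waves), " waves (", x$scale_type, ")\n", sep = "")
  if (!is.null(x$parcel_map)) {
    cat("  parcels:", paste(sprintf("%s[%d]", names(x$parcel_map),
                                    lengths(x$parcel_map)), collapse = ", "), "\n")
  }
  if (length(x$covariates)) cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

# Per-domain item counts of the adolescent-cohort preset. The instrument
# carries 42 items measured identically at all four waves; the split
# across the four correlated domains is a package convention.
.zproso_domain_sizes <- c(int = 13, ext = 12, pro = 8, adhd = 9)

#' Adolescent-cohort measurement preset (42 Likert items, 4 domains, 4 waves)
#'
#' Emulates a z-proso-like design: 42 five-point Likert items indicating
#' four correlated domains (internalizing, externalizing/aggression,
#' reverse-coded prosociality, ADHD) measured at four waves.
#' Prosociality items are flagged reverse-coded: higher scores always
#' mean more pathology after recoding.
#'
#' @return An `lcs_design`.
#' @export
design_zproso <- function() {
  sizes <- .zproso_domain_sizes
  items <- tibble::tibble(
    item = sprintf("item%02d", seq_len(sum(sizes))),
    domain = rep(names(sizes), sizes)
  )
  measurement_design(
    items = items,
    waves = 1:4,
    scale_type = "continuous-likert",
    reverse_coded = items$item[items$domain == "pro"]
  )
}

# EURO-D symptom names and their parcel allocation: eight affective
# suffering items and four motivation items.
.eurod_parcels <- list(
  aff = c("sadness", "suicidality", "guilt", "sleeplessness",
          "irritability", "appetite", "fatigue", "tearfulness"),
  mot = c("pessimism", "interest", "concentration", "enjoyment")
)

#' Older-adult cohort measurement preset (12 binary symptoms, 2 parcels, 5 waves)
#'
#' Emulates a SHARE-like design: the 12 binary EURO-D depression symptoms
#' over five waves, aggregated into an "affective suffering" parcel
#' (8 items, range 0-8) and a "motivation" parcel (4 items, range 0-4),
#' with baseline age as an observed covariate.
#'
#' @return An `lcs_design`.
#' @export
design_share <- function() {
  items <- tibble::tibble(
    item = unlist(.eurod_parcels, use.names = FALSE),
    domain = rep(names(.eurod_parcels), lengths(.eurod_parcels))
  )
  measurement_design(
    items = items,
    waves = 1:5,
    scale_type = "binary-symptom",
    parcel_map = .eurod_parcels,
    covariates = "age"
  )
}
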