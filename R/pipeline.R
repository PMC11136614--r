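# Study-shaped orchestration: CSV input, the head-to-head model
# comparison with invariance and exploratory variants, and the
# model/parameter recovery experiments.

#' Read a wide longitudinal panel CSV
#'
#' Parses the `<item>_w<t>` header convention (blank cells are missing),
#' infers items and waves, and optionally applies the design's reverse
#' coding (Likert-like items are reflected about the scale midpoint,
#' binary items flipped).
#'
#' @param path CSV file path.
#' @param design Optional `lcs_design` to validate columns against.
#' @param apply_reverse Recode the design's reverse-coded items
#'   (default `FALSE`; simulated cohorts are already coded
#'   pathology-positive).
#' @param likert_max Scale maximum used when reflecting Likert items.
#' @return A tibble with an attached `"panel_meta"` attribute (items,
#'   waves, covariate columns).
#' @export
read_panel_csv <- function(path, design = NULL, apply_reverse = FALSE,
                           likert_max = 5) {
  raw <- utils::read.csv(path, check.names = FALSE, na.strings = c("", "NA"))
  if (anyDuplicated(colnames(raw))) {
    dup <- colnames(raw)[duplicated(colnames(raw))]
    stop("parse error: duplicated columns: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  data <- tibble::as_tibble(raw)
  m <- regmatches(colnames(data), regexec("^(.*)_w([0-9]+)$", colnames(data)))
  is_iw <- lengths(m) == 3
  items <- unique(vapply(m[is_iw], `[`, character(1), 2))
  waves <- sort(unique(as.integer(vapply(m[is_iw], `[`, character(1), 3))))
  covs <- setdiff(colnames(data)[!is_iw], "person")
  if (!is.null(design)) {
    unknown <- setdiff(items, c(design$items$item,
                                names(design$parcel_map %||% list())))
    if (length(unknown)) {
      stop("parse error: unknown items: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (apply_reverse && length(design$reverse_coded)) {
      for (it in design$reverse_coded) {
        for (w in waves) {
          cn <- paste0(it, "_w", w)
          if (!cn %in% colnames(data)) next
          data[[cn]] <- if (design$scale_type == "binary-symptom")
            1 - data[[cn]] else (likert_max + 1) - data[[cn]]
        }
      }
    }
  }
  attr(data, "panel_meta") <- list(items = items, waves = waves,
                                   covariates = covs)
  data
}

# choose the theory-model builders appropriate for a design
study_builders <- function(design) {
  parcels <- design$parcel_map
  if (!is.null(parcels) && length(parcels) == 2) {
    list(common_cause = function(variant = "preregistered", ...)
           build_common_cause_depression(design, variant, ...),
         mutualism = function(variant = "preregistered", ...)
           build_mutualism_bivariate(design, variant, ...))
  } else {
    list(common_cause = function(variant = "preregistered", ...)
           build_common_cause_pfactor(design, variant, ...),
         mutualism = function(variant = "preregistered", ...)
           build_mutualism_multivariate(design, variant, ...))
  }
}

#' Run the study-shaped analysis end to end
#'
#' Data in (CSV path or simulation config), then: optional measurement
#' invariance sequence on the common-cause model, the two preregistered
#' theory models, the comparison table with Akaike/Schwarz weights,
#' exploratory variants with likelihood-ratio tests against their
#' preregistered base, and a run log. Fully deterministic given the
#' configuration.
#'
#' @param input Either a path to a wide CSV, an `lcs_sim_config`, or an
#'   `lcs_cohort`.
#' @param design Required when `input` is a CSV path.
#' @param variants Character vector of exploratory variant tags fitted
#'   on top of each compatible preregistered model (e.g.
#'   `"free-change-covariances"`, `"age-on-change"`).
#' @param invariance Run the invariance sequence (default `FALSE`; the
#'   sequence refits the measurement model at four levels).
#' @param alpha Significance level used when annotating estimates.
#' @param beta_floor Standardized effect-size floor for flagging
#'   coupling/self-feedback estimates as substantive.
#' @param seed Seed for fitting restarts (and simulation when `input`
#'   is a config).
#' @param out_dir Optional directory; when given, JSON and markdown
#'   reports are written there.
#' @param ... Passed to [fit_lcs()].
#' @return A list of class `lcs_study`: `comparison`, `fits`,
#'   `variant_fits`, `lrt`, `invariance`, `annotated`, `log`.
#' @export
run_study <- function(input, design = NULL, variants = character(),
                      invariance = FALSE, alpha = 0.05, beta_floor = 0.10,
                      seed = 1, out_dir = NULL, ...) {
  log <- c(sprintf("lcscomp run_study | seed %d | %s", seed,
                   format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  if (inherits(input, "lcs_sim_config")) {
    cohort <- simulate_cohort(input)
    data <- cohort$data; design <- cohort$design
    log <- c(log, sprintf("input: simulated cohort (%s world, n = %d, seed %d)",
                          input$world, input$n, input$seed))
  } else if (inherits(input, "lcs_cohort")) {
    data <- input$data; design <- input$design
    log <- c(log, sprintf("input: cohort object (%s world, n = %d)",
                          input$config$world, nrow(data)))
  } else {
    if (is.null(design)) stop("reading a CSV requires `design`", call. = FALSE)
    data <- read_panel_csv(input, design)
    log <- c(log, sprintf("input: %s (%d rows)", input, nrow(data)))
  }
  builders <- study_builders(design)

  inv <- NULL
  if (invariance) {
    inv <- tryCatch(
      invariance_sequence(data, builders$common_cause(), seed = seed, ...),
      error = function(e) { log <<- c(log, paste("invariance failed:",
                                                 conditionMessage(e))); NULL })
    if (!is.null(inv)) log <- c(log, "invariance sequence: done")
  }

  fits <- list()
  for (nm in names(builders)) {
    fits[[nm]] <- tryCatch(fit_lcs(data, builders[[nm]](), seed = seed, ...),
                           error = function(e) e)
    log <- c(log, sprintf("fit %s: %s", nm,
                          if (inherits(fits[[nm]], "error"))
                            conditionMessage(fits[[nm]]) else
                            sprintf("logLik %.3f, chi2 %.3f, df %d",
                                    fits[[nm]]$loglik, fits[[nm]]$chisq,
                                    fits[[nm]]$df)))
  }
  ok <- !vapply(fits, inherits, logical(1), "error")
  comparison <- if (sum(ok) >= 2) compare_models(fits[ok]) else NULL

  variant_fits <- list(); lrt_rows <- list()
  for (vt in variants) {
    for (nm in names(builders)[ok]) {
      sp <- tryCatch(builders[[nm]](variant = vt), error = function(e) NULL)
      if (is.null(sp)) next
      key <- paste0(nm, ":", vt)
      ft <- tryCatch(fit_lcs(data, sp, seed = seed, ...), error = function(e) e)
      variant_fits[[key]] <- ft
      if (inherits(ft, "error")) {
        log <- c(log, sprintf("variant %s failed: %s", key, conditionMessage(ft)))
        next
      }
      base <- fits[[nm]]
      restricted <- if (ft$n_free >= base$n_free) base else ft
      full <- if (ft$n_free >= base$n_free) ft else base
      tl <- tryCatch(lrt(restricted, full), error = function(e) NULL)
      if (!is.null(tl)) {
        tl$comparison <- key
        lrt_rows[[key]] <- tl
      }
      log <- c(log, sprintf("variant %s: delta df %d", key,
                            abs(ft$n_free - base$n_free)))
    }
  }

  annotated <- NULL
  if (ok[["mutualism"]]) {
    est <- tidy(fits$mutualism)
    foc <- est[grepl("^(phi_|gamma_)", est$label), , drop = FALSE]
    foc$significant <- !is.na(foc$p.value) & foc$p.value < alpha
    foc$substantive <- foc$significant & !is.na(foc$beta) &
      abs(foc$beta) >= beta_floor
    annotated <- foc
  }

  out <- structure(list(
    comparison = comparison, fits = fits, variant_fits = variant_fits,
    lrt = if (length(lrt_rows)) dplyr::bind_rows(lrt_rows) else NULL,
    invariance = inv, annotated = annotated, log = log,
    seed = seed, design = design
  ), class = "lcs_study")

  if (!is.null(out_dir)) write_study_reports(out, out_dir)
  out
}

write_study_reports <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(study$comparison)) {
    writeLines(jsonlite::toJSON(study$comparison, dataframe = "columns",
                                auto_unbox = TRUE, digits = NA),
               file.path(out_dir, "comparison.json"))
    writeLines(comparison_markdown(study$comparison),
               file.path(out_dir, "comparison.md"))
  }
  for (nm in names(study$fits)) {
    if (!inherits(study$fits[[nm]], "error")) {
      fit_to_json(study$fits[[nm]], file.path(out_dir, paste0("fit_", nm, ".json")))
    }
  }
  if (!is.null(study$invariance)) {
    invariance_to_json(study$invariance, file.path(out_dir, "invariance.json"))
  }
  if (!is.null(study$lrt)) {
    writeLines(jsonlite::toJSON(study$lrt, dataframe = "columns",
                                auto_unbox = TRUE, digits = NA),
               file.path(out_dir, "lrt.json"))
  }
  writeLines(study$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.lcs_study <- function(x, ...) {
  cat("<lcs_study>\n")
  if (!is.null(x$comparison)) print(tibble::as_tibble(
    x$comparison[, c("model", "chisq", "df", "cfi", "aic", "bic",
                     "akaike_weight")]))
  invisible(x)
}

#' Model- and parameter-recovery experiment
#'
#' For each generating world, simulates `replicates` cohorts (seeds
#' derived from the master seed), fits both theory models to each, and
#' tabulates per world x fitted model: convergence rate, the fraction
#' of replicates each model wins on Akaike weight and on Schwarz
#' weight, and (when the fitted model matches the generating world on
#' a direct-score design) bias and RMSE of every self-feedback and
#' coupling parameter.
#'
#' @param configs Named list of `lcs_sim_config` objects, one per
#'   generating world (e.g. `list(mutualism = ..., common_cause = ...)`).
#' @param replicates Number of replicates per world (>= 2).
#' @param seed Master seed; replicate seeds are derived from it.
#' @param ... Passed to [fit_lcs()].
#' @return A list of class `lcs_recovery`: `wins` (per world win
#'   fractions and convergence rates), `bias` (per-parameter bias/RMSE
#'   where applicable), `detail` (per-replicate glance rows).
#' @export
recovery_experiment <- function(configs, replicates = 10, seed = 1, ...) {
  stopifnot(replicates >= 2)
  detail <- list(); biases <- list()
  for (world in names(configs)) {
    cfg <- configs[[world]]
    builders <- study_builders(cfg$design)
    for (r in seq_len(replicates)) {
      rep_seed <- (seed * 1000 + 7 * r + match(world, names(configs))) %% 2147483647
      cohort <- simulate_cohort(cfg, seed = rep_seed)
      fits <- lapply(names(builders), function(nm)
        tryCatch(fit_lcs(cohort$data, builders[[nm]](), seed = rep_seed, ...),
                 error = function(e) NULL))
      names(fits) <- names(builders)
      row <- tibble::tibble(
        world = world, replicate = r,
        cc_converged = !is.null(fits$common_cause) &&
          fits$common_cause$convergence$converged,
        mut_converged = !is.null(fits$mutualism) &&
          fits$mutualism$convergence$converged,
        cc_aic = if (!is.null(fits$common_cause)) fits$common_cause$aic else NA_real_,
        mut_aic = if (!is.null(fits$mutualism)) fits$mutualism$aic else NA_real_,
        cc_bic = if (!is.null(fits$common_cause)) fits$common_cause$bic else NA_real_,
        mut_bic = if (!is.null(fits$mutualism)) fits$mutualism$bic else NA_real_
      )
      detail[[length(detail) + 1]] <- row
      # parameter bias for the model that matches the generating world,
      # when the generating scale is the observed scale (direct scores)
      match_model <- if (cfg$world == "mutualism") "mutualism" else "common_cause"
      ft <- fits[[match_model]]
      if (!is.null(ft) && direct_scale(cfg)) {
        truth <- trajectory_theta(ft$spec, cfg$params,
                                  age_mean = cfg$age_mean,
                                  age_var = cfg$age_sd^2, partial = TRUE)
        truth <- truth[!is.na(truth)]
        if (length(truth)) {
          dyn <- grep("^(phi_|gamma_)", names(truth), value = TRUE)
          biases[[length(biases) + 1]] <- tibble::tibble(
            world = world, replicate = r, label = dyn,
            truth = as.numeric(truth[dyn]),
            estimate = as.numeric(ft$theta[dyn]))
        }
      }
    }
  }
  detail <- dplyr::bind_rows(detail)
  wins <- detail |>
    dplyr::group_by(.data$world) |>
    dplyr::summarise(
      replicates = dplyr::n(),
      cc_convergence = mean(.data$cc_converged),
      mut_convergence = mean(.data$mut_converged),
      mut_aic_win = mean(.data$mut_aic < .data$cc_aic, na.rm = TRUE),
      cc_aic_win = mean(.data$cc_aic < .data$mut_aic, na.rm = TRUE),
      mut_bic_win = mean(.data$mut_bic < .data$cc_bic, na.rm = TRUE),
      cc_bic_win = mean(.data$cc_bic < .data$mut_bic, na.rm = TRUE),
      .groups = "drop")
  bias <- NULL
  if (length(biases)) {
    bias <- dplyr::bind_rows(biases) |>
      dplyr::group_by(.data$world, .data$label) |>
      dplyr::summarise(
        truth = .data$truth[1],
        bias = mean(.data$estimate - .data$truth),
        rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
        mc_se = stats::sd(.data$estimate) / sqrt(dplyr::n()),
        .groups = "drop")
  }
  structure(list(wins = wins, bias = bias, detail = detail, seed = seed),
            class = "lcs_recovery")
}

# TRUE when observed scores equal the latent scores (identity emission)
direct_scale <- function(cfg) {
  m <- cfg$measurement
  cfg$discretize == "none" && all(m$loading == 1) && all(m$intercept == 0) &&
    all(m$resid_sd == 0) &&
    (is.null(cfg$design$parcel_map) ||
       all(lengths(cfg$design$parcel_map) == 1))
}

#' @export
print.lcs_recovery <- function(x, ...) {
  cat("<lcs_recovery>\n")
  print(x$wins)
  invisible(x)
}

#' Direct-score bivariate simulation preset
#'
#' A two-domain design whose observed scores are the latent scores
#' themselves (identity emission, no residual): the cleanest setting
#' for parameter-recovery and simulator/engine duality checks, since
#' the fitted direct-score models match the generator exactly.
#'
#' @param n Persons.
#' @param waves Number of waves.
#' @param world Generating world; the common-cause world uses a single
#'   liability expanded into the two series.
#' @param gamma Coupling in the mutualism world.
#' @param missing_rate MCAR rate.
#' @param age Include a baseline age covariate.
#' @param seed Seed.
#' @return An `lcs_sim_config`.
#' @export
config_bivariate_direct <- function(n = 1500, waves = 4,
                                    world = c("mutualism", "common-cause"),
                                    gamma = 0.2, missing_rate = 0,
                                    age = FALSE, seed = 1) {
  world <- match.arg(world)
  items <- tibble::tibble(item = c("aff", "mot"), domain = c("aff", "mot"))
  design <- measurement_design(
    items, seq_len(waves), scale_type = "continuous-likert",
    parcel_map = list(aff = "aff", mot = "mot"),
    covariates = if (age) "age" else character())
  measurement <- tibble::tibble(
    item = c("aff", "mot"), domain = c("aff", "mot"),
    loading = 1, intercept = 0, resid_sd = 0, prevalence = NA_real_)
  params <- if (world == "mutualism") {
    trajectory_params(c("aff", "mot"), waves, phi = -0.2, gamma = gamma,
                      covariate_slopes = if (age) list(age = 0.012))
  } else {
    trajectory_params("dep", waves, phi = -0.2, gamma = 0,
                      covariate_slopes = if (age) list(age = 0.012))
  }
  sim_config(design, world, n, params, measurement = measurement,
             second_order = if (world == "common-cause")
               list(loadings = c(1, 0.8), intercepts = 0, dist_sd = sqrt(0.3)),
             missing_rate = missing_rate, discretize = "none", seed = seed)
}
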