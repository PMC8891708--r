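#' Canonical growth-model specifications
#'
#' `make_model1_spec()` is the domain-only growth model: six within-cell terms
#' (intercept, age, age^2, domain, age x domain, age^2 x domain), each crossed
#' with the two parcel-label indicators (18 fixed effects), with participant
#' random effects on {intercept, age, domain} and parcel random effects on
#' {intercept, age, age^2, domain}, both with full covariance (35 parameters).
#'
#' `make_model2_spec()` adds the target factor and all its nested interactions
#' (12 within-cell terms, 36 fixed effects), with participant random effects
#' on the eight coefficient equations carrying participant deviations
#' (intercept, age, domain, age x domain, target, target x domain,
#' age x target, age x target x domain) and parcel random effects on all 12,
#' both with full covariance (151 parameters).
#'
#' @param random_participant,random_parcel integer term indices for the two
#'   random blocks (see [growth_terms()]); defaults give the canonical
#'   structures.
#' @param covariance `"full"` or `"diagonal"` for both blocks.
#' @return a [growth_model_spec()].
#' @export
make_model1_spec <- function(random_participant = c(0, 1, 3),
                             random_parcel = c(0, 1, 2, 3),
                             covariance = "full") {
  growth_model_spec(
    "Model 1 - Domain", base_terms = 0:5,
    random_blocks = list(re_block("participant", random_participant, covariance),
                         re_block("parcel", random_parcel, covariance)))
}

#' @rdname make_model1_spec
#' @export
make_model2_spec <- function(random_participant = c(0, 1, 3, 4, 6, 7, 8, 10),
                             random_parcel = 0:11,
                             covariance = "full") {
  growth_model_spec(
    "Model 2 - Domain x Target", base_terms = 0:11,
    random_blocks = list(re_block("participant", random_participant, covariance),
                         re_block("parcel", random_parcel, covariance)))
}

#' Reference fixed-effect estimates for the domain-by-target model
#'
#' Published point estimates from a previously reported fit of the
#' domain-by-target growth model to a three-wave adolescent cohort (BOLD
#' response standardized within parcel, age centered at 13). Useful as the
#' planted truth in recovery experiments and for reconstructing simple slopes
#' from the coefficient scale.
#'
#' @return named numeric vector over the 36 `gamma_*` fixed effects.
#' @export
reference_gamma <- function() {
  c(gamma_000 = -0.004, gamma_001.self = -0.033, gamma_001.soc = 0.242,
    gamma_100 = 0.003, gamma_101.self = 0.007, gamma_101.soc = 0.018,
    gamma_200 = 0.000, gamma_201.self = 0.001, gamma_201.soc = -0.004,
    gamma_300 = 0.013, gamma_301.self = 0.066, gamma_301.soc = 0.118,
    gamma_400 = 0.000, gamma_401.self = -0.006, gamma_401.soc = -0.005,
    gamma_500 = -0.003, gamma_501.self = 0.006, gamma_501.soc = 0.005,
    gamma_600 = 0.004, gamma_601.self = 0.255, gamma_601.soc = -0.051,
    gamma_700 = -0.006, gamma_701.self = -0.022, gamma_701.soc = 0.098,
    gamma_800 = 0.002, gamma_801.self = 0.026, gamma_801.soc = 0.006,
    gamma_900 = -0.002, gamma_901.self = -0.011, gamma_901.soc = 0.004,
    gamma_1000 = 0.003, gamma_1001.self = -0.006, gamma_1001.soc = -0.014,
    gamma_1100 = 0.000, gamma_1101.self = 0.009, gamma_1101.soc = -0.001)
}

#' Bonferroni correction
#'
#' `min(1, m * p)`; monotone in both arguments and idempotent at the cap.
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @param m number of comparisons in the family (integer >= 1).
#' @return adjusted p value(s).
#' @export
bonferroni_adjust <- function(p, m) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p must be in [0, 1]")
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 1 ||
      m != round(m))
    stop("m must be a single integer >= 1")
  pmin(1, m * p)
}

## Factor metadata for the two condition contrasts a simple slope can probe.
.slope_factors <- list(
  target_diff = list(vary = "target", condition_on = "domain",
                     codes = c(Academic = -0.5, Social = 0.5)),
  domain_diff = list(vary = "domain", condition_on = "target",
                     codes = c(Other = -0.5, Self = 0.5)))

#' Contrast weights for a simple slope of a condition difference
#'
#' For the difference between the two levels of one factor (target: Self minus
#' Other; domain: Social minus Academic), conditioned on a fixed level of the
#' other factor and a parcel label, returns the fixed-effect weights of either
#' the instantaneous age slope of that difference at a given age
#' (`component = "linear"`, which places `2 (age - 13)` on the quadratic
#' terms) or its quadratic (curvature) coefficient (`component = "quadratic"`).
#' Within-label slopes sum the base (control) column and the matching label
#' interaction column.
#'
#' @param contrast `"target_diff"` (Self - Other) or `"domain_diff"`
#'   (Social - Academic).
#' @param conditioning level of the other factor (e.g. `"Social"` for
#'   `target_diff`), or its numeric +/-0.5 code.
#' @param parcel_label `"control"`, `"self"` or `"social"`.
#' @param age age in years at which the slope is taken (default 13).
#' @param component `"linear"` or `"quadratic"`.
#' @return named numeric weights over `gamma_*` coefficients.
#' @export
slope_weights <- function(contrast = c("target_diff", "domain_diff"),
                          conditioning, parcel_label, age = 13,
                          component = c("linear", "quadratic")) {
  contrast <- match.arg(contrast)
  component <- match.arg(component)
  if (!parcel_label %in% .parcel_labels)
    stop("parcel_label must be one of: ", paste(.parcel_labels, collapse = ", "))
  sf <- .slope_factors[[contrast]]
  code <- if (is.character(conditioning)) {
    if (!conditioning %in% names(sf$codes))
      stop("conditioning level must be one of: ",
           paste(names(sf$codes), collapse = ", "))
    unname(sf$codes[conditioning])
  } else as.numeric(conditioning)
  terms <- growth_terms()
  terms <- terms[terms[[sf$vary]], , drop = FALSE]
  c0 <- age - 13
  w <- numeric(0)
  for (i in seq_len(nrow(terms))) {
    pow <- terms$age_pow[i]
    base <- if (component == "linear") {
      if (pow == 1L) 1 else if (pow == 2L) 2 * c0 else 0
    } else {
      if (pow == 2L) 1 else 0
    }
    if (base == 0) next
    if (terms[[sf$condition_on]][i]) base <- base * code
    nm <- paste0("gamma_", terms$beta[i], "00")
    w[nm] <- base
    if (parcel_label != "control") {
      suffix <- if (parcel_label == "self") "01.self" else "01.soc"
      w[paste0("gamma_", terms$beta[i], suffix)] <- base
    }
  }
  w
}

#' Simple slope of a condition difference at a given age
#'
#' Applies [slope_weights()] to a fitted domain-by-target model (or to a plain
#' named coefficient vector, in which case only the point estimate is
#' returned).
#'
#' @inheritParams slope_weights
#' @param fit an [fit_lmm()] result, or a named numeric vector of fixed
#'   effects.
#' @param df_method passed to [wald_contrast()].
#' @return a `contrast_result` (or a single number for a plain coefficient
#'   vector).
#' @export
simple_slope <- function(fit, contrast = c("target_diff", "domain_diff"),
                         conditioning, parcel_label, age = 13,
                         component = c("linear", "quadratic"),
                         df_method = "satterthwaite") {
  w <- slope_weights(contrast, conditioning, parcel_label, age, component)
  if (is.numeric(fit) && !is.null(names(fit))) {
    miss <- setdiff(names(w), names(fit))
    if (length(miss)) stop("coefficient vector lacks: ",
                           paste(miss, collapse = ", "))
    return(sum(w * fit[names(w)]))
  }
  wald_contrast(fit, w, df_method = df_method)
}

## prediction covariate row for one (label, domain, target, age) cell over the
## coefficients actually present in a coefficient vector
.prediction_row <- function(coef_names, parcel_label, domain, target, age_c) {
  parsed <- regmatches(coef_names,
                       regexec("^gamma_([0-9]+)0(0|1\\.(self|soc))$", coef_names))
  x <- numeric(length(coef_names))
  codes <- code_condition(domain, target)
  for (i in seq_along(coef_names)) {
    pp <- parsed[[i]]
    if (length(pp) == 0L) stop("unparseable coefficient name: ", coef_names[i])
    beta <- as.integer(pp[2])
    tr <- growth_terms(beta)
    v <- age_c^tr$age_pow
    if (tr$domain) v <- v * codes$domain
    if (tr$target) v <- v * codes$target
    lab_part <- pp[4]
    if (lab_part == "") x[i] <- v
    else if (lab_part == "self" && parcel_label == "self") x[i] <- v
    else if (lab_part == "soc" && parcel_label == "social") x[i] <- v
  }
  x
}

#' Predict developmental trajectories
#'
#' Fixed-effect predicted means per (parcel label, domain, target, age) cell
#' over an age grid; optionally per-parcel predicted curves adding the
#' parcel-level predicted random deviations (requires a fit with
#' `blups = TRUE`).
#'
#' @param fit an [fit_lmm()] result (or named coefficient vector).
#' @param age_grid ages in years (default `seq(9, 17, 0.1)`, the sampled
#'   range).
#' @param cells data.frame with columns `parcel_label`, `domain`, `target`;
#'   default all 12 combinations.
#' @param blups logical; add per-parcel curves (fit must carry BLUPs and
#'   `parcel_labels` must give each parcel's label).
#' @param parcel_labels named character vector (parcel id -> label) used when
#'   `blups = TRUE`.
#' @param age_range ages outside this range trigger an extrapolation warning.
#' @return data.frame with columns `parcel_label`, `domain`, `target`, `age`,
#'   `predicted` (plus `parcel_id` for per-parcel rows).
#' @export
predict_trajectories <- function(fit, age_grid = seq(9, 17, 0.1), cells = NULL,
                                 blups = FALSE, parcel_labels = NULL,
                                 age_range = c(9, 17.5)) {
  gamma <- if (inherits(fit, "lmm_fit")) fit$gamma else fit
  if (is.null(names(gamma))) stop("fit must carry named coefficients")
  if (any(age_grid < age_range[1] | age_grid > age_range[2]))
    warning("age grid extends beyond ", age_range[1], "-", age_range[2],
            " years; predictions are extrapolations")
  if (is.null(cells))
    cells <- expand.grid(parcel_label = .parcel_labels,
                         domain = c("Academic", "Social"),
                         target = c("Other", "Self"),
                         stringsAsFactors = FALSE)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    preds <- vapply(age_grid, function(a)
      sum(.prediction_row(names(gamma), cells$parcel_label[i],
                          cells$domain[i], cells$target[i], a - 13) * gamma),
      0)
    out[[i]] <- data.frame(parcel_label = cells$parcel_label[i],
                           domain = cells$domain[i], target = cells$target[i],
                           age = age_grid, predicted = preds,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (blups) {
    if (!inherits(fit, "lmm_fit") || is.null(fit$blups$parcel))
      stop("per-parcel curves need a fit computed with blups = TRUE and a parcel block")
    if (is.null(parcel_labels)) stop("parcel_labels required for blups = TRUE")
    u <- fit$blups$parcel
    terms <- growth_terms(fit$env$ds$blocks[[
      which(vapply(fit$env$ds$blocks, `[[`, "", "grouping") == "parcel")]]$terms)
    percurve <- list()
    for (k in rownames(u)) {
      lab <- unname(parcel_labels[k])
      if (is.na(lab)) stop("no label for parcel ", k)
      for (i in seq_len(nrow(cells))) {
        if (cells$parcel_label[i] != lab) next
        codes <- code_condition(cells$domain[i], cells$target[i])
        devs <- vapply(age_grid, function(a) {
          v <- (a - 13)^terms$age_pow
          v[terms$domain] <- v[terms$domain] * codes$domain
          v[terms$target] <- v[terms$target] * codes$target
          sum(u[k, ] * v)
        }, 0)
        fixed <- res$predicted[res$parcel_label == lab &
                                 res$domain == cells$domain[i] &
                                 res$target == cells$target[i]]
        percurve[[length(percurve) + 1L]] <-
          data.frame(parcel_label = lab, domain = cells$domain[i],
                     target = cells$target[i], age = age_grid,
                     predicted = fixed + devs, parcel_id = k,
                     stringsAsFactors = FALSE)
      }
    }
    attr(res, "parcel_curves") <- do.call(rbind, percurve)
  }
  res
}

## The hypothesis families: coefficient tests plus age-13 simple slopes, with
## the Bonferroni family size used for each.
.hypothesis_rows <- function() {
  list(
    list(id = "H1", name = "Age x Domain x Label (social)",
         coef = "gamma_401.soc", m = 2),
    list(id = "H1", name = "Age^2 x Domain x Label (social)",
         coef = "gamma_501.soc", m = 2),
    list(id = "H2", name = "Age x Target x Label (self)",
         coef = "gamma_801.self", m = 2),
    list(id = "H2", name = "Age^2 x Target x Label (self)",
         coef = "gamma_901.self", m = 2),
    list(id = "H3A", name = "Age x Target x Domain x Label (social)",
         coef = "gamma_1001.soc", m = 4),
    list(id = "H3A", name = "Age^2 x Target x Domain x Label (social)",
         coef = "gamma_1101.soc", m = 4),
    list(id = "H3A", name = "Self (Social - Academic) age slope, social parcels",
         slope = list("domain_diff", "Self", "social", "linear"), m = 4),
    list(id = "H3A", name = "Self (Social - Academic) age^2 slope, social parcels",
         slope = list("domain_diff", "Self", "social", "quadratic"), m = 4),
    list(id = "H3B", name = "Age x Target x Domain x Label (self)",
         coef = "gamma_1001.self", m = 4),
    list(id = "H3B", name = "Age^2 x Target x Domain x Label (self)",
         coef = "gamma_1101.self", m = 4),
    list(id = "H3B", name = "Social (Self - Other) age slope, self parcels",
         slope = list("target_diff", "Social", "self", "linear"), m = 4),
    list(id = "H3B", name = "Social (Self - Other) age^2 slope, self parcels",
         slope = list("target_diff", "Social", "self", "quadratic"), m = 4))
}

#' Hypothesis ledger for the domain-by-target model
#'
#' Runs the coefficient tests and age-13 simple-slope contrasts for the four
#' developmental hypotheses (H1: domain moderation in social parcels; H2:
#' target moderation in self parcels; H3A/H3B: the four-way interactions and
#' their targeted simple slopes), Bonferroni-corrected within family (m = 2
#' for H1 and H2, m = 4 for each of H3A and H3B).
#'
#' @param fit a domain-by-target [fit_lmm()] result.
#' @param df_method passed to [wald_contrast()].
#' @param alpha significance level for the decision text (default 0.05).
#' @return data.frame with one row per test: `hypothesis`, `name`, `estimate`,
#'   `se`, `t`, `df`, `p`, `m`, `adjusted_p`, `decision`.
#' @export
hypothesis_ledger <- function(fit, df_method = "satterthwaite", alpha = 0.05) {
  rows <- lapply(.hypothesis_rows(), function(r) {
    cr <- if (!is.null(r$coef))
      wald_contrast(fit, setNames(1, r$coef), df_method = df_method)
    else
      simple_slope(fit, r$slope[[1]], r$slope[[2]], r$slope[[3]],
                   component = r$slope[[4]], df_method = df_method)
    adj <- bonferroni_adjust(cr$p, r$m)
    data.frame(hypothesis = r$id, name = r$name, estimate = cr$estimate,
               se = cr$se, t = cr$t, df = cr$df, p = cr$p, m = r$m,
               adjusted_p = adj,
               decision = if (adj < alpha) "significant (adjusted)"
                          else "not significant (adjusted)",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the growth-curve analysis end to end
#'
#' Builds and fits the domain-only and domain-by-target models, compares them
#' by AIC, assembles the coefficient table of the selected model, runs the
#' hypothesis ledger, predicts developmental trajectories, and records a run
#' manifest. Estimates are REML by default; the AIC comparison refits both
#' models by ML (warm-started at the REML covariance parameters) unless
#' `aic_objective = "REML"`.
#'
#' @param obs a validated observation table.
#' @param config list of options: `objective` (`"REML"`), `aic_objective`
#'   (`"ML"`), `df_method` (`"satterthwaite"`), `model1_spec`, `model2_spec`
#'   (override the canonical specifications, e.g. with reduced random
#'   structures), `age_grid`, `control` (passed to [fit_lmm()]).
#' @return an object of class `growth_analysis`: `fits`, `aic_fits`,
#'   `comparison`, `selected`, `coefficients`, `ledger`, `trajectories`,
#'   `manifest`, `errors`.
#' @export
run_growth_analysis <- function(obs, config = list()) {
  defaults <- list(objective = "REML", aic_objective = "ML",
                   df_method = "satterthwaite",
                   model1_spec = make_model1_spec(),
                   model2_spec = make_model2_spec(),
                   age_grid = seq(9, 17, 0.1), control = list())
  cfg <- defaults
  cfg[names(config)] <- config  # replace, never merge, nested objects
  validate_observations(obs)
  for (f in c("domain", "target"))
    if (length(unique(as.character(obs[[f]]))) < 2L)
      stop("both levels of ", f, " must be present")
  errors <- list()
  d1 <- build_design(obs, cfg$model1_spec)
  d2 <- build_design(obs, cfg$model2_spec)
  fit1 <- fit_lmm(d1, objective = cfg$objective, control = cfg$control)
  fit2 <- fit_lmm(d2, objective = cfg$objective, control = cfg$control)
  if (cfg$aic_objective != cfg$objective) {
    a1 <- fit_lmm(d1, objective = cfg$aic_objective, start = fit1$theta,
                  control = cfg$control)
    a2 <- fit_lmm(d2, objective = cfg$aic_objective, start = fit2$theta,
                  control = cfg$control)
  } else {
    a1 <- fit1; a2 <- fit2
  }
  comparison <- compare_models(a1, a2)
  selected_fit <- if (comparison$selected == "b") fit2 else fit1
  coefficients <- tryCatch(
    coefficient_table(selected_fit, df_method = cfg$df_method),
    error = function(e) { errors$coefficients <<- conditionMessage(e); NULL })
  ledger <- tryCatch(
    hypothesis_ledger(fit2, df_method = cfg$df_method),
    error = function(e) { errors$ledger <<- conditionMessage(e); NULL })
  trajectories <- tryCatch(
    predict_trajectories(selected_fit, age_grid = cfg$age_grid),
    error = function(e) { errors$trajectories <<- conditionMessage(e); NULL })
  manifest <- list(
    package_version = as.character(utils::packageVersion("parcelgrowth")),
    n_obs = nrow(obs),
    n_participants = length(unique(obs$participant_id)),
    n_parcels = length(unique(obs$parcel_id)),
    objective = cfg$objective, aic_objective = cfg$aic_objective,
    df_method = cfg$df_method,
    model1 = cfg$model1_spec$name, model2 = cfg$model2_spec$name,
    n_params = c(model1 = count_parameters(cfg$model1_spec),
                 model2 = count_parameters(cfg$model2_spec)))
  structure(list(fits = list(model1 = fit1, model2 = fit2),
                 aic_fits = list(model1 = a1, model2 = a2),
                 comparison = comparison,
                 selected = if (comparison$selected == "b") "model2" else "model1",
                 coefficients = coefficients, ledger = ledger,
                 trajectories = trajectories, manifest = manifest,
                 errors = errors),
            class = "growth_analysis")
}

#' @export
print.growth_analysis <- function(x, ...) {
  cat("Growth-curve analysis\n")
  cat(sprintf("  AIC: model1 = %.1f, model2 = %.1f, delta = %.1f -> %s selected\n",
              x$comparison$aic_a, x$comparison$aic_b, x$comparison$delta_aic,
              x$selected))
  if (!is.null(x$ledger)) {
    sig <- x$ledger[x$ledger$adjusted_p < 0.05, c("hypothesis", "name",
                                                  "estimate", "adjusted_p")]
    cat("  tests significant after Bonferroni correction:",
        if (nrow(sig)) "" else "none", "\n")
    if (nrow(sig)) print(sig, row.names = FALSE)
  }
  if (length(x$errors)) cat("  stages failed:",
                            paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' Write growth-analysis outputs
#'
#' Emits the coefficient table and hypothesis ledger as tab-separated values,
#' the model comparison and run manifest as JSON, and the trajectory grid as
#' TSV, into a directory.
#'
#' @param results a [run_growth_analysis()] bundle.
#' @param dir output directory (created if absent).
#' @export
write_growth_results <- function(results, dir) {
  stopifnot(inherits(results, "growth_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(results$coefficients)) tsv(results$coefficients,
                                          "coefficients.tsv")
  if (!is.null(results$ledger)) tsv(results$ledger, "hypothesis_ledger.tsv")
  if (!is.null(results$trajectories)) tsv(results$trajectories,
                                          "trajectories.tsv")
  jsonlite::write_json(results$comparison, file.path(dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(results$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Refit the published analysis on the deposited observation table
#'
#' Runs the full domain-only versus domain-by-target comparison, with the
#' canonical random-effects structures, on a local copy of the deposited
#' parcel-level observation table (tab-separated, see [read_observations()]).
#' This is the full-scale external check: at the published cohort size
#' (135 sessions x 4 conditions x 352 parcels) it is a long-running
#' computation and its agreement with the published coefficient table also
#' depends on matching the original estimation software's objective and
#' convergence behavior.
#'
#' @param path path to the deposited observation table (TSV).
#' @param config passed to [run_growth_analysis()]; defaults to the published
#'   configuration (REML estimates, ML AIC comparison).
#' @return a `growth_analysis` bundle.
#' @export
reproduce_published_fit <- function(path, config = list()) {
  if (!file.exists(path))
    stop("observation table not found at '", path,
         "'; download the deposited parcel-level data and point `path` at it")
  obs <- read_observations(path)
  run_growth_analysis(obs, config)
}
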