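## Synthetic accelerated-longitudinal cohorts with the statistical structure
## the growth models assume: retention-patterned waves, truncated-normal ages
## linked within participant, crossed participant/parcel random effects, and
## small NIfTI fixtures for the extraction stage.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

.rtruncnorm <- function(n, mean, sd, range) {
  out <- numeric(n); need <- seq_len(n)
  for (i in 1:1000) {
    out[need] <- rnorm(length(need), mean, sd)
    need <- which(out < range[1] | out > range[2])
    if (!length(need)) return(out)
  }
  stop("truncated-normal sampling failed; check range against mean/sd")
}

#' Accelerated three-wave cohort design
#'
#' Describes the sampling design of a three-wave accelerated longitudinal
#' cohort: per-wave age distributions, a retention pattern (how many
#' participants contribute which subsets of waves), within-participant
#' inter-wave age gaps, and parcel counts per category. The default is the
#' study-scale design: waves of 57/44/34 sessions with age means 10.08,
#' 13.06, 16.33 years (SDs 0.32, 0.33, 0.46), 35/17/22 participants with
#' 1/2/3 waves, and 19/44/289 self/social/control parcels.
#'
#' @param patterns named integer vector of participant counts per wave subset
#'   (names from "1", "2", "3", "12", "13", "23", "123").
#' @param age_mean,age_sd per-wave age distribution (years).
#' @param gap_mean,gap_sd means/SDs (years) of the wave-1-to-2 and 2-to-3 age
#'   gaps, linked within participant.
#' @param age_range truncation bounds for simulated ages.
#' @param parcels named integer vector `c(self=, social=, control=)`.
#' @param wave_n optional per-wave session counts; derived from `patterns` if
#'   omitted, validated against them if given.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(patterns = c("1" = 21, "2" = 7, "3" = 7, "12" = 12,
                                       "13" = 2, "23" = 3, "123" = 22),
                          age_mean = c(10.08, 13.06, 16.33),
                          age_sd = c(0.32, 0.33, 0.46),
                          gap_mean = c(2.98, 3.27), gap_sd = c(0.3, 0.3),
                          age_range = c(9, 17.5),
                          parcels = c(self = 19, social = 44, control = 289),
                          wave_n = NULL) {
  valid <- c("1", "2", "3", "12", "13", "23", "123")
  bad <- setdiff(names(patterns), valid)
  if (length(bad)) stop("invalid retention pattern(s): ",
                        paste(bad, collapse = ", "))
  if (any(patterns < 0) || sum(patterns) < 1)
    stop("retention counts must be non-negative with at least one participant")
  derived <- vapply(1:3, function(w)
    sum(patterns[grepl(as.character(w), names(patterns))]), 0)
  if (is.null(wave_n)) wave_n <- derived
  else if (!identical(as.numeric(wave_n), as.numeric(derived)))
    stop("wave_n (", paste(wave_n, collapse = "/"),
         ") inconsistent with retention patterns (",
         paste(derived, collapse = "/"), ")")
  if (!all(c("self", "social", "control") %in% names(parcels)))
    stop("parcels must name self, social and control counts")
  structure(list(patterns = patterns, wave_n = wave_n, age_mean = age_mean,
                 age_sd = age_sd, gap_mean = gap_mean, gap_sd = gap_sd,
                 age_range = age_range, parcels = parcels),
            class = "cohort_design")
}

#' Reduced-scale cohort design for recovery experiments
#'
#' The study-scale retention proportions scaled down to 40 participants
#' (73 sessions) and 30 parcels (6 self, 9 social, 15 control), keeping
#' simulation-fit replicates fast.
#'
#' @param ... overrides passed to [cohort_design()].
#' @export
reduced_cohort_design <- function(...) {
  cohort_design(patterns = c("1" = 11, "2" = 4, "3" = 4, "12" = 6, "13" = 1,
                             "23" = 2, "123" = 12),
                parcels = c(self = 6, social = 9, control = 15), ...)
}

.sim_cohort <- function(design) {
  pats <- rep(names(design$patterns), design$patterns)
  np <- length(pats)
  ids <- sprintf("P%03d", seq_len(np))
  base <- .rtruncnorm(np, design$age_mean[1], design$age_sd[1],
                      design$age_range)
  g1 <- .rtruncnorm(np, design$gap_mean[1], design$gap_sd[1], c(0.5, 6))
  g2 <- .rtruncnorm(np, design$gap_mean[2], design$gap_sd[2], c(0.5, 6))
  ages <- cbind(base, base + g1, base + g1 + g2)
  ages <- pmin(pmax(ages, design$age_range[1]), design$age_range[2])
  rows <- list()
  for (i in seq_len(np)) {
    waves <- as.integer(strsplit(pats[i], "")[[1]])
    rows[[i]] <- data.frame(participant_id = ids[i], wave = waves,
                            age_years = ages[i, waves],
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate a cohort's demographics
#'
#' Draws participants according to the design's retention pattern; each
#' participant gets a truncated-normal wave-1 baseline age and linked
#' inter-wave gaps, so the per-wave age means and SDs reproduce the design's.
#' Deterministic given the seed.
#'
#' @param design a [cohort_design()].
#' @param seed integer seed.
#' @return data.frame with columns `participant_id`, `wave`, `age_years`
#'   (one row per observed session).
#' @export
simulate_cohort <- function(design, seed) {
  stopifnot(inherits(design, "cohort_design"))
  .with_seed(seed, .sim_cohort(design))
}

#' Configuration of a generative simulation
#'
#' Bundles the generative truth for [simulate_observations()]: fixed effects,
#' per-block random-effect covariance matrices (response-scale), residual
#' variance, a sampling design, and a seed.
#'
#' @param true_gamma named numeric vector over (a subset of) the model's
#'   `gamma_*` fixed effects; unnamed coefficients are zero.
#' @param participant_cov,parcel_cov symmetric PSD covariance matrices, one
#'   row/column per random term of the matching block (`NULL` for a model
#'   without that block).
#' @param residual_var residual variance (> 0, or 0 for a noise-free surface).
#' @param design a [cohort_design()].
#' @param seed integer seed.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(true_gamma, participant_cov = NULL,
                              parcel_cov = NULL, residual_var = 1,
                              design = reduced_cohort_design(), seed = 1L) {
  for (m in list(participant_cov, parcel_cov)) {
    if (is.null(m)) next
    if (!isSymmetric(unname(m), tol = 1e-8)) stop("covariance must be symmetric")
    if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop("covariance must be positive semidefinite")
  }
  if (residual_var < 0) stop("residual_var must be >= 0")
  structure(list(true_gamma = true_gamma, participant_cov = participant_cov,
                 parcel_cov = parcel_cov, residual_var = residual_var,
                 design = design, seed = as.integer(seed)),
            class = "simulation_config")
}

.psd_sqrt <- function(m) {
  if (max(abs(m)) == 0) return(m)
  e <- eigen(m, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(m)) %*% t(e$vectors)
}

.resolve_gamma <- function(true_gamma, xnames) {
  bad <- setdiff(names(true_gamma), xnames)
  if (length(bad)) stop("true_gamma names not in the model: ",
                        paste(bad, collapse = ", "))
  g <- setNames(numeric(length(xnames)), xnames)
  g[names(true_gamma)] <- true_gamma
  g
}

#' Simulate an observation table from generative truth
#'
#' Builds the full session-by-condition-by-parcel grid of the design, then
#' draws participant deviations `u_j ~ N(0, Psi_j)`, parcel deviations
#' `u_k ~ N(0, Psi_k)` and residuals `e ~ N(0, sigma^2)`, and sets the
#' response to `X gamma + Z_j u_j + Z_k u_k + e`. Bitwise reproducible from
#' `(seed, config)`.
#'
#' @param config a [simulation_config()].
#' @param spec the [growth_model_spec()] defining the fixed terms and random
#'   blocks (covariance dimensions are validated against it).
#' @return a validated observation table.
#' @export
simulate_observations <- function(config, spec) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(spec, "growth_model_spec"))
  covs <- list(participant = config$participant_cov,
               parcel = config$parcel_cov)
  for (b in spec$random_blocks) {
    m <- covs[[b$grouping]]
    if (is.null(m) || nrow(m) != length(b$terms))
      stop("covariance for the ", b$grouping, " block must be ",
           length(b$terms), "x", length(b$terms))
  }
  .with_seed(config$seed, {
    demo <- .sim_cohort(config$design)
    pc <- config$design$parcels
    parcel_ids <- seq_len(sum(pc))
    parcel_lab <- rep(c("self", "social", "control"),
                      times = pc[c("self", "social", "control")])
    grid <- expand.grid(session = seq_len(nrow(demo)),
                        domain = c("Academic", "Social"),
                        target = c("Other", "Self"),
                        parcel = parcel_ids, stringsAsFactors = FALSE)
    obs <- data.frame(
      participant_id = demo$participant_id[grid$session],
      wave = demo$wave[grid$session],
      age_years = demo$age_years[grid$session],
      age_c = demo$age_years[grid$session] - 13,
      domain = grid$domain, target = grid$target,
      parcel_id = grid$parcel,
      parcel_label = parcel_lab[grid$parcel],
      bold = 0, stringsAsFactors = FALSE)
    des <- build_design(obs, spec)
    g <- .resolve_gamma(config$true_gamma, colnames(des$X))
    y <- as.numeric(des$X %*% g)
    for (bi in seq_along(des$blocks)) {
      blk <- des$blocks[[bi]]
      S <- covs[[blk$grouping]]
      u <- matrix(rnorm(length(blk$levels) * blk$q),
                  length(blk$levels), blk$q) %*% .psd_sqrt(S)
      y <- y + as.numeric(blk$Z %*% as.vector(t(u)))
    }
    if (config$residual_var > 0)
      y <- y + rnorm(nrow(obs), 0, sqrt(config$residual_var))
    obs$bold <- y
    obs
  })
}

#' Generate a NIfTI image/atlas fixture pair
#'
#' Builds an integer-labeled atlas volume from disjoint box-shaped parcels and
#' an image whose in-parcel values are the requested means plus Gaussian
#' noise (background zero). Used to exercise the extraction stage end to end.
#'
#' @param shape 3-vector of volume dimensions.
#' @param parcel_geometry named list (names = parcel ids) of
#'   `list(lo = c(x, y, z), hi = c(x, y, z))` voxel-index boxes; boxes must be
#'   disjoint.
#' @param parcel_means numeric vector of in-parcel means, one per parcel.
#' @param noise_sd Gaussian noise SD (0 for exact means).
#' @param seed integer seed.
#' @param pixdim voxel size in mm (default 3).
#' @param dir optional directory; when given, writes `image.nii.gz` and
#'   `atlas.nii.gz` there.
#' @return list with `image` and `atlas` (`niftiImage` volumes) and, when
#'   written, `paths`.
#' @export
generate_nifti_fixture <- function(shape, parcel_geometry, parcel_means,
                                   noise_sd = 0, seed = 1L,
                                   pixdim = c(3, 3, 3), dir = NULL) {
  if (length(parcel_means) != length(parcel_geometry))
    stop("one mean per parcel required")
  atlas <- array(0L, dim = shape)
  for (i in seq_along(parcel_geometry)) {
    g <- parcel_geometry[[i]]
    id <- as.integer(names(parcel_geometry)[i])
    if (is.na(id) || id <= 0) stop("parcel ids must be positive integers")
    box <- atlas[g$lo[1]:g$hi[1], g$lo[2]:g$hi[2], g$lo[3]:g$hi[3]]
    if (any(box != 0L)) stop("overlapping parcel regions at id ", id)
    atlas[g$lo[1]:g$hi[1], g$lo[2]:g$hi[2], g$lo[3]:g$hi[3]] <- id
  }
  img <- array(0, dim = shape)
  .with_seed(seed, {
    for (i in seq_along(parcel_geometry)) {
      id <- as.integer(names(parcel_geometry)[i])
      vox <- which(atlas == id)
      img[vox] <- parcel_means[i] +
        if (noise_sd > 0) rnorm(length(vox), 0, noise_sd) else 0
    }
  })
  image_n <- RNifti::asNifti(img)
  atlas_n <- RNifti::asNifti(atlas)
  RNifti::pixdim(image_n) <- pixdim
  RNifti::pixdim(atlas_n) <- pixdim
  out <- list(image = image_n, atlas = atlas_n)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    pi_ <- file.path(dir, "image.nii.gz"); pa <- file.path(dir, "atlas.nii.gz")
    RNifti::writeNifti(image_n, pi_); RNifti::writeNifti(atlas_n, pa)
    out$paths <- c(image = pi_, atlas = pa)
  }
  out
}

#' Simulation-based parameter recovery experiment
#'
#' Repeatedly simulates from the generative truth, fits the model, and
#' records fixed-effect estimates, confidence-interval coverage of the truth,
#' and (optionally) the p value of the primary target-moderation test
#' (the age-by-target-by-self-label coefficient), reporting per-coefficient
#' bias, RMSE and empirical coverage with Monte-Carlo standard errors.
#'
#' @param config a [simulation_config()] (its `seed` is replaced per
#'   replicate).
#' @param spec the [growth_model_spec()] to simulate from and fit.
#' @param replicates number of replicates (>= 1).
#' @param seed master seed from which per-replicate seeds are drawn.
#' @param objective passed to [fit_lmm()].
#' @param level confidence level for coverage (default 0.95).
#' @param ci_method `"normal"` (default; z intervals, appropriate at these
#'   observation counts) or `"satterthwaite"`.
#' @param h2_test logical; also record the p value of the
#'   `gamma_801.self` test per replicate.
#' @param warm_start logical; start each replicate's optimization at the
#'   previous successful replicate's covariance parameters (default `TRUE`;
#'   the optimizer still iterates to each replicate's own optimum).
#' @param control passed to [fit_lmm()].
#' @return an object of class `recovery_report`.
#' @export
recovery_experiment <- function(config, spec, replicates, seed = 1L,
                                objective = "REML", level = 0.95,
                                ci_method = c("normal", "satterthwaite"),
                                h2_test = FALSE, warm_start = TRUE,
                                control = list()) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(spec, "growth_model_spec"))
  ci_method <- match.arg(ci_method)
  if (!is.numeric(replicates) || replicates < 1)
    stop("replicates must be >= 1")
  replicates <- as.integer(replicates)
  rep_seeds <- .with_seed(seed, sample.int(2^31 - 2, replicates))
  est <- se <- cover <- NULL
  h2p <- rep(NA_real_, replicates)
  failures <- character(0)
  truth <- NULL
  last_theta <- NULL
  for (r in seq_len(replicates)) {
    res <- tryCatch({
      cfg <- config; cfg$seed <- rep_seeds[r]
      obs <- simulate_observations(cfg, spec)
      des <- build_design(obs, spec)
      fit_lmm(des, objective = objective, control = control,
              start = if (warm_start) last_theta else NULL)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) { failures[as.character(r)] <- res; next }
    fit <- res
    last_theta <- fit$theta
    if (is.null(truth))
      truth <- .resolve_gamma(config$true_gamma, names(fit$gamma))
    if (is.null(est)) {
      p <- length(fit$gamma)
      est <- se <- matrix(NA_real_, replicates, p,
                          dimnames = list(NULL, names(fit$gamma)))
      cover <- matrix(NA, replicates, p,
                      dimnames = list(NULL, names(fit$gamma)))
    }
    est[r, ] <- fit$gamma
    sev <- sqrt(diag(fit$gamma_cov))
    se[r, ] <- sev
    crit <- if (ci_method == "normal") stats::qnorm(1 - (1 - level) / 2)
            else NA  # per-coefficient t criticals below
    if (ci_method == "normal") {
      cover[r, ] <- abs(fit$gamma - truth) <= crit * sev
    } else {
      for (j in seq_along(fit$gamma)) {
        dfj <- satterthwaite_df(fit, setNames(1, names(fit$gamma)[j]))
        cover[r, j] <- abs(fit$gamma[j] - truth[j]) <=
          qt(1 - (1 - level) / 2, dfj) * sev[j]
      }
    }
    if (h2_test && "gamma_801.self" %in% names(fit$gamma)) {
      cr <- wald_contrast(fit, c(gamma_801.self = 1),
                          df_method = if (ci_method == "normal") "normal"
                                      else "satterthwaite")
      h2p[r] <- cr$p
    }
  }
  ok <- which(!is.na(est[, 1]))
  R <- length(ok)
  if (R == 0L) stop("all replicates failed; first error: ", failures[1])
  percoef <- data.frame(
    term = colnames(est),
    true = as.numeric(truth[colnames(est)]),
    mean_est = colMeans(est[ok, , drop = FALSE]),
    bias = colMeans(est[ok, , drop = FALSE]) - truth[colnames(est)],
    mcse_bias = apply(est[ok, , drop = FALSE], 2, sd) / sqrt(R),
    rmse = sqrt(colMeans((est[ok, , drop = FALSE] -
                            matrix(truth[colnames(est)], R, ncol(est),
                                   byrow = TRUE))^2)),
    coverage = colMeans(cover[ok, , drop = FALSE]),
    stringsAsFactors = FALSE, row.names = NULL)
  percoef$mcse_coverage <- sqrt(percoef$coverage * (1 - percoef$coverage) / R)
  out <- list(per_coefficient = percoef, replicates = replicates,
              n_ok = R, n_failed = replicates - R, failures = failures,
              level = level, ci_method = ci_method, seed = seed)
  if (h2_test) {
    pr <- h2p[ok]
    out$h2 <- list(alpha = 0.05, rejection_rate = mean(pr < 0.05),
                   mcse = sqrt(mean(pr < 0.05) * (1 - mean(pr < 0.05)) / R),
                   n = R)
  }
  structure(out, class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery over", x$n_ok, "of", x$replicates, "replicates (",
      100 * x$level, "% ", x$ci_method, " CIs)\n", sep = "")
  print(utils::head(x$per_coefficient[, c("term", "true", "bias", "rmse",
                                          "coverage")], 12), row.names = FALSE)
  if (!is.null(x$h2))
    cat(sprintf("  target-moderation test: rejection rate %.3f (MCSE %.3f) at alpha %.2f\n",
                x$h2$rejection_rate, x$h2$mcse, x$h2$alpha))
  invisible(x)
}

#' @rdname recovery_experiment
#' @param report a `recovery_report`.
#' @param path output JSON path.
#' @export
write_recovery_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
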