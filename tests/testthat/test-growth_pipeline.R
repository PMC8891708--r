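test_that("canonical specifications carry the published structure", {
  s1 <- make_model1_spec(); s2 <- make_model2_spec()
  expect_identical(count_parameters(s1), 35L)
  expect_identical(count_parameters(s2), 151L)
  expect_true(all(s1$base_terms$name %in% s2$base_terms$name))
  expect_length(gamma_names(s2), 36L)
  ## reduced random structures remain configurable
  s2r <- make_model2_spec(random_participant = 0, random_parcel = 0)
  expect_identical(count_parameters(s2r), 36L + 1L + 1L + 1L)
})

test_that("Bonferroni correction caps, validates, and is monotone", {
  expect_equal(bonferroni_adjust(0.340, 2), 0.680)
  expect_equal(bonferroni_adjust(0.006, 4), 0.024)
  expect_equal(bonferroni_adjust(0.9, 2), 1.0)
  expect_equal(bonferroni_adjust(1, 5), 1)
  p <- seq(0, 1, 0.05)
  expect_true(all(diff(bonferroni_adjust(p, 3)) >= 0))
  expect_true(all(bonferroni_adjust(p, 4) >= bonferroni_adjust(p, 2)))
  expect_error(bonferroni_adjust(-0.1, 2), "\\[0, 1\\]")
  expect_error(bonferroni_adjust(0.5, 0), "m must be")
  expect_error(bonferroni_adjust(0.5, 2.5), "m must be")
})

test_that("simple slopes reconstruct the published age-13 contrasts", {
  g <- reference_gamma()
  ## Self - Other slope for Social items in self parcels at age 13:
  ## 0.002 + 0.026 + 0.5 (0.003 - 0.006)
  expect_equal(simple_slope(g, "target_diff", "Social", "self"), 0.0265)
  ## Social - Academic slope for Self target in social parcels:
  ## 0.000 - 0.005 + 0.5 (0.003 - 0.014)
  expect_equal(simple_slope(g, "domain_diff", "Self", "social"), -0.0105)
  ## quadratic (curvature) components of the same contrasts
  expect_equal(simple_slope(g, "domain_diff", "Self", "social",
                            component = "quadratic"), 0.0015)
  expect_equal(simple_slope(g, "target_diff", "Social", "self",
                            component = "quadratic"), -0.0085)
  expect_error(slope_weights("target_diff", "Social", "visual"),
               "parcel_label")
  expect_error(slope_weights("target_diff", "Peer", "self"), "conditioning")
})

test_that("a model with no quadratic effects has an age-invariant slope", {
  g <- reference_gamma()
  g[grepl("^gamma_(2|5|9|11)0", names(g))] <- 0
  s13 <- simple_slope(g, "target_diff", "Social", "self", age = 13)
  s10 <- simple_slope(g, "target_diff", "Social", "self", age = 10)
  s16 <- simple_slope(g, "target_diff", "Social", "self", age = 16)
  expect_equal(s13, s10)
  expect_equal(s13, s16)
})

test_that("simple slope equals the finite-difference derivative of the contrast curve", {
  g <- reference_gamma()
  h <- 1e-5
  for (age in c(10, 13, 16)) {
    tr <- predict_trajectories(g, age_grid = c(age - h, age + h),
                               cells = data.frame(parcel_label = "self",
                                                  domain = "Social",
                                                  target = c("Self", "Other")))
    diff_curve <- tr$predicted[tr$target == "Self"] -
      tr$predicted[tr$target == "Other"]
    fd <- (diff_curve[2] - diff_curve[1]) / (2 * h)
    an <- simple_slope(g, "target_diff", "Social", "self", age = age)
    expect_equal(an, fd, tolerance = 1e-7)
  }
})

test_that("trajectory prediction honours the intercept and linearity identities", {
  g <- reference_gamma()
  cells <- expand.grid(parcel_label = "control",
                       domain = c("Academic", "Social"),
                       target = c("Other", "Self"), stringsAsFactors = FALSE)
  tr <- predict_trajectories(g, age_grid = 13, cells = cells)
  ## all-cells average at age 13 in control parcels is the intercept exactly
  expect_equal(mean(tr$predicted), unname(g["gamma_000"]))
  ## Self - Other difference equals the target-contrast prediction everywhere
  grid <- seq(9, 17, 1)
  tr2 <- predict_trajectories(g, age_grid = grid,
                              cells = expand.grid(parcel_label = "self",
                                                  domain = "Social",
                                                  target = c("Other", "Self"),
                                                  stringsAsFactors = FALSE))
  diffc <- tr2$predicted[tr2$target == "Self"] -
    tr2$predicted[tr2$target == "Other"]
  wts <- vapply(grid, function(a) {
    x_self <- parcelgrowth:::.prediction_row(names(g), "self", "Social",
                                             "Self", a - 13)
    x_oth <- parcelgrowth:::.prediction_row(names(g), "self", "Social",
                                            "Other", a - 13)
    sum((x_self - x_oth) * g)
  }, 0)
  expect_equal(diffc, wts)
  ## quadratic curves have constant second differences on an even grid
  tr3 <- predict_trajectories(g, age_grid = seq(9, 17, 0.5),
                              cells = data.frame(parcel_label = "social",
                                                 domain = "Social",
                                                 target = "Self"))
  d2 <- diff(tr3$predicted, differences = 2)
  expect_equal(max(d2) - min(d2), 0, tolerance = 1e-12)
  ## extrapolation warns but still predicts
  expect_warning(predict_trajectories(g, age_grid = c(5, 13)), "extrapolat")
})

test_that("the end-to-end analysis selects the target-moderated model when target effects exist", {
  spec_gen <- growth_model_spec(
    "gen", 0:11, list(re_block("participant", 0), re_block("parcel", 0)))
  truth <- reference_gamma()
  truth["gamma_601.self"] <- 0.255  # strong target moderation
  cfg <- simulation_config(truth, participant_cov = matrix(0.04),
                           parcel_cov = matrix(0.09), residual_var = 0.4,
                           design = reduced_cohort_design(), seed = 71)
  obs <- simulate_observations(cfg, spec_gen)
  res <- run_growth_analysis(obs, config = list(
    model1_spec = make_model1_spec(random_participant = 0, random_parcel = 0),
    model2_spec = make_model2_spec(random_participant = 0, random_parcel = 0),
    df_method = "normal"))
  expect_identical(res$selected, "model2")
  expect_lt(res$comparison$delta_aic, -2)
  expect_equal(nrow(res$coefficients), 36L)
  expect_identical(res$manifest$n_params, c(model1 = 21L, model2 = 39L))
  expect_s3_class(res$ledger, "data.frame")
  expect_equal(nrow(res$ledger), 12L)
  expect_true(all(res$ledger$adjusted_p >= res$ledger$p - 1e-15))
  ## the planted moderation is recovered as significant
  h2 <- res$ledger[res$ledger$name == "Age x Target x Label (self)", ]
  expect_true(is.finite(h2$p))
  tgt <- res$coefficients[res$coefficients$term == "gamma_601.self", ]
  expect_lt(abs(tgt$estimate - 0.255), 0.1)

  dir <- withr::local_tempdir()
  write_growth_results(res, dir)
  expect_true(all(file.exists(file.path(dir, c("coefficients.tsv",
                                               "hypothesis_ledger.tsv",
                                               "trajectories.tsv",
                                               "comparison.json",
                                               "manifest.json")))))
})

test_that("without target effects the domain-only model wins and extra terms sit near zero", {
  spec_gen <- growth_model_spec(
    "gen", 0:11, list(re_block("participant", 0), re_block("parcel", 0)))
  truth <- reference_gamma()
  truth[grepl("^gamma_(6|7|8|9|10|11)", names(truth))] <- 0
  cfg <- simulation_config(truth, participant_cov = matrix(0.04),
                           parcel_cov = matrix(0.09), residual_var = 0.4,
                           design = reduced_cohort_design(), seed = 72)
  obs <- simulate_observations(cfg, spec_gen)
  res <- run_growth_analysis(obs, config = list(
    model1_spec = make_model1_spec(random_participant = 0, random_parcel = 0),
    model2_spec = make_model2_spec(random_participant = 0, random_parcel = 0),
    df_method = "normal"))
  expect_identical(res$selected, "model1")
  m2 <- res$fits$model2
  extra <- setdiff(names(m2$gamma), gamma_names(make_model1_spec()))
  z <- m2$gamma[extra] / sqrt(diag(m2$gamma_cov)[extra])
  expect_true(mean(abs(z) < 2.6) > 0.9)
})

test_that("relabeling parcels leaves the fitted coefficients unchanged", {
  spec <- growth_model_spec(
    "toy", 0:5, list(re_block("participant", 0), re_block("parcel", c(0, 1))))
  cfg <- simulation_config(reference_gamma()[gamma_names(spec)],
                           participant_cov = matrix(0.04),
                           parcel_cov = diag(c(0.09, 0.01)),
                           residual_var = 0.4,
                           design = reduced_cohort_design(), seed = 73)
  obs <- simulate_observations(cfg, spec)
  ## permute parcel ids (bijectively) keeping labels attached
  ids <- sort(unique(obs$parcel_id))
  set.seed(2); new_ids <- sample(ids)
  obs2 <- obs
  obs2$parcel_id <- new_ids[match(obs$parcel_id, ids)]
  f1 <- fit_lmm(build_design(obs, spec))
  f2 <- fit_lmm(build_design(obs2, spec))
  expect_equal(f1$gamma, f2$gamma, tolerance = 1e-6)
})

test_that("hypothesis ledger covers the published contrast set with family sizes", {
  led <- parcelgrowth:::.hypothesis_rows()
  ids <- vapply(led, `[[`, "", "id")
  expect_equal(table(ids)[c("H1", "H2", "H3A", "H3B")],
               c(H1 = 2L, H2 = 2L, H3A = 4L, H3B = 4L), ignore_attr = TRUE)
  ms <- vapply(led, `[[`, 0, "m")
  expect_true(all(ms[ids %in% c("H1", "H2")] == 2))
  expect_true(all(ms[ids %in% c("H3A", "H3B")] == 4))
  coefs <- unlist(lapply(led, `[[`, "coef"))
  expect_setequal(coefs, c("gamma_401.soc", "gamma_501.soc", "gamma_801.self",
                           "gamma_901.self", "gamma_1001.soc",
                           "gamma_1101.soc", "gamma_1001.self",
                           "gamma_1101.self"))
})

test_that("per-parcel predicted curves average to fixed curve plus mean deviation", {
  spec <- growth_model_spec(
    "toy", 0:5, list(re_block("participant", 0), re_block("parcel", c(0, 1))))
  cfg <- simulation_config(reference_gamma()[gamma_names(spec)],
                           participant_cov = matrix(0.04),
                           parcel_cov = diag(c(0.09, 0.01)),
                           residual_var = 0.4,
                           design = reduced_cohort_design(), seed = 74)
  obs <- simulate_observations(cfg, spec)
  fit <- fit_lmm(build_design(obs, spec), blups = TRUE)
  labs <- tapply(obs$parcel_label, obs$parcel_id, `[`, 1)
  grid <- seq(9, 17, 2)
  tr <- predict_trajectories(fit, age_grid = grid, blups = TRUE,
                             parcel_labels = labs)
  pc <- attr(tr, "parcel_curves")
  expect_false(is.null(pc))
  cell <- pc[pc$parcel_label == "control" & pc$domain == "Social" &
               pc$target == "Self", ]
  avg <- tapply(cell$predicted, cell$age, mean)
  fixed <- tr$predicted[tr$parcel_label == "control" & tr$domain == "Social" &
                          tr$target == "Self"]
  ctrl_ids <- names(labs)[labs == "control"]
  u <- fit$blups$parcel[ctrl_ids, , drop = FALSE]
  mean_dev <- mean(u[, 1]) + mean(u[, 2]) * (grid - 13)
  expect_equal(as.numeric(avg), fixed + mean_dev, tolerance = 1e-10)
})

test_that("the external reproduction entry point validates its input contract", {
  expect_error(reproduce_published_fit(file.path(tempdir(), "no-such.tsv")),
               "deposited")
  ## a table in the deposited layout is accepted and routed through the
  ## full pipeline (tiny synthetic stand-in, reduced random structure)
  spec <- growth_model_spec(
    "toy", 0:11, list(re_block("participant", 0), re_block("parcel", 0)))
  cfg <- simulation_config(reference_gamma(), participant_cov = matrix(0.04),
                           parcel_cov = matrix(0.09), residual_var = 0.4,
                           design = reduced_cohort_design(), seed = 75)
  obs <- simulate_observations(cfg, spec)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_observations(obs, p)
  res <- reproduce_published_fit(p, config = list(
    model1_spec = make_model1_spec(random_participant = 0, random_parcel = 0),
    model2_spec = make_model2_spec(random_participant = 0, random_parcel = 0),
    df_method = "normal"))
  expect_s3_class(res, "growth_analysis")
  expect_equal(res$manifest$n_obs, nrow(obs))
})
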