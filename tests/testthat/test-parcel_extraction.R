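# Standard 2-parcel box geometry reused across extraction tests.
two_parcel_geometry <- list(
  "5" = list(lo = c(2, 2, 2), hi = c(5, 5, 5)),
  "9" = list(lo = c(8, 3, 3), hi = c(12, 8, 6)))

test_that("grid alignment is validated exactly, naming the differing attribute", {
  fx <- generate_nifti_fixture(c(16, 12, 10), two_parcel_geometry,
                               c(1, -1), seed = 1)
  ok <- validate_alignment(fx$image, fx$atlas)
  expect_true(ok$ok)
  bad_shape <- array(0, dim = c(17, 12, 10))
  r <- validate_alignment(bad_shape, fx$atlas)
  expect_false(r$ok)
  expect_match(r$mismatches, "shape")
  resampled <- RNifti::asNifti(array(0, dim = c(16, 12, 10)))
  RNifti::pixdim(resampled) <- c(2, 2, 2)
  r <- validate_alignment(resampled, fx$atlas)
  expect_false(r$ok)
  expect_match(r$mismatches, "spacing")
  expect_error(extract_parcel_means(bad_shape, fx$atlas), "mismatch")
})

test_that("parcel means equal a brute-force voxel loop, with NaN voxels dropped", {
  set.seed(33)
  fx <- generate_nifti_fixture(c(16, 12, 10), two_parcel_geometry,
                               c(0.7, -0.4), noise_sd = 0.5, seed = 2,
                               pixdim = c(1, 1, 1))
  img <- array(as.numeric(fx$image), dim = dim(fx$image))
  img[3, 3, 3] <- NaN  # inside parcel 5
  res <- extract_parcel_means(img, fx$atlas)
  lab <- array(as.integer(fx$atlas), dim = dim(fx$atlas))
  for (id in c(5L, 9L)) {
    vox <- img[lab == id]
    expect_equal(res$raw_mean[res$parcel_id == id],
                 mean(vox[is.finite(vox)]), tolerance = 1e-12)
  }
  ## constant field -> exact mean; whole-volume parcel -> global mean
  const <- array(7, dim = dim(img))
  res2 <- extract_parcel_means(const, fx$atlas)
  expect_equal(res2$raw_mean, c(7, 7))
  one <- array(1L, dim = c(4, 4, 4))
  vals <- array(rnorm(64), dim = c(4, 4, 4))
  expect_equal(extract_parcel_means(vals, one)$raw_mean, mean(vals))
  ## simple worked values: {1, 2, 3, NaN} averages to 2
  a <- array(0L, c(4, 1, 1)); a[1:4] <- 1L
  v <- array(c(1, 2, 3, NaN), c(4, 1, 1))
  expect_equal(extract_parcel_means(v, a)$raw_mean, 2)
  ## all-non-finite parcel -> NA with warning
  v[1:4] <- NaN
  expect_warning(r3 <- extract_parcel_means(v, a), "no finite")
  expect_true(is.na(r3$raw_mean))
})

test_that("within-parcel standardization divides by the pooled sample SD", {
  est <- data.frame(participant_id = rep(c("a", "b", "c"), 2),
                    wave = 1L,
                    domain = "Social", target = "Self",
                    parcel_id = rep(c(1L, 2L), each = 3),
                    raw_mean = c(-2, 0, 2, 5, 5, 5))
  expect_warning(out <- standardize_within_parcel(est), "excluded")
  ## parcel 1: SD(n-1) of {-2, 0, 2} is 2 -> {-1, 0, 1}; parcel 2 constant ->
  ## dropped
  expect_equal(out$std_value, c(-1, 0, 1))
  expect_true(all(out$parcel_id == 1L))
  ## idempotent up to the recomputed SD: second pass leaves unit-SD parcels
  again <- out
  again$raw_mean <- again$std_value
  again$std_value <- NULL
  out2 <- standardize_within_parcel(again)
  expect_equal(out2$std_value, out$std_value)
})

test_that("outlier exclusion removes exactly the rows beyond z grand SDs", {
  set.seed(44)
  est <- data.frame(parcel_id = rep(1:10, each = 20),
                    std_value = rnorm(200))
  est$std_value[37] <- 10
  res <- exclude_outliers(est, z_threshold = 3)
  ## brute-force reference
  gm <- mean(est$std_value); gs <- sd(est$std_value)
  manual <- which(abs(est$std_value - gm) > 3 * gs)
  expect_identical(sort(as.integer(rownames(res$excluded))), manual)
  expect_true(37L %in% manual)
  expect_equal(res$report$n_excluded, length(manual))
  expect_equal(res$report$fraction, length(manual) / 200)
  ## all values within 1 SD -> nothing removed
  tight <- data.frame(std_value = seq(-0.5, 0.5, length.out = 50))
  expect_equal(exclude_outliers(tight)$report$n_excluded, 0L)
  ## monotonicity: z = 4 removals are a subset of z = 3 removals
  r3 <- exclude_outliers(est, 3); r4 <- exclude_outliers(est, 4)
  expect_true(all(rownames(r4$excluded) %in% rownames(r3$excluded)))
  ## deterministic: identical rerun
  expect_identical(exclude_outliers(est, 3)$report, r3$report)
})

test_that("assembly joins labels and ages, counts rows, and lists offenders", {
  est <- expand.grid(participant_id = c("a", "b"), wave = 1L,
                     domain = c("Academic", "Social"),
                     target = c("Other", "Self"),
                     parcel_id = 1:3, stringsAsFactors = FALSE)
  est$std_value <- rnorm(nrow(est))
  labels <- data.frame(parcel_id = 1:3,
                       parcel_label = c("self", "social", "control"))
  demo <- data.frame(participant_id = c("a", "b"), wave = 1L,
                     age_years = c(10.5, 15.2))
  obs <- assemble_observations(est, labels, demo)
  expect_equal(nrow(obs), 2 * 1 * 4 * 3)
  expect_equal(obs$age_c, obs$age_years - 13)
  ## one excluded row propagates to the row count
  obs2 <- assemble_observations(est[-5, ], labels, demo)
  expect_equal(nrow(obs2), 23L)
  expect_error(assemble_observations(est, labels[-2, ], demo), "parcel")
  expect_error(assemble_observations(est, labels, demo[-1, ]),
               "without an age")
})

test_that("full extraction chain round-trips through fixture volumes", {
  geom <- list("1" = list(lo = c(1, 1, 1), hi = c(4, 4, 4)),
               "2" = list(lo = c(6, 1, 1), hi = c(9, 4, 4)),
               "3" = list(lo = c(1, 6, 1), hi = c(4, 9, 4)))
  meta <- expand.grid(participant_id = c("a", "b"), wave = 1L,
                      domain = c("Academic", "Social"),
                      target = c("Other", "Self"), stringsAsFactors = FALSE)
  set.seed(9)
  means <- matrix(rnorm(nrow(meta) * 3), nrow(meta), 3)
  fxs <- lapply(seq_len(nrow(meta)), function(i)
    generate_nifti_fixture(c(10, 10, 5), geom, means[i, ], noise_sd = 0,
                           seed = i))
  est <- extract_cohort(lapply(fxs, `[[`, "image"), fxs[[1]]$atlas, meta)
  expect_equal(nrow(est), nrow(meta) * 3)
  ## noise-free: extracted means equal planted means exactly
  expect_equal(matrix(est$raw_mean, nrow(meta), 3, byrow = TRUE), means,
               ignore_attr = TRUE, tolerance = 1e-12)
  std <- standardize_within_parcel(est)
  for (k in 1:3)
    expect_equal(sd(std$std_value[std$parcel_id == k]), 1, tolerance = 1e-12)
  kept <- exclude_outliers(std)$retained
  labels <- data.frame(parcel_id = 1:3,
                       parcel_label = c("control", "self", "social"))
  demo <- data.frame(participant_id = c("a", "b"), wave = 1L,
                     age_years = c(11, 15))
  obs <- assemble_observations(kept, labels, demo)
  expect_s3_class(obs, "data.frame")
  expect_equal(nrow(obs), nrow(kept))
})

test_that("fixture generation rejects overlapping parcels and respects the seed", {
  overlap <- list("1" = list(lo = c(1, 1, 1), hi = c(4, 4, 4)),
                  "2" = list(lo = c(3, 3, 3), hi = c(6, 6, 6)))
  expect_error(generate_nifti_fixture(c(8, 8, 8), overlap, c(1, 2)),
               "overlap")
  f1 <- generate_nifti_fixture(c(16, 12, 10), two_parcel_geometry, c(1, -1),
                               noise_sd = 0.3, seed = 5)
  f2 <- generate_nifti_fixture(c(16, 12, 10), two_parcel_geometry, c(1, -1),
                               noise_sd = 0.3, seed = 5)
  expect_identical(as.numeric(f1$image), as.numeric(f2$image))
  ## noisy extraction approaches the planted mean within the CLT bound
  res <- extract_parcel_means(f1$image, f1$atlas)
  nv <- res$n_voxels
  expect_true(all(abs(res$raw_mean - c(1, -1)) <= 3 * 0.3 / sqrt(nv)))
})

test_that("parcel labels and exclusion reports serialize to their formats", {
  labels <- data.frame(parcel_id = 1:4,
                       parcel_label = c("self", "social", "control",
                                        "control"))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_parcel_labels(labels, p)
  expect_equal(read_parcel_labels(p), labels)
  rep <- exclude_outliers(data.frame(std_value = rnorm(50)))$report
  j <- withr::local_tempfile(fileext = ".json")
  write_exclusion_report(rep, j)
  back <- jsonlite::read_json(j)
  expect_equal(back$n_total, 50L)
  expect_equal(back$threshold, 3)
})
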