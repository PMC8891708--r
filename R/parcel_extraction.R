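## Parcel-level signal extraction and harmonization: mean-over-parcel
## extraction against an integer-labeled atlas, within-parcel
## standardization, and grand-mean outlier exclusion.

.as_volume <- function(x) {
  if (is.character(x)) x <- RNifti::readNifti(x)
  if (!(is.array(x) && length(dim(x)) == 3L))
    stop("expected a 3D volume (array, niftiImage, or NIfTI file path)")
  x
}

.grid_meta <- function(x) {
  pd <- tryCatch(RNifti::pixdim(x), error = function(e) NULL)
  if (is.null(pd) || !length(pd)) pd <- rep(1, 3)
  list(shape = dim(x), pixdim = round(pd[seq_len(3)], 6))
}

#' Check that an image and an atlas share a voxel grid
#'
#' Passes only when shape and voxel spacing match exactly; no implicit
#' resampling is ever performed.
#'
#' @param image a 3D volume (array, `niftiImage`, or file path).
#' @param atlas the integer-labeled parcellation volume on the same grid.
#' @return list with `ok` (logical) and `mismatches` (character vector naming
#'   the differing attributes).
#' @export
validate_alignment <- function(image, atlas) {
  mi <- .grid_meta(.as_volume(image))
  ma <- .grid_meta(.as_volume(atlas))
  mism <- character(0)
  if (!identical(unname(mi$shape), unname(ma$shape)))
    mism <- c(mism, sprintf("shape (image %s vs atlas %s)",
                            paste(mi$shape, collapse = "x"),
                            paste(ma$shape, collapse = "x")))
  else if (!isTRUE(all.equal(unname(mi$pixdim), unname(ma$pixdim))))
    mism <- c(mism, sprintf("voxel spacing (image %s vs atlas %s)",
                            paste(mi$pixdim, collapse = "x"),
                            paste(ma$pixdim, collapse = "x")))
  list(ok = length(mism) == 0L, mismatches = mism)
}

#' Extract per-parcel mean signal from one volume
#'
#' Arithmetic mean of the image values over each parcel's voxels (label 0 is
#' background and excluded). Non-finite voxels are dropped from both the
#' numerator and denominator; a parcel with no finite voxel yields `NA` with
#' a warning.
#'
#' @param image a 3D volume aligned with `atlas`.
#' @param atlas integer-labeled parcellation volume.
#' @return data.frame with columns `parcel_id`, `raw_mean`, `n_voxels`
#'   (finite voxels used).
#' @export
extract_parcel_means <- function(image, atlas) {
  image <- .as_volume(image); atlas <- .as_volume(atlas)
  va <- validate_alignment(image, atlas)
  if (!va$ok) stop("image/atlas grid mismatch: ",
                   paste(va$mismatches, collapse = "; "))
  lab <- as.integer(round(as.vector(atlas)))
  val <- as.numeric(as.vector(image))
  keep <- lab != 0L
  lab <- lab[keep]; val <- val[keep]
  ids <- sort(unique(lab))
  fin <- is.finite(val)
  sums <- rowsum(ifelse(fin, val, 0), lab)
  cnts <- rowsum(as.numeric(fin), lab)
  m <- as.numeric(sums) / as.numeric(cnts)
  m[cnts == 0] <- NA_real_
  if (any(cnts == 0))
    warning("parcel(s) with no finite voxels: ",
            paste(ids[cnts == 0], collapse = ", "))
  data.frame(parcel_id = ids, raw_mean = m, n_voxels = as.integer(cnts))
}

#' Extract parcel means for a whole cohort
#'
#' Applies [extract_parcel_means()] to one contrast volume per session and
#' condition and binds the results into a long table.
#'
#' @param images list of 3D volumes (or file paths), one per row of `meta`.
#' @param atlas the shared parcellation volume.
#' @param meta data.frame with columns `participant_id`, `wave`, `domain`,
#'   `target` describing each image.
#' @return data.frame with columns `participant_id`, `wave`, `domain`,
#'   `target`, `parcel_id`, `raw_mean`.
#' @export
extract_cohort <- function(images, atlas, meta) {
  req <- c("participant_id", "wave", "domain", "target")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("meta lacks column(s): ", paste(miss, collapse = ", "))
  if (length(images) != nrow(meta))
    stop("images and meta must have one entry per session-condition")
  atlas <- .as_volume(atlas)
  out <- vector("list", length(images))
  for (i in seq_along(images)) {
    pm <- extract_parcel_means(images[[i]], atlas)
    out[[i]] <- data.frame(meta[i, req, drop = FALSE], pm,
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Standardize estimates within parcel
#'
#' Divides each parcel's estimates by that parcel's sample standard deviation
#' (denominator n - 1) computed over all sessions and conditions (pooling
#' `"parcel"`, the default) or within each condition cell (`"cell"`). No mean
#' centering is applied, so condition contrasts are preserved. Parcels (or
#' cells) with fewer than two finite values or zero variance are excluded
#' with a warning.
#'
#' @param estimates long table from [extract_cohort()] (needs `parcel_id` and
#'   `raw_mean`; `domain`/`target` required for cell-wise pooling).
#' @param pooling `"parcel"` or `"cell"`.
#' @return `estimates` with an added `std_value` column, excluded rows
#'   dropped.
#' @export
standardize_within_parcel <- function(estimates, pooling = c("parcel", "cell")) {
  pooling <- match.arg(pooling)
  if (!all(c("parcel_id", "raw_mean") %in% names(estimates)))
    stop("estimates needs columns parcel_id and raw_mean")
  key <- if (pooling == "parcel") as.character(estimates$parcel_id)
         else paste(estimates$parcel_id, estimates$domain, estimates$target,
                    sep = "\r")
  keep <- is.finite(estimates$raw_mean)
  sds <- tapply(estimates$raw_mean[keep], key[keep], stats::sd)
  ns <- tapply(estimates$raw_mean[keep], key[keep], length)
  bad <- names(sds)[!is.finite(sds) | sds == 0 | ns < 2]
  if (length(bad)) {
    warning(length(bad), " parcel group(s) excluded (zero or undefined SD): ",
            paste(utils::head(sub("\r.*", "", bad), 10), collapse = ", "),
            if (length(bad) > 10) ", ..." else "")
  }
  ok <- keep & !(key %in% bad)
  est <- estimates[ok, , drop = FALSE]
  est$std_value <- est$raw_mean / as.numeric(sds[key[ok]])
  est
}

#' Exclude grand-mean outliers
#'
#' Removes standardized observations farther than `z_threshold` grand
#' standard deviations from the grand mean, both computed once over all
#' standardized observations.
#'
#' @param estimates table with a `std_value` column.
#' @param z_threshold threshold in grand SD units (default 3).
#' @return list with `retained`, `excluded` (the dropped rows), and `report`
#'   (`n_total`, `n_excluded`, `fraction`, `threshold`, `grand_mean`,
#'   `grand_sd`).
#' @export
exclude_outliers <- function(estimates, z_threshold = 3) {
  if (!"std_value" %in% names(estimates))
    stop("estimates needs a std_value column (run standardize_within_parcel)")
  v <- estimates$std_value
  gm <- mean(v); gs <- stats::sd(v)
  out <- abs(v - gm) > z_threshold * gs
  list(retained = estimates[!out, , drop = FALSE],
       excluded = estimates[out, , drop = FALSE],
       report = list(n_total = length(v), n_excluded = sum(out),
                     fraction = sum(out) / length(v),
                     threshold = z_threshold, grand_mean = gm, grand_sd = gs))
}

#' @rdname exclude_outliers
#' @param report the `report` element of an [exclude_outliers()] result.
#' @param path output path for the JSON exclusion report.
#' @export
write_exclusion_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Assemble the observation table
#'
#' Joins retained standardized estimates to parcel categories and session
#' ages, producing the long-format table the growth models consume.
#'
#' @param estimates retained rows from [exclude_outliers()] (needs
#'   `participant_id`, `wave`, `domain`, `target`, `parcel_id`, `std_value`).
#' @param labels data.frame with columns `parcel_id` and `parcel_label`
#'   (values in control/self/social), one row per parcel.
#' @param demographics data.frame with columns `participant_id`, `wave`,
#'   `age_years`.
#' @return a validated observation table (see [validate_observations()]).
#' @export
assemble_observations <- function(estimates, labels, demographics) {
  if (anyDuplicated(labels$parcel_id))
    stop("duplicate parcel_id in label table")
  miss_lab <- setdiff(unique(estimates$parcel_id), labels$parcel_id)
  if (length(miss_lab))
    stop("parcel(s) without a category: ", paste(miss_lab, collapse = ", "))
  bad_lab <- setdiff(unique(as.character(labels$parcel_label)), .parcel_labels)
  if (length(bad_lab))
    stop("unknown parcel_label level(s): ", paste(bad_lab, collapse = ", "))
  dk <- paste(demographics$participant_id, demographics$wave, sep = "\r")
  if (anyDuplicated(dk)) stop("duplicate (participant, wave) in demographics")
  ek <- paste(estimates$participant_id, estimates$wave, sep = "\r")
  miss_dem <- setdiff(unique(ek), dk)
  if (length(miss_dem))
    stop("session(s) without an age: ",
         paste(gsub("\r", " wave ", miss_dem), collapse = ", "))
  age <- demographics$age_years[match(ek, dk)]
  obs <- data.frame(
    participant_id = as.character(estimates$participant_id),
    wave = as.integer(estimates$wave),
    age_years = age, age_c = age - 13,
    domain = as.character(estimates$domain),
    target = as.character(estimates$target),
    parcel_id = as.integer(estimates$parcel_id),
    parcel_label = as.character(
      labels$parcel_label[match(estimates$parcel_id, labels$parcel_id)]),
    bold = estimates$std_value, stringsAsFactors = FALSE)
  validate_observations(obs)
  obs
}

#' Read / write a parcel-category table
#'
#' Tab-separated values with header `parcel_id  parcel_label`.
#'
#' @param labels data.frame with `parcel_id`, `parcel_label`.
#' @param path file path.
#' @export
write_parcel_labels <- function(labels, path) {
  utils::write.table(labels[, c("parcel_id", "parcel_label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parcel_labels
#' @export
read_parcel_labels <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("parcel_id", "parcel_label") %in% names(d)))
    stop("label file needs columns parcel_id and parcel_label")
  d
}
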