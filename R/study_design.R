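#' @importFrom stats setNames
NULL

## Canonical term table for the domain-by-target polynomial growth models.
## Each within-cell growth term is a product over {1, age_c, age_c^2, domain,
## target}; `beta` is the coefficient-equation index used in the gamma naming
## scheme (gamma_<beta>00 for control parcels, gamma_<beta>01.self/.soc for the
## label-moderation columns).
.term_table <- data.frame(
  beta    = 0:11,
  name    = c("Intercept", "Age", "Age^2", "Domain",
              "Age x Domain", "Age^2 x Domain",
              "Target", "Target x Domain",
              "Age x Target", "Age^2 x Target",
              "Age x Target x Domain", "Age^2 x Target x Domain"),
  age_pow = c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 0L, 1L, 2L, 1L, 2L),
  domain  = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE,
              FALSE, TRUE, FALSE, FALSE, TRUE, TRUE),
  target  = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
              TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE
)

#' Growth-model term table
#'
#' Returns the canonical table of within-cell growth terms used by the two
#' domain-by-target growth models. Each row is a product of centered age
#' powers and the +/-0.5-coded domain and target factors; `beta` is the index
#' used in the `gamma_<beta>...` coefficient naming scheme.
#'
#' @param beta integer vector of term indices to return (default all 12).
#' @return a data.frame with columns `beta`, `name`, `age_pow`, `domain`,
#'   `target`.
#' @export
growth_terms <- function(beta = 0:11) {
  if (!all(beta %in% .term_table$beta))
    stop("unknown term indices: ", paste(setdiff(beta, .term_table$beta), collapse = ", "))
  .term_table[match(beta, .term_table$beta), , drop = FALSE]
}

#' Center age at 13 years
#'
#' Ages are centered at 13 years so that the model intercept is the expected
#' response of a 13-year-old; the quadratic growth term is the square of the
#' centered value.
#'
#' @param age_years numeric vector of ages in years.
#' @return `age_years - 13`.
#' @export
center_age <- function(age_years) {
  if (!is.numeric(age_years) || any(!is.finite(age_years)))
    stop("age_years must be finite numeric")
  age_years - 13
}

#' Factor codes for the evaluation design
#'
#' The two task factors are coded -0.5/+0.5 (Academic/Social for domain,
#' Other/Self for target) so that the intercept averages over factor levels.
#'
#' @param domain character vector with levels "Academic"/"Social".
#' @param target character vector with levels "Other"/"Self".
#' @return named list with numeric vectors `domain` and `target`.
#' @export
code_condition <- function(domain, target) {
  list(domain = .code_factor(domain, c(Academic = -0.5, Social = 0.5), "domain"),
       target = .code_factor(target, c(Other = -0.5, Self = 0.5), "target"))
}

.code_factor <- function(x, map, what) {
  bad <- setdiff(unique(as.character(x)), names(map))
  if (length(bad))
    stop("unknown ", what, " level(s): ", paste(bad, collapse = ", "),
         "; valid levels: ", paste(names(map), collapse = ", "))
  unname(map[as.character(x)])
}

.parcel_labels <- c("control", "self", "social")

#' Construct a random-effects block
#'
#' @param grouping `"participant"` or `"parcel"`.
#' @param terms integer vector of term (`beta`) indices receiving group
#'   deviations.
#' @param covariance `"full"` (unstructured, q(q+1)/2 parameters) or
#'   `"diagonal"` (q parameters).
#' @return an object of class `re_block`.
#' @export
re_block <- function(grouping = c("participant", "parcel"), terms,
                     covariance = c("full", "diagonal")) {
  grouping <- match.arg(grouping)
  covariance <- match.arg(covariance)
  terms <- as.integer(terms)
  if (length(terms) < 1L) stop("a random-effects block needs at least one term")
  if (anyDuplicated(terms)) stop("duplicate terms in random-effects block")
  structure(list(grouping = grouping, terms = terms, covariance = covariance),
            class = "re_block")
}

#' Construct a growth-model specification
#'
#' A specification is an ordered list of within-cell growth terms, a flag that
#' every term is crossed with the parcel-label indicators (treatment coding,
#' control as reference), and the random-effects blocks for the two crossed
#' grouping factors.
#'
#' @param name model name.
#' @param base_terms integer vector of term (`beta`) indices (see
#'   [growth_terms()]).
#' @param random_blocks list of [re_block()] objects.
#' @param label_moderation logical; cross every base term with the self/social
#'   label indicators (default `TRUE`).
#' @return an object of class `growth_model_spec`.
#' @export
growth_model_spec <- function(name, base_terms, random_blocks = list(),
                              label_moderation = TRUE) {
  terms <- growth_terms(base_terms)
  for (b in random_blocks) {
    if (!inherits(b, "re_block")) stop("random_blocks must be re_block objects")
    if (!all(b$terms %in% terms$beta))
      stop("random-effects block references terms absent from base_terms: ",
           paste(setdiff(b$terms, terms$beta), collapse = ", "))
  }
  structure(list(name = name, base_terms = terms,
                 random_blocks = random_blocks,
                 label_moderation = isTRUE(label_moderation)),
            class = "growth_model_spec")
}

#' @export
print.growth_model_spec <- function(x, ...) {
  cat("Growth model spec:", x$name, "\n")
  cat("  base terms (", nrow(x$base_terms), "): ",
      paste(x$base_terms$name, collapse = ", "), "\n", sep = "")
  cat("  label moderation:", x$label_moderation,
      "-> fixed columns:", .n_fixed(x), "\n")
  for (b in x$random_blocks)
    cat("  random (", b$grouping, ", ", b$covariance, "): ",
        paste(growth_terms(b$terms)$name, collapse = ", "), "\n", sep = "")
  cat("  parameters:", count_parameters(x), "\n")
  invisible(x)
}

.n_fixed <- function(spec) {
  nrow(spec$base_terms) * if (spec$label_moderation) 3L else 1L
}

#' Count estimated parameters of a growth model
#'
#' Total model degrees of freedom: one per fixed-effect column, q(q+1)/2 per
#' full-covariance random block (q per diagonal block), plus one residual
#' variance. Additive over blocks and invariant to term ordering.
#'
#' @param spec a [growth_model_spec()].
#' @return integer parameter count.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "growth_model_spec"))
  p <- .n_fixed(spec)
  for (b in spec$random_blocks) {
    q <- length(b$terms)
    p <- p + if (b$covariance == "full") q * (q + 1L) / 2L else q
  }
  as.integer(p + 1L)
}

## gamma column names for one base term: control column plus the two
## label-moderation columns (treatment coding, control reference).
.gamma_names <- function(beta, label_moderation = TRUE) {
  base <- paste0("gamma_", beta, "00")
  if (!label_moderation) return(base)
  c(base, paste0("gamma_", beta, "01.self"), paste0("gamma_", beta, "01.soc"))
}

#' Fixed-effect column names of a specification
#'
#' @param spec a [growth_model_spec()].
#' @return character vector of `gamma_*` column names, one per fixed effect.
#' @export
gamma_names <- function(spec) {
  stopifnot(inherits(spec, "growth_model_spec"))
  unlist(lapply(spec$base_terms$beta, .gamma_names, spec$label_moderation))
}

## Evaluate the base covariate of each term for every observation row.
.term_covariates <- function(obs, terms) {
  codes <- code_condition(obs$domain, obs$target)
  out <- matrix(NA_real_, nrow(obs), nrow(terms))
  for (i in seq_len(nrow(terms))) {
    v <- rep(1, nrow(obs))
    if (terms$age_pow[i] > 0) v <- v * obs$age_c^terms$age_pow[i]
    if (terms$domain[i]) v <- v * codes$domain
    if (terms$target[i]) v <- v * codes$target
    out[, i] <- v
  }
  colnames(out) <- terms$name
  out
}

#' Validate an observation table
#'
#' Checks the long-format parcel-level table: required columns, factor levels,
#' exact age centering, finite responses, and uniqueness of
#' (participant, wave, domain, target, parcel) keys.
#'
#' @param obs a data.frame (see [assemble_observations()]).
#' @return `obs`, invisibly, on success; otherwise an error.
#' @export
validate_observations <- function(obs) {
  req <- c("participant_id", "wave", "age_years", "age_c", "domain", "target",
           "parcel_id", "parcel_label", "bold")
  miss <- setdiff(req, names(obs))
  if (length(miss)) stop("observation table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(obs) == 0L) stop("observation table is empty")
  if (any(!is.finite(obs$age_years))) stop("non-finite age_years")
  if (max(abs(obs$age_c - (obs$age_years - 13))) > 0)
    stop("age_c must equal age_years - 13 exactly")
  code_condition(obs$domain, obs$target)  # validates levels
  bad_lab <- setdiff(unique(as.character(obs$parcel_label)), .parcel_labels)
  if (length(bad_lab))
    stop("unknown parcel_label level(s): ", paste(bad_lab, collapse = ", "))
  if (any(!is.finite(obs$bold))) stop("non-finite bold response(s)")
  key <- paste(obs$participant_id, obs$wave, obs$domain, obs$target,
               obs$parcel_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (participant, wave, domain, target, parcel) rows")
  invisible(obs)
}

#' Build fixed and random design matrices
#'
#' Realizes the coefficient-equation decomposition: each within-cell growth
#' term contributes three fixed columns (control/base, crossed with the self
#' indicator, crossed with the social indicator), and each random block an
#' incidence design mapping observations to group levels with the term
#' covariates as per-observation values.
#'
#' @param obs a validated observation table.
#' @param spec a [growth_model_spec()].
#' @return an object of class `design_matrices` with elements `X` (dense fixed
#'   matrix, `gamma_*` column names), `blocks` (per random block: sparse `Z`,
#'   group levels, term indices), and `y` (the response).
#' @export
build_design <- function(obs, spec) {
  stopifnot(inherits(spec, "growth_model_spec"))
  validate_observations(obs)
  n <- nrow(obs)
  base_cov <- .term_covariates(obs, spec$base_terms)
  lab <- as.character(obs$parcel_label)
  i_self <- as.numeric(lab == "self")
  i_soc  <- as.numeric(lab == "social")
  ncol_per <- if (spec$label_moderation) 3L else 1L
  X <- matrix(0, n, nrow(spec$base_terms) * ncol_per)
  cn <- character(ncol(X))
  for (t in seq_len(nrow(spec$base_terms))) {
    j <- (t - 1L) * ncol_per
    X[, j + 1L] <- base_cov[, t]
    if (spec$label_moderation) {
      X[, j + 2L] <- base_cov[, t] * i_self
      X[, j + 3L] <- base_cov[, t] * i_soc
    }
    cn[j + seq_len(ncol_per)] <-
      .gamma_names(spec$base_terms$beta[t], spec$label_moderation)
  }
  colnames(X) <- cn

  blocks <- lapply(spec$random_blocks, function(b) {
    fac <- switch(b$grouping,
                  participant = factor(obs$participant_id),
                  parcel = factor(obs$parcel_id))
    q <- length(b$terms)
    lev <- levels(fac)
    tc <- .term_covariates(obs, growth_terms(b$terms))
    ## Z columns are level-major: level 1's q terms, then level 2's, ...
    ii <- rep(seq_len(n), q)
    jj <- as.vector(outer((as.integer(fac) - 1L) * q, seq_len(q), `+`))
    Z <- Matrix::sparseMatrix(i = ii, j = jj, x = as.vector(tc),
                              dims = c(n, length(lev) * q))
    list(grouping = b$grouping, terms = b$terms, covariance = b$covariance,
         q = q, levels = lev, term_names = growth_terms(b$terms)$name, Z = Z)
  })
  structure(list(X = X, blocks = blocks, y = obs$bold, n = n),
            class = "design_matrices")
}

#' Write / read the observation-table interchange format
#'
#' Tab-separated values, UTF-8, "." decimal, fixed header
#' `participant_id  wave  age  domain  target  parcel_id  parcel_label  bold`.
#' Reading recomputes `age_c = age - 13`.
#'
#' @param obs observation table.
#' @param path file path.
#' @return `read_observations` returns a validated observation table.
#' @export
write_observations <- function(obs, path) {
  validate_observations(obs)
  out <- data.frame(participant_id = obs$participant_id, wave = obs$wave,
                    age = obs$age_years, domain = obs$domain,
                    target = obs$target, parcel_id = obs$parcel_id,
                    parcel_label = obs$parcel_label, bold = obs$bold)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  req <- c("participant_id", "wave", "age", "domain", "target", "parcel_id",
           "parcel_label", "bold")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("observation file lacks column(s): ",
                         paste(miss, collapse = ", "))
  obs <- data.frame(participant_id = as.character(d$participant_id),
                    wave = as.integer(d$wave),
                    age_years = as.numeric(d$age),
                    age_c = as.numeric(d$age) - 13,
                    domain = d$domain, target = d$target,
                    parcel_id = as.integer(d$parcel_id),
                    parcel_label = d$parcel_label,
                    bold = as.numeric(d$bold),
                    stringsAsFactors = FALSE)
  validate_observations(obs)
  obs
}
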