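# Independent dense-matrix oracle for the mixed-model deviance: builds the
# full marginal covariance V0 = I + Z Lambda Lambda' Z' and evaluates the
# Gaussian (restricted) likelihood directly with base R dense algebra,
# profiling beta and sigma^2 analytically.  Shares nothing with the package's
# sparse/penalized solver beyond the documented theta layout.

oracle_lambda <- function(theta, blocks) {
  parts <- list(); off <- 0L
  for (b in blocks) {
    q <- b$q
    lam <- matrix(0, q, q)
    if (b$covariance == "full") {
      np <- q * (q + 1L) / 2L
      sl <- theta[off + seq_len(np)]
      lam[lower.tri(lam, diag = TRUE)] <- sl
      diag(lam) <- exp(diag(lam))
    } else {
      np <- q
      diag(lam) <- exp(theta[off + seq_len(np)])
    }
    nlev <- length(b$levels)
    parts[[length(parts) + 1L]] <- kronecker(diag(nlev), lam)
    off <- off + np
  }
  if (length(parts) == 1L) parts[[1L]]
  else {
    dims <- vapply(parts, nrow, 0L)
    out <- matrix(0, sum(dims), sum(dims))
    at <- 0L
    for (p in parts) {
      idx <- at + seq_len(nrow(p)); out[idx, idx] <- p; at <- at + nrow(p)
    }
    out
  }
}

oracle_deviance <- function(theta, design, objective = "REML") {
  X <- design$X; y <- design$y; n <- nrow(X); p <- ncol(X)
  if (length(design$blocks)) {
    Z <- as.matrix(do.call(cbind, lapply(design$blocks, `[[`, "Z")))
    Lam <- oracle_lambda(theta, design$blocks)
    V0 <- diag(n) + Z %*% tcrossprod(Lam) %*% t(Z)
  } else {
    V0 <- diag(n)
  }
  Vi <- solve(V0)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  q2 <- as.numeric(t(r) %*% Vi %*% r)
  ldV <- as.numeric(determinant(V0, logarithm = TRUE)$modulus)
  if (objective == "REML") {
    s2 <- q2 / (n - p)
    ldV + as.numeric(determinant(XtViX, logarithm = TRUE)$modulus) +
      (n - p) * (1 + log(2 * pi * s2))
  } else {
    s2 <- q2 / n
    ldV + n * (1 + log(2 * pi * s2))
  }
}

# Hand-built design container for generic engine tests (the engine only needs
# X, per-block sparse Z with level-major columns, and y).
manual_design <- function(X, y, groups = list()) {
  n <- nrow(X)
  blocks <- lapply(groups, function(g) {
    fac <- factor(g$factor)
    q <- ncol(g$covariates)
    ii <- rep(seq_len(n), q)
    jj <- as.vector(outer((as.integer(fac) - 1L) * q, seq_len(q), `+`))
    Z <- Matrix::sparseMatrix(i = ii, j = jj, x = as.vector(g$covariates),
                              dims = c(n, nlevels(fac) * q))
    list(grouping = g$grouping, terms = seq_len(q) - 1L,
         covariance = if (is.null(g$covariance)) "full" else g$covariance,
         q = q, levels = levels(fac),
         term_names = colnames(g$covariates), Z = Z)
  })
  structure(list(X = X, blocks = blocks, y = y, n = n),
            class = "design_matrices")
}

# Small random crossed-design generator for the oracle battery.
random_crossed_design <- function(n_g1, n_g2, reps, q1 = 1L, q2 = 1L,
                                  cov1 = "full", cov2 = "full") {
  d <- expand.grid(g1 = seq_len(n_g1), g2 = seq_len(n_g2),
                   rep = seq_len(reps))
  n <- nrow(d)
  x <- rnorm(n)
  X <- cbind("(Intercept)" = 1, x = x)
  cov_mat <- function(q) {
    m <- cbind(1, if (q > 1) matrix(rnorm(n * (q - 1L)), n) else NULL)
    colnames(m) <- paste0("t", seq_len(q)); m
  }
  y <- rnorm(n)
  manual_design(X, y, list(
    list(grouping = "participant", factor = d$g1, covariates = cov_mat(q1),
         covariance = cov1),
    list(grouping = "parcel", factor = d$g2, covariates = cov_mat(q2),
         covariance = cov2)))
}

# Default generative truth used by simulation-based engine tests: Model 1
# structure at the reduced cohort scale.
model1_sim_config <- function(seed = 1L, residual_var = 0.5) {
  spec <- make_model1_spec()
  Psi_j <- diag(c(0.05, 0.004, 0.01))
  Psi_j[1, 2] <- Psi_j[2, 1] <- 0.005
  Psi_k <- diag(c(0.09, 0.008, 0.0015, 0.02))
  Psi_k[1, 2] <- Psi_k[2, 1] <- 0.01
  list(spec = spec,
       config = simulation_config(
         true_gamma = reference_gamma()[gamma_names(spec)],
         participant_cov = Psi_j, parcel_cov = Psi_k,
         residual_var = residual_var,
         design = reduced_cohort_design(), seed = seed))
}
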