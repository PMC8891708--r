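#' @import Matrix
#' @importFrom stats optim pt qt rnorm sd var
NULL

## ---------------------------------------------------------------------------
## Estimation core: Gaussian linear mixed models with crossed random effects,
## fitted by minimizing the profiled (restricted) deviance over the relative
## covariance factors.  Writing y = X gamma + Z Lambda(theta) u + e with
## u ~ N(0, sigma^2 I), e ~ N(0, sigma^2 I), the penalized normal equations
##   [ Lt Zt Z L + I   Lt Zt X ] [u]   [ Lt Zt y ]
##   [ Xt Z L          Xt X    ] [g] = [ Xt y    ]
## are solved by a sparse Cholesky factor of the (1,1) block followed by block
## elimination; gamma and sigma^2 are profiled out analytically, leaving only
## theta to optimize.  Per-block covariance: Psi_b = sigma^2 lambda_b lambda_b'.
## ---------------------------------------------------------------------------

## theta layout per full-covariance block: lower triangle of lambda_b in
## column-major order, with DIAGONAL entries stored on the log scale (so the
## optimization is unconstrained); off-diagonals are free.  Diagonal blocks
## store the q log-scales only.
.theta_layout <- function(blocks) {
  lay <- list(); off <- 0L
  for (b in seq_along(blocks)) {
    q <- blocks[[b]]$q
    if (blocks[[b]]$covariance == "full") {
      idx <- which(lower.tri(diag(q), diag = TRUE))
      np <- length(idx)
      dpos <- match(which(row(diag(q)) == col(diag(q))), idx)
    } else {
      np <- q; dpos <- seq_len(q); idx <- NULL
    }
    lay[[b]] <- list(q = q, np = np, offset = off, tri_idx = idx,
                     diag_pos = dpos, covariance = blocks[[b]]$covariance)
    off <- off + np
  }
  attr(lay, "ntheta") <- off
  lay
}

.theta_init <- function(layout) {
  th <- numeric(attr(layout, "ntheta"))  # log-diag 0 => unit scales, off-diag 0
  th
}

.theta_lower <- function(layout, lower_logdiag = -8) {
  lo <- rep(-Inf, attr(layout, "ntheta"))
  for (l in layout) lo[l$offset + l$diag_pos] <- lower_logdiag
  lo
}

## lambda_b (dense q x q lower-triangular) from the block's theta slice
.block_lambda <- function(theta, l) {
  q <- l$q
  lam <- matrix(0, q, q)
  sl <- theta[l$offset + seq_len(l$np)]
  if (l$covariance == "full") {
    lam[l$tri_idx] <- sl
    diag(lam) <- exp(sl[l$diag_pos])
  } else {
    diag(lam) <- exp(sl)
  }
  lam
}

## Per-block relative-factor entry values implied by theta (diagonal entries
## exponentiated), concatenated over blocks in layout order.
.lambda_values <- function(theta, layout) {
  unlist(lapply(layout, function(l) {
    sl <- theta[l$offset + seq_len(l$np)]
    sl[l$diag_pos] <- exp(sl[l$diag_pos])
    sl
  }), use.names = FALSE)
}

## Precompute the cross-products the deviance needs; done once per (X, Z, y).
.make_devstruct <- function(design) {
  X <- design$X; y <- design$y
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("fixed-effect design is rank deficient; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  blocks <- lapply(design$blocks, function(b)
    list(grouping = b$grouping, terms = b$terms, covariance = b$covariance,
         q = b$q, nlev = length(b$levels), levels = b$levels,
         term_names = b$term_names))
  if (length(design$blocks)) {
    Z <- do.call(cbind, lapply(design$blocks, `[[`, "Z"))
    ZtZ <- Matrix::forceSymmetric(Matrix::crossprod(Z))
    ZtX <- as.matrix(Matrix::crossprod(Z, X))
    Zty <- as.numeric(Matrix::crossprod(Z, y))
  } else {
    ZtZ <- NULL; ZtX <- NULL; Zty <- NULL
  }
  ds <- list(XtX = crossprod(X), Xty = as.numeric(crossprod(X, y)),
             yty = sum(y^2), ZtZ = ZtZ, ZtX = ZtX, Zty = Zty,
             n = nrow(X), p = ncol(X), xnames = colnames(X),
             blocks = blocks, qtot = if (length(blocks))
               sum(vapply(blocks, function(b) b$q * b$nlev, 0)) else 0L)
  ds$layout <- .theta_layout(blocks)
  if (ds$qtot > 0L) {
    ## Fill machinery for Lambda = bdiag over blocks of kron(I_nlev, lambda_b):
    ## row/col indices of every replicated lambda entry plus the index of the
    ## lambda value it holds, so each evaluation only assigns values.
    ij <- NULL; entry <- integer(0)
    boff <- 0L; eoff <- 0L
    for (b in seq_along(blocks)) {
      l <- ds$layout[[b]]; q <- l$q; nlev <- blocks[[b]]$nlev
      if (l$covariance == "full") {
        rc <- which(lower.tri(diag(q), diag = TRUE), arr.ind = TRUE)
      } else {
        rc <- cbind(seq_len(q), seq_len(q))
      }
      lev0 <- rep((seq_len(nlev) - 1L) * q, each = nrow(rc))
      ij <- rbind(ij, cbind(boff + lev0 + rc[rep(seq_len(nrow(rc)), nlev), 1L],
                            boff + lev0 + rc[rep(seq_len(nrow(rc)), nlev), 2L]))
      entry <- c(entry, rep(eoff + seq_len(l$np), nlev))
      boff <- boff + q * nlev
      eoff <- eoff + l$np
    }
    ds$lam_ij <- ij; ds$lam_entry <- entry
    isdiag <- logical(attr(ds$layout, "ntheta"))
    for (l in ds$layout) isdiag[l$offset + l$diag_pos] <- TRUE
    ds$theta_isdiag <- isdiag
    ds$dense <- ds$qtot <= 800L
    if (ds$dense) {
      ds$ZtZd <- as.matrix(ds$ZtZ)
      ds$Lam0 <- matrix(0, ds$qtot, ds$qtot)
    } else {
      tmpl <- Matrix::sparseMatrix(i = ij[, 1L], j = ij[, 2L],
                                   x = as.double(entry),
                                   dims = c(ds$qtot, ds$qtot))
      ds$lam_xmap <- as.integer(tmpl@x)
      tmpl@x <- rep(1, length(tmpl@x))
      ds$Lam_tmpl <- tmpl
    }
  }
  ds
}

## Deviance and by-products at a given theta.  sigma2 = NULL profiles the
## residual variance out; a supplied value gives the non-profiled deviance
## (used for the Satterthwaite curvature).
.dev_components <- function(theta, ds, REML = TRUE, sigma2 = NULL,
                            want = c("dev")) {
  n <- ds$n; p <- ds$p
  if (ds$qtot > 0L) {
    lv <- .lambda_values(theta, ds$layout)
    if (ds$dense) {
      Lambda <- ds$Lam0
      Lambda[ds$lam_ij] <- lv[ds$lam_entry]
      B <- ds$ZtZd %*% Lambda
      A <- crossprod(Lambda, B)
      diag(A) <- diag(A) + 1
      R <- chol(A)
      ldL2 <- 2 * sum(log(diag(R)))
      LtZty <- drop(crossprod(Lambda, ds$Zty))
      LtZtX <- crossprod(Lambda, ds$ZtX)
      cu <- backsolve(R, LtZty, transpose = TRUE)
      RZX <- backsolve(R, LtZtX, transpose = TRUE)
      ch <- R
    } else {
      Lambda <- ds$Lam_tmpl
      Lambda@x <- lv[ds$lam_xmap]
      A <- Matrix::forceSymmetric(Matrix::crossprod(Lambda, ds$ZtZ %*% Lambda))
      ch <- Matrix::Cholesky(A + Matrix::Diagonal(ds$qtot), LDL = FALSE,
                             perm = TRUE)
      ldL2 <- 2 * as.numeric(Matrix::determinant(ch, logarithm = TRUE,
                                                 sqrt = TRUE)$modulus)
      LtZty <- as.numeric(Matrix::crossprod(Lambda, ds$Zty))
      LtZtX <- as.matrix(Matrix::crossprod(Lambda, ds$ZtX))
      cu <- as.numeric(Matrix::solve(ch, Matrix::solve(ch, LtZty, system = "P"),
                                     system = "L"))
      RZX <- as.matrix(Matrix::solve(ch, Matrix::solve(ch, LtZtX, system = "P"),
                                     system = "L"))
    }
    RXtRX <- ds$XtX - crossprod(RZX)
  } else {
    Lambda <- NULL; ch <- NULL; cu <- numeric(0); RZX <- NULL
    ldL2 <- 0; RXtRX <- ds$XtX
  }
  RX <- tryCatch(chol(RXtRX), error = function(e)
    stop("penalized fixed-effect system not positive definite: ",
         conditionMessage(e)))
  rhs <- ds$Xty - if (ds$qtot > 0L) as.numeric(crossprod(RZX, cu)) else 0
  cbeta <- forwardsolve(t(RX), rhs)
  pwrss <- max(ds$yty - sum(cu^2) - sum(cbeta^2), 0)
  ldRX2 <- 2 * sum(log(diag(RX)))
  nmp <- if (REML) n - p else n
  if (is.null(sigma2)) {
    dev <- ldL2 + (if (REML) ldRX2 else 0) +
      nmp * (1 + log(2 * pi * pwrss / nmp))
    s2 <- pwrss / nmp
  } else {
    dev <- ldL2 + (if (REML) ldRX2 else 0) +
      nmp * log(2 * pi * sigma2) + pwrss / sigma2
    s2 <- sigma2
  }
  if (identical(want, "dev")) return(dev)
  beta <- backsolve(RX, cbeta)
  names(beta) <- ds$xnames
  out <- list(dev = dev, beta = beta, sigma2 = s2, pwrss = pwrss,
              ldL2 = ldL2, ldRX2 = ldRX2, RX = RX)
  if ("grad" %in% want && ds$qtot > 0L && ds$dense) {
    ## Analytic gradient of the profiled deviance (dense path).  With
    ## M = Lt C L + I (C = ZtZ), W = Lt Zt X, S = Xt X - Wt Minv W and the
    ## envelope theorem for the penalized residual sum of squares:
    ##   d log|M|  = 2 tr(Li Minv Lt C)
    ##   d log|S|  = -2 tr(Li K Xt Z) + 2 tr(Li K S Kt Lt C),  K = Minv W Sinv
    ##   d pwrss   = -2 tr(Li u (Zt r)t),  r = y - Z L u - X beta
    ## where Li is the elementary derivative of Lambda for one factor entry.
    R <- ch
    u <- drop(backsolve(R, cu - RZX %*% beta))
    Zr <- ds$Zty - drop(B %*% u) - drop(ds$ZtX %*% beta)
    LtC <- t(B)
    Fm <- 2 * backsolve(R, backsolve(R, LtC, transpose = TRUE))
    if (REML) {
      K <- backsolve(R, RZX) %*% chol2inv(RX)
      Fm <- Fm - 2 * (K %*% t(ds$ZtX)) +
        2 * (K %*% (crossprod(RX) %*% (t(K) %*% LtC)))
    }
    cfac <- if (REML) n - p else n
    Ft <- t(Fm)
    vals <- Ft[ds$lam_ij] -
      (2 * cfac / pwrss) * u[ds$lam_ij[, 2L]] * Zr[ds$lam_ij[, 1L]]
    g <- drop(rowsum(vals, ds$lam_entry))
    g[ds$theta_isdiag] <- g[ds$theta_isdiag] * lv[ds$theta_isdiag]
    out$grad <- g
    out$u_modes <- u
  }
  if ("u" %in% want && ds$qtot > 0L) {
    ustar <- cu - RZX %*% beta
    if (ds$dense) {
      out$u <- drop(backsolve(ch, ustar))
    } else {
      out$u <- as.numeric(Matrix::solve(ch, Matrix::solve(ch, ustar,
                                                          system = "Lt"),
                                        system = "Pt"))
    }
    out$b <- as.numeric(Lambda %*% out$u)
  }
  out
}

#' Profiled deviance of a crossed-random-effects mixed model
#'
#' Evaluates -2 times the profiled log-(restricted-)likelihood at the given
#' relative covariance parameters, with the fixed effects and residual
#' variance concentrated out analytically. Computed via a sparse Cholesky
#' factorization of the penalized normal equations.
#'
#' @param theta numeric vector of covariance parameters (per block: the lower
#'   triangle of the relative Cholesky factor, column-major, diagonal entries
#'   on the log scale; diagonal blocks store the q log-scales).
#' @param design a [build_design()] result.
#' @param y response vector (defaults to the response stored in `design`).
#' @param objective `"REML"` or `"ML"`.
#' @return the deviance (a single number).
#' @export
profiled_deviance <- function(theta, design, y = design$y,
                              objective = c("REML", "ML")) {
  objective <- match.arg(objective)
  design$y <- y
  ds <- .make_devstruct(design)
  if (length(theta) != attr(ds$layout, "ntheta"))
    stop("theta has length ", length(theta), "; expected ",
         attr(ds$layout, "ntheta"))
  .dev_components(theta, ds, REML = objective == "REML")
}

#' Fit a crossed-random-effects growth model
#'
#' Minimizes the profiled deviance over the relative covariance factors
#' (quasi-Newton on an unconstrained parameterization: log-diagonal, free
#' off-diagonal), then recovers fixed effects, their covariance, per-block
#' covariance matrices and the residual variance. Boundary (singular) fits are
#' reported, not raised as errors.
#'
#' @param design a [build_design()] result.
#' @param y response vector (defaults to the response stored in `design`).
#' @param objective `"REML"` (default, used for reported estimates) or `"ML"`
#'   (used for information-criterion comparison).
#' @param start optional starting value for the covariance parameters.
#' @param control list: `maxit` (default 400), `factr` (L-BFGS-B tolerance,
#'   default 1e7), `lower_logdiag` (bound on log relative scales, default -8),
#'   `singular_tol` (relative scale below which a block diagonal is flagged at
#'   the boundary, default 1e-3).
#' @param blups logical; also compute predicted group deviations.
#' @return an object of class `lmm_fit`: named fixed effects `gamma`, their
#'   covariance `gamma_cov`, `sigma2`, per-block `Psi`, `theta`, `deviance`,
#'   `n_params`, `aic` (= deviance + 2 n_params), `converged`, `singular`,
#'   and (optionally) `blups`.
#' @export
fit_lmm <- function(design, y = design$y, objective = c("REML", "ML"),
                    start = NULL, control = list(), blups = FALSE) {
  objective <- match.arg(objective)
  REML <- objective == "REML"
  ctrl <- utils::modifyList(list(maxit = 400L, factr = 1e7,
                                 lower_logdiag = -8, singular_tol = 1e-3),
                            control)
  design$y <- y
  ds <- .make_devstruct(design)
  ntheta <- attr(ds$layout, "ntheta")
  degenerate <- FALSE
  if (ntheta > 0L) {
    th0 <- if (is.null(start)) .theta_init(ds$layout) else start
    if (length(th0) != ntheta) stop("start has wrong length")
    ## exact interpolation (zero residual) leaves the covariance scales
    ## unidentified; report the boundary fit rather than optimizing noise
    c0 <- .dev_components(th0, ds, REML, want = c("dev", "beta"))
    if (c0$pwrss <= 1e-12 * max(ds$yty, 1)) {
      warning("response is interpolated exactly; variance components are ",
              "unidentified and reported at the boundary")
      degenerate <- TRUE
      theta <- .theta_lower(ds$layout, ctrl$lower_logdiag)
      theta[!ds$theta_isdiag] <- 0
      converged <- TRUE
      optinfo <- list(convergence = 0L, degenerate = TRUE)
    }
  }
  if (ntheta > 0L && !degenerate) {
    ## analytic gradient on the dense path unless finite differences are
    ## requested; fn and gr share one evaluation per point
    if (isTRUE(ds$dense) && !isTRUE(ctrl$fd_gradient)) {
      cache <- new.env(parent = emptyenv())
      evalpt <- function(th) {
        if (!identical(th, cache$th)) {
          cache$res <- .dev_components(th, ds, REML, want = c("dev", "grad"))
          cache$th <- th
        }
        cache$res
      }
      fn <- function(th) evalpt(th)$dev
      gr <- function(th) evalpt(th)$grad
    } else {
      fn <- function(th) .dev_components(th, ds, REML)
      gr <- NULL
    }
    opt <- optim(th0, fn, gr, method = "L-BFGS-B",
                 lower = .theta_lower(ds$layout, ctrl$lower_logdiag),
                 control = list(maxit = ctrl$maxit, factr = ctrl$factr))
    theta <- opt$par
    converged <- opt$convergence == 0L
    optinfo <- list(convergence = opt$convergence, message = opt$message,
                    counts = opt$counts)
  } else if (ntheta == 0L) {
    theta <- numeric(0); converged <- TRUE; optinfo <- list(convergence = 0L)
  }
  want <- if (blups) c("dev", "u") else c("dev", "beta")
  comp <- .dev_components(theta, ds, REML, want = want)
  gamma_cov <- comp$sigma2 * chol2inv(comp$RX)
  dimnames(gamma_cov) <- list(ds$xnames, ds$xnames)
  Psi <- list(); singular <- FALSE
  for (b in seq_along(ds$blocks)) {
    lam <- .block_lambda(theta, ds$layout[[b]])
    P <- comp$sigma2 * tcrossprod(lam)
    dimnames(P) <- list(ds$blocks[[b]]$term_names, ds$blocks[[b]]$term_names)
    Psi[[ds$blocks[[b]]$grouping]] <- P
    if (any(diag(lam) < ctrl$singular_tol)) singular <- TRUE
  }
  n_params <- ds$p + ntheta + 1L
  fit <- list(gamma = comp$beta, gamma_cov = gamma_cov, sigma2 = comp$sigma2,
              Psi = Psi, theta = theta, objective = objective,
              deviance = comp$dev, n_params = n_params,
              aic = comp$dev + 2 * n_params, converged = converged,
              singular = singular, n = ds$n, p = ds$p, optinfo = optinfo,
              env = new.env(parent = emptyenv()))
  fit$env$ds <- ds
  if (blups && ds$qtot > 0L) {
    off <- 0L; bl <- list()
    for (b in seq_along(ds$blocks)) {
      blk <- ds$blocks[[b]]
      m <- matrix(comp$b[off + seq_len(blk$q * blk$nlev)], nrow = blk$nlev,
                  ncol = blk$q, byrow = TRUE,
                  dimnames = list(blk$levels, blk$term_names))
      bl[[blk$grouping]] <- m
      off <- off + blk$q * blk$nlev
    }
    fit$blups <- bl
  }
  class(fit) <- "lmm_fit"
  fit
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Cross-classified linear mixed model (", x$objective, ")\n", sep = "")
  cat("  n =", x$n, " fixed effects =", x$p, " parameters =", x$n_params, "\n")
  cat("  deviance =", format(x$deviance, digits = 10),
      " AIC =", format(x$aic, digits = 10), "\n")
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  if (x$singular) cat("  note: boundary (singular) covariance fit\n")
  cat("  sigma^2 =", format(x$sigma2, digits = 6), "\n")
  invisible(x)
}

## non-profiled deviance as a function of eta = c(theta, log sigma);
## curvature input for the Satterthwaite approximation.
.devfun_eta <- function(eta, ds, REML) {
  k <- length(eta)
  .dev_components(eta[-k], ds, REML, sigma2 = exp(2 * eta[k]))
}

.contrast_var <- function(eta, ds, REML, w) {
  k <- length(eta)
  comp <- .dev_components(eta[-k], ds, REML, sigma2 = exp(2 * eta[k]),
                          want = c("dev", "beta"))
  s2 <- exp(2 * eta[k])
  ri <- backsolve(comp$RX, w, transpose = TRUE)
  s2 * sum(ri^2)
}

.fd_grad <- function(f, x, h = 1e-4) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    hi <- h * max(1, abs(x[i])); e <- numeric(length(x)); e[i] <- hi
    g[i] <- (f(x + e) - f(x - e)) / (2 * hi)
  }
  g
}

.fd_hessian <- function(f, x, h = 1e-4) {
  k <- length(x)
  H <- matrix(0, k, k)
  hv <- h * pmax(1, abs(x))
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- numeric(k); ei[i] <- hv[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / hv[i]^2
    if (i < k) for (j in (i + 1L):k) {
      ej <- numeric(k); ej[j] <- hv[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * hv[i] * hv[j])
    }
  }
  H
}

#' Satterthwaite degrees of freedom for a fixed-effect contrast
#'
#' Moment-matching degrees of freedom `df = 2 V^2 / Var(V)` for
#' `V = Var(c' gamma_hat)`, with `Var(V)` from the delta method: the gradient
#' of `V` with respect to the covariance parameters (relative factors plus log
#' residual scale) combined with the inverse curvature (finite-difference
#' Hessian) of the deviance at the optimum. Falls back to the normal
#' approximation (`df = Inf`, with a warning) when the curvature is not
#' positive definite.
#'
#' @param fit an [fit_lmm()] result.
#' @param weights named numeric contrast over the fitted coefficients.
#' @return degrees of freedom (positive scalar, possibly `Inf`).
#' @export
satterthwaite_df <- function(fit, weights) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!fit$converged)
    warning("Satterthwaite df requested for a fit that did not converge")
  ds <- fit$env$ds
  w <- .resolve_weights(weights, names(fit$gamma))
  REML <- fit$objective == "REML"
  eta <- c(fit$theta, 0.5 * log(fit$sigma2))
  h_at <- function(e) .contrast_var(e, ds, REML, w)
  V <- h_at(eta)
  g <- .fd_grad(h_at, eta)
  H <- fit$env$eta_hessian
  if (is.null(H)) {
    H <- .fd_hessian(function(e) .devfun_eta(e, ds, REML), eta)
    fit$env$eta_hessian <- H
  }
  W <- tryCatch(2 * chol2inv(chol(H)), error = function(e) NULL)
  if (is.null(W)) {
    warning("deviance curvature not positive definite; using df = Inf")
    return(Inf)
  }
  varV <- as.numeric(t(g) %*% W %*% g)
  if (!is.finite(varV) || varV <= 0) {
    warning("non-positive variance of the contrast variance; using df = Inf")
    return(Inf)
  }
  2 * V^2 / varV
}

.resolve_weights <- function(weights, coefs) {
  if (is.null(names(weights)))
    stop("contrast weights must be named over fitted coefficients")
  bad <- setdiff(names(weights), coefs)
  if (length(bad)) stop("contrast names coefficient(s) absent from the fit: ",
                        paste(bad, collapse = ", "))
  w <- setNames(numeric(length(coefs)), coefs)
  w[names(weights)] <- weights
  if (all(w == 0)) stop("degenerate all-zero contrast")
  w
}

#' Wald test of a linear contrast of fixed effects
#'
#' Estimate, standard error, t statistic, Satterthwaite degrees of freedom,
#' two-sided p value and 95% confidence interval for `c' gamma`.
#'
#' @param fit an [fit_lmm()] result.
#' @param weights named numeric contrast weights (unnamed coefficients get 0).
#' @param df_method `"satterthwaite"` (default) or `"normal"` (`df = Inf`).
#' @param level confidence level (default 0.95).
#' @return an object of class `contrast_result` with fields `weights`,
#'   `estimate`, `se`, `t`, `df`, `p`, `ci`.
#' @export
wald_contrast <- function(fit, weights,
                          df_method = c("satterthwaite", "normal"),
                          level = 0.95) {
  stopifnot(inherits(fit, "lmm_fit"))
  df_method <- match.arg(df_method)
  w <- .resolve_weights(weights, names(fit$gamma))
  est <- sum(w * fit$gamma)
  se <- sqrt(as.numeric(t(w) %*% fit$gamma_cov %*% w))
  df <- if (df_method == "satterthwaite") satterthwaite_df(fit, w) else Inf
  tval <- est / se
  pval <- 2 * pt(-abs(tval), df = df)
  crit <- qt(1 - (1 - level) / 2, df = df)
  structure(list(weights = w, estimate = est, se = se, t = tval, df = df,
                 p = pval, ci = c(est - crit * se, est + crit * se),
                 level = level),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("contrast: b = %.4f [%.4f, %.4f], se = %.4f, t(%.1f) = %.2f, p = %.4g\n",
              x$estimate, x$ci[1], x$ci[2], x$se, x$df, x$t, x$p))
  invisible(x)
}

#' Compare two fitted models by AIC
#'
#' Reports both AICs and their difference (`fit_b - fit_a`). The second model
#' is selected when its AIC is lower by at least 2; the first when its AIC is
#' lower by at least 2; otherwise the more parsimonious model (fewer
#' parameters) is selected.
#'
#' @param fit_a,fit_b [fit_lmm()] results for the same observations and
#'   objective.
#' @return list with `aic_a`, `aic_b`, `delta_aic`, `selected` (`"a"`/`"b"`),
#'   and `n_params`.
#' @export
compare_models <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "lmm_fit"), inherits(fit_b, "lmm_fit"))
  if (fit_a$n != fit_b$n)
    stop("models were fitted to differing observation counts (",
         fit_a$n, " vs ", fit_b$n, ")")
  if (fit_a$objective != fit_b$objective)
    stop("models were fitted under differing objectives")
  delta <- fit_b$aic - fit_a$aic
  selected <- if (delta <= -2) "b" else if (delta >= 2) "a"
  else if (fit_b$n_params < fit_a$n_params) "b" else "a"
  list(aic_a = fit_a$aic, aic_b = fit_b$aic, delta_aic = delta,
       selected = selected,
       n_params = c(a = fit_a$n_params, b = fit_b$n_params))
}

#' Serialize a fitted model to JSON
#'
#' Writes the coefficient table (estimate, se, t, Satterthwaite or normal df,
#' p, CI), per-block covariance matrices, residual variance, deviance, AIC
#' and convergence information.
#'
#' @param fit an [fit_lmm()] result.
#' @param path output path.
#' @param df_method passed to [wald_contrast()]; `"normal"` avoids the
#'   curvature computation for large models.
#' @export
write_fit_json <- function(fit, path, df_method = "normal") {
  tab <- coefficient_table(fit, df_method = df_method)
  out <- list(coefficients = tab,
              Psi = lapply(fit$Psi, function(m) as.data.frame(m)),
              sigma2 = fit$sigma2, objective = fit$objective,
              deviance = fit$deviance, n_params = fit$n_params,
              aic = fit$aic,
              convergence = list(converged = fit$converged,
                                 singular = fit$singular))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Coefficient table of a fitted model
#'
#' One row per fixed effect with estimate, 95% CI, t, df and p, mirroring the
#' usual mixed-model reporting layout.
#'
#' @param fit an [fit_lmm()] result.
#' @param df_method `"satterthwaite"` or `"normal"`.
#' @return data.frame with columns `term`, `estimate`, `se`, `ci_lower`,
#'   `ci_upper`, `t`, `df`, `p`.
#' @export
coefficient_table <- function(fit, df_method = c("satterthwaite", "normal")) {
  df_method <- match.arg(df_method)
  rows <- lapply(names(fit$gamma), function(nm) {
    cr <- wald_contrast(fit, setNames(1, nm), df_method = df_method)
    data.frame(term = nm, estimate = cr$estimate, se = cr$se,
               ci_lower = cr$ci[1], ci_upper = cr$ci[2], t = cr$t,
               df = cr$df, p = cr$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
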