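#' Model-implied covariance of a path model
#'
#' Standard covariance algebra for simultaneous-equation (path) models: with
#' endogenous equations \eqn{y = By + Gx + e}, \eqn{A = (I-B)^{-1}} gives
#' \eqn{Cov(y) = A (G \Phi G' + \Psi) A'}, \eqn{Cov(y, x) = A G \Phi},
#' \eqn{Cov(x) = \Phi}. Requires every feedback loop to be stable (spectral
#' radius of B below 1); an unstable loop has no meaningful implied covariance.
#'
#' @param coeffs [path_coefficients()] object.
#' @return Symmetric covariance matrix over all observed variables, ordered as
#'   in the spec.
#' @export
implied_covariance <- function(coeffs) {
  stopifnot(inherits(coeffs, "mrue_path_coefficients"))
  B <- coeffs$B; G <- coeffs$G; Phi <- coeffs$Phi; Psi <- coeffs$Psi
  sr <- if (nrow(B)) max(Mod(eigen(B, only.values = TRUE)$values)) else 0
  if (sr >= 1) {
    stop("feedback loop among {", paste(colnames(B), collapse = ", "),
         "} is unstable (spectral radius ", signif(sr, 3),
         " >= 1); implied covariance undefined", call. = FALSE)
  }
  A <- solve(diag(nrow(B)) - B)
  Syy <- A %*% (G %*% Phi %*% t(G) + Psi) %*% t(A)
  Syx <- A %*% G %*% Phi
  vars <- coeffs$spec$variables
  endo <- coeffs$spec$endogenous
  exo <- coeffs$spec$exogenous
  Sigma <- matrix(0, length(vars), length(vars), dimnames = list(vars, vars))
  Sigma[endo, endo] <- Syy
  if (length(exo)) {
    Sigma[endo, exo] <- Syx
    Sigma[exo, endo] <- t(Syx)
    Sigma[exo, exo] <- Phi
  }
  (Sigma + t(Sigma)) / 2
}

# Free-parameter bookkeeping for the ML fit: returns index maps and functions
# translating between a parameter vector theta and the coefficient matrices.
param_map <- function(spec, S) {
  endo <- spec$endogenous; exo <- spec$exogenous
  eB <- spec$edges[spec$edges$source %in% endo, , drop = FALSE]
  eG <- spec$edges[spec$edges$source %in% exo, , drop = FALSE]
  phi_idx <- which(lower.tri(diag(length(exo)), diag = TRUE), arr.ind = TRUE)
  ecov <- spec$error_covariances
  n_free <- nrow(eB) + nrow(eG) + nrow(phi_idx) + length(endo) + length(ecov)

  unpack <- function(theta) {
    k <- 0L
    B <- matrix(0, length(endo), length(endo), dimnames = list(endo, endo))
    if (nrow(eB)) {
      B[cbind(eB$target, eB$source)] <- theta[k + seq_len(nrow(eB))]
      k <- k + nrow(eB)
    }
    G <- matrix(0, length(endo), length(exo), dimnames = list(endo, exo))
    if (nrow(eG)) {
      G[cbind(eG$target, eG$source)] <- theta[k + seq_len(nrow(eG))]
      k <- k + nrow(eG)
    }
    Phi <- matrix(0, length(exo), length(exo), dimnames = list(exo, exo))
    if (nrow(phi_idx)) {
      Phi[phi_idx] <- theta[k + seq_len(nrow(phi_idx))]
      Phi[phi_idx[, c(2, 1), drop = FALSE]] <- Phi[phi_idx]
      k <- k + nrow(phi_idx)
    }
    Psi <- matrix(0, length(endo), length(endo), dimnames = list(endo, endo))
    diag(Psi) <- exp(theta[k + seq_along(endo)])  # log-parameterized variances
    k <- k + length(endo)
    for (pr in ecov) {
      k <- k + 1L
      Psi[pr[1], pr[2]] <- Psi[pr[2], pr[1]] <- theta[k]
    }
    list(B = B, G = G, Phi = Phi, Psi = Psi)
  }

  start <- function() {
    # per-equation least squares on the sample moments gives good starts for
    # the recursive part of the model; feedback edges start near zero too
    theta_B <- numeric(nrow(eB)); theta_G <- numeric(nrow(eG))
    psi0 <- diag(S)[endo] * 0.5
    for (y in endo) {
      parents <- spec$edges$source[spec$edges$target == y]
      if (!length(parents)) next
      b <- tryCatch(solve(S[parents, parents, drop = FALSE],
                          S[parents, y]),
                    error = function(e) rep(0, length(parents)))
      names(b) <- parents
      resid <- S[y, y] - sum(b * S[parents, y])
      psi0[y] <- max(resid, 0.05 * S[y, y])
      for (p in parents) {
        iB <- which(eB$target == y & eB$source == p)
        if (length(iB)) theta_B[iB] <- b[p]
        iG <- which(eG$target == y & eG$source == p)
        if (length(iG)) theta_G[iG] <- b[p]
      }
    }
    phi0 <- S[exo, exo, drop = FALSE][phi_idx]
    c(theta_B, theta_G, phi0, log(psi0), rep(0, length(ecov)))
  }

  list(n_free = n_free, unpack = unpack, start = start,
       labels = c(paste0(eB$source, "->", eB$target),
                  paste0(eG$source, "->", eG$target),
                  paste0("phi:", exo[phi_idx[, 2]], "~", exo[phi_idx[, 1]]),
                  paste0("psi:", endo),
                  vapply(ecov, function(p) paste0("psi:", p[1], "~", p[2]), "")))
}

ml_discrepancy <- function(S, Sigma) {
  p <- nrow(S)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  logdetS <- determinant(S, logarithm = TRUE)$modulus
  logdetSig <- 2 * sum(log(diag(ch)))
  Sinv_S <- chol2inv(ch) %*% S
  as.numeric(logdetSig + sum(diag(Sinv_S)) - logdetS - p)
}

#' Fit a path model by maximum likelihood
#'
#' Minimizes the ML covariance-structure discrepancy
#' \eqn{F_{ML} = \ln|\Sigma(\theta)| + tr(S\Sigma(\theta)^{-1}) - \ln|S| - p}
#' over the free parameters (path coefficients, exogenous covariances,
#' structural error variances and any specified error covariances) with a
#' quasi-Newton optimizer and multiple jittered starts, which guards against
#' local minima in non-recursive (feedback) models.
#'
#' @param sample_cov Sample covariance (or correlation) matrix over the
#'   spec's variables; symmetric positive definite.
#' @param n Sample size behind `sample_cov`.
#' @param spec [path_model_spec()].
#' @param start Optional numeric start vector (advanced; see the fitted
#'   object's `param_labels`).
#' @param tol Relative convergence tolerance for the optimizer.
#' @param standardized If TRUE (default) the model is fitted to the
#'   correlation matrix so coefficients are standardized path coefficients.
#' @param n_starts Number of optimizer starts (first from per-equation least
#'   squares, the rest jittered).
#' @param seed Seed for the jittered starts.
#' @return Object of class `mrue_path_fit`: coefficients
#'   ([path_coefficients()]), discrepancy, chi2, df, p_value, gfi, agfi, nfi,
#'   rmsea, stability, r2 (per endogenous variable), converged, n.
#' @export
fit_ml <- function(sample_cov, n, spec, start = NULL, tol = 1e-10,
                   standardized = TRUE, n_starts = 5, seed = 1L) {
  stopifnot(inherits(spec, "mrue_path_spec"))
  vars <- spec$variables
  if (is.null(dimnames(sample_cov)) || !all(vars %in% rownames(sample_cov))) {
    stop("`sample_cov` must have dimnames covering the model variables",
         call. = FALSE)
  }
  S <- sample_cov[vars, vars]
  if (!isSymmetric(unname(S), tol = 1e-8)) stop("`sample_cov` must be symmetric",
                                                call. = FALSE)
  S <- (S + t(S)) / 2
  if (standardized) S <- cov2cor(S)
  if (min(eigen(S, only.values = TRUE)$values) <= 0) {
    stop("`sample_cov` must be positive definite", call. = FALSE)
  }
  p <- length(vars)
  pm <- param_map(spec, S)
  df <- p * (p + 1) / 2 - pm$n_free
  if (df < 0) stop("model not identified: ", pm$n_free,
                   " free parameters exceed ", p * (p + 1) / 2,
                   " sample moments", call. = FALSE)
  if (n <= pm$n_free) stop("sample size must exceed the number of free parameters",
                           call. = FALSE)

  objective <- function(theta) {
    m <- pm$unpack(theta)
    sr <- if (nrow(m$B)) max(Mod(eigen(m$B, only.values = TRUE)$values)) else 0
    if (!is.finite(sr) || sr >= 1) return(1e8 + 1e6 * max(sr - 1, 1))
    co <- structure(list(B = m$B, G = m$G, Phi = m$Phi, Psi = m$Psi,
                         spec = spec), class = "mrue_path_coefficients")
    Sigma <- tryCatch(implied_covariance(co), error = function(e) NULL)
    if (is.null(Sigma)) return(1e8)
    f <- ml_discrepancy(S, Sigma)
    if (!is.finite(f)) return(1e8)
    f
  }

  starts <- list(if (is.null(start)) pm$start() else start)
  if (n_starts > 1) {
    jit <- local({
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
      lapply(seq_len(n_starts - 1), function(i)
        starts[[1]] + rnorm(length(starts[[1]]), sd = 0.05))
    })
    starts <- c(starts, jit)
  }
  best <- NULL
  for (s0 in starts) {
    opt <- tryCatch(
      optim(s0, objective, method = "BFGS",
            control = list(maxit = 1000, reltol = tol)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("optimization failed from every start", call. = FALSE)
  converged <- best$convergence == 0 && best$value < 1e7
  m <- pm$unpack(best$par)
  coeffs <- structure(list(B = m$B, G = m$G, Phi = m$Phi, Psi = m$Psi,
                           spec = spec, standardized = standardized),
                      class = "mrue_path_coefficients")
  Sigma <- implied_covariance(coeffs)
  F_ml <- max(best$value, 0)
  if (df == 0 && F_ml < 1e-6) F_ml <- 0  # saturated model fits exactly
  chi2 <- (n - 1) * F_ml
  # independence baseline for the normed fit index
  F_base <- ml_discrepancy(S, diag(diag(S)))
  baseline_chi2 <- (n - 1) * F_base
  fi <- fit_indices(chi2, df, n, S, Sigma, baseline_chi2)
  endo <- spec$endogenous
  r2 <- 1 - diag(coeffs$Psi) / diag(Sigma[endo, endo, drop = FALSE])
  r2 <- pmin(pmax(r2, 0), 1)
  structure(list(coefficients = coeffs, discrepancy = F_ml, chi2 = chi2,
                 df = df, p_value = fi$p_value, gfi = fi$gfi, agfi = fi$agfi,
                 nfi = fi$nfi, rmsea = fi$rmsea,
                 stability = stability_index(coeffs$B),
                 r2 = r2, converged = converged, n = n,
                 sample_cov = S, implied_cov = Sigma,
                 param_labels = pm$labels, par = best$par),
            class = "mrue_path_fit")
}

#' @export
print.mrue_path_fit <- function(x, ...) {
  cat("ML path-model fit (n =", x$n, ")\n")
  cat(sprintf("  chi2 = %.3f on df = %d (p = %s), F_ML = %.5f\n",
              x$chi2, x$df, format(round(x$p_value, 3)), x$discrepancy))
  cat(sprintf("  GFI = %.3f  AGFI = %s  NFI = %.3f  RMSEA = %s\n",
              x$gfi, format(round(x$agfi, 3)), x$nfi, format(round(x$rmsea, 3))))
  cat(sprintf("  stability index = %.3f  converged: %s\n",
              x$stability, x$converged))
  B <- x$coefficients$B; G <- x$coefficients$G
  nz <- which(B != 0, arr.ind = TRUE)
  for (i in seq_len(nrow(nz)))
    cat(sprintf("  %s -> %s: %.3f\n", colnames(B)[nz[i, 2]],
                rownames(B)[nz[i, 1]], B[nz[i, , drop = FALSE]]))
  nz <- which(G != 0, arr.ind = TRUE)
  for (i in seq_len(nrow(nz)))
    cat(sprintf("  %s -> %s: %.3f\n", colnames(G)[nz[i, 2]],
                rownames(G)[nz[i, 1]], G[nz[i, , drop = FALSE]]))
  invisible(x)
}

#' Covariance-structure fit indices
#'
#' GFI, AGFI, NFI, RMSEA and the chi-square p-value from the fitted and
#' baseline discrepancies. For a saturated model (df = 0) RMSEA and AGFI are
#' undefined and returned as NA.
#'
#' @param chi2 Model chi-square, `(n-1) * F_ML`.
#' @param df Model degrees of freedom.
#' @param n Sample size.
#' @param sample_cov,implied_cov Sample and model-implied covariance matrices.
#' @param baseline_chi2 Chi-square of the independence (diagonal) baseline.
#' @return List with gfi, agfi, nfi, rmsea, p_value.
#' @export
fit_indices <- function(chi2, df, n, sample_cov, implied_cov, baseline_chi2) {
  stopifnot(df >= 0, n > 1, chi2 >= 0)
  p <- nrow(sample_cov)
  W <- solve(implied_cov, sample_cov)
  I_p <- diag(p)
  gfi <- 1 - sum(diag((W - I_p) %*% (W - I_p))) / sum(diag(W %*% W))
  agfi <- if (df > 0) 1 - (p * (p + 1) / (2 * df)) * (1 - gfi) else NA_real_
  nfi <- if (is.finite(baseline_chi2) && baseline_chi2 > 0)
    1 - chi2 / baseline_chi2 else NA_real_
  rmsea <- if (df > 0) sqrt(max((chi2 - df) / (df * (n - 1)), 0)) else NA_real_
  p_value <- if (df > 0) pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  list(gfi = gfi, agfi = agfi, nfi = nfi, rmsea = rmsea, p_value = p_value)
}

#' Simulate observations from a path model
#'
#' Draws multivariate normal data with the model-implied covariance (zero
#' means); used for parameter-recovery checks.
#'
#' @param coeffs [path_coefficients()] object.
#' @param n Number of rows.
#' @return n x p numeric matrix with the spec's variable names.
#' @export
simulate_path_data <- function(coeffs, n) {
  Sigma <- implied_covariance(coeffs)
  L <- chol(Sigma)
  z <- matrix(rnorm(n * nrow(Sigma)), n, nrow(Sigma))
  x <- z %*% L
  colnames(x) <- rownames(Sigma)
  x
}
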