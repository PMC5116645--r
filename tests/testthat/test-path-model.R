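test_that("model specification validates structure", {
  expect_error(path_model_spec(c("a", "b"), "a", "b -> a"), "exogenous")
  expect_error(path_model_spec(c("a", "b"), "a", "a -> a"), "self-edges")
  expect_error(path_model_spec(c("a", "b"), "a", "a -> c"), "unknown")
  spec <- path_model_spec(c("a", "b", "c"), "a", c("a -> b", "b -> c", "c -> b"))
  expect_s3_class(spec, "mrue_path_spec")
  expect_identical(spec$endogenous, c("b", "c"))
})

test_that("implied covariance matches hand algebra", {
  # null model: block diagonal of Phi and Psi
  spec <- path_model_spec(c("x", "y"), "x", "x -> y")
  co <- path_coefficients(spec, c("x->y" = 0),
                          Psi = matrix(0.7, 1, 1, dimnames = list("y", "y")))
  Sigma <- implied_covariance(co)
  expect_equal(Sigma["x", "y"], 0)
  expect_equal(Sigma["y", "y"], 0.7)
  # single edge with unit variances: cov = b, var(y) = b^2 + psi
  co <- path_coefficients(spec, c("x->y" = 0.6),
                          Psi = matrix(0.64, 1, 1, dimnames = list("y", "y")))
  Sigma <- implied_covariance(co)
  expect_equal(Sigma["x", "y"], 0.6)
  expect_equal(Sigma["y", "y"], 1)
  expect_true(min(eigen(Sigma, only.values = TRUE)$values) >= 0)
})

test_that("divergent feedback loops are rejected", {
  spec <- path_model_spec(c("u", "v"), character(), c("u -> v", "v -> u"))
  co <- path_coefficients(spec, c("u->v" = 1.2, "v->u" = 1.0))
  expect_error(implied_covariance(co), "unstable")
  expect_error(decompose_effects(co, mode = "series-limit"), "diverges")
})

test_that("saturated model fits exactly and single-edge truth is recovered", {
  spec <- path_model_spec(c("x", "y"), "x", "x -> y")
  truth <- path_coefficients(spec, c("x->y" = 0.6),
                             Psi = matrix(0.64, 1, 1, dimnames = list("y", "y")))
  set.seed(501)
  dat <- simulate_path_data(truth, 10000)
  fit <- fit_ml(cov(dat), 10000, spec)
  expect_true(fit$converged)
  expect_identical(fit$df, 0)
  expect_equal(fit$discrepancy, 0)
  expect_equal(fit$chi2, 0)
  expect_lt(abs(fit$coefficients$G["y", "x"] - 0.6), 0.02)
})

test_that("feedback-loop model recovers generating sign pattern", {
  truth <- grassland_coefficients()
  set.seed(502)
  dat <- simulate_path_data(truth, 5000)
  fit <- fit_ml(cov(dat), 5000, default_model_spec(), standardized = FALSE)
  expect_true(fit$converged)
  for (m in c("B", "G")) {
    est <- fit$coefficients[[m]]
    tru <- truth[[m]]
    nz <- which(tru != 0)
    expect_true(all(sign(est[nz]) == sign(tru[nz])),
                info = paste("sign mismatch in", m))
    expect_lt(max(abs(est[nz] - tru[nz])), 0.06)
  }
  expect_true(all(fit$r2 >= 0 & fit$r2 <= 1))
  expect_equal(fit$chi2, (fit$n - 1) * fit$discrepancy)
})

test_that("non-identified models are refused", {
  # 2 observed variables (3 moments) but 4 free parameters
  spec <- path_model_spec(c("u", "v"), character(),
                          c("u -> v", "v -> u"))
  S <- matrix(c(1, 0.3, 0.3, 1), 2, 2, dimnames = list(c("u", "v"), c("u", "v")))
  expect_error(fit_ml(S, 100, spec), "not identified")
})

test_that("fit indices follow their closed forms", {
  S <- diag(3); dimnames(S) <- list(letters[1:3], letters[1:3])
  fi <- fit_indices(chi2 = 2, df = 2, n = 100, S, S, baseline_chi2 = 50)
  expect_equal(fi$rmsea, 0)     # chi2 == df: exact-fit boundary
  expect_equal(fi$gfi, 1)       # implied equals sample
  expect_equal(fi$nfi, 1 - 2 / 50)
  # chi-square upper tail at df = 2 is exp(-chi2/2)
  fi2 <- fit_indices(2.412, 2, 126, S, S, 50)
  expect_equal(fi2$p_value, exp(-1.206))
  expect_equal(round(fi2$p_value, 3), 0.299)
  fi0 <- fit_indices(0, 0, 100, S, S, 50)
  expect_true(is.na(fi0$rmsea) && is.na(fi0$agfi) && is.na(fi0$p_value))
})

test_that("stability index is the maximal loop product magnitude", {
  # acyclic
  B <- matrix(c(0, 0.5, 0, 0), 2, 2)
  expect_identical(stability_index(B), 0)
  # published two-variable feedback loop
  B2 <- matrix(c(0, 0.23, -0.11, 0), 2, 2,
               dimnames = list(c("eps", "mRUE"), c("eps", "mRUE")))
  expect_equal(stability_index(B2), 0.23 * 0.11)
  expect_equal(signif(stability_index(B2), 2), 0.025)
  # eigenvalue alternative gives the loop square root here
  expect_equal(stability_index(B2, method = "eigen"), sqrt(0.23 * 0.11))
  # three-cycle product
  B3 <- matrix(0, 3, 3)
  B3[2, 1] <- 0.5; B3[3, 2] <- 0.4; B3[1, 3] <- -0.5
  expect_equal(stability_index(B3), 0.1)
  # invariance to reordering of the endogenous variables
  perm <- c(3, 1, 2)
  expect_equal(stability_index(B3[perm, perm]), stability_index(B3))
  # grassland model: single loop eps <-> mRUE
  expect_equal(signif(stability_index(grassland_coefficients()), 2), 0.025)
})

test_that("normality diagnostics recover known moments", {
  set.seed(503)
  x <- rnorm(50000)
  expect_lt(abs(skewness(x)), 0.05)
  expect_lt(abs(kurtosis(x) - 3), 0.05)
  expect_equal(skewness(c(-1, 1, -1, 1, -1, 1)), 0)
  expect_error(skewness(rep(2, 10)), "constant")
  d <- normality_diagnostics(matrix(rnorm(3000), ncol = 3,
                                    dimnames = list(NULL, c("a", "b", "c"))))
  expect_identical(d$univariate$variable, c("a", "b", "c"))
  expect_gt(d$mardia$b1p_p, 1e-4)
})

test_that("Mardia p-values are null-calibrated", {
  set.seed(504)
  p_skew <- p_kurt <- numeric(200)
  for (i in 1:200) {
    m <- mardia(matrix(rnorm(150 * 3), 150, 3))
    p_skew[i] <- m$b1p_p
    p_kurt[i] <- m$b2p_p
  }
  expect_gt(suppressWarnings(ks.test(p_skew, "punif"))$p.value, 0.01)
  expect_gt(suppressWarnings(ks.test(p_kurt, "punif"))$p.value, 0.01)
})
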