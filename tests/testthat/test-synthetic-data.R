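test_that("precipitation levels scale ambient rainfall", {
  expect_equal(precipitation_for_level(380, 0), 380)
  expect_equal(precipitation_for_level(380, -0.6), 152)
  expect_equal(precipitation_for_level(380, 0.6), 608)
  expect_error(precipitation_for_level(380, -1), "exceed -1")
})

test_that("default design yields a valid 126-record randomized block table", {
  tab <- generate_experiment(experiment_design(seed = 701), generator_params())
  expect_identical(nrow(tab), 126L)
  expect_identical(length(unique(tab$treatment)), 7L)
  expect_identical(length(unique(tab$block)), 6L)
  expect_identical(length(unique(tab$year)), 3L)
  # validation passes with zero dropped rows
  expect_silent(out <- validate_records(tab, strict = TRUE))
  expect_identical(nrow(out), 126L)
  # a fresh seed gives a different table; the same seed reproduces it
  tab2 <- generate_experiment(experiment_design(seed = 701), generator_params())
  expect_identical(tab, tab2)
  tab3 <- generate_experiment(experiment_design(seed = 702), generator_params())
  expect_false(identical(tab$anpp, tab3$anpp))
})

test_that("noiseless control plots sit exactly at the baseline means", {
  p <- generator_params(log_sds = c(apar = 0, par = 0, tr = 0, ms = 0,
                                    n_uptake = 0, ns = 0, anpp = 0),
                        block_sd = 0, year_sd = 0)
  tab <- generate_experiment(experiment_design(seed = 703), p)
  ck <- tab[tab$treatment == 0, ]
  mu <- p$log_means
  expect_equal(unique(ck$anpp), exp(mu[["anpp"]]))
  expect_equal(unique(ck$ms), exp(mu[["ms"]]))
  expect_equal(unique(ck$apar), exp(mu[["apar"]]))
  # derived control efficiencies are then deterministic
  es <- compute_efficiency_set(ck)
  expect_equal(unique(round(es$eps_l, 12)), round(exp(mu[["apar"]] - mu[["par"]]), 12))
})

test_that("control-plot log means converge to baselines in large samples", {
  tab <- generate_experiment(experiment_design(reps = 600, seed = 704),
                             generator_params())
  expect_identical(nrow(tab), 12600L)
  ck <- tab[tab$treatment == 0, ]
  mu <- generator_params()$log_means
  for (v in c("apar", "par", "tr", "ms", "n_uptake", "ns", "anpp")) {
    expect_lt(abs(mean(log(ck[[v]])) - mu[[v]]), 0.05)
  }
})

test_that("mean absorption rate rises along the precipitation gradient", {
  # systematic gradient property, evaluated at high replication where the
  # level-mean standard error is far below the smallest treatment gap
  tab <- generate_experiment(experiment_design(reps = 600, seed = 705),
                             generator_params())
  es <- compute_efficiency_set(tab)
  level_means <- tapply(es$eps, tab$treatment, mean)
  expect_true(all(diff(level_means[order(as.numeric(names(level_means)))]) > 0))
})

test_that("path fit on pooled generations recovers the structural coefficients", {
  spec <- path_model_spec(
    variables = c("Ms", "Tr", "aPAR", "N_uptake"),
    exogenous = c("Ms", "Tr"),
    edges = c("Tr -> N_uptake", "Ms -> aPAR", "N_uptake -> aPAR"))
  p <- generator_params()
  tabs <- lapply(1:10, function(s)
    generate_experiment(experiment_design(seed = 710 + s), p))
  tab <- do.call(rbind, tabs)
  expect_identical(nrow(tab), 1260L)
  dat <- data.frame(Ms = log(tab$ms), Tr = log(tab$tr),
                    aPAR = log(tab$apar), N_uptake = log(tab$n_uptake))
  fit <- fit_ml(cov(dat), nrow(dat), spec, standardized = TRUE)
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients$G["N_uptake", "Tr"] - p$beta_tr_nuptake), 0.05)
  expect_lt(abs(fit$coefficients$G["aPAR", "Ms"] - p$beta_ms_apar), 0.05)
  expect_lt(abs(fit$coefficients$B["aPAR", "N_uptake"] - p$beta_nuptake_apar),
            0.05)
})

test_that("calibration to control targets is exact and reversible", {
  targets <- c(wue = 0.0005, lue = 0.012, nue = 62.47, anpp = 221.04)
  p <- calibrate_to_control(generator_params(), targets)
  expect_equal(exp(p$log_means[["apar"]]), 221.04 / 0.012)  # 18420
  # noiseless control record reproduces the targets exactly
  p0 <- p
  p0$log_sds[] <- 0; p0$block_sd <- 0; p0$year_sd <- 0
  tab <- generate_experiment(experiment_design(seed = 706), p0)
  es <- compute_efficiency_set(tab[tab$treatment == 0, ][1, ])
  expect_equal(es$nue, 62.47)
  expect_equal(es$wue, 0.0005)
  expect_equal(es$lue, 0.012)
  expect_equal(es$anpp, 221.04)
  # calibrating to a record's own efficiencies returns its own baselines
  p2 <- calibrate_to_control(p, c(wue = es$wue, lue = es$lue, nue = es$nue,
                                  anpp = es$anpp))
  expect_equal(p2$log_means, p$log_means)
  # infeasible targets (absorption rate >= 1) are rejected
  bad <- generator_params()
  bad$log_means["par"] <- bad$log_means["apar"] - 0.5
  expect_error(generate_experiment(experiment_design(), bad),
               "absorption rate >= 1")
  expect_error(calibrate_to_control(p, c(wue = -1, lue = 0.01, nue = 60,
                                         anpp = 200)), "positive")
})

test_that("structural coefficients leaving no residual variance are rejected", {
  expect_error(generator_params(beta_precip_ms = 0.99, block_sd = 0.2),
               "residual variance")
})
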