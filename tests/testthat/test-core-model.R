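test_that("caloric conversion maps energy to mass-equivalent units", {
  expect_identical(caloric_convert(0, 19.38), 0)
  expect_equal(caloric_convert(19.38, 19.38), 1000)
  expect_equal(caloric_convert(1, 19.38), 51.5996, tolerance = 1e-6)
  expect_error(caloric_convert(1, 0), "caloric_value")
  expect_error(caloric_convert(-1, 19.38), "non-negative")
})

test_that("geometric mean is exact, stable and domain-checked", {
  expect_equal(geometric_mean(c(7.3, 7.3, 7.3)), 7.3)
  expect_equal(geometric_mean(c(1, 8)), sqrt(8))
  expect_error(geometric_mean(c(2, 0, 5)), "positive")
  expect_error(geometric_mean(numeric(0)), "at least one")
  # permutation invariance and min/max bounds on random positive inputs
  set.seed(401)
  for (i in 1:50) {
    x <- exp(rnorm(sample(2:8, 1), sd = 3))
    g <- geometric_mean(x)
    expect_equal(g, geometric_mean(sample(x)))
    expect_gte(g, min(x))
    expect_lte(g, max(x))
  }
})

test_that("single-resource efficiency and absorption ratios", {
  # nitrogen use efficiency at published control-plot magnitudes
  expect_equal(compute_rue(221.04, 3.53833), 62.47, tolerance = 1e-5)
  expect_equal(compute_rue(50, 50), 1)
  expect_equal(compute_rue(100, 200000), 5e-4)
  expect_equal(compute_epsilon(5, 5), 1)
  expect_equal(compute_epsilon(37, 100), 0.37)
  expect_error(compute_epsilon(5, 4), "exceeds")
  expect_error(compute_epsilon(0, 4), "positive")
  expect_error(compute_rue(100, 0), "positive")
})

test_that("efficiency set reproduces hand-computed ratios and composites", {
  rec <- data.frame(plot_id = "x", treatment = 0, year = 2010,
                    anpp = 200, par = 60000, apar = 22000,
                    ms = 3.3e6, tr = 440000, ns = 40, n_uptake = 3.3)
  es <- compute_efficiency_set(rec)
  expect_equal(es$wue, 200 / 440000)
  expect_equal(es$lue, 200 / 22000)
  expect_equal(es$nue, 200 / 3.3)
  expect_equal(es$eps_l, 22000 / 60000)
  expect_equal(es$eps_w, 440000 / 3.3e6)
  expect_equal(es$eps_n, 3.3 / 40)
  expect_equal(es$mrue, (es$wue * es$lue * es$nue)^(1 / 3))
  expect_equal(es$eps, (es$eps_l * es$eps_w * es$eps_n)^(1 / 3))
  expect_equal(reconstruct_anpp(es), 200, tolerance = 1e-12)
})

test_that("full absorption with production at the available geometric mean gives unit composites", {
  rec <- data.frame(plot_id = "x", treatment = 0, year = 2010,
                    anpp = geometric_mean(c(300, 500, 40)),
                    par = 300, apar = 300, ms = 500, tr = 500,
                    ns = 40, n_uptake = 40)
  es <- compute_efficiency_set(rec)
  expect_equal(es$eps_l, 1)
  expect_equal(es$eps, 1)
  expect_equal(es$mrue, 1, tolerance = 1e-12)
})

test_that("reconstruction identity and per-resource identity hold on random records", {
  rec <- random_records(1000, seed = 7)
  es <- compute_efficiency_set(rec)
  expect_lt(max(abs(reconstruct_anpp(es) / rec$anpp - 1)), 1e-10)
  # available_i * eps_i * RUE_i = anpp for each resource
  expect_equal(rec$par * es$eps_l * es$lue, rec$anpp, tolerance = 1e-12)
  expect_equal(rec$ms * es$eps_w * es$wue, rec$anpp, tolerance = 1e-12)
  expect_equal(rec$ns * es$eps_n * es$nue, rec$anpp, tolerance = 1e-12)
})

test_that("efficiencies transform covariantly under rescaling", {
  rec <- random_records(20, seed = 11)
  es <- compute_efficiency_set(rec)
  # scaling production and all absorbed amounts leaves absorption rates for
  # scaled availables; scaling production alone scales every RUE and mRUE
  c_fac <- 3.7
  rec2 <- rec
  rec2$anpp <- rec$anpp * c_fac
  es2 <- compute_efficiency_set(rec2)
  expect_equal(es2$wue, es$wue * c_fac)
  expect_equal(es2$lue, es$lue * c_fac)
  expect_equal(es2$nue, es$nue * c_fac)
  expect_equal(es2$mrue, es$mrue * c_fac, tolerance = 1e-12)
  expect_equal(es2$eps, es$eps)
  rec3 <- rec
  for (cl in c("apar", "tr", "n_uptake", "par", "ms", "ns"))
    rec3[[cl]] <- rec[[cl]] * c_fac
  es3 <- compute_efficiency_set(rec3)
  expect_equal(es3$eps, es$eps, tolerance = 1e-12)
})

test_that("record validation enforces positivity and absorbed <= available", {
  rec <- random_records(5, seed = 3)
  rec$apar[3] <- rec$par[3] * 1.5
  expect_error(validate_records(rec), "row 3.*apar > par")
  expect_warning(out <- validate_records(rec, strict = FALSE), "dropping 1")
  expect_identical(nrow(out), 4L)
  rec2 <- random_records(4, seed = 4)
  rec2$anpp[2] <- -1
  expect_error(validate_records(rec2), "non-positive anpp")
  expect_error(validate_records(rec2[, -4]), "missing column")
})
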