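test_that("variable draws are reproducible, positive and calibrated", {
  cfg <- mc_config(n = 200, seed = 31)
  t1 <- draw_variables(cfg)
  t2 <- draw_variables(cfg)
  expect_identical(t1, t2)                 # same seed, same table
  expect_true(all(t1 > 0))
  # zero-sd specs give the constant means
  cfg0 <- mc_config(specs = data.frame(name = c("A", "B"), mean = c(4, 9),
                                       sd = c(0, 0)), n = 10)
  expect_equal(unname(draw_variables(cfg0)[, "A"]), rep(4, 10))
  # law of large numbers at the default aPAR specification
  cfgN <- mc_config(n = 100000, seed = 32)
  big <- draw_variables(cfgN)
  expect_lt(abs(mean(big[, "aPAR"]) - 10), 0.01)
  expect_lt(abs(sd(big[, "aPAR"]) - 0.3), 0.01)
})

test_that("composites evaluate the ratio formulas", {
  tab <- matrix(rep(c(10, 11, 13, 15, 1.2, 3.7, 5.3), each = 4), nrow = 4,
                dimnames = list(NULL, c("aPAR", "PAR", "Tr", "Ms",
                                        "N_uptake", "N_avail", "ANPP")))
  eps <- composite_from_draws(tab, "eps")
  # ((10/11)(13/15)(1.2/3.7))^(1/3) = 0.2555282555^(1/3), exact arithmetic
  expect_equal(unique(round(eps, 5)), 0.63457)
  mrue <- composite_from_draws(tab, "mrue")
  expect_equal(unique(round(mrue, 5)), 0.98454)  # 5.3 / 156^(1/3)
  tab1 <- tab; tab1[, c("PAR", "Ms", "N_avail")] <- tab[, c("aPAR", "Tr", "N_uptake")]
  expect_equal(unname(composite_from_draws(tab1, "eps")), rep(1, 4))
  expect_error(composite_from_draws(tab[, -1], "eps"), "lacks column")
})

test_that("spurious R2 matches the delta-method oracle for the five shared pairs", {
  pairs <- list(c("aPAR", "eps"), c("N_uptake", "eps"), c("Tr", "eps"),
                c("Ms", "eps"), c("N_uptake", "mrue"))
  cfg <- mc_config(seed = 33)
  for (pr in pairs) {
    d <- spurious_r2(cfg, pr[1], pr[2])
    expect_true(all(d$r2_samples >= 0 & d$r2_samples <= 1))
    expect_true(all(diff(d$quantiles) >= 0))
    a <- analytic_spurious_r2(cfg$specs, pr[1], pr[2], n = cfg$n)
    expect_lt(abs(d$mean_r2 - a), 2 * d$mc_standard_error + 0.002,
              label = paste(pr[1], pr[2], "MC vs analytic"))
  }
  # bit-for-bit reproducibility under a fixed seed
  d1 <- spurious_r2(cfg, "aPAR", "eps")
  d2 <- spurious_r2(cfg, "aPAR", "eps")
  expect_identical(d1$r2_samples, d2$r2_samples)
})

test_that("a variable outside the composite gives the independence baseline", {
  cfg <- mc_config(seed = 34)
  d <- spurious_r2(cfg, "Ms", "mrue")  # Ms does not enter mrue
  expect_lt(abs(d$mean_r2 - 1 / (cfg$n - 1)), 0.003)
  expect_equal(analytic_spurious_r2(cfg$specs, "Ms", "mrue", n = Inf), 0)
})

test_that("degenerate configurations are handled explicitly", {
  sp <- mc_variable_specs()
  sp$sd[sp$name != "aPAR"] <- 0
  # composite still varies through aPAR itself; zero out the common variable
  sp2 <- mc_variable_specs(); sp2$sd <- rep(0, 7)
  cfg2 <- mc_config(specs = sp2, n = 20, reps = 3, seed = 35)
  expect_warning(d <- spurious_r2(cfg2, "aPAR", "eps"), "degenerate")
  expect_equal(d$mean_r2, 0)
  # analytic oracle: sd-0 common variable leaves only the finite-sample term
  sp3 <- mc_variable_specs(); sp3$sd[sp3$name == "aPAR"] <- 0
  expect_equal(analytic_spurious_r2(sp3, "aPAR", "eps", n = 126),
               (1 - analytic_spurious_r2(sp3, "aPAR", "eps", n = Inf))^2 / 126)
  expect_warning(
    analytic_spurious_r2(data.frame(name = c("aPAR", "PAR"), mean = c(1, 1),
                                    sd = c(0.9, 0.1)), "aPAR", "eps"),
    "delta approximation")
})

test_that("dispersion scans follow the analytic monotonicities", {
  # equal scaling of both sds leaves the spurious correlation unchanged
  sc <- sd_scaling_scan(multipliers = c(1, 2, 5), reps = 300, seed = 36)
  means <- vapply(sc, function(d) d$mean_r2, 1)
  ses <- vapply(sc, function(d) d$mc_standard_error, 1)
  expect_lt(max(means) - min(means), 3 * max(ses) + 0.01)
  expect_lt(abs(means[["T1"]] - 0.5), 0.02)  # rho^2 = 1/2 by symmetry
  # growing the independent variable's sd shrinks the common share
  rs <- sd_ratio_scan(multiples = c(2, 5, 10), reps = 300, seed = 37)
  rmeans <- vapply(rs, function(d) d$mean_r2, 1)
  expect_true(rmeans[["T2"]] > rmeans[["T5"]]
              && rmeans[["T5"]] > rmeans[["T10"]])
  expect_lt(abs(rmeans[["T2"]] - 1 / 5), 0.03)  # 1/(1+2^2)
})

test_that("sample size leaves the mean unchanged but shrinks the spread", {
  sz <- sample_size_scan(sizes = c(500, 1000, 2000, 10000), reps = 300,
                         seed = 38)
  means <- vapply(sz, function(d) d$mean_r2, 1)
  ses <- vapply(sz, function(d) d$mc_standard_error, 1)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_lt(abs(means[i] - means[j]), 2 * (ses[i] + ses[j]) + 0.002)
  }
  iqr <- vapply(sz, function(d) d$quantiles[[4]] - d$quantiles[[2]], 1)
  expect_true(all(diff(iqr) < 0))
})

test_that("letter groupings separate what the tests separate", {
  mk <- function(x) mrue:::new_spurious_distribution("A", "eps", x, 100)
  set.seed(39)
  base <- runif(400, 0.2, 0.3)
  same <- compare_groups(list(g1 = mk(base), g2 = mk(base)))
  expect_identical(same$letters[1], same$letters[2])
  far <- compare_groups(list(lo = mk(base), hi = mk(base + 0.5)))
  expect_false(far$letters[1] == far$letters[2])
  # extremes differ, middle overlaps both: a / ab / b
  tri <- compare_groups(list(lo = mk(base),
                             mid = mk(base + 0.004),
                             hi = mk(base + 0.008)))
  expect_identical(sort(nchar(tri$letters)), c(1L, 1L, 2L))
  expect_identical(tri$letters[tri$group == "mid"], "ab")
  expect_error(compare_groups(list(mk(base))), "at least two")
})

test_that("importance weighting of spurious contributions", {
  expect_equal(weighted_spurious(0.1, 0.28), 0.028)
  expect_equal(weighted_spurious(0.04, 0.05), 0.002)
  expect_equal(weighted_spurious(0.7, 0), 0)
  expect_error(weighted_spurious(1.2, 0.5), "0, 1")
})
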