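#' Factorial layout of the synthetic precipitation-gradient experiment
#'
#' A randomized-block design: precipitation manipulation levels (fractions of
#' ambient precipitation, default -60% to +60% in 20% steps) crossed with
#' blocks (replicates) and years.
#'
#' @param deltas Precipitation delta fractions, each > -1.
#' @param reps Number of blocks (>= 1), default 6.
#' @param years Number of years, default 3.
#' @param base_precip Ambient annual precipitation in mm, default 380.
#' @param seed Optional RNG seed for [generate_experiment()].
#' @return List of class `mrue_design`; total records = levels x reps x years.
#' @export
experiment_design <- function(deltas = seq(-0.6, 0.6, by = 0.2), reps = 6,
                              years = 3, base_precip = 380, seed = NULL) {
  deltas <- round(deltas, 10)
  if (any(deltas <= -1)) stop("precipitation deltas must exceed -1", call. = FALSE)
  if (reps < 1 || years < 1) stop("`reps` and `years` must be >= 1", call. = FALSE)
  if (base_precip <= 0) stop("`base_precip` must be positive", call. = FALSE)
  structure(list(deltas = deltas, reps = as.integer(reps),
                 years = as.integer(years), base_precip = base_precip,
                 seed = seed),
            class = "mrue_design")
}

#' Annual precipitation under a manipulation level
#'
#' @param base Ambient precipitation, mm.
#' @param delta Manipulation fraction (> -1), e.g. -0.6 for a 60% exclusion.
#' @return `base * (1 + delta)`, mm.
#' @export
precipitation_for_level <- function(base, delta) {
  if (any(delta <= -1)) stop("`delta` must exceed -1", call. = FALSE)
  if (any(base <= 0)) stop("`base` must be positive", call. = FALSE)
  base * (1 + delta)
}

#' Structural parameters of the synthetic experiment generator
#'
#' Variables are generated on the log scale (Gaussian noise there is
#' multiplicative on the measurement scale, appropriate for strictly positive
#' accumulations): each variable's log value is `log_mean + log_sd * z`, with
#' the unit-variance scores `z` linked by standardized structural
#' coefficients. Precipitation (via its standardized log driver) raises soil
#' water and transpiration; transpiration carries nitrogen uptake (mass
#' flow); soil water and nitrogen uptake raise absorbed light; production
#' follows a log-linear combination of transpiration, absorbed light,
#' nitrogen uptake and soil water. Block and year intercepts are shared
#' random effects on the water-driven scores. The default log means and sds
#' are the observed log-scale magnitudes of a semi-arid grassland experiment;
#' the default structural coefficients carry the signs and magnitudes of its
#' fitted path model.
#'
#' @param log_means,log_sds Named vectors over apar, par, tr, ms, n_uptake,
#'   ns, anpp.
#' @param beta_precip_ms,beta_precip_tr Standardized effect of the
#'   precipitation driver on soil water / transpiration scores.
#' @param beta_tr_nuptake,beta_ms_apar,beta_nuptake_apar Standardized
#'   structural coefficients among the resource scores.
#' @param anpp_loadings Standardized loadings of the production score on
#'   (tr, apar, n_uptake, ms); the default negative soil-water loading
#'   induces the declining-marginal-returns signature (water suppresses the
#'   composite use efficiency while raising the absorption rate).
#' @param block_sd,year_sd Standard deviations (on the unit-variance score
#'   scale) of the shared block and year random intercepts.
#' @return List of class `mrue_generator_params`.
#' @export
generator_params <- function(
    log_means = c(apar = 10, par = 11, tr = 13, ms = 15,
                  n_uptake = 1.2, ns = 3.7, anpp = 5.3),
    log_sds = c(apar = 0.3, par = 0.04, tr = 0.3, ms = 0.2,
                n_uptake = 0.05, ns = 0.17, anpp = 0.4),
    beta_precip_ms = 0.85, beta_precip_tr = 0.75,
    beta_tr_nuptake = 0.32, beta_ms_apar = 0.58, beta_nuptake_apar = 0.35,
    anpp_loadings = c(tr = 0.40, apar = 0.30, n_uptake = 0.30, ms = -0.35),
    block_sd = 0.1, year_sd = 0.1) {
  vars <- c("apar", "par", "tr", "ms", "n_uptake", "ns", "anpp")
  if (!all(vars %in% names(log_means)) || !all(vars %in% names(log_sds))) {
    stop("log_means and log_sds must name all of: ",
         paste(vars, collapse = ", "), call. = FALSE)
  }
  if (any(log_sds < 0)) stop("log sds must be non-negative", call. = FALSE)
  if (block_sd < 0 || year_sd < 0) stop("random-effect sds must be non-negative",
                                        call. = FALSE)
  p <- list(log_means = log_means[vars], log_sds = log_sds[vars],
            beta_precip_ms = beta_precip_ms, beta_precip_tr = beta_precip_tr,
            beta_tr_nuptake = beta_tr_nuptake, beta_ms_apar = beta_ms_apar,
            beta_nuptake_apar = beta_nuptake_apar,
            anpp_loadings = anpp_loadings[c("tr", "apar", "n_uptake", "ms")],
            block_sd = block_sd, year_sd = year_sd)
  # residual variances must be positive for unit-variance scores
  rv <- score_residuals(p)
  bad <- names(rv)[rv < 0]
  if (length(bad)) {
    stop("structural coefficients leave no residual variance for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(p, class = "mrue_generator_params")
}

# Residual variances keeping every score at unit variance, plus the implied
# covariance pieces needed for the production equation.
score_residuals <- function(p) {
  re2 <- p$block_sd^2 + p$year_sd^2
  r_ms <- 1 - p$beta_precip_ms^2 - re2
  r_tr <- 1 - p$beta_precip_tr^2 - re2
  c_mt <- p$beta_precip_ms * p$beta_precip_tr + re2  # cov(ms, tr) scores
  r_nup <- 1 - p$beta_tr_nuptake^2
  c_mn <- p$beta_tr_nuptake * c_mt
  r_apar <- 1 - (p$beta_ms_apar^2 + p$beta_nuptake_apar^2 +
                   2 * p$beta_ms_apar * p$beta_nuptake_apar * c_mn)
  # covariance matrix of (tr, apar, n_uptake, ms) scores
  c_tn <- p$beta_tr_nuptake
  c_ta <- p$beta_ms_apar * c_mt + p$beta_nuptake_apar * c_tn
  c_na <- p$beta_ms_apar * c_mn + p$beta_nuptake_apar
  c_ma <- p$beta_ms_apar + p$beta_nuptake_apar * c_mn
  C <- matrix(c(1,    c_ta, c_tn, c_mt,
                c_ta, 1,    c_na, c_ma,
                c_tn, c_na, 1,    c_mn,
                c_mt, c_ma, c_mn, 1), 4, 4,
              dimnames = list(c("tr", "apar", "n_uptake", "ms"),
                              c("tr", "apar", "n_uptake", "ms")))
  l <- p$anpp_loadings
  r_anpp <- 1 - as.numeric(t(l) %*% C %*% l)
  c(ms = r_ms, tr = r_tr, n_uptake = r_nup, apar = r_apar, anpp = r_anpp)
}

#' Generate a synthetic resource-record table
#'
#' Draws one realization of the randomized-block precipitation-gradient
#' experiment described by `design` and `params`. Control plots sit exactly
#' at the baseline log means in the noiseless limit (the precipitation driver
#' is scaled but not centred). Physical invariants (absorbed <= available)
#' hold for every returned row: rows violating them in the far Gaussian tail
#' are resampled, and a parameter set whose mean structure already implies an
#' absorption rate >= 1 is rejected outright.
#'
#' @param design [experiment_design()].
#' @param params [generator_params()].
#' @return data.frame of validated resource records (one row per
#'   plot x year) with columns plot_id, block, treatment, precip_mm, year,
#'   anpp, par, apar, ms, tr, ns, n_uptake.
#' @examples
#' tab <- generate_experiment(experiment_design(seed = 1), generator_params())
#' nrow(tab)  # 126
#' @export
generate_experiment <- function(design, params = generator_params()) {
  stopifnot(inherits(design, "mrue_design"),
            inherits(params, "mrue_generator_params"))
  mu <- params$log_means
  if (mu["apar"] >= mu["par"] || mu["tr"] >= mu["ms"] ||
      mu["n_uptake"] >= mu["ns"]) {
    off <- c("apar >= par", "tr >= ms", "n_uptake >= ns")[
      c(mu["apar"] >= mu["par"], mu["tr"] >= mu["ms"],
        mu["n_uptake"] >= mu["ns"])]
    stop("baseline log means imply absorption rate >= 1 (",
         paste(off, collapse = ", "), ")", call. = FALSE)
  }
  if (!is.null(design$seed)) set.seed(design$seed)

  grid <- expand.grid(block = seq_len(design$reps),
                      delta = design$deltas,
                      year_i = seq_len(design$years))
  m <- nrow(grid)
  x_raw <- log1p(grid$delta)
  s <- sd(log1p(design$deltas))
  x <- if (length(design$deltas) > 1 && s > 0) x_raw / s else x_raw

  u_b <- rnorm(design$reps, 0, params$block_sd)
  v_y <- rnorm(design$years, 0, params$year_sd)
  re <- u_b[grid$block] + v_y[grid$year_i]
  rv <- score_residuals(params)

  draw_rows <- function(idx) {
    k <- length(idx)
    z_ms <- params$beta_precip_ms * x[idx] + re[idx] + sqrt(rv["ms"]) * rnorm(k)
    z_tr <- params$beta_precip_tr * x[idx] + re[idx] + sqrt(rv["tr"]) * rnorm(k)
    z_nup <- params$beta_tr_nuptake * z_tr + sqrt(rv["n_uptake"]) * rnorm(k)
    z_apar <- params$beta_ms_apar * z_ms + params$beta_nuptake_apar * z_nup +
      sqrt(rv["apar"]) * rnorm(k)
    z_par <- rnorm(k)
    z_ns <- rnorm(k)
    l <- params$anpp_loadings
    z_anpp <- l["tr"] * z_tr + l["apar"] * z_apar + l["n_uptake"] * z_nup +
      l["ms"] * z_ms + sqrt(rv["anpp"]) * rnorm(k)
    sg <- params$log_sds
    data.frame(
      anpp = exp(mu["anpp"] + sg["anpp"] * z_anpp),
      par = exp(mu["par"] + sg["par"] * z_par),
      apar = exp(mu["apar"] + sg["apar"] * z_apar),
      ms = exp(mu["ms"] + sg["ms"] * z_ms),
      tr = exp(mu["tr"] + sg["tr"] * z_tr),
      ns = exp(mu["ns"] + sg["ns"] * z_ns),
      n_uptake = exp(mu["n_uptake"] + sg["n_uptake"] * z_nup),
      row.names = NULL)
  }

  vals <- draw_rows(seq_len(m))
  for (iter in seq_len(50)) {
    bad <- vals$apar > vals$par | vals$tr > vals$ms | vals$n_uptake > vals$ns
    if (!any(bad)) break
    vals[bad, ] <- draw_rows(which(bad))
    if (iter == 50) stop("could not satisfy absorbed <= available after 50 resampling passes",
                         call. = FALSE)
  }

  lbl <- ifelse(grid$delta == 0, "CK",
                paste0("P", ifelse(grid$delta > 0, "+", "-"),
                       round(abs(grid$delta) * 10)))
  out <- cbind(
    data.frame(plot_id = paste0(lbl, "_B", grid$block),
               block = grid$block,
               treatment = grid$delta,
               precip_mm = precipitation_for_level(design$base_precip, grid$delta),
               year = 2009L + grid$year_i),
    vals)
  validate_records(out, strict = TRUE)
  out
}

#' Calibrate generator baselines to control-plot targets
#'
#' Adjusts the baseline log means so a noiseless control-plot record
#' reproduces given control-plot efficiencies and production exactly
#' (closed form: absorbed_i = ANPP / RUE_i). The available-resource log
#' means keep their offsets from the corresponding absorbed means, which
#' preserves the baseline absorption rates.
#'
#' @param params [generator_params()].
#' @param targets Named numeric vector with wue, lue, nue (ratios, e.g.
#'   0.0005 for 0.05%) and anpp (g m^-2 yr^-1), all positive.
#' @return A recalibrated `mrue_generator_params`.
#' @examples
#' p <- calibrate_to_control(generator_params(),
#'   c(wue = 0.0005, lue = 0.012, nue = 62.47, anpp = 221.04))
#' exp(p$log_means["apar"])  # 221.04 / 0.012
#' @export
calibrate_to_control <- function(params, targets) {
  stopifnot(inherits(params, "mrue_generator_params"))
  need <- c("wue", "lue", "nue", "anpp")
  if (!all(need %in% names(targets))) {
    stop("`targets` must name ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(targets[need] <= 0)) stop("targets must be positive", call. = FALSE)
  mu <- params$log_means
  gap <- c(par = unname(mu["par"] - mu["apar"]),
           ms = unname(mu["ms"] - mu["tr"]),
           ns = unname(mu["ns"] - mu["n_uptake"]))
  mu["anpp"] <- log(targets[["anpp"]])
  mu["tr"] <- log(targets[["anpp"]] / targets[["wue"]])
  mu["apar"] <- log(targets[["anpp"]] / targets[["lue"]])
  mu["n_uptake"] <- log(targets[["anpp"]] / targets[["nue"]])
  mu["par"] <- mu["apar"] + gap["par"]
  mu["ms"] <- mu["tr"] + gap["ms"]
  mu["ns"] <- mu["n_uptake"] + gap["ns"]
  if (any(gap <= 0)) {
    stop("calibration implies absorption rate >= 1 for: ",
         paste(names(gap)[gap <= 0], collapse = ", "), call. = FALSE)
  }
  params$log_means <- mu
  params
}
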