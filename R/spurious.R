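#' Default variable specifications for the spurious-correlation Monte Carlo
#'
#' Means and standard deviations, on the measurement (log-accumulation) scale,
#' of the seven variables entering the composite absorption rate and use
#' efficiency: absorbed and incident light (aPAR, PAR), transpiration and soil
#' water (Tr, Ms), nitrogen uptake and available nitrogen (N_uptake, N_avail),
#' and production (ANPP).
#'
#' @return data.frame with columns name, mean, sd.
#' @export
mc_variable_specs <- function() {
  data.frame(
    name = c("aPAR", "PAR", "Tr", "Ms", "N_uptake", "N_avail", "ANPP"),
    mean = c(10, 11, 13, 15, 1.2, 3.7, 5.3),
    sd = c(0.3, 0.04, 0.3, 0.2, 0.05, 0.17, 0.4))
}

#' Configuration for the spurious-correlation Monte Carlo
#'
#' @param specs data.frame(name, mean, sd) of variable specifications;
#'   defaults to [mc_variable_specs()].
#' @param n Per-replicate sample size (>= 3); default 126, the size of a
#'   7-level x 6-replicate x 3-year experiment.
#' @param reps Number of Monte Carlo replicates (>= 1), default 1000.
#' @param seed Optional RNG seed for reproducibility.
#' @param correlate_on_log If TRUE (default) correlations are computed between
#'   log-transformed variable and composite, matching an analysis pipeline
#'   that log-transforms before modelling. At the small coefficients of
#'   variation involved the raw-scale results differ negligibly.
#' @return List of class `mrue_mc_config`.
#' @export
mc_config <- function(specs = mc_variable_specs(), n = 126, reps = 1000,
                      seed = NULL, correlate_on_log = TRUE) {
  stopifnot(is.data.frame(specs), all(c("name", "mean", "sd") %in% names(specs)))
  if (any(specs$mean <= 0)) stop("variable means must be positive (variables enter ratios and logs)",
                                 call. = FALSE)
  if (any(specs$sd < 0)) stop("variable sds must be non-negative", call. = FALSE)
  if (n < 3) stop("`n` must be at least 3", call. = FALSE)
  if (reps < 1) stop("`reps` must be at least 1", call. = FALSE)
  structure(list(specs = specs, n = as.integer(n), reps = as.integer(reps),
                 seed = seed, correlate_on_log = isTRUE(correlate_on_log)),
            class = "mrue_mc_config")
}

#' Draw one Monte Carlo replicate table
#'
#' Independent normal draws per variable; non-positive draws (which would
#' break the ratios and logs downstream) are rejection-resampled, and the
#' rejection rate is reported via the `rejections` attribute. A rejection
#' rate above 10% aborts, since the normal specification is then a poor
#' model for a positive quantity.
#'
#' @param config An `mrue_mc_config`.
#' @param seed Seed to set before drawing (default: the config's seed; pass
#'   NULL to continue the current RNG stream).
#' @return n x p numeric matrix, columns named as in the specs, with
#'   attribute `rejections` (count of resampled draws).
#' @export
draw_variables <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "mrue_mc_config"))
  if (!is.null(seed)) set.seed(seed)
  sp <- config$specs
  n <- config$n
  out <- matrix(NA_real_, n, nrow(sp), dimnames = list(NULL, sp$name))
  rejections <- 0L
  for (j in seq_len(nrow(sp))) {
    x <- rnorm(n, sp$mean[j], sp$sd[j])
    tries <- 0L
    while (any(bad <- x <= 0)) {
      rejections <- rejections + sum(bad)
      tries <- tries + 1L
      if (rejections > 0.1 * n * nrow(sp) && tries > 10L) {
        stop("rejection rate above 10% for variable `", sp$name[j],
             "`; mean/sd imply frequent non-positive draws", call. = FALSE)
      }
      x[bad] <- rnorm(sum(bad), sp$mean[j], sp$sd[j])
    }
    out[, j] <- x
  }
  attr(out, "rejections") <- rejections
  out
}

#' Composite indices from a replicate table
#'
#' The composite absorption rate
#' `eps = ((aPAR/PAR) * (Tr/Ms) * (N_uptake/N_avail))^(1/3)` and the composite
#' use efficiency `mrue = ANPP / (aPAR * Tr * N_uptake)^(1/3)` computed
#' row-wise.
#'
#' @param table Matrix/data.frame containing the needed columns.
#' @param which `"eps"` or `"mrue"`.
#' @return Numeric vector of per-row composite values.
#' @export
composite_from_draws <- function(table, which = c("eps", "mrue")) {
  which <- match.arg(which)
  needed <- if (which == "eps") c("aPAR", "PAR", "Tr", "Ms", "N_uptake", "N_avail")
            else c("ANPP", "aPAR", "Tr", "N_uptake")
  missing_cols <- setdiff(needed, colnames(table))
  if (length(missing_cols)) {
    stop("table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tab <- as.data.frame(table)
  if (which == "eps") {
    ((tab$aPAR / tab$PAR) * (tab$Tr / tab$Ms) *
       (tab$N_uptake / tab$N_avail))^(1 / 3)
  } else {
    tab$ANPP / (tab$aPAR * tab$Tr * tab$N_uptake)^(1 / 3)
  }
}

new_spurious_distribution <- function(common, which, samples, n) {
  qs <- quantile(samples, c(0.10, 0.25, 0.50, 0.75, 0.90), names = TRUE)
  structure(list(common = common, composite = which, r2_samples = samples,
                 mean_r2 = mean(samples), quantiles = qs,
                 mc_standard_error = sd(samples) / sqrt(length(samples)),
                 n = n, reps = length(samples)),
            class = "mrue_spurious")
}

#' @export
print.mrue_spurious <- function(x, ...) {
  cat(sprintf("Spurious R2: %s vs %s (n = %d, reps = %d)\n",
              x$common, x$composite, x$n, x$reps))
  cat(sprintf("  mean = %.4f (MC SE %.5f)\n", x$mean_r2, x$mc_standard_error))
  cat("  quantiles:", paste(names(x$quantiles),
                            sprintf("%.4f", x$quantiles)), "\n")
  invisible(x)
}

#' Monte Carlo spurious determination coefficient
#'
#' Quantifies the correlation that arises between a composite index and one of
#' its own component variables even when all components are drawn
#' independently: per replicate, draws the variable table, computes the
#' composite, and takes the squared Pearson correlation between the (log of
#' the) common variable and the (log of the) composite; aggregates the
#' replicate R-squared values into a distribution summary.
#'
#' @param config An `mrue_mc_config` (its seed, if any, fixes the whole run).
#' @param common Name of the common variable.
#' @param which `"eps"` or `"mrue"`. A `common` variable absent from the
#'   chosen composite's formula is allowed and gives the null baseline
#'   (mean R-squared near 1/(n-1)).
#' @return Object of class `mrue_spurious` with elements r2_samples, mean_r2,
#'   quantiles (10/25/50/75/90), mc_standard_error.
#' @examples
#' cfg <- mc_config(n = 126, reps = 100, seed = 42)
#' spurious_r2(cfg, "aPAR", "eps")
#' @export
spurious_r2 <- function(config, common, which = c("eps", "mrue")) {
  stopifnot(inherits(config, "mrue_mc_config"))
  which <- match.arg(which)
  if (!common %in% config$specs$name) {
    stop("unknown variable: ", common, call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  samples <- numeric(config$reps)
  warned <- FALSE
  for (r in seq_len(config$reps)) {
    tab <- draw_variables(config, seed = NULL)
    comp <- composite_from_draws(tab, which)
    x <- tab[, common]
    if (config$correlate_on_log) {
      x <- log(x); comp <- log(comp)
    }
    if (sd(comp) == 0 || sd(x) == 0) {
      if (!warned) {
        warning("degenerate replicate (constant variable or composite); ",
                "R2 reported as 0", call. = FALSE)
        warned <- TRUE
      }
      samples[r] <- 0
    } else {
      samples[r] <- cor(x, comp)^2
    }
  }
  new_spurious_distribution(common, which, samples, config$n)
}

# signed log-scale loading of each variable in each composite
composite_loadings <- function(which) {
  if (which == "eps") {
    c(aPAR = 1 / 3, PAR = -1 / 3, Tr = 1 / 3, Ms = -1 / 3,
      N_uptake = 1 / 3, N_avail = -1 / 3)
  } else {
    c(ANPP = 1, aPAR = -1 / 3, Tr = -1 / 3, N_uptake = -1 / 3)
  }
}

#' Delta-method approximation to the spurious R-squared
#'
#' Independent verification oracle for [spurious_r2()]: at small coefficients
#' of variation, `log X` is approximately normal with sd `sd(X)/mean(X)`, the
#' log composite is the corresponding signed linear combination, and the
#' population squared correlation between the common variable and the
#' composite is `rho^2 = (c * cv_common)^2 / sum((c_i * cv_i)^2)` with `c_i`
#' the composite's log-scale loadings. The expected sample R-squared adds the
#' finite-sample bias `(1 - rho^2)^2 / n`.
#'
#' @param specs data.frame(name, mean, sd).
#' @param common Common variable name.
#' @param which `"eps"` or `"mrue"`.
#' @param n Sample size for the finite-sample bias term (default 126;
#'   use `Inf` for the population value).
#' @return Scalar approximate expected R-squared.
#' @export
analytic_spurious_r2 <- function(specs, common, which = c("eps", "mrue"),
                                 n = 126) {
  which <- match.arg(which)
  if (!common %in% specs$name) stop("unknown variable: ", common, call. = FALSE)
  cv <- setNames(specs$sd / specs$mean, specs$name)
  if (any(cv >= 0.5)) {
    warning("coefficient of variation >= 0.5 for ",
            paste(specs$name[cv >= 0.5], collapse = ", "),
            "; the small-CV delta approximation degrades", call. = FALSE)
  }
  load <- composite_loadings(which)
  load <- load[names(load) %in% names(cv)]  # absent variables act as constants
  contrib <- (load * cv[names(load)])^2
  var_comp <- sum(contrib)
  rho2 <- if (common %in% names(load) && var_comp > 0)
    contrib[common] / var_comp else 0
  unname(rho2 + if (is.finite(n)) (1 - rho2)^2 / n else 0)
}

# Generic two-variable scan machinery for sensitivity analyses: A is the
# common variable, B the independent one; the eps-type composite is A/B
# (common in the numerator), the mrue-type composite is B/A (common in the
# denominator). Correlation between log A and the log composite.
scan_run <- function(n, mean_ab, sd_a, sd_b, reps, which) {
  specs <- data.frame(name = c("A", "B"), mean = mean_ab, sd = c(sd_a, sd_b))
  cfg <- mc_config(specs = specs, n = n, reps = reps, seed = NULL)
  samples <- numeric(reps)
  for (r in seq_len(reps)) {
    tab <- draw_variables(cfg, seed = NULL)
    comp <- if (which == "eps") tab[, "A"] / tab[, "B"] else tab[, "B"] / tab[, "A"]
    samples[r] <- cor(log(tab[, "A"]), log(comp))^2
  }
  new_spurious_distribution("A", which, samples, n)
}

#' Sensitivity scans for the spurious correlation of ratio composites
#'
#' Three stochastic scans over a generic two-variable setup (common variable A
#' and independent variable B, both with mean 20, initial SD(A) = 1, n = 200,
#' 1000 replicates per scenario):
#' \describe{
#'   \item{`sd_scaling_scan()`}{both SDs set to `multiplier * sd_a`; the
#'     population correlation is invariant to this common scaling.}
#'   \item{`sd_ratio_scan()`}{SD(B) set to `multiple * sd_a`; the common
#'     variable's share of the composite variance, and hence the spurious
#'     R-squared, shrinks as the multiple grows.}
#'   \item{`sample_size_scan()`}{n varied with SDs held at `sd_a`; means are
#'     stable while replicate-to-replicate variability shrinks.}
#' }
#'
#' @param multipliers,multiples,sizes Scenario values.
#' @param which `"eps"` (common variable in the numerator) or `"mrue"`
#'   (common variable in the denominator).
#' @param n,mean,sd_a,reps Base setup parameters.
#' @param seed Optional seed fixing the whole scan.
#' @return Named list of `mrue_spurious` distributions, one per scenario.
#' @export
sd_scaling_scan <- function(multipliers = c(1, 2, 5), which = c("eps", "mrue"),
                            n = 200, mean = 20, sd_a = 1, reps = 1000,
                            seed = NULL) {
  which <- match.arg(which)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(multipliers, function(m)
    scan_run(n, c(mean, mean), m * sd_a, m * sd_a, reps, which))
  names(out) <- paste0("T", multipliers)
  out
}

#' @rdname sd_scaling_scan
#' @export
sd_ratio_scan <- function(multiples = c(2, 5, 10), which = c("eps", "mrue"),
                          n = 200, mean = 20, sd_a = 1, reps = 1000,
                          seed = NULL) {
  which <- match.arg(which)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(multiples, function(m)
    scan_run(n, c(mean, mean), sd_a, m * sd_a, reps, which))
  names(out) <- paste0("T", multiples)
  out
}

#' @rdname sd_scaling_scan
#' @export
sample_size_scan <- function(sizes = c(500, 1000, 2000, 10000),
                             which = c("eps", "mrue"), mean = 20, sd_a = 1,
                             reps = 1000, seed = NULL) {
  which <- match.arg(which)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(sizes, function(nn)
    scan_run(nn, c(mean, mean), sd_a, sd_a, reps, which))
  names(out) <- as.character(sizes)
  out
}

#' Compact letter display for groups of Monte Carlo distributions
#'
#' All-pairs Welch t-tests on the per-replicate R-squared samples with Holm
#' family-wise correction; groups sharing a letter are not significantly
#' different. Letters are assigned by sweeping the mean-ordered groups and
#' collecting maximal runs of mutually non-significant groups.
#'
#' @param distributions Named list (>= 2) of `mrue_spurious` objects with
#'   equal replicate counts.
#' @param alpha Family-wise significance level (default 0.05).
#' @return data.frame: group, mean_r2, letters.
#' @export
compare_groups <- function(distributions, alpha = 0.05) {
  if (length(distributions) < 2L) {
    stop("need at least two distributions to compare", call. = FALSE)
  }
  stopifnot(all(vapply(distributions, inherits, TRUE, "mrue_spurious")))
  reps <- vapply(distributions, function(d) d$reps, 1L)
  if (length(unique(reps)) != 1L) {
    stop("distributions must have equal replicate counts", call. = FALSE)
  }
  k <- length(distributions)
  nm <- names(distributions)
  if (is.null(nm)) nm <- paste0("G", seq_len(k))
  means <- vapply(distributions, function(d) d$mean_r2, 1)
  ord <- order(means)
  pairs <- combn(k, 2)
  pvals <- apply(pairs, 2, function(ij) {
    x <- distributions[[ij[1]]]$r2_samples
    y <- distributions[[ij[2]]]$r2_samples
    if (sd(x) == 0 && sd(y) == 0) return(if (mean(x) == mean(y)) 1 else 0)
    t.test(x, y)$p.value
  })
  padj <- p.adjust(pvals, method = "holm")
  nonsig <- diag(TRUE, k)
  for (j in seq_len(ncol(pairs))) {
    ns <- padj[j] >= alpha
    nonsig[pairs[1, j], pairs[2, j]] <- ns
    nonsig[pairs[2, j], pairs[1, j]] <- ns
  }
  # maximal runs of mutually non-significant groups along the mean ordering
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && all(nonsig[ord[i:(j + 1)], ord[i:(j + 1)]])) j <- j + 1
    runs[[length(runs) + 1L]] <- i:j
  }
  keep <- !vapply(seq_along(runs), function(a)
    any(vapply(seq_along(runs), function(b)
      a != b && all(runs[[a]] %in% runs[[b]]), TRUE)), TRUE)
  runs <- runs[keep]
  letter_of <- character(k)
  for (a in seq_along(runs)) {
    for (i in runs[[a]]) {
      letter_of[ord[i]] <- paste0(letter_of[ord[i]], letters[a])
    }
  }
  data.frame(group = nm, mean_r2 = unname(means), letters = letter_of,
             row.names = NULL)
}

#' Importance-weighted spurious contribution
#'
#' Scales a spurious R-squared by the relative-importance share of the common
#' variable, giving its weighted contribution to the apparent explained
#' variance.
#'
#' @param spurious_mean_r2 Mean spurious R-squared, in `[0, 1]`.
#' @param importance_share Relative-importance share (fraction), in `[0, 1]`.
#' @return Their product.
#' @examples
#' weighted_spurious(0.1, 0.28)  # 0.028
#' @export
weighted_spurious <- function(spurious_mean_r2, importance_share) {
  if (any(spurious_mean_r2 < 0 | spurious_mean_r2 > 1) ||
      any(importance_share < 0 | importance_share > 1)) {
    stop("inputs must lie in [0, 1]", call. = FALSE)
  }
  spurious_mean_r2 * importance_share
}
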