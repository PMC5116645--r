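# Shared fixtures: the grassland feedback path model with its published
# standardized coefficients, the printed effect table, and random-record
# generators used by property tests.

grassland_coefficients <- function(Phi = NULL, Psi = NULL) {
  spec <- default_model_spec()
  cf <- c("Ms->aPAR" = 0.58, "N_uptake->aPAR" = 0.35, "Tr->N_uptake" = 0.32,
          "Ms->eps" = -0.15, "Tr->eps" = 0.43, "aPAR->eps" = 0.3,
          "N_uptake->eps" = 0.67,
          "Ms->mRUE" = -0.49, "N_uptake->mRUE" = 0.66,
          "eps->mRUE" = 0.23, "mRUE->eps" = -0.11)
  if (is.null(Phi)) {
    Phi <- matrix(c(1, 0.4, 0.4, 1), 2, 2,
                  dimnames = list(c("Ms", "Tr"), c("Ms", "Tr")))
  }
  if (is.null(Psi)) {
    endo <- c("aPAR", "N_uptake", "eps", "mRUE")
    Psi <- diag(c(0.5, 0.7, 0.2, 0.2))
    dimnames(Psi) <- list(endo, endo)
  }
  path_coefficients(spec, cf, Phi = Phi, Psi = Psi)
}

# Direct/indirect standardized effects as published for the grassland model
# (effect-table entries, not recomputed from the rounded coefficients).
grassland_printed_effects <- function() {
  effect_table(data.frame(
    source = c("Ms", "Ms", "Ms",
               "Tr", "Tr", "Tr", "Tr",
               "aPAR",
               "N_uptake", "N_uptake", "N_uptake",
               "eps", "mRUE"),
    target = c("aPAR", "eps", "mRUE",
               "N_uptake", "aPAR", "eps", "mRUE",
               "eps",
               "aPAR", "eps", "mRUE",
               "mRUE", "eps"),
    direct = c(0.58, -0.15, -0.49,
               0.32, NA, 0.43, NA,
               0.3,
               0.35, 0.67, 0.66,
               0.23, -0.11),
    indirect = c(NA, 0.20, NA,
                 NA, 0.11, 0.25, 0.21,
                 NA,
                 NA, 0.03, NA,
                 NA, NA)))
}

# Random valid resource records spanning realistic log-scale magnitudes.
random_records <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  par <- exp(rnorm(n, 11, 0.5))
  ms <- exp(rnorm(n, 15, 0.5))
  ns <- exp(rnorm(n, 3.7, 0.3))
  data.frame(
    plot_id = paste0("p", seq_len(n)),
    treatment = sample(c(-0.6, -0.4, -0.2, 0, 0.2, 0.4, 0.6), n, replace = TRUE),
    year = sample(2010:2012, n, replace = TRUE),
    anpp = exp(rnorm(n, 5.3, 0.4)),
    par = par, apar = par * runif(n, 0.05, 0.95),
    ms = ms, tr = ms * runif(n, 0.05, 0.95),
    ns = ns, n_uptake = ns * runif(n, 0.05, 0.95))
}

# Independent LMG oracle: average sequential R2 increments over all p!
# orderings, with R2 from lm() on each cumulative predictor set.
lmg_by_orderings <- function(x, y) {
  x <- as.matrix(x); p <- ncol(x)
  r2 <- function(cols) {
    if (!length(cols)) return(0)
    summary(lm(y ~ x[, cols, drop = FALSE]))$r.squared
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(rest) c(v[i], rest))))
  }
  shares <- numeric(p)
  all_orders <- perms(seq_len(p))
  for (ord in all_orders) {
    prev <- 0
    for (j in seq_along(ord)) {
      cur <- r2(ord[seq_len(j)])
      shares[ord[j]] <- shares[ord[j]] + (cur - prev)
      prev <- cur
    }
  }
  shares / length(all_orders)
}

# Random sparse acyclic path models with coefficients, for decomposition
# equivalence properties.
random_acyclic_coefficients <- function(seed) {
  set.seed(seed)
  nv <- sample(4:6, 1)
  vars <- paste0("v", seq_len(nv))
  n_exo <- sample(1:2, 1)
  # edges only from lower to higher index: acyclic by construction
  pairs <- which(upper.tri(matrix(0, nv, nv)), arr.ind = TRUE)
  pairs <- pairs[sample(nrow(pairs), ceiling(nrow(pairs) * 0.6)), , drop = FALSE]
  pairs <- pairs[pairs[, 2] > n_exo, , drop = FALSE]  # no edges into exogenous
  spec <- path_model_spec(vars, vars[seq_len(n_exo)],
                          data.frame(source = vars[pairs[, 1]],
                                     target = vars[pairs[, 2]]))
  cf <- setNames(runif(nrow(pairs), -0.8, 0.8),
                 paste0(vars[pairs[, 1]], "->", vars[pairs[, 2]]))
  path_coefficients(spec, cf)
}
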