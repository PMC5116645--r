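#' mrue: multiple resource use efficiency modelling
#'
#' Tools for the multiplicative decomposition of aboveground net primary
#' production (ANPP) into available resources, resource absorption rates and
#' resource use efficiencies, together with the statistical machinery used to
#' analyse the decomposition: non-recursive path analysis, effect
#' decomposition, LMG relative importance, and Monte Carlo quantification of
#' spurious correlation among ratio-derived indices.
#'
#' @section Model overview:
#' For a single resource i, annual production satisfies the identity
#' \deqn{ANPP = R_{avail,i} \cdot \epsilon_i \cdot RUE_i}
#' where \eqn{\epsilon_i} is the absorbed/available fraction and
#' \eqn{RUE_i = ANPP / R_{absorbed,i}}. With several resources the composite
#' form uses geometric means across resources:
#' \deqn{ANPP = \bar{R}_{avail} \cdot \epsilon \cdot mRUE}
#' with \eqn{mRUE = (\prod_i RUE_i)^{1/n}}, \eqn{\epsilon = (\prod_i
#' \epsilon_i)^{1/n}} and \eqn{\bar{R}_{avail} = (\prod_i R_{avail,i})^{1/n}}.
#' The identity holds exactly, which is both the model's appeal and the source
#' of spurious correlation between the composites and their components.
#'
#' @docType package
#' @name mrue-package
#' @aliases mrue
#' @importFrom stats cor cov cov2cor optim p.adjust pchisq pnorm quantile
#'   rnorm sd setNames t.test
#' @importFrom utils combn modifyList read.csv write.csv
"_PACKAGE"

# Columns a resource-record table must carry, in canonical order.
RECORD_COLUMNS <- c("plot_id", "treatment", "year", "anpp",
                    "par", "apar", "ms", "tr", "ns", "n_uptake")

TREATMENT_LEVELS <- c(-0.6, -0.4, -0.2, 0, 0.2, 0.4, 0.6)

#' Convert light from energy to mass-equivalent units
#'
#' Incident and absorbed photosynthetically active radiation are usually
#' reported in MJ m^-2; dividing by the plant caloric value expresses them in
#' g m^-2 of dry-matter equivalent so that light shares units with water and
#' nitrogen in the efficiency algebra.
#'
#' @param energy Energy flux in MJ m^-2 (non-negative).
#' @param caloric_value Plant caloric value in kJ g^-1; the default 19.38 is
#'   representative of semi-arid grassland vegetation.
#' @return Mass-equivalent quantity in g m^-2: \code{energy * 1000 / caloric_value}.
#' @examples
#' caloric_convert(19.38)        # 1000 g m^-2
#' caloric_convert(1, 19.38)     # 51.6 g m^-2
#' @export
caloric_convert <- function(energy, caloric_value = 19.38) {
  if (!is.numeric(caloric_value) || length(caloric_value) != 1L ||
      !is.finite(caloric_value) || caloric_value <= 0) {
    stop("`caloric_value` must be a single positive number (kJ g^-1)",
         call. = FALSE)
  }
  if (any(energy < 0, na.rm = TRUE)) {
    stop("`energy` must be non-negative", call. = FALSE)
  }
  energy * 1000 / caloric_value
}

#' Geometric mean
#'
#' Computed in log space for numerical stability; all inputs must be strictly
#' positive since the quantities entering the composites are physical amounts
#' and ratios.
#'
#' @param x Numeric vector of strictly positive values, length >= 1.
#' @return \code{(prod(x))^(1/length(x))}.
#' @examples
#' geometric_mean(c(1, 8))  # sqrt(8)
#' @export
geometric_mean <- function(x) {
  if (length(x) == 0L) stop("`x` must contain at least one value", call. = FALSE)
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("`x` must be finite numeric", call. = FALSE)
  }
  if (any(x <= 0)) {
    stop("geometric mean is defined for strictly positive values only",
         call. = FALSE)
  }
  exp(mean(log(x)))
}

#' Single-resource use efficiency
#'
#' \eqn{RUE_i = ANPP / R_{absorbed,i}}: dry matter produced per unit of
#' absorbed resource. Dimensionless when both are in g m^-2 yr^-1. Values may
#' exceed 1 (nitrogen use efficiency in grasslands is typically in the tens).
#'
#' @param anpp Production, g m^-2 yr^-1 (> 0).
#' @param absorbed Absorbed resource, g m^-2 yr^-1 (> 0).
#' @return anpp / absorbed, vectorised.
#' @export
compute_rue <- function(anpp, absorbed) {
  if (any(absorbed <= 0, na.rm = TRUE)) {
    stop("`absorbed` must be strictly positive", call. = FALSE)
  }
  if (any(anpp <= 0, na.rm = TRUE)) {
    stop("`anpp` must be strictly positive", call. = FALSE)
  }
  anpp / absorbed
}

#' Single-resource absorption rate
#'
#' \eqn{\epsilon_i = R_{absorbed,i} / R_{avail,i}}, the fraction of the
#' available resource the vegetation actually takes up; constrained to (0, 1].
#'
#' @param absorbed Absorbed resource amount (> 0).
#' @param available Available resource amount (> 0, >= absorbed).
#' @return absorbed / available, vectorised.
#' @export
compute_epsilon <- function(absorbed, available) {
  if (any(available <= 0, na.rm = TRUE)) {
    stop("`available` must be strictly positive", call. = FALSE)
  }
  if (any(absorbed <= 0, na.rm = TRUE)) {
    stop("`absorbed` must be strictly positive", call. = FALSE)
  }
  if (any(absorbed > available, na.rm = TRUE)) {
    stop("absorbed resource exceeds available resource", call. = FALSE)
  }
  absorbed / available
}

#' Validate a resource-record table
#'
#' Checks the schema and the physical invariants: all quantities strictly
#' positive and absorbed never exceeding available (aPAR <= PAR, Tr <= Ms,
#' N_uptake <= Ns).
#'
#' @param records data.frame with columns plot_id, treatment, year, anpp, par,
#'   apar, ms, tr, ns, n_uptake (resource units g m^-2 yr^-1).
#' @param strict If TRUE (default) any invalid row is an error naming the
#'   offending rows; if FALSE invalid rows are dropped with a warning.
#' @return The validated (possibly filtered) data.frame, invisibly classed as
#'   before.
#' @export
validate_records <- function(records, strict = TRUE) {
  if (!is.data.frame(records)) stop("`records` must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(RECORD_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  num_cols <- setdiff(RECORD_COLUMNS, c("plot_id", "treatment", "year"))
  bad <- rep(FALSE, nrow(records))
  why <- character(nrow(records))
  for (cl in num_cols) {
    v <- records[[cl]]
    if (!is.numeric(v)) stop("column `", cl, "` must be numeric", call. = FALSE)
    nonpos <- !is.finite(v) | v <= 0
    why[nonpos & !bad] <- paste0("non-positive ", cl)
    bad <- bad | nonpos
  }
  for (pair in list(c("apar", "par"), c("tr", "ms"), c("n_uptake", "ns"))) {
    viol <- !bad & records[[pair[1]]] > records[[pair[2]]]
    why[viol] <- paste0(pair[1], " > ", pair[2])
    bad <- bad | viol
  }
  if (any(bad)) {
    msg <- paste0("row ", which(bad), ": ", why[bad], collapse = "; ")
    if (strict) stop("invalid resource records - ", msg, call. = FALSE)
    warning("dropping ", sum(bad), " invalid row(s) - ", msg, call. = FALSE)
    records <- records[!bad, , drop = FALSE]
  }
  invisible(records)
}

#' Per-record efficiency set
#'
#' Computes, for each row of a resource-record table, the three single-resource
#' use efficiencies (WUE, LUE, NUE), the three absorption rates, and the
#' composites mRUE, epsilon and the geometric-mean available resource. The
#' nine derived quantities satisfy the exact reconstruction identity
#' \code{r_avail_comp * eps * mrue == anpp}.
#'
#' @param records data.frame of resource records (see [validate_records()]).
#' @param strict Passed to [validate_records()].
#' @return data.frame: the key columns of the input plus wue, lue, nue, eps_l,
#'   eps_w, eps_n, mrue, eps, r_avail_comp.
#' @examples
#' rec <- data.frame(plot_id = "CK_B1", treatment = 0, year = 2010,
#'   anpp = 200, par = 60000, apar = 22000, ms = 3.3e6, tr = 4.4e5,
#'   ns = 40, n_uptake = 3.3)
#' es <- compute_efficiency_set(rec)
#' es$r_avail_comp * es$eps * es$mrue  # 200
#' @export
compute_efficiency_set <- function(records, strict = TRUE) {
  records <- validate_records(records, strict = strict)
  out <- records[, intersect(c("plot_id", "treatment", "year", "anpp"),
                             names(records)), drop = FALSE]
  out$wue <- compute_rue(records$anpp, records$tr)
  out$lue <- compute_rue(records$anpp, records$apar)
  out$nue <- compute_rue(records$anpp, records$n_uptake)
  out$eps_l <- compute_epsilon(records$apar, records$par)
  out$eps_w <- compute_epsilon(records$tr, records$ms)
  out$eps_n <- compute_epsilon(records$n_uptake, records$ns)
  # geometric means row-wise, in log space
  out$mrue <- exp((log(out$wue) + log(out$lue) + log(out$nue)) / 3)
  out$eps <- exp((log(out$eps_l) + log(out$eps_w) + log(out$eps_n)) / 3)
  out$r_avail_comp <- exp((log(records$par) + log(records$ms) + log(records$ns)) / 3)
  class(out) <- c("mrue_efficiency", class(out))
  out
}

#' Reconstruct production from an efficiency set
#'
#' The multiplicative identity of the composite model: production equals the
#' geometric-mean available resource times the composite absorption rate times
#' the composite use efficiency.
#'
#' @param set data.frame from [compute_efficiency_set()] (needs columns
#'   r_avail_comp, eps, mrue).
#' @return Numeric vector of reconstructed ANPP, g m^-2 yr^-1.
#' @export
reconstruct_anpp <- function(set) {
  needed <- c("r_avail_comp", "eps", "mrue")
  if (!all(needed %in% names(set))) {
    stop("`set` must contain columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  set$r_avail_comp * set$eps * set$mrue
}
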