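#' LMG relative-importance decomposition of R-squared
#'
#' Distributes the R-squared of a linear regression across predictors by
#' averaging, over all p! orderings in which predictors could enter the model,
#' the increase in R-squared contributed by each predictor when it enters
#' (the LMG / Shapley decomposition). Computed exactly by enumerating the
#' 2^p subset models and applying the combinatorial weights
#' \eqn{w(s) = s! (p - s - 1)! / p!}, which is feasible for the small
#' predictor sets of efficiency analyses (capped at p = 12).
#'
#' @param predictors n x p numeric data.frame or matrix of full column rank.
#' @param response Numeric vector of length n.
#' @return Object of class `mrue_relimp`: data.frame with columns predictor,
#'   lmg_share (fraction of response variance) and normalized_pct
#'   (share / total R-squared, percent); attribute `total_r2`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- x %*% c(1, 0.5, 0) + rnorm(100)
#' lmg(x, y)
#' @export
lmg <- function(predictors, response) {
  x <- as.matrix(predictors)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(response)
  n <- nrow(x); p <- ncol(x)
  if (p < 1L) stop("need at least one predictor", call. = FALSE)
  if (p > 12L) stop("LMG enumeration capped at 12 predictors (got ", p, ")",
                    call. = FALSE)
  if (n <= p) stop("need more observations than predictors", call. = FALSE)
  if (length(y) != n) stop("response length must match predictor rows",
                           call. = FALSE)
  if (qr(cbind(1, x))$rank < p + 1L) {
    stop("predictors are collinear (rank deficient)", call. = FALSE)
  }
  sy <- sd(y)
  if (sy == 0) stop("constant response", call. = FALSE)

  # R^2 for every predictor subset from the correlation structure
  xs <- scale(x); ys <- as.numeric(scale(y))
  Rxx <- crossprod(xs) / (n - 1)
  rxy <- crossprod(xs, ys) / (n - 1)
  r2_subset <- numeric(2^p)  # index = bitmask + 1
  for (mask in seq_len(2^p - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0)
    r2_subset[mask + 1L] <- as.numeric(
      crossprod(rxy[idx], solve(Rxx[idx, idx, drop = FALSE], rxy[idx])))
  }

  wts <- factorial(0:(p - 1)) * factorial((p - 1):0) / factorial(p)
  shares <- numeric(p)
  full <- 2^p - 1L
  for (k in seq_len(p)) {
    bit_k <- 2^(k - 1L)
    others <- bitwAnd(0:full, bitwNot(bit_k))
    sub <- unique(others[others >= 0 & others <= full])
    for (mask in sub) {
      s <- sum(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0)
      shares[k] <- shares[k] +
        wts[s + 1L] * (r2_subset[bitwOr(mask, bit_k) + 1L] - r2_subset[mask + 1L])
    }
  }
  total_r2 <- r2_subset[full + 1L]
  out <- data.frame(predictor = colnames(x), lmg_share = shares,
                    row.names = NULL)
  out$normalized_pct <- if (total_r2 > 0) 100 * shares / total_r2 else NA_real_
  structure(out, total_r2 = total_r2, class = c("mrue_relimp", "data.frame"))
}

#' Normalize LMG shares to percentages of explained variance
#'
#' @param result An `mrue_relimp` object from [lmg()].
#' @return Named numeric vector of percentages summing to 100.
#' @export
contribution_percentages <- function(result) {
  stopifnot(inherits(result, "mrue_relimp"))
  total <- attr(result, "total_r2")
  if (!isTRUE(total > 0)) {
    stop("total R-squared is zero; percentages undefined", call. = FALSE)
  }
  setNames(100 * result$lmg_share / total, result$predictor)
}

#' @export
print.mrue_relimp <- function(x, ...) {
  cat(sprintf("LMG decomposition (total R2 = %.4f)\n", attr(x, "total_r2")))
  print.data.frame(cbind(x["predictor"],
                         lmg_share = round(x$lmg_share, 4),
                         pct = round(x$normalized_pct, 2)), row.names = FALSE)
  invisible(x)
}
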