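#' Moment-based skewness and kurtosis
#'
#' Classical biased moment estimators: skewness \eqn{g_1 = m_3 / m_2^{3/2}}
#' and kurtosis \eqn{g_2 = m_4 / m_2^2} (so a normal sample has kurtosis near
#' 3, not 0).
#'
#' @param x Numeric vector (length >= 2, non-constant).
#' @return Scalar estimate.
#' @export
skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) stop("need at least two observations", call. = FALSE)
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) stop("moments undefined for a constant sample", call. = FALSE)
  mean((x - mean(x))^3) / m2^1.5
}

#' @rdname skewness
#' @export
kurtosis <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) stop("need at least two observations", call. = FALSE)
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) stop("moments undefined for a constant sample", call. = FALSE)
  mean((x - mean(x))^4) / m2^2
}

#' Mardia's multivariate normality statistics
#'
#' Multivariate skewness \eqn{b_{1,p} = n^{-2} \sum_{ij} g_{ij}^3} and
#' kurtosis \eqn{b_{2,p} = n^{-1} \sum_i g_{ii}^2}, where
#' \eqn{g_{ij} = (x_i - \bar{x})' S^{-1} (x_j - \bar{x})} with the ML
#' (divide-by-n) covariance. Under multivariate normality
#' \eqn{n b_{1,p} / 6} is asymptotically chi-squared with
#' \eqn{p(p+1)(p+2)/6} degrees of freedom, and
#' \eqn{(b_{2,p} - p(p+2)) / \sqrt{8 p (p+2) / n}} is standard normal.
#'
#' @param x Numeric matrix or data.frame, n rows (observations) x p columns.
#' @return List: b1p, b1p_stat, b1p_df, b1p_p, b2p, b2p_z, b2p_p, n, p.
#' @export
mardia <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n <= p) stop("need more observations than variables", call. = FALSE)
  xc <- scale(x, center = TRUE, scale = FALSE)
  S <- crossprod(xc) / n
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("singular covariance (constant or collinear columns)", call. = FALSE))
  G <- xc %*% Sinv %*% t(xc)
  b1p <- sum(G^3) / n^2
  b2p <- sum(diag(G)^2) / n
  b1p_stat <- n * b1p / 6
  b1p_df <- p * (p + 1) * (p + 2) / 6
  b2p_z <- (b2p - p * (p + 2)) / sqrt(8 * p * (p + 2) / n)
  list(b1p = b1p, b1p_stat = b1p_stat, b1p_df = b1p_df,
       b1p_p = pchisq(b1p_stat, b1p_df, lower.tail = FALSE),
       b2p = b2p, b2p_z = b2p_z, b2p_p = 2 * pnorm(-abs(b2p_z)),
       n = n, p = p)
}

#' Univariate and multivariate normality diagnostics for a variable table
#'
#' The screening step run before a maximum-likelihood path analysis:
#' per-variable skewness and kurtosis plus Mardia's multivariate statistics
#' with their asymptotic p-values.
#'
#' @param data Numeric data.frame or matrix (observations x variables).
#' @return List with `univariate` (data.frame: variable, skewness, kurtosis)
#'   and `mardia` (see [mardia()]).
#' @export
normality_diagnostics <- function(data) {
  x <- as.matrix(data)
  if (!is.numeric(x)) stop("`data` must be numeric", call. = FALSE)
  uni <- data.frame(
    variable = colnames(x),
    skewness = apply(x, 2, skewness),
    kurtosis = apply(x, 2, kurtosis),
    row.names = NULL)
  list(univariate = uni, mardia = mardia(x))
}
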