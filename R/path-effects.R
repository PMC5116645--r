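# Adjacency list (source -> targets) of the combined B/G coefficient graph,
# with edge weights, over all observed variables.
coef_graph <- function(coeffs) {
  spec <- coeffs$spec
  vars <- spec$variables
  W <- matrix(0, length(vars), length(vars), dimnames = list(vars, vars))
  endo <- spec$endogenous; exo <- spec$exogenous
  W[endo, endo] <- coeffs$B
  if (length(exo)) W[endo, exo] <- coeffs$G
  # keep structural zeros distinct from absent edges: use the spec's edge set
  keep <- matrix(FALSE, length(vars), length(vars), dimnames = dimnames(W))
  keep[cbind(spec$edges$target, spec$edges$source)] <- TRUE
  W[!keep] <- 0
  list(W = W, has_edge = keep, vars = vars)
}

# All simple directed paths source -> target with at most max_len edges and
# no intermediate vertex from `exclude`; returns the sum of coefficient
# products and (optionally) the path list.
sum_simple_paths <- function(g, source, target, max_len = Inf,
                             exclude = character(), keep_paths = FALSE) {
  paths <- list(); total <- 0
  walk <- function(v, visited, prod, len) {
    nexts <- g$vars[g$has_edge[, v]]
    for (w in nexts) {
      pw <- prod * g$W[w, v]
      if (w == target) {
        total <<- total + pw
        if (keep_paths) paths[[length(paths) + 1L]] <<-
            list(path = c(visited, w), effect = pw)
      } else if (!(w %in% visited) && !(w %in% exclude) && len + 1 < max_len) {
        walk(w, c(visited, w), pw, len + 1)
      }
    }
  }
  if (max_len >= 1) walk(source, source, 1, 0)
  list(total = total, paths = paths)
}

#' Direct, indirect and total effects of a path model
#'
#' Decomposes the effect of every variable on every endogenous variable.
#' In `"path-sum"` mode the total effect is the sum over simple directed
#' paths (no repeated variables) of the products of coefficients along each
#' path — the conventional hand arithmetic of published effect tables, which
#' does not amplify effects around feedback loops. In `"series-limit"` mode
#' the total effect is taken from the closed forms \eqn{(I-B)^{-1} - I}
#' (endogenous sources) and \eqn{(I-B)^{-1} G} (exogenous sources), the limit
#' of summing walks of all lengths; it requires the spectral radius of B to
#' be below 1 and differs from path-sum only in cyclic models. In both modes
#' the direct effect is the corresponding coefficient and
#' indirect = total - direct.
#'
#' @param coeffs [path_coefficients()] object.
#' @param mode `"path-sum"` (default) or `"series-limit"`.
#' @param max_path_len Maximum number of edges per path in path-sum mode.
#' @param exclude Variables that may not act as intermediaries in path-sum
#'   mode (they may still be sources or targets). Published effect tables for
#'   models with several joint outcomes often restrict indirect effects to
#'   paths through the mediating resource variables, excluding routes through
#'   the other outcome; this argument reproduces that convention.
#' @return An effect table (class `mrue_effect_table`): data.frame with
#'   columns source, target, direct, indirect, total; attribute `mode`.
#' @seealso [aggregate_effects()], [path_effect()], [stability_index()]
#' @export
decompose_effects <- function(coeffs, mode = c("path-sum", "series-limit"),
                              max_path_len = Inf, exclude = character()) {
  stopifnot(inherits(coeffs, "mrue_path_coefficients"))
  mode <- match.arg(mode)
  if (mode == "series-limit" && length(exclude)) {
    stop("`exclude` applies to path-sum mode only", call. = FALSE)
  }
  spec <- coeffs$spec
  g <- coef_graph(coeffs)
  endo <- spec$endogenous
  if (mode == "series-limit") {
    sr <- if (nrow(coeffs$B)) max(Mod(eigen(coeffs$B, only.values = TRUE)$values)) else 0
    if (sr >= 1) {
      stop("series-limit decomposition diverges: spectral radius ",
           signif(sr, 3), " >= 1", call. = FALSE)
    }
    A <- solve(diag(nrow(coeffs$B)) - coeffs$B)
    tot_endo <- A - diag(nrow(A))
    tot_exo <- A %*% coeffs$G
  }
  rows <- expand.grid(source = spec$variables, target = endo,
                      stringsAsFactors = FALSE)
  rows <- rows[rows$source != rows$target, , drop = FALSE]
  rows$direct <- g$W[cbind(rows$target, rows$source)]
  rows$total <- NA_real_
  for (i in seq_len(nrow(rows))) {
    if (mode == "path-sum") {
      rows$total[i] <- sum_simple_paths(g, rows$source[i], rows$target[i],
                                        max_len = max_path_len,
                                        exclude = exclude)$total
    } else {
      rows$total[i] <- if (rows$source[i] %in% endo)
        tot_endo[rows$target[i], rows$source[i]]
      else tot_exo[rows$target[i], rows$source[i]]
    }
  }
  rows$indirect <- rows$total - rows$direct
  effect_table(rows[, c("source", "target", "direct", "indirect")], mode = mode)
}

#' Build an effect table
#'
#' Either produced by [decompose_effects()] or constructed directly from a
#' published table of direct and indirect standardized effects.
#'
#' @param effects data.frame with columns source, target, direct, indirect
#'   (NA treated as 0).
#' @param mode Provenance label, e.g. `"path-sum"`, `"series-limit"` or
#'   `"printed"`.
#' @return data.frame of class `mrue_effect_table` with total = direct +
#'   indirect.
#' @export
effect_table <- function(effects, mode = "printed") {
  stopifnot(is.data.frame(effects),
            all(c("source", "target", "direct", "indirect") %in% names(effects)))
  effects$direct[is.na(effects$direct)] <- 0
  effects$indirect[is.na(effects$indirect)] <- 0
  effects$total <- effects$direct + effects$indirect
  rownames(effects) <- NULL
  structure(effects[, c("source", "target", "direct", "indirect", "total")],
            mode = mode, class = c("mrue_effect_table", "data.frame"))
}

#' Effect transmitted along one explicit path
#'
#' The product of the coefficients along an ordered chain of variables —
#' e.g. the effect of transpiration on use efficiency transmitted through
#' nitrogen uptake only.
#'
#' @param coeffs [path_coefficients()] object.
#' @param path Character vector of variable names, first = source,
#'   last = target; every consecutive pair must be an edge of the model.
#' @return The scalar product of coefficients along the path.
#' @export
path_effect <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "mrue_path_coefficients"), length(path) >= 2)
  g <- coef_graph(coeffs)
  if (!all(path %in% g$vars)) {
    stop("unknown variable(s): ",
         paste(setdiff(path, g$vars), collapse = ", "), call. = FALSE)
  }
  prod <- 1
  for (i in seq_len(length(path) - 1L)) {
    if (!g$has_edge[path[i + 1], path[i]]) {
      stop("no edge ", path[i], " -> ", path[i + 1], call. = FALSE)
    }
    prod <- prod * g$W[path[i + 1], path[i]]
  }
  prod
}

#' Aggregate effect components over a group of source variables
#'
#' Sums selected components (direct, indirect, or both = total) of the effects
#' of a set of source variables on one target — the arithmetic behind grouped
#' statements such as "the water-related variables jointly affect the
#' absorption rate by beta = ...".
#'
#' @param table An `mrue_effect_table`.
#' @param sources Character vector of source variables (may be empty: sum 0).
#' @param target Single target variable.
#' @param components Which components to include: subset of
#'   `c("direct", "indirect")`; both by default (i.e. total effects).
#' @return Scalar sum of the requested standardized effects.
#' @export
aggregate_effects <- function(table, sources, target,
                              components = c("direct", "indirect")) {
  stopifnot(inherits(table, "mrue_effect_table"))
  components <- match.arg(components, several.ok = TRUE)
  known <- unique(c(table$source, table$target))
  unknown <- setdiff(c(sources, target), known)
  if (length(unknown)) {
    stop("variable(s) not in effect table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(sources) == 0L) return(0)
  rows <- table[table$source %in% sources & table$target == target, ,
                drop = FALSE]
  sum(unlist(rows[, components, drop = FALSE]))
}

#' Feedback-loop stability index
#'
#' Enumerates the elementary directed cycles of the endogenous coefficient
#' matrix and returns the maximum over cycles of the magnitude of the product
#' of coefficients around the cycle (0 for acyclic models). A non-recursive
#' model is considered stable when the index is below 1. The alternative
#' `"eigen"` method returns the spectral radius of B, which bounds the decay
#' of walk contributions but does not match the loop-product convention of
#' published stability indices.
#'
#' @param B Endogenous coefficient matrix (entry `[target, source]`), or a
#'   [path_coefficients()] object.
#' @param method `"loop-product"` (default) or `"eigen"`.
#' @return Non-negative scalar.
#' @examples
#' B <- matrix(c(0, 0.23, -0.11, 0), 2, 2,
#'             dimnames = list(c("eps", "mRUE"), c("eps", "mRUE")))
#' stability_index(B)  # 0.0253
#' @export
stability_index <- function(B, method = c("loop-product", "eigen")) {
  method <- match.arg(method)
  if (inherits(B, "mrue_path_coefficients")) B <- B$B
  B <- as.matrix(B)
  if (nrow(B) != ncol(B)) stop("B must be square", call. = FALSE)
  if (nrow(B) == 0L) return(0)
  if (method == "eigen") {
    return(max(Mod(eigen(B, only.values = TRUE)$values)))
  }
  n <- nrow(B)
  best <- 0
  # elementary cycles, anchored at their smallest-index vertex
  walk <- function(v, anchor, visited, prod) {
    for (w in seq_len(n)) {
      if (B[w, v] == 0) next
      pw <- prod * B[w, v]
      if (w == anchor) {
        best <<- max(best, abs(pw))
      } else if (w > anchor && !(w %in% visited)) {
        walk(w, anchor, c(visited, w), pw)
      }
    }
  }
  for (s in seq_len(n)) walk(s, s, s, 1)
  best
}
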