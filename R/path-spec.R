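#' Specify a path-analysis model over observed variables
#'
#' A path model is a set of directed edges among observed variables, with a
#' designated exogenous subset. Cycles among endogenous variables are allowed
#' (non-recursive models, e.g. a feedback loop between an absorption-rate
#' composite and a use-efficiency composite); edges into exogenous variables
#' and self-edges are not.
#'
#' @param variables Character vector of variable names (order is kept).
#' @param exogenous Subset of `variables` treated as exogenous.
#' @param edges Directed edges: either a two-column data.frame/matrix
#'   (source, target) or a character vector of `"source -> target"` strings.
#' @param error_covariances Optional list/character of endogenous pairs whose
#'   structural errors may covary, same formats as `edges` but unordered
#'   (`"a ~~ b"` strings accepted).
#' @return An object of class `mrue_path_spec`.
#' @examples
#' spec <- path_model_spec(
#'   variables = c("Ms", "Tr", "aPAR", "N_uptake", "eps", "mRUE"),
#'   exogenous = c("Ms", "Tr"),
#'   edges = c("Ms -> aPAR", "N_uptake -> aPAR", "Tr -> N_uptake",
#'             "Ms -> eps", "Tr -> eps", "aPAR -> eps", "N_uptake -> eps",
#'             "Ms -> mRUE", "N_uptake -> mRUE",
#'             "eps -> mRUE", "mRUE -> eps"))
#' @export
path_model_spec <- function(variables, exogenous, edges,
                            error_covariances = NULL) {
  variables <- as.character(variables)
  if (anyDuplicated(variables)) stop("duplicate variable names", call. = FALSE)
  exogenous <- as.character(exogenous)
  if (!all(exogenous %in% variables)) {
    stop("exogenous variables not in `variables`: ",
         paste(setdiff(exogenous, variables), collapse = ", "), call. = FALSE)
  }
  edges <- parse_edges(edges)
  bad <- !(edges$source %in% variables) | !(edges$target %in% variables)
  if (any(bad)) {
    stop("edge refers to unknown variable: ",
         paste(unique(c(edges$source[bad], edges$target[bad])), collapse = ", "),
         call. = FALSE)
  }
  if (any(edges$source == edges$target)) stop("self-edges forbidden", call. = FALSE)
  if (any(edges$target %in% exogenous)) {
    stop("edges into exogenous variables forbidden: ",
         paste(unique(edges$target[edges$target %in% exogenous]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(paste(edges$source, edges$target))) {
    stop("duplicate edges", call. = FALSE)
  }
  endogenous <- setdiff(variables, exogenous)
  ecov <- parse_pairs(error_covariances)
  if (!is.null(ecov)) {
    if (!all(unlist(ecov) %in% endogenous)) {
      stop("error covariances must link endogenous variables", call. = FALSE)
    }
  }
  structure(list(variables = variables, exogenous = exogenous,
                 endogenous = endogenous, edges = edges,
                 error_covariances = ecov),
            class = "mrue_path_spec")
}

parse_edges <- function(edges) {
  if (is.character(edges)) {
    parts <- strsplit(edges, "->", fixed = TRUE)
    if (any(lengths(parts) != 2L)) {
      stop("edges must be of the form 'source -> target'", call. = FALSE)
    }
    edges <- data.frame(source = trimws(vapply(parts, `[`, "", 1L)),
                        target = trimws(vapply(parts, `[`, "", 2L)))
  } else {
    edges <- as.data.frame(edges)
    names(edges)[1:2] <- c("source", "target")
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
  }
  edges
}

parse_pairs <- function(pairs) {
  if (is.null(pairs) || length(pairs) == 0L) return(NULL)
  if (is.character(pairs)) {
    parts <- strsplit(pairs, "~~", fixed = TRUE)
    if (any(lengths(parts) != 2L)) {
      stop("covariance pairs must be of the form 'a ~~ b'", call. = FALSE)
    }
    pairs <- lapply(parts, function(p) trimws(p))
  }
  lapply(pairs, function(p) sort(as.character(p)))
}

#' @export
print.mrue_path_spec <- function(x, ...) {
  cat("Path model:", length(x$variables), "observed variables (",
      length(x$exogenous), "exogenous ),", nrow(x$edges), "edges\n")
  cat("  ", paste(x$edges$source, "->", x$edges$target), sep = "\n  ")
  if (!is.null(x$error_covariances)) {
    cat("  error covariances:",
        paste(vapply(x$error_covariances, paste, "", collapse = " ~~ "),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Assemble coefficient matrices for a path model
#'
#' Builds the endogenous-on-endogenous matrix B, the endogenous-on-exogenous
#' matrix G, the exogenous covariance Phi and the structural error covariance
#' Psi from named edge coefficients (standardized path coefficients by
#' convention).
#'
#' @param spec A [path_model_spec()].
#' @param coefficients Named numeric vector; names `"source->target"` (spaces
#'   optional) matching the spec's edges. Edges not named get coefficient 0.
#' @param Phi Optional exogenous covariance matrix (defaults to identity,
#'   i.e. standardized uncorrelated exogenous variables).
#' @param Psi Optional endogenous error covariance matrix (defaults to a
#'   diagonal completing unit implied variances where possible, otherwise
#'   identity scaled by 0.5).
#' @param standardized Logical flag recording the scale of the coefficients.
#' @return Object of class `mrue_path_coefficients` with elements B, G, Phi,
#'   Psi, spec, standardized.
#' @export
path_coefficients <- function(spec, coefficients = numeric(), Phi = NULL,
                              Psi = NULL, standardized = TRUE) {
  stopifnot(inherits(spec, "mrue_path_spec"))
  endo <- spec$endogenous
  exo <- spec$exogenous
  B <- matrix(0, length(endo), length(endo), dimnames = list(endo, endo))
  G <- matrix(0, length(endo), length(exo), dimnames = list(endo, exo))
  if (length(coefficients)) {
    nm <- gsub("[[:space:]]", "", names(coefficients))
    parts <- strsplit(nm, "->", fixed = TRUE)
    for (i in seq_along(coefficients)) {
      src <- parts[[i]][1]; tgt <- parts[[i]][2]
      if (is.na(tgt) || !tgt %in% endo || !src %in% spec$variables) {
        stop("unknown coefficient name: ", names(coefficients)[i], call. = FALSE)
      }
      has_edge <- any(spec$edges$source == src & spec$edges$target == tgt)
      if (!has_edge) {
        stop("coefficient given for absent edge: ", src, " -> ", tgt,
             call. = FALSE)
      }
      if (src %in% endo) B[tgt, src] <- coefficients[i]
      else G[tgt, src] <- coefficients[i]
    }
  }
  if (is.null(Phi)) {
    Phi <- diag(length(exo))
    dimnames(Phi) <- list(exo, exo)
  }
  if (is.null(Psi)) {
    Psi <- diag(0.5, length(endo))
    dimnames(Psi) <- list(endo, endo)
  }
  stopifnot(isSymmetric(unname(Phi)), isSymmetric(unname(Psi)))
  if (any(diag(Psi) <= 0)) stop("Psi diagonal must be positive", call. = FALSE)
  structure(list(B = B, G = G, Phi = Phi, Psi = Psi, spec = spec,
                 standardized = isTRUE(standardized)),
            class = "mrue_path_coefficients")
}

#' Read / write the plain-text model specification format
#'
#' The format has one variable name per line under `variables:`, the exogenous
#' subset under `exogenous:`, one `source -> target` line per edge under
#' `edges:`, and optional `a ~~ b` lines under `covary:`. Blank lines and
#' `#` comments are ignored.
#'
#' @param path File path.
#' @return [read_model_spec()]: an `mrue_path_spec`.
#' @export
read_model_spec <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- NA_character_
  acc <- list(variables = character(), exogenous = character(),
              edges = character(), covary = character())
  for (ln in lines) {
    if (grepl("^(variables|exogenous|edges|covary):$", ln)) {
      section <- sub(":$", "", ln)
    } else {
      if (is.na(section)) stop("content before any section header: ", ln,
                               call. = FALSE)
      acc[[section]] <- c(acc[[section]], ln)
    }
  }
  path_model_spec(variables = acc$variables, exogenous = acc$exogenous,
                  edges = acc$edges,
                  error_covariances = if (length(acc$covary)) acc$covary)
}

#' @param spec An `mrue_path_spec` to serialize.
#' @rdname read_model_spec
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "mrue_path_spec"))
  lines <- c("variables:", spec$variables,
             "exogenous:", spec$exogenous,
             "edges:", paste(spec$edges$source, "->", spec$edges$target))
  if (!is.null(spec$error_covariances)) {
    lines <- c(lines, "covary:",
               vapply(spec$error_covariances, paste, "", collapse = " ~~ "))
  }
  writeLines(lines, path)
  invisible(path)
}
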