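#' Define a linear mutational path
#'
#' A linear mutational path describes a population of cells that acquire
#' mutations sequentially: type-1 cells (the founding population) mutate to
#' type 2, type 2 to type 3, and so on. Cells of type `n` divide at rate
#' `alpha[n]`, die at rate `beta[n]`, and mutate to type `n + 1` at rate
#' `nu[n]`, all independently; a mutation event leaves the parent cell in
#' place and adds one cell of the next type. The process starts from a single
#' type-1 cell, and the type-1 population must be supercritical
#' (`alpha[1] > beta[1]`).
#'
#' Type indexing is 1-based throughout: type 1 is the founding population and
#' a cell of type `n` carries `n - 1` mutations relative to it.
#'
#' @param alpha Numeric vector of per-type division rates (1/time), length
#'   `N >= 1`.
#' @param beta Numeric vector of per-type death rates (1/time), same length.
#' @param nu Numeric vector of per-type mutation rates to the next type
#'   (1/time), same length. `nu[N]` is unused (there is no type `N + 1`) and
#'   defaults to 0. For `n < N`, `nu[n]` must be positive, otherwise types
#'   beyond `n` are unreachable.
#' @param labels Optional character vector of per-type names.
#'
#' @return An object of class `mutation_path`: a list with elements `alpha`,
#'   `beta`, `nu`, `labels`, and `n_types`.
#'
#' @examples
#' # The three-type path with net growth rates 0.3, 0.1, 0.6
#' path <- mutation_path(alpha = c(1.1, 1, 1.1),
#'                       beta  = c(0.8, 0.9, 0.5),
#'                       nu    = c(0.01, 0.01, 0))
#' path
#' @seealso [fitness_profile()], [surviving_lineage_path()],
#'   [read_mutation_path()]
#' @export
mutation_path <- function(alpha, beta, nu = NULL, labels = NULL) {
  alpha <- as.numeric(alpha)
  beta <- as.numeric(beta)
  n_types <- length(alpha)
  if (n_types < 1L) stop("at least one type is required")
  if (length(beta) != n_types) {
    stop("'alpha' and 'beta' must have the same length")
  }
  if (is.null(nu)) nu <- numeric(n_types)
  nu <- as.numeric(nu)
  if (length(nu) != n_types) {
    stop("'nu' must have the same length as 'alpha' (nu[N] is unused)")
  }
  rates <- c(alpha, beta, nu)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("all rates must be finite and non-negative")
  }
  if (alpha[1L] <= beta[1L]) {
    stop("type 1 must be supercritical: alpha[1] > beta[1] is required")
  }
  if (n_types > 1L && any(nu[-n_types] <= 0)) {
    bad <- which(nu[-n_types] <= 0)[1L]
    stop(sprintf(
      "nu[%d] must be positive: type %d is unreachable otherwise", bad, bad + 1L
    ))
  }
  if (is.null(labels)) {
    labels <- paste("type", seq_len(n_types))
  } else {
    labels <- as.character(labels)
    if (length(labels) != n_types) stop("'labels' must have one entry per type")
  }
  structure(
    list(alpha = alpha, beta = beta, nu = nu, labels = labels,
         n_types = n_types),
    class = "mutation_path"
  )
}

#' @export
print.mutation_path <- function(x, ...) {
  cat(sprintf("Linear mutational path with %d type(s)\n", x$n_types))
  df <- data.frame(
    type = x$labels,
    alpha = x$alpha,
    beta = x$beta,
    nu = x$nu,
    lambda = x$alpha - x$beta
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' Read a mutational path from a parameter file
#'
#' Reads a JSON (or YAML) parameter file with keys `alpha`, `beta`, `nu`
#' (arrays of equal length) and optionally `labels` and `tie_tol`. The
#' `tie_tol` entry, if present, is attached as an attribute so that callers
#' constructing a [fitness_profile()] can pick it up.
#'
#' @param file Path to a `.json`, `.yaml`, or `.yml` file.
#' @return A [mutation_path()] object, with attribute `tie_tol` if the file
#'   specified one.
#' @export
read_mutation_path <- function(file) {
  if (!file.exists(file)) stop("parameter file not found: ", file)
  ext <- tolower(tools::file_ext(file))
  params <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML parameter files")
    }
    yaml::read_yaml(file)
  } else {
    jsonlite::fromJSON(file)
  }
  for (key in c("alpha", "beta")) {
    if (is.null(params[[key]])) stop("parameter file is missing '", key, "'")
  }
  if (!is.null(params$nu) && length(params$nu) == length(params$alpha) - 1L) {
    params$nu <- c(params$nu, 0)  # nu for the final type is unused
  }
  path <- mutation_path(params$alpha, params$beta, params$nu, params$labels)
  if (!is.null(params$tie_tol)) attr(path, "tie_tol") <- params$tie_tol
  path
}

#' Adjust mutation rates to track surviving lineages
#'
#' The arrival-time law describes the first cell of a type; that cell's
#' lineage may still die out. The first type-(n+1) cell whose lineage
#' survives forever obeys the same logistic law after the mutation rate
#' `nu[n]` is thinned by the survival probability `lambda[n+1] / alpha[n+1]`
#' of a type-(n+1) lineage. This function returns a copy of the path with
#' every mutation rate so adjusted. All type-(n+1) lineages eventually go
#' extinct unless `lambda[n+1] > 0`, so the adjustment requires every
#' downstream type to be supercritical.
#'
#' @param path A [mutation_path()].
#' @return A [mutation_path()] with `nu[n]` replaced by
#'   `nu[n] * lambda[n+1] / alpha[n+1]` for `n < N`.
#' @export
surviving_lineage_path <- function(path) {
  stopifnot(inherits(path, "mutation_path"))
  n <- path$n_types
  if (n < 2L) return(path)
  lam <- path$alpha - path$beta
  if (any(lam[-1L] <= 0)) {
    bad <- which(lam[-1L] <= 0)[1L] + 1L
    stop(sprintf(
      paste("all lineages of type %d eventually go extinct (lambda[%d] <= 0);",
            "the surviving-lineage arrival time is undefined"), bad, bad))
  }
  nu <- path$nu
  idx <- seq_len(n - 1L)
  nu[idx] <- nu[idx] * lam[idx + 1L] / path$alpha[idx + 1L]
  mutation_path(path$alpha, path$beta, nu, path$labels)
}
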