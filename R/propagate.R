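#' Random-walk configuration
#'
#' @param r restart probability in `(0, 1]`. The walk teleports back to the
#'   seed distribution with probability `r` at each step; larger `r` keeps
#'   the stationary profile more local to the seeds. Default 0.7, the
#'   conventional choice in gene-prioritization random walks.
#' @param tol convergence tolerance on the distance between successive
#'   iterates (default `1e-6`).
#' @param max_iter iteration cap; reaching it yields `converged = FALSE`
#'   plus a warning, not an error.
#' @param norm `"L1"` (sum of absolute differences, default) or `"Linf"`
#'   (maximum absolute difference).
#' @return A list of class `walk_config`.
#' @export
walk_config <- function(r = 0.7, tol = 1e-6, max_iter = 1000L,
                        norm = c("L1", "Linf")) {
  norm <- match.arg(norm)
  if (r <= 0 || r > 1) stop_rwrdr("restart probability r must be in (0, 1]")
  stopifnot(tol > 0, max_iter >= 1)
  structure(list(r = r, tol = tol, max_iter = as.integer(max_iter),
                 norm = norm),
            class = "walk_config")
}

#' Random walk with restart to its stationary profile
#'
#' Iterates `P_{t+1} = (1 - r) A' P_t + r P_0` from `P_0` until the distance
#' between successive iterates drops below `cfg$tol`, and returns the
#' stationary node-probability profile. With a column-stochastic `A_prime`
#' and a normalized seed, every iterate remains a probability distribution.
#'
#' @param A_prime column-stochastic transition matrix from
#'   [transition_matrix] (dense or sparse).
#' @param p0 normalized seed vector (e.g. from [direct_seed]).
#' @param cfg a [walk_config].
#' @return A list of class `rwr_profile`: `values` (named numeric vector),
#'   `iterations`, `converged`, and `deltas` (the per-iteration distance
#'   between successive iterates, for convergence diagnostics).
#' @export
propagate <- function(A_prime, p0, cfg = walk_config()) {
  n <- nrow(A_prime)
  if (length(p0) != n) {
    stop_rwrdr("seed length ", length(p0), " does not match network size ", n)
  }
  r <- cfg$r
  p <- as.numeric(p0)
  p0n <- p
  converged <- FALSE
  iter <- 0L
  deltas <- numeric()
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    p_next <- (1 - r) * as.numeric(A_prime %*% p) + r * p0n
    delta <- if (cfg$norm == "L1") sum(abs(p_next - p)) else max(abs(p_next - p))
    deltas[iter] <- delta
    p <- p_next
    if (delta < cfg$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("random walk did not converge in %d iterations", iter))
  }
  names(p) <- rownames(A_prime) %||% names(p0)
  structure(list(values = p, iterations = iter, converged = converged,
                 deltas = deltas),
            class = "rwr_profile")
}

#' @export
print.rwr_profile <- function(x, ...) {
  cat(sprintf("rwr_profile: %d nodes, %d iteration(s), converged: %s\n",
              length(x$values), x$iterations, x$converged))
  invisible(x)
}

#' Exact stationary profile by direct linear solve
#'
#' The fixed point of the restart iteration satisfies
#' `(I - (1 - r) A') P = r P_0`; this solves that system directly. It is the
#' closed-form counterpart of [propagate] and is used as an independent
#' oracle in the test suite.
#'
#' @inheritParams propagate
#' @param r restart probability in `(0, 1]`.
#' @return An `rwr_profile` with `iterations = 0` and `converged = TRUE`.
#' @export
solve_closed_form <- function(A_prime, p0, r) {
  if (r <= 0 || r > 1) stop_rwrdr("restart probability r must be in (0, 1]")
  n <- nrow(A_prime)
  stopifnot(length(p0) == n)
  M <- Matrix::Diagonal(n) - (1 - r) * A_prime
  p <- tryCatch(as.numeric(Matrix::solve(M, r * as.numeric(p0))),
                error = function(e) {
                  stop_rwrdr("singular restart system: ", conditionMessage(e))
                })
  names(p) <- rownames(A_prime) %||% names(p0)
  structure(list(values = p, iterations = 0L, converged = TRUE),
            class = "rwr_profile")
}

#' Propagate a map of seed vectors
#'
#' Applies [propagate] to each seed, in lexicographic key order. An entity
#' whose walk fails raises a warning and is dropped; the call errors only if
#' every entity fails.
#'
#' @param A_prime transition matrix.
#' @param seeds named list of seed vectors.
#' @param cfg a [walk_config].
#' @return A named list of `rwr_profile` objects (sorted keys).
#' @export
propagate_all <- function(A_prime, seeds, cfg = walk_config()) {
  stopifnot(length(seeds) > 0L, !is.null(names(seeds)))
  out <- list()
  for (id in lex_sort(names(seeds))) {
    prof <- tryCatch(propagate(A_prime, seeds[[id]], cfg),
                     error = function(e) {
                       warning(sprintf("propagation failed for '%s': %s",
                                       id, conditionMessage(e)))
                       NULL
                     })
    if (!is.null(prof)) out[[id]] <- prof
  }
  if (length(out) == 0L) stop_rwrdr("propagation failed for every entity")
  out
}

#' Write a stationary profile as TSV
#'
#' One `node-id <TAB> probability` row per node, in network node order, at
#' full double precision.
#'
#' @param profile an `rwr_profile` (or bare numeric vector with names).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  v <- if (inherits(profile, "rwr_profile")) profile$values else profile
  writeLines(c("#node\tprobability",
               paste(names(v), fmt_num(as.numeric(v)), sep = "\t")),
             path)
  invisible(path)
}
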