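#' Principal-eigenvector priorities of a judgment matrix
#'
#' For a fully transitive reciprocal matrix (a_ij = w_i / w_j) every column
#' is proportional to the weight vector and the only non-trivial eigenvalue
#' is n. Real judgments are rarely fully transitive, so the priority vector
#' is taken as the eigenvector of the largest eigenvalue lambda_max; by
#' Perron-Frobenius a positive matrix has a unique dominant eigenvalue with
#' a strictly positive eigenvector, computed here by power iteration without
#' deflation. Weights are normalised to sum 1 (distributive mode).
#'
#' @param M positive reciprocal square matrix (an `ahp_judgment` or plain
#'   matrix); dimnames, if present, name the elements.
#' @param tol convergence tolerance: iteration stops when successive
#'   normalised vectors differ by less than `tol` in max norm.
#' @param max_iter iteration budget; exceeding it signals pathological input.
#' @return An object of class `ahp_priority`: list with `node_id`,
#'   `elements`, `weights` (named, sums to 1), `lambda_max`, `n`,
#'   `iterations`.
#' @examples
#' A <- matrix(c(1, 3, 5, 1/3, 1, 3, 1/5, 1/3, 1), 3, 3, byrow = TRUE)
#' principal_priorities(A)$weights  # ~ (0.637, 0.258, 0.105)
#' @export
principal_priorities <- function(M, tol = 1e-12, max_iter = 10000L) {
  check_judgment_matrix(M, tol = 1e-9)
  n <- nrow(M)
  elements <- rownames(M)
  if (is.null(elements)) elements <- paste0("e", seq_len(n))
  node_id <- attr(M, "node_id")
  if (is.null(node_id)) node_id <- "node"
  M <- unclass(M)
  attributes(M) <- list(dim = c(n, n))

  w <- rep(1 / n, n)
  it <- 0L
  repeat {
    it <- it + 1L
    v <- as.vector(M %*% w)
    v <- v / sum(v)
    if (max(abs(v - w)) < tol) { w <- v; break }
    w <- v
    if (it >= max_iter)
      stop("power iteration did not converge within ", max_iter,
           " iterations; the matrix is pathological", call. = FALSE)
  }
  # with sum(w) = 1, sum(M w) estimates lambda_max
  lambda_max <- sum(M %*% w)
  structure(list(node_id = node_id, elements = elements,
                 weights = stats::setNames(w, elements),
                 lambda_max = lambda_max, n = n, iterations = it),
            class = "ahp_priority")
}

#' Random Index: expected consistency index of random reciprocal matrices
#'
#' Tabulated constants for matrix dimensions 1 to 9 (classic values derived
#' from random matrices with entries on the 1-9 comparison grid). RI(1) and
#' RI(2) are 0: matrices of dimension up to 2 are always consistent.
#'
#' @param n matrix dimension, 1 to 9.
#' @return The tabulated RI constant.
#' @export
random_index <- function(n) {
  ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45)
  if (!is.numeric(n) || length(n) != 1L || n != round(n) || n < 1 || n > 9)
    stop("Random Index is tabulated for n = 1..9 only; supply a custom RI ",
         "to consistency_report() for larger matrices", call. = FALSE)
  ri[n]
}

#' Consistency screening of a judgment matrix
#'
#' The consistency index CI = (lambda_max - n) / (n - 1) measures deviation
#' from transitivity (zero iff a_ij = a_ik * a_kj for all triples). The
#' consistency ratio CR = CI / RI(n) compares it with random judgments;
#' CR <= 0.1 is the conventional acceptance threshold, relaxed to 0.2 for
#' complex hierarchies when re-elicitation is impractical. For n <= 2 the
#' matrix is always consistent and CR is defined as 0.
#'
#' @param M positive reciprocal matrix, or an `ahp_priority` already
#'   computed from one.
#' @param primary_threshold CR acceptance threshold (default 0.1).
#' @param relaxed_threshold relaxed threshold (default 0.2).
#' @param RI optional custom Random Index (required for n > 9).
#' @return An `ahp_consistency` list: `node_id`, `n`, `lambda_max`, `CI`,
#'   `RI`, `CR`, `pass_primary`, `pass_relaxed`.
#' @export
consistency_report <- function(M, primary_threshold = 0.1,
                               relaxed_threshold = 0.2, RI = NULL) {
  stopifnot(primary_threshold <= relaxed_threshold)
  pr <- if (inherits(M, "ahp_priority")) M else principal_priorities(M)
  n <- pr$n
  ci <- if (n <= 2L) 0 else (pr$lambda_max - n) / (n - 1)
  ci <- max(ci, 0)  # numerical floor: lambda_max >= n in exact arithmetic
  if (is.null(RI)) RI <- if (n <= 2L) 0 else random_index(n)
  cr <- if (n <= 2L) 0 else ci / RI
  structure(list(node_id = pr$node_id, n = n, lambda_max = pr$lambda_max,
                 CI = ci, RI = RI, CR = cr,
                 pass_primary = cr <= primary_threshold,
                 pass_relaxed = cr <= relaxed_threshold),
            class = "ahp_consistency")
}

#' Monte-Carlo re-derivation of Random Index constants
#'
#' Provenance check for the shipped table: simulates random reciprocal
#' matrices with upper-triangle entries drawn uniformly from a comparison
#' grid and returns the mean CI. Published RI tables differ somewhat with
#' the simulation design (grid and sample size), so this is a sanity band,
#' not a reproduction to printed precision.
#'
#' @param n matrix dimension.
#' @param reps number of random matrices.
#' @param grid comparison grid to draw entries from (default the full
#'   1/9..9 grid the classic table is based on).
#' @return Mean consistency index over the draws.
#' @export
simulate_random_index <- function(n, reps = 2000L,
                                  grid = c(1 / (9:2), 1:9)) {
  stopifnot(n >= 3)
  cis <- vapply(seq_len(reps), function(r) {
    A <- diag(1, n)
    A[upper.tri(A)] <- sample(grid, n * (n - 1) / 2, replace = TRUE)
    A[lower.tri(A)] <- 1 / t(A)[lower.tri(A)]
    pr <- principal_priorities(A, tol = 1e-10, max_iter = 50000L)
    (pr$lambda_max - n) / (n - 1)
  }, numeric(1))
  mean(cis)
}

#' Aggregate local weights into global need weights
#'
#' Two-level distributive aggregation: the global weight of need i in
#' category m is `GW_i = LW_i^m * CW^m`, the product of its local weight
#' within the category and the category's weight at the goal. Because
#' category weights sum to 1 and each category's local weights sum to 1,
#' the global weights sum to 1 over all needs.
#'
#' @param category_priorities `ahp_priority` at the goal node (elements are
#'   category ids).
#' @param local_priorities named list of `ahp_priority`, one per category id.
#' @param responder_id optional responder label carried into the result.
#' @return An `ahp_global` list: `responder_id`, `category_weights` (named),
#'   `local_weights` (named, over all needs), `global_weights` (named, sums
#'   to 1), `category_of` (named map need -> category).
#' @export
global_weights <- function(category_priorities, local_priorities,
                           responder_id = NA_character_) {
  cw <- category_priorities$weights
  miss <- setdiff(names(cw), names(local_priorities))
  if (length(miss) > 0L)
    stop("missing local priorities for categor", if (length(miss) > 1) "ies " else "y ",
         paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(local_priorities), names(cw))
  if (length(extra) > 0L)
    stop("local priorities for unknown categor",
         if (length(extra) > 1) "ies " else "y ",
         paste(extra, collapse = ", "), call. = FALSE)

  lw <- numeric(0); gw <- numeric(0); cat_of <- character(0)
  for (cid in names(cw)) {
    lp <- local_priorities[[cid]]
    lw <- c(lw, lp$weights)
    gw <- c(gw, lp$weights * cw[[cid]])
    cat_of[names(lp$weights)] <- cid
  }
  structure(list(responder_id = responder_id, category_weights = cw,
                 local_weights = lw, global_weights = gw,
                 category_of = cat_of),
            class = "ahp_global")
}

#' Rank needs by global weight
#'
#' Needs are sorted by descending global weight; exact ties keep the
#' hierarchy (input) order and are flagged.
#'
#' @param gp an `ahp_global` (or a named numeric vector of weights).
#' @param k how many needs to return (default all).
#' @return Data frame with columns `rank`, `need_id`, `GW`, `tied`.
#' @export
rank_needs <- function(gp, k = NULL) {
  gw <- if (inherits(gp, "ahp_global")) gp$global_weights else gp
  if (is.null(k)) k <- length(gw)
  if (k > length(gw)) stop("k exceeds the number of needs", call. = FALSE)
  ord <- order(-gw)  # stable: ties keep input (hierarchy) order
  gws <- gw[ord]
  tied <- duplicated(gws) | duplicated(gws, fromLast = TRUE)
  out <- data.frame(rank = seq_along(gws), need_id = names(gws),
                    GW = unname(gws), tied = tied, stringsAsFactors = FALSE)
  out[seq_len(k), , drop = FALSE]
}

#' @export
print.ahp_priority <- function(x, ...) {
  cat("Priorities at node '", x$node_id, "' (n = ", x$n,
      ", lambda_max = ", format(x$lambda_max, digits = 6), ")\n", sep = "")
  print(round(x$weights, 4))
  invisible(x)
}

#' @export
print.ahp_consistency <- function(x, ...) {
  cat(sprintf("Node '%s': n = %d, lambda_max = %.4f, CI = %.4f, RI = %.2f, CR = %.4f [%s]\n",
              x$node_id, x$n, x$lambda_max, x$CI, x$RI, x$CR,
              if (x$pass_primary) "pass" else if (x$pass_relaxed)
                "pass (relaxed only)" else "FAIL"))
  invisible(x)
}
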