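#' Spearman rank correlation with mid-rank ties
#'
#' Ranks each vector ascending, assigning tied values the average of the
#' ranks they span, then returns the Pearson correlation of the two rank
#' vectors. This is the tie-aware form required when weights are reported
#' at coarse precision: rounded priority profiles routinely contain exact
#' ties, and mid-ranks are what makes published concordance values
#' reproducible from printed tables.
#'
#' @param x,y numeric weight vectors over the same ordered items,
#'   length >= 3.
#' @return Spearman's rho in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    stop("profiles have different lengths (", length(x), " vs ", length(y),
         ")", call. = FALSE)
  if (length(x) < 3L)
    stop("need at least 3 items to rank", call. = FALSE)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("rank correlation is undefined for a constant profile (all items tied)",
         call. = FALSE)
  # identical rankings are exactly 1 by definition; don't let the Pearson
  # arithmetic lose an ulp on the boundary case
  if (all(rx == ry)) return(1)
  stats::cor(rx, ry)
}

# all n! permutation rho values against the identity ranking, cached per n
perm_rho_table <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    perms <- permutations_of(n)
    base <- seq_len(n)
    rhos <- as.vector(stats::cor(t(perms), base))
    cache[[key]] <<- rhos
    rhos
  }
})

# all permutations of 1:n as an n! x n integer matrix, lexicographic
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    block <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
    out[row + seq_len(nrow(sub)), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' P-value for Spearman's rho
#'
#' Small samples (n <= 8) use the exact permutation null: all n! rank
#' permutations of one untied vector against the other, counting
#' |rho_perm| >= |rho_obs| (two-sided) or rho_perm >= rho_obs (one-sided,
#' for positive rho). Larger samples use the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom; a
#' |rho| of exactly 1 under the approximation falls back to the exact
#' enumeration bound 2/n! (or 1/n!) rather than returning 0.
#'
#' @param rho observed correlation.
#' @param n number of ranked items (>= 3).
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return The p-value.
#' @export
spearman_pvalue <- function(rho, n, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(n >= 3, abs(rho) <= 1 + 1e-12)
  rho <- max(min(rho, 1), -1)
  if (n <= 8L) {
    rhos <- perm_rho_table(n)
    eps <- 1e-12
    if (alternative == "two.sided") {
      mean(abs(rhos) >= abs(rho) - eps)
    } else {
      mean(rhos >= rho - eps)
    }
  } else {
    if (abs(rho) >= 1 - 1e-12) {
      p1 <- 1 / factorial(n)
      return(if (alternative == "two.sided") 2 * p1 else
             if (rho > 0) p1 else 1 - p1)
    }
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    if (alternative == "two.sided") 2 * stats::pt(-abs(t), df = n - 2)
    else stats::pt(t, df = n - 2, lower.tail = FALSE)
  }
}

#' Pairwise concordance between responders' priority profiles
#'
#' Computes Spearman's rho (mid-rank ties) and its p-value for every pair of
#' responders over a shared ordered item set, and flags pairs significant at
#' `alpha`. All pairs are always computed and reported; presentation-layer
#' suppression of non-significant cells is left to the caller.
#'
#' @param profiles named list of numeric weight vectors (one per responder),
#'   all over the same ordered items; or a numeric matrix with items as rows
#'   and responders as columns.
#' @param alpha significance level for the mask (default 0.05).
#' @param alternative passed to [spearman_pvalue()].
#' @return An `ahp_concordance` list: `responders`, `rho` (symmetric matrix,
#'   unit diagonal), `p` (symmetric, NA diagonal), `significant` (logical,
#'   `p < alpha`), `alpha`, `n_items`.
#' @export
concordance_matrix <- function(profiles, alpha = 0.05,
                               alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (is.matrix(profiles))
    profiles <- stats::setNames(
      lapply(seq_len(ncol(profiles)), function(j) {
        stats::setNames(profiles[, j], rownames(profiles))
      }), colnames(profiles))
  if (length(profiles) < 2L)
    stop("need at least 2 responder profiles", call. = FALSE)
  ids <- names(profiles)
  if (is.null(ids)) ids <- paste0("R", seq_along(profiles))
  items <- names(profiles[[1]])
  for (p in profiles) {
    if (length(p) != length(profiles[[1]]) ||
        (!is.null(items) && !identical(names(p), items)))
      stop("responder profiles must share an identical ordered item set",
           call. = FALSE)
  }
  m <- length(profiles)
  n_items <- length(profiles[[1]])
  rho <- diag(1, m); p <- matrix(NA_real_, m, m)
  dimnames(rho) <- dimnames(p) <- list(ids, ids)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    # a responder who tied every item has no ranking: the pair is reported
    # as NA rather than aborting the study
    r <- tryCatch(spearman_rho(profiles[[i]], profiles[[j]]),
                  error = function(e) {
                    warning("rho undefined for pair (", ids[i], ", ", ids[j],
                            "): ", conditionMessage(e), call. = FALSE)
                    NA_real_
                  })
    pv <- if (is.na(r)) NA_real_ else spearman_pvalue(r, n_items, alternative)
    rho[i, j] <- rho[j, i] <- r
    p[i, j] <- p[j, i] <- pv
  }
  structure(list(responders = ids, rho = rho, p = p,
                 significant = !is.na(p) & p < alpha,
                 alpha = alpha, n_items = n_items),
            class = "ahp_concordance")
}

#' @export
print.ahp_concordance <- function(x, digits = 2, ...) {
  cat("Concordance over", x$n_items, "items,", length(x$responders),
      "responders (alpha =", x$alpha, ")\n")
  disp <- matrix(sprintf("%.*f(%.3f)", digits, x$rho, x$p),
                 nrow(x$rho), dimnames = dimnames(x$rho))
  diag(disp) <- "1"
  print(disp, quote = FALSE)
  invisible(x)
}
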