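# shared generators for the suite

toy_hierarchy <- function() {
  new_hierarchy("toy goal", list(
    list(id = "c1", label = "first", children = list(
      list(id = "a", label = "A"), list(id = "b", label = "B"),
      list(id = "c", label = "C"))),
    list(id = "c2", label = "second", children = list(
      list(id = "d", label = "D"), list(id = "e", label = "E")))))
}

ct_hierarchy <- function() {
  load_hierarchy(system.file("extdata", "ct_hierarchy.yaml",
                             package = "ahpelicit"))
}

# random positive reciprocal matrix; grid = TRUE draws from the 1-9
# comparison grid, otherwise entries are lognormal ratios
random_reciprocal <- function(n, grid = TRUE) {
  A <- diag(1, n)
  m <- n * (n - 1) / 2
  A[upper.tri(A)] <- if (grid) {
    sample(c(1 / (9:2), 1:9), m, replace = TRUE)
  } else {
    exp(stats::rnorm(m, 0, 1))
  }
  A[lower.tri(A)] <- 1 / t(A)[lower.tri(A)]
  A
}

# fully transitive matrix from a weight vector
consistent_matrix <- function(w) {
  outer(w, w, "/")
}

# dense-eigendecomposition oracle for the dominant eigenpair
eigen_oracle <- function(A) {
  e <- eigen(A)
  k <- which.max(Re(e$values))
  v <- Re(e$vectors[, k])
  if (sum(v) < 0) v <- -v
  list(lambda = Re(e$values[k]), weights = v / sum(v))
}

# max transitivity violation max |a_ij - a_ik a_kj|
transitivity_gap <- function(A) {
  n <- nrow(A)
  g <- 0
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    g <- max(g, abs(A[i, j] - A[i, k] * A[k, j]))
  g
}
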