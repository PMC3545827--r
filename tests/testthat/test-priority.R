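test_that("the all-ones matrix gives uniform weights with lambda_max = n", {
  for (n in c(3L, 4L)) {
    pr <- principal_priorities(matrix(1, n, n))
    expect_equal(unname(pr$weights), rep(1 / n, n), tolerance = 1e-12)
    expect_equal(pr$lambda_max, n, tolerance = 1e-12)
  }
})

test_that("a fully transitive matrix returns its generating weights exactly", {
  w <- c(0.58, 0.28, 0.14)
  pr <- principal_priorities(consistent_matrix(w))
  expect_equal(unname(pr$weights), w, tolerance = 1e-10)
  expect_equal(pr$lambda_max, 3, tolerance = 1e-10)
})

test_that("the 1-3-5 ladder matrix matches the dense eigen oracle", {
  A <- matrix(c(1, 3, 5, 1 / 3, 1, 3, 1 / 5, 1 / 3, 1), 3, 3, byrow = TRUE)
  pr <- principal_priorities(A)
  o <- eigen_oracle(A)
  expect_equal(unname(pr$weights), o$weights, tolerance = 1e-10)
  expect_equal(pr$lambda_max, o$lambda, tolerance = 1e-10)
  # frozen values from the oracle
  expect_equal(unname(round(pr$weights, 3)), c(0.637, 0.258, 0.105))
  expect_equal(pr$lambda_max, 3.0385, tolerance = 1e-4)
  cr <- consistency_report(A)
  expect_equal(cr$CI, (pr$lambda_max - 3) / 2, tolerance = 1e-12)
  expect_lt(abs(cr$CI - 0.0193), 1e-4)
  expect_equal(cr$CR, cr$CI / 0.58, tolerance = 1e-12)
  expect_lt(abs(cr$CR - 0.0332), 1e-4)
  expect_true(cr$pass_primary)
})

test_that("power iteration agrees with the eigen oracle on random matrices", {
  set.seed(101)
  for (r in 1:200) {
    n <- sample(3:9, 1)
    A <- random_reciprocal(n, grid = (r %% 2 == 0))
    pr <- principal_priorities(A)
    o <- eigen_oracle(A)
    expect_equal(unname(pr$weights), o$weights, tolerance = 1e-8)
    expect_equal(pr$lambda_max, o$lambda, tolerance = 1e-8)
    expect_true(pr$lambda_max >= n - 1e-9)
    expect_equal(sum(pr$weights), 1, tolerance = 1e-12)
    expect_true(all(pr$weights > 0))
  }
})

test_that("lambda_max equals n exactly when and only when judgments are transitive", {
  set.seed(7)
  for (r in 1:25) {
    n <- sample(3:6, 1)
    w <- rgamma(n, 1); w <- w / sum(w)
    C <- consistent_matrix(w)
    expect_lt(transitivity_gap(C), 1e-12)
    expect_equal(principal_priorities(C)$lambda_max, n, tolerance = 1e-9)
    expect_equal(consistency_report(C)$CR, 0, tolerance = 1e-9)

    A <- random_reciprocal(n, grid = FALSE)
    if (transitivity_gap(A) > 1e-6)
      expect_gt(principal_priorities(A)$lambda_max, n)
  }
})

test_that("priorities and consistency are permutation-equivariant", {
  set.seed(11)
  for (r in 1:20) {
    n <- sample(3:7, 1)
    A <- random_reciprocal(n)
    dimnames(A) <- list(paste0("e", 1:n), paste0("e", 1:n))
    p <- sample(n)
    B <- A[p, p]
    pa <- principal_priorities(A); pb <- principal_priorities(B)
    expect_equal(unname(pb$weights), unname(pa$weights[p]), tolerance = 1e-10)
    expect_equal(pb$lambda_max, pa$lambda_max, tolerance = 1e-10)
    ca <- consistency_report(A); cb <- consistency_report(B)
    expect_equal(cb$CI, ca$CI, tolerance = 1e-10)
    expect_equal(cb$CR, ca$CR, tolerance = 1e-10)
  }
})

test_that("the Random Index table matches the classic constants", {
  expect_identical(random_index(1), 0)
  expect_identical(random_index(2), 0)
  expect_identical(random_index(3), 0.58)
  expect_identical(random_index(4), 0.90)
  expect_identical(random_index(9), 1.45)
  expect_error(random_index(10), "custom RI")
  expect_error(random_index(0), "custom RI")
})

test_that("Monte-Carlo mean CI of random grid matrices lands near the RI table", {
  # published RI tables vary with simulation design; this is a sanity band
  set.seed(2024)
  expect_equal(simulate_random_index(3, reps = 1500), random_index(3),
               tolerance = 0.25)
  expect_equal(simulate_random_index(4, reps = 800), random_index(4),
               tolerance = 0.25)
})

test_that("consistency thresholds order correctly: primary pass implies relaxed", {
  # grid matrix with CR ~= 0.14: fails at 0.1, passes at 0.2
  A <- matrix(c(1, 1 / 5, 1 / 3, 5, 1, 1 / 2, 3, 2, 1), 3, 3, byrow = TRUE)
  cr <- consistency_report(A)
  expect_gt(cr$CR, 0.1); expect_lt(cr$CR, 0.2)
  expect_false(cr$pass_primary)
  expect_true(cr$pass_relaxed)
  # n = 2 is always consistent by convention
  cr2 <- consistency_report(matrix(c(1, 4, 1 / 4, 1), 2, 2))
  expect_identical(cr2$CR, 0)
  expect_true(cr2$pass_primary)
})

test_that("global weights multiply local by category weight and sum to 1", {
  cats <- structure(list(node_id = "goal", elements = c("perf", "safe"),
                         weights = c(perf = 0.22, safe = 0.78),
                         lambda_max = 2, n = 2L, iterations = 1L),
                    class = "ahp_priority")
  mk_local <- function(nid, w) structure(
    list(node_id = nid, elements = names(w), weights = w,
         lambda_max = length(w), n = length(w), iterations = 1L),
    class = "ahp_priority")
  loc <- list(perf = mk_local("perf", c(sr = 0.32, sw = 0.68)),
              safe = mk_local("safe", c(pm = 0.66, cm = 0.34)))
  gp <- global_weights(cats, loc, "r1")
  expect_equal(unname(gp$global_weights["sr"]), 0.32 * 0.22)
  expect_equal(round(gp$global_weights[["sr"]], 2), 0.07)
  expect_equal(sum(gp$global_weights), 1, tolerance = 1e-12)
  expect_identical(unname(gp$category_of["pm"]), "safe")

  # worked example from the published emergency profile: .66 x .60 -> .40
  expect_equal(round(0.66 * 0.60, 2), 0.40)

  # single category: global equals local
  one <- structure(list(node_id = "goal", elements = "only",
                        weights = c(only = 1), lambda_max = 1, n = 1L,
                        iterations = 1L), class = "ahp_priority")
  gp1 <- global_weights(one, list(only = mk_local("only", c(a = 0.7, b = 0.3))))
  expect_identical(gp1$global_weights, gp1$local_weights)

  expect_error(global_weights(cats, loc["perf"]), "missing local priorities")
  expect_error(global_weights(cats, c(loc, list(extra = loc$perf))),
               "unknown categor")
})

test_that("rank_needs sorts descending, keeps hierarchy order on ties, flags them", {
  gw <- c(n1 = 0.1, n2 = 0.4, n3 = 0.1, n4 = 0.4)
  rk <- rank_needs(gw)
  expect_identical(rk$need_id, c("n2", "n4", "n1", "n3"))
  expect_true(all(rk$tied))
  rk1 <- rank_needs(c(a = 0.2, b = 0.5, c = 0.3), k = 1)
  expect_identical(rk1$need_id, "b")
  expect_false(rk1$tied)
  expect_error(rank_needs(gw, k = 5), "exceeds")
})
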