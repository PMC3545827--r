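test_that("latent profiles live on simplices and are seed-deterministic", {
  cfg <- simulation_config(ct_hierarchy(), n_responders = 3, seed = 42)
  p1 <- sample_latent_profile(cfg, 1)
  expect_equal(sum(p1$category_weights), 1, tolerance = 1e-12)
  for (lw in p1$local_weights)
    expect_equal(sum(lw), 1, tolerance = 1e-12)
  expect_equal(sum(p1$global_weights), 1, tolerance = 1e-12)
  expect_true(all(p1$global_weights > 0))
  # repeated calls with same seed and index are identical
  expect_identical(p1, sample_latent_profile(cfg, 1))
  # different index gives a different draw
  expect_false(identical(p1$category_weights,
                         sample_latent_profile(cfg, 2)$category_weights))
  # profile draws do not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(sample_latent_profile(cfg, 1)); b <- runif(1)
  expect_identical(a, b)
})

test_that("large concentration pulls latent weights towards uniform", {
  h <- toy_hierarchy()
  cfg <- simulation_config(h, concentration = 400, seed = 8)
  maxw <- vapply(1:300, function(i)
    max(sample_latent_profile(cfg, i)$category_weights), numeric(1))
  # two categories: uniform is 1/2; at concentration 400 the max stays close
  expect_lt(mean(maxw), 1 / 2 + 0.05)
  expect_gt(mean(maxw), 1 / 2 - 1e-12)
})

test_that("noiseless unquantized judgments are exactly consistent", {
  w <- c(a = 0.6, b = 0.3, c = 0.1)
  A <- judgments_from_profile(w, sigma = 0, quantize = FALSE)
  expect_lt(transitivity_gap(A), 1e-12)
  expect_equal(consistency_report(A)$CR, 0, tolerance = 1e-9)
  expect_equal(unname(principal_priorities(A)$weights), unname(w),
               tolerance = 1e-10)
})

test_that("quantized judgments live on the scale grid and preserve separated rankings", {
  w <- c(a = 0.6, b = 0.3, c = 0.1)
  A <- judgments_from_profile(w, sigma = 0, quantize = TRUE)
  grid <- c(1 / 5, 1 / 4, 1 / 3, 1 / 2, 1, 2, 3, 4, 5)
  off <- A[upper.tri(A) | lower.tri(A)]
  expect_true(all(vapply(off, function(v)
    any(abs(v - grid) < 1e-12), logical(1))))
  expect_identical(as.vector(A * t(A)), rep(1, 9))
  rec <- principal_priorities(A)$weights
  expect_identical(order(-rec), order(-w))
})

test_that("mean consistency ratio degrades monotonically with noise", {
  crs <- vapply(c(0, 0.3, 0.6), function(sg) {
    mean(vapply(1:150, function(i) {
      set.seed(1000 + i)  # same latent weights at every noise level
      w <- rgamma(4, 1); w <- w / sum(w); names(w) <- paste0("x", 1:4)
      A <- judgments_from_profile(w, sigma = sg, quantize = TRUE,
                                  seed = 33 + i)
      consistency_report(A)$CR
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(crs) > 0))
})

test_that("the noiseless unquantized study inverts exactly end to end", {
  h <- ct_hierarchy()
  cfg <- simulation_config(h, n_responders = 4, sigma = 0,
                           quantize = FALSE, seed = 5)
  st <- simulate_study(cfg)
  expect_null(st$responses)
  rep <- run_study(h, st$matrices)
  expect_true(all(rep$consistency$CR < 1e-9))
  rr <- recovery_report(st$truth, rep$global)
  expect_true(all(rr$L1 < 1e-8))
  expect_true(all(rr$rho == 1))
  expect_true(all(rr$top_k_overlap == 5))
})

test_that("responders sharing one latent profile are perfectly concordant", {
  h <- ct_hierarchy()
  cfg <- simulation_config(h, n_responders = 1, sigma = 0,
                           quantize = FALSE, seed = 12)
  prof <- sample_latent_profile(cfg, 1)
  mk <- function() {
    nodes <- comparison_nodes(h)
    ms <- lapply(names(nodes), function(nid) {
      w <- if (nid == h$goal) prof$category_weights
           else prof$local_weights[[nid]]
      judgments_from_profile(w, sigma = 0, quantize = FALSE, node_id = nid)
    })
    setNames(ms, names(nodes))
  }
  rep <- run_study(h, list(twin_a = mk(), twin_b = mk()))
  expect_identical(rep$concordance_need$rho["twin_a", "twin_b"], 1)
})

test_that("quantized simulated studies round-trip through the CSV response format", {
  h <- ct_hierarchy()
  cfg <- simulation_config(h, n_responders = 3, sigma = 0.1,
                           quantize = TRUE, seed = 77)
  st <- simulate_study(cfg)
  expect_identical(nrow(st$responses),
                   3L * (6L + 4L * 3L))  # goal 4 choose 2 + 4 nodes of 3
  d <- withr::local_tempdir()
  files <- export_simulated_study(st, d)
  rep_file <- run_study(h, unname(files["responses"]))
  rep_mem <- run_study(h, st$matrices)
  expect_equal(weight_table(rep_file)$GW, weight_table(rep_mem)$GW,
               tolerance = 1e-12)
  truth <- jsonlite::read_json(unname(files["truth"]))
  expect_identical(length(truth$truth), 3L)
  expect_identical(truth$config$seed, 77L)
})

test_that("recovery_report computes identity and closed-form L1 cases", {
  h <- toy_hierarchy()
  cfg <- simulation_config(h, n_responders = 2, sigma = 0,
                           quantize = FALSE, seed = 3)
  st <- simulate_study(cfg)
  # two categories cannot be rank-correlated (< 3 items): warned, not fatal
  expect_warning(rep <- run_study(h, st$matrices), "rho undefined")
  rr <- recovery_report(st$truth, rep$global, k = 3)
  expect_true(all(rr$L1 < 1e-9))
  expect_true(all(rr$rho == 1))
  expect_true(all(rr$top_k_overlap == 3))

  # uniform recovered vs concentrated truth: L1 = sum |w_i - 1/n|
  truth1 <- st$truth[1]
  n <- length(truth1[[1]]$global_weights)
  uni <- rep$global[1]
  uni[[1]]$global_weights[] <- 1 / n
  rr2 <- recovery_report(truth1, uni)
  expect_equal(rr2$L1, sum(abs(truth1[[1]]$global_weights - 1 / n)),
               tolerance = 1e-12)

  bad <- rep$global
  bad[[1]]$responder_id <- "stranger"
  expect_error(recovery_report(st$truth, bad), "responder ids differ")
})

test_that("simulations are byte-identical under a fixed seed", {
  h <- toy_hierarchy()
  cfg <- simulation_config(h, n_responders = 3, sigma = 0.2,
                           quantize = TRUE, seed = 99)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$responses, s2$responses)
  expect_identical(s1$truth, s2$truth)
})
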