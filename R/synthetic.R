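#' Simulation configuration for synthetic responders
#'
#' Synthetic responders carry latent priority vectors (one simplex for the
#' categories, one per category for its needs) from which pairwise judgments
#' are generated as true ratios w_i / w_j, optionally perturbed by
#' multiplicative log-normal noise and snapped to the verbal response grid.
#' This gives ground truth for end-to-end validation: with sigma = 0 and no
#' quantization the pipeline must invert exactly.
#'
#' @param hierarchy an `ahp_hierarchy`.
#' @param n_responders number of synthetic responders.
#' @param concentration symmetric Dirichlet concentration for latent weight
#'   sampling; 1 is uniform on the simplex, larger values pull towards
#'   equal weights, smaller towards sharply peaked priorities.
#' @param sigma standard deviation of the log-scale multiplicative noise on
#'   each elicited ratio (0 = perfectly transitive judgments).
#' @param quantize snap perturbed ratios to the judgment scale grid
#'   (in log space) so they are expressible as verbal grades.
#' @param scale an `ahp_scale` used when quantizing.
#' @param seed integer seed; fixed seed gives byte-identical simulations.
#' @return An `ahp_simconfig` list echoing the arguments.
#' @export
simulation_config <- function(hierarchy, n_responders = 5L,
                              concentration = 1, sigma = 0,
                              quantize = TRUE, scale = adapted_scale(),
                              seed = 1L) {
  stopifnot(inherits(hierarchy, "ahp_hierarchy"),
            n_responders >= 1, concentration > 0, sigma >= 0,
            is.logical(quantize))
  structure(list(hierarchy = hierarchy,
                 n_responders = as.integer(n_responders),
                 concentration = concentration, sigma = sigma,
                 quantize = quantize, scale = scale,
                 seed = as.integer(seed)),
            class = "ahp_simconfig")
}

# derived 32-bit seed for (simulation seed, responder index, node index);
# keeps per-responder/per-node draws reproducible in isolation
derive_seed <- function(seed, responder = 0L, node = 0L) {
  as.integer((as.double(seed) * 2654435.0 + responder * 97561.0 +
                node * 1013.0) %% 2147483647)
}

# one draw from a symmetric Dirichlet via normalised gammas
rdirichlet1 <- function(n, concentration) {
  g <- stats::rgamma(n, shape = concentration, rate = 1)
  # guard against all-zero underflow at tiny concentrations
  while (sum(g) == 0) g <- stats::rgamma(n, shape = concentration, rate = 1)
  g / sum(g)
}

#' Sample a latent priority profile
#'
#' Draws the responder's category weights and per-category local weights
#' from symmetric Dirichlet distributions and derives the implied global
#' weights. Deterministic given (config seed, responder index).
#'
#' @param cfg an `ahp_simconfig`.
#' @param index responder index (1-based).
#' @return An `ahp_latent` list: `responder_id`, `category_weights`,
#'   `local_weights` (named list per category), `global_weights` (named over
#'   all needs).
#' @export
sample_latent_profile <- function(cfg, index) {
  stopifnot(inherits(cfg, "ahp_simconfig"), index >= 1)
  h <- cfg$hierarchy
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, responder = index, node = 0L))

  cw <- stats::setNames(rdirichlet1(length(h$categories), cfg$concentration),
                        h$categories)
  lw <- lapply(h$categories, function(cid)
    stats::setNames(rdirichlet1(length(h$children[[cid]]), cfg$concentration),
                    h$children[[cid]]))
  names(lw) <- h$categories
  gw <- unlist(lapply(h$categories, function(cid) lw[[cid]] * cw[[cid]]),
               use.names = TRUE)
  gw <- gw[h$needs]
  structure(list(responder_id = sprintf("S%02d", index),
                 category_weights = cw, local_weights = lw,
                 global_weights = gw),
            class = "ahp_latent")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a judgment matrix from latent weights
#'
#' The noiseless judgment for elements i, j is the true ratio w_i / w_j
#' (fully transitive by construction). Each upper-triangle entry is
#' perturbed multiplicatively: a_ij = (w_i / w_j) * exp(eps_ij) with
#' eps_ij ~ Normal(0, sigma^2), and the lower triangle is set to exact
#' reciprocals, which keeps the matrix valid at any sigma. With
#' `quantize = TRUE` each perturbed entry is snapped to the nearest scale
#' grid value in log space (so reciprocal pairs snap consistently) before
#' the reciprocal fill.
#'
#' @param weights named positive weight vector for one node's children.
#' @param sigma log-scale noise standard deviation.
#' @param quantize snap to the scale grid.
#' @param scale an `ahp_scale`.
#' @param seed integer seed for the perturbation draws (already derived;
#'   see [derive_seed()] callers), or NULL to use the current RNG stream.
#' @param node_id node label for the resulting matrix.
#' @return An `ahp_judgment` matrix.
#' @export
judgments_from_profile <- function(weights, sigma = 0, quantize = TRUE,
                                   scale = adapted_scale(), seed = NULL,
                                   node_id = "node") {
  stopifnot(all(weights > 0))
  n <- length(weights)
  ids <- names(weights)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  A <- diag(1, n)
  dimnames(A) <- list(ids, ids)
  log_grid <- log(scale$value)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    lv <- log(weights[[i]] / weights[[j]])
    if (sigma > 0) lv <- lv + stats::rnorm(1L, 0, sigma)
    # snap in log space but store the grid value itself, so a_ij is exactly
    # a scale value and a_ji its stored reciprocal
    A[i, j] <- if (quantize) scale$value[which.min(abs(lv - log_grid))]
               else exp(lv)
    A[j, i] <- 1 / A[i, j]
  }
  structure(A, node_id = node_id, class = c("ahp_judgment", "matrix", "array"))
}

#' Simulate a complete elicitation study
#'
#' Draws a latent profile per responder and generates one judgment matrix
#' per comparison node (goal plus each category). When `quantize = TRUE`
#' the judgments are expressible as verbal grades, and a response table in
#' the standard CSV layout (`responder_id, node_id, left_id, right_id,
#' grade`) is attached, built by reading each matrix back along the node's
#' balanced schedule. Ground truth is always attached for recovery scoring.
#'
#' @param cfg an `ahp_simconfig`.
#' @return An `ahp_simstudy` list: `config`, `truth` (list of `ahp_latent`),
#'   `matrices` (list per responder of named lists node -> `ahp_judgment`),
#'   `responses` (data frame, or NULL when `quantize = FALSE`).
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "ahp_simconfig"))
  h <- cfg$hierarchy
  nodes <- comparison_nodes(h)
  node_ids <- names(nodes)
  schedules <- build_schedules(h)

  truth <- lapply(seq_len(cfg$n_responders), function(i)
    sample_latent_profile(cfg, i))
  names(truth) <- vapply(truth, `[[`, character(1), "responder_id")

  matrices <- lapply(seq_len(cfg$n_responders), function(i) {
    prof <- truth[[i]]
    ms <- lapply(seq_along(node_ids), function(k) {
      nid <- node_ids[k]
      w <- if (nid == h$goal) prof$category_weights
           else prof$local_weights[[nid]]
      judgments_from_profile(w, sigma = cfg$sigma, quantize = cfg$quantize,
                             scale = cfg$scale,
                             seed = derive_seed(cfg$seed, i, k),
                             node_id = nid)
    })
    stats::setNames(ms, node_ids)
  })
  names(matrices) <- names(truth)

  responses <- NULL
  if (cfg$quantize) {
    rows <- list()
    for (rid in names(matrices)) for (nid in node_ids) {
      sch <- schedules[[nid]]
      A <- matrices[[rid]][[nid]]
      rows[[length(rows) + 1L]] <- data.frame(
        responder_id = rid, node_id = nid,
        left_id = sch$left_id, right_id = sch$right_id,
        grade = value_to_grade(
          A[cbind(sch$left_id, sch$right_id)], cfg$scale),
        stringsAsFactors = FALSE)
    }
    responses <- do.call(rbind, rows)
  }
  structure(list(config = cfg, truth = truth, matrices = matrices,
                 responses = responses),
            class = "ahp_simstudy")
}

#' Export a simulated study to disk
#'
#' Writes the response table in the standard CSV layout plus a `truth.json`
#' sidecar holding the latent profiles and simulation settings, so recovery
#' can be scored by an independent run.
#'
#' @param study an `ahp_simstudy` with `quantize = TRUE`.
#' @param dir output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
export_simulated_study <- function(study, dir) {
  stopifnot(inherits(study, "ahp_simstudy"))
  if (is.null(study$responses))
    stop("only quantized studies have a grade-level response table to export",
         call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  resp_path <- file.path(dir, "responses.csv")
  utils::write.csv(study$responses, resp_path, row.names = FALSE)
  truth <- lapply(study$truth, function(t) list(
    responder_id = t$responder_id,
    category_weights = as.list(t$category_weights),
    local_weights = lapply(t$local_weights, as.list),
    global_weights = as.list(t$global_weights)))
  cfg <- study$config
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(config = list(n_responders = cfg$n_responders,
                       concentration = cfg$concentration,
                       sigma = cfg$sigma, quantize = cfg$quantize,
                       seed = cfg$seed),
         truth = truth),
    truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(responses = resp_path, truth = truth_path))
}

#' Score recovery of latent priorities
#'
#' Compares pipeline-recovered global weights against the latent truth,
#' per responder: L1 distance between the weight vectors, Spearman rho of
#' the induced rankings, and the size of the top-k overlap.
#'
#' @param truth list of `ahp_latent` (e.g. `study$truth`).
#' @param recovered list of `ahp_global` with matching responder ids.
#' @param k top-k cutoff for the overlap metric (default 5).
#' @return Data frame with columns `responder_id`, `L1`, `rho`,
#'   `top_k_overlap`.
#' @export
recovery_report <- function(truth, recovered, k = 5L) {
  rec_ids <- vapply(recovered, `[[`, character(1), "responder_id")
  names(recovered) <- rec_ids
  tru_ids <- vapply(truth, `[[`, character(1), "responder_id")
  if (!setequal(tru_ids, rec_ids))
    stop("responder ids differ between truth and recovered sets", call. = FALSE)
  rows <- lapply(tru_ids, function(rid) {
    tg <- truth[[match(rid, tru_ids)]]$global_weights
    rg <- recovered[[rid]]$global_weights[names(tg)]
    kk <- min(k, length(tg))
    top_t <- rank_needs(tg, kk)$need_id
    top_r <- rank_needs(rg, kk)$need_id
    data.frame(responder_id = rid,
               L1 = sum(abs(tg - rg)),
               # a recovered profile with all needs tied has no ranking
               rho = tryCatch(spearman_rho(tg, rg),
                              error = function(e) NA_real_),
               top_k_overlap = length(intersect(top_t, top_r)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
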