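#' Run a full elicitation study
#'
#' End-to-end orchestration: per responder and per comparison node, build
#' the judgment matrix from the response table, compute principal-eigenvector
#' priorities and consistency, aggregate local weights into global need
#' weights, and compute responder-by-responder concordance at both the
#' category level and the need (global-weight) level.
#'
#' Responders with any node above the CR threshold fail the consistency
#' gate: they are reported and flagged for re-elicitation, and excluded from
#' the concordance matrices unless `include_inconsistent = TRUE`.
#'
#' @param hierarchy an `ahp_hierarchy` (or path to a config file).
#' @param responses response table with columns `responder_id`, `node_id`,
#'   `left_id`, `right_id`, `grade` (or path to such a CSV); alternatively a
#'   named list per responder of named lists node id -> judgment matrix,
#'   as produced by [simulate_study()].
#' @param scale an `ahp_scale` used to convert grades.
#' @param cr_threshold consistency gate (default 0.1; use 0.2 for the
#'   relaxed regime).
#' @param include_inconsistent include gate-failing responders in the
#'   concordance matrices.
#' @param alpha significance level for concordance masks.
#' @return An `ahp_study_report` list: `hierarchy`, `priorities` (per
#'   responder, per node), `global` (list of `ahp_global`), `consistency`
#'   (data frame responder x node), `gate` (data frame responder_id,
#'   pass, action), `concordance_category`, `concordance_need` (or NULL if
#'   fewer than 2 gated responders), `advisories`, `meta`.
#' @export
run_study <- function(hierarchy, responses, scale = adapted_scale(),
                      cr_threshold = 0.1, include_inconsistent = FALSE,
                      alpha = 0.05) {
  if (is.character(hierarchy)) hierarchy <- load_hierarchy(hierarchy)
  stopifnot(inherits(hierarchy, "ahp_hierarchy"))
  h <- hierarchy
  nodes <- comparison_nodes(h)
  schedules <- build_schedules(h)

  if (is.character(responses))
    responses <- utils::read.csv(responses, stringsAsFactors = FALSE)

  if (is.data.frame(responses)) {
    need_cols <- c("responder_id", "node_id", "left_id", "right_id", "grade")
    if (!all(need_cols %in% names(responses)))
      stop("response table must have columns ",
           paste(need_cols, collapse = ", "), call. = FALSE)
    matrices <- lapply(split(responses, responses$responder_id), function(rr) {
      ms <- lapply(names(nodes), function(nid) {
        rows <- rr[rr$node_id == nid, , drop = FALSE]
        if (nrow(rows) == 0L)
          stop("responder '", rr$responder_id[1],
               "' has no answers for node '", nid, "'", call. = FALSE)
        resp <- ingest_responses(schedules[[nid]], rows, scale)
        build_judgment_matrix(resp, nodes[[nid]], nid)
      })
      stats::setNames(ms, names(nodes))
    })
  } else {
    matrices <- responses
  }
  rids <- names(matrices)

  priorities <- lapply(matrices, function(ms) lapply(ms, principal_priorities))
  cons_rows <- list()
  for (rid in rids) for (nid in names(nodes)) {
    cr <- consistency_report(priorities[[rid]][[nid]],
                             primary_threshold = cr_threshold)
    cons_rows[[length(cons_rows) + 1L]] <- data.frame(
      responder_id = rid, node_id = nid, n = cr$n,
      lambda_max = cr$lambda_max, CI = cr$CI, RI = cr$RI, CR = cr$CR,
      pass = cr$CR <= cr_threshold, stringsAsFactors = FALSE)
  }
  consistency <- do.call(rbind, cons_rows)

  gate <- do.call(rbind, lapply(rids, function(rid) {
    ok <- all(consistency$pass[consistency$responder_id == rid])
    data.frame(responder_id = rid, pass = ok,
               action = if (ok) "accepted"
                        else "re-elicitation required (CR above threshold)",
               stringsAsFactors = FALSE)
  }))

  global <- lapply(rids, function(rid) {
    global_weights(priorities[[rid]][[h$goal]],
                   priorities[[rid]][h$categories], responder_id = rid)
  })
  names(global) <- rids

  use <- if (include_inconsistent) rids else gate$responder_id[gate$pass]
  conc_cat <- conc_need <- NULL
  if (length(use) >= 2L) {
    cat_profiles <- lapply(global[use], function(g)
      g$category_weights[h$categories])
    need_profiles <- lapply(global[use], function(g)
      g$global_weights[h$needs])
    conc_cat <- concordance_matrix(cat_profiles, alpha = alpha)
    conc_need <- concordance_matrix(need_profiles, alpha = alpha)
  }

  structure(list(
    hierarchy = h, priorities = priorities, global = global,
    consistency = consistency, gate = gate,
    concordance_category = conc_cat, concordance_need = conc_need,
    advisories = validate_advisories(h),
    meta = list(cr_threshold = cr_threshold,
                include_inconsistent = include_inconsistent,
                alpha = alpha, n_responders = length(rids),
                timestamp = format(Sys.time(), tz = "UTC"))),
    class = "ahp_study_report")
}

#' Flat weight table from a study report
#'
#' @param report an `ahp_study_report`.
#' @return Data frame with columns `responder_id`, `category_id`, `need_id`,
#'   `LW`, `CW`, `GW` at full precision.
#' @export
weight_table <- function(report) {
  h <- report$hierarchy
  rows <- lapply(report$global, function(g) {
    data.frame(responder_id = g$responder_id,
               category_id = unname(g$category_of[h$needs]),
               need_id = h$needs,
               LW = unname(g$local_weights[h$needs]),
               CW = unname(g$category_weights[g$category_of[h$needs]]),
               GW = unname(g$global_weights[h$needs]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export study reports to CSV files plus a manifest
#'
#' Writes `weights.csv` (full precision), `weights_display.csv` (two-decimal
#' GW with parenthesised LW, the conventional presentation), the
#' `consistency.csv` node-by-responder CR table, the concordance matrices
#' (`category_rho.csv`, `category_pvalues.csv`, `category_significant.csv`
#' and the `need_*` counterparts) when at least two responders passed the
#' gate, `advisories.csv` when any advisory fired, and a `manifest.json`
#' listing every written file with its MD5 checksum. Re-exporting an
#' identical report produces byte-identical files.
#'
#' @param report an `ahp_study_report`.
#' @param dir output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
export_reports <- function(report, dir) {
  stopifnot(inherits(report, "ahp_study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  put <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    written[[name]] <<- p
  }

  wt <- weight_table(report)
  put(wt, "weights.csv")
  disp <- wt
  disp$GW <- sprintf("%.2f", wt$GW)
  disp$LW <- sprintf("(%.2f)", wt$LW)
  disp$CW <- sprintf("%.2f", wt$CW)
  put(disp, "weights_display.csv")

  cons <- report$consistency
  cr_wide <- stats::reshape(
    cons[, c("responder_id", "node_id", "CR")],
    idvar = "node_id", timevar = "responder_id", direction = "wide")
  names(cr_wide) <- sub("^CR\\.", "", names(cr_wide))
  put(cr_wide, "consistency.csv")
  put(report$gate, "gate.csv")

  notes <- list()
  write_conc <- function(conc, prefix) {
    if (is.null(conc)) {
      notes[[length(notes) + 1L]] <<- paste0(
        prefix, " concordance omitted: fewer than 2 responders passed the gate")
      return(invisible(NULL))
    }
    as_df <- function(m) data.frame(responder_id = rownames(m), m,
                                    check.names = FALSE,
                                    stringsAsFactors = FALSE)
    put(as_df(conc$rho), paste0(prefix, "_rho.csv"))
    put(as_df(conc$p), paste0(prefix, "_pvalues.csv"))
    put(as_df(conc$significant), paste0(prefix, "_significant.csv"))
  }
  write_conc(report$concordance_category, "category")
  write_conc(report$concordance_need, "need")

  if (nrow(report$advisories) > 0L) put(report$advisories, "advisories.csv")

  manifest <- list(
    files = lapply(names(written), function(nm) list(
      name = nm, md5 = unname(tools::md5sum(written[[nm]])))),
    notes = notes,
    cr_threshold = report$meta$cr_threshold,
    alpha = report$meta$alpha,
    n_responders = report$meta$n_responders)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  written[["manifest.json"]] <- mp
  invisible(unlist(written))
}

#' Load the packaged CT-scanner study fixture
#'
#' The published study elicited needs for a new CT scanner from five senior
#' clinicians (radiology, ear surgery, elective neurology, emergency
#' neurology, emergency). The fixture holds the printed two-decimal tables:
#' category weights, local and global need weights, per-questionnaire
#' consistency ratios, and the printed concordance values. Raw judgment
#' matrices were not published, so the consistency ratios are display data,
#' not reproducible quantities.
#'
#' Integrity is checked on load: each responder's category weights must sum
#' to 1 within 0.01 and each category's local-weight triple to 1 within
#' 0.02 (printed-rounding slack).
#'
#' @return An `ahp_study_fixture` list: `hierarchy`, `responders`,
#'   `category_weights` (category x responder matrix), `need_weights`
#'   (long data frame responder/category/need with `GW`, `LW`),
#'   `consistency` (long data frame), `printed_rho_category`,
#'   `printed_rho_need` (data frames of the printed concordance cells).
#' @export
load_study_fixture <- function() {
  ext <- function(f) system.file("extdata", f, package = "ahpelicit",
                                 mustWork = TRUE)
  h <- load_hierarchy(ext("ct_hierarchy.yaml"))
  cw_long <- utils::read.csv(ext("study_category_weights.csv"),
                             stringsAsFactors = FALSE)
  nw <- utils::read.csv(ext("study_need_weights.csv"),
                        stringsAsFactors = FALSE)
  cons <- utils::read.csv(ext("study_consistency.csv"),
                          stringsAsFactors = FALSE)
  rho_cat <- utils::read.csv(ext("study_printed_rho_category.csv"),
                             stringsAsFactors = FALSE)
  rho_need <- utils::read.csv(ext("study_printed_rho_need.csv"),
                              stringsAsFactors = FALSE)

  responders <- unique(cw_long$responder_id)
  cw <- matrix(NA_real_, length(h$categories), length(responders),
               dimnames = list(h$categories, responders))
  cw[cbind(cw_long$category_id, cw_long$responder_id)] <- cw_long$CW

  csums <- colSums(cw)
  if (any(abs(csums - 1) > 0.011))
    stop("fixture integrity: category weights of ",
         paste(responders[abs(csums - 1) > 0.011], collapse = ", "),
         " do not sum to 1 within printed rounding", call. = FALSE)
  for (rid in responders) for (cid in h$categories) {
    s <- sum(nw$LW[nw$responder_id == rid & nw$category_id == cid])
    if (abs(s - 1) > 0.021)
      stop("fixture integrity: local weights of ", rid, "/", cid,
           " sum to ", s, call. = FALSE)
  }

  structure(list(hierarchy = h, responders = responders,
                 category_weights = cw, need_weights = nw,
                 consistency = cons,
                 printed_rho_category = rho_cat,
                 printed_rho_need = rho_need),
            class = "ahp_study_fixture")
}

#' Reproduce the published concordance and aggregation results
#'
#' Three checks against the printed tables, all computed from the fixture's
#' two-decimal weights: (a) the two-level aggregation identity
#' |GW - LW x CW| <= 0.01 over all 60 (responder, need) cells; (b) the
#' need-level Spearman matrix (mid-rank ties) over the global-weight columns
#' matches every printed value within `rho_tol` before rounding; (c) the
#' category-level matrix reproduces the printed rho = 1 cells exactly.
#' Consistency ratios are carried for display only: without the raw judgment
#' matrices they cannot be recomputed.
#'
#' @param fixture an `ahp_study_fixture`; default loads the packaged one.
#' @param rho_tol tolerance on printed concordance values (default 0.005).
#' @return An `ahp_repro_report` list with per-check data frames
#'   (`aggregation`, `need_rho`, `category_rho`), the full computed
#'   concordance objects, per-responder top-5 rankings, and an overall
#'   `pass` flag.
#' @export
reproduce_study_tables <- function(fixture = load_study_fixture(),
                                   rho_tol = 0.005) {
  h <- fixture$hierarchy
  nw <- fixture$need_weights
  cw <- fixture$category_weights

  # (a) aggregation identity on printed values
  agg <- nw
  agg$CW <- cw[cbind(agg$category_id, agg$responder_id)]
  agg$product <- agg$LW * agg$CW
  agg$abs_err <- abs(agg$GW - agg$product)
  agg$ok <- agg$abs_err <= 0.01 + 1e-12

  # GW profiles per responder, hierarchy order
  profiles <- lapply(fixture$responders, function(rid) {
    sub <- nw[nw$responder_id == rid, ]
    stats::setNames(sub$GW[match(h$needs, sub$need_id)], h$needs)
  })
  names(profiles) <- fixture$responders
  conc_need <- concordance_matrix(profiles)

  cat_profiles <- lapply(fixture$responders, function(rid)
    stats::setNames(cw[h$categories, rid], h$categories))
  names(cat_profiles) <- fixture$responders
  conc_cat <- concordance_matrix(cat_profiles)

  # (b) printed need-level rho cells
  need_rho <- fixture$printed_rho_need
  need_rho$computed <- conc_need$rho[cbind(need_rho$responder_a,
                                           need_rho$responder_b)]
  need_rho$abs_err <- abs(need_rho$computed - need_rho$rho)
  need_rho$ok <- need_rho$abs_err <= rho_tol + 1e-12

  # (c) printed category-level rho = 1 cells, exact
  cat_rho <- fixture$printed_rho_category
  cat_rho$computed <- conc_cat$rho[cbind(cat_rho$responder_a,
                                         cat_rho$responder_b)]
  cat_rho$ok <- ifelse(cat_rho$rho == 1, cat_rho$computed == 1,
                       abs(cat_rho$computed - cat_rho$rho) <= rho_tol)

  top5 <- lapply(profiles, rank_needs, k = 5L)

  structure(list(aggregation = agg, need_rho = need_rho,
                 category_rho = cat_rho,
                 concordance_need = conc_need,
                 concordance_category = conc_cat,
                 top5 = top5,
                 pass = all(agg$ok) && all(need_rho$ok) && all(cat_rho$ok)),
            class = "ahp_repro_report")
}

#' @export
print.ahp_repro_report <- function(x, ...) {
  cat("Reproduction of the published study tables\n")
  cat(sprintf("  aggregation identity (60 cells, tol 0.01): %s (max err %.4f)\n",
              if (all(x$aggregation$ok)) "ok" else "FAIL",
              max(x$aggregation$abs_err)))
  cat(sprintf("  need-level rho (%d printed cells): %s (max err %.4f)\n",
              nrow(x$need_rho),
              if (all(x$need_rho$ok)) "ok" else "FAIL",
              max(x$need_rho$abs_err)))
  cat(sprintf("  category-level rho (%d printed cells): %s\n",
              nrow(x$category_rho),
              if (all(x$category_rho$ok)) "ok" else "FAIL"))
  invisible(x)
}
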