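#' Goal/category/need hierarchies
#'
#' An AHP needs hierarchy is a fixed three-level tree: one goal node, whose
#' children are categories, whose children are the need leaves. All priority
#' weights in the pipeline hang on this structure: one judgment matrix is
#' elicited per category (comparing its needs) plus one at the goal
#' (comparing the categories), and global need weights are the product of the
#' two levels. Deeper trees are rejected: the two-level aggregation
#' `GW = LW * CW` is only defined for this shape.
#'
#' @name hierarchy
NULL

#' Construct a hierarchy from its parts
#'
#' Usually called via [load_hierarchy()]; exposed so hierarchies can be built
#' programmatically (e.g. by the synthetic-responder simulator or in tests).
#'
#' @param goal_label human-readable label of the goal node.
#' @param categories ordered list; each element a list with `id`, `label`,
#'   and `children` — itself an ordered list of `list(id=, label=)` leaves.
#' @param goal_id id token for the goal node (default `"goal"`).
#' @return An object of class `ahp_hierarchy` with components
#'   `goal` (id), `labels` (named character, id -> label),
#'   `categories` (ordered character vector of category ids),
#'   `needs` (ordered character vector of leaf ids, category-major order),
#'   `children` (named list, category id -> ordered leaf ids),
#'   `parent` (named character, need id -> category id).
#' @export
new_hierarchy <- function(goal_label, categories, goal_id = "goal") {
  if (!is.character(goal_label) || length(goal_label) != 1L)
    stop("goal_label must be a single string", call. = FALSE)
  if (length(categories) < 1L)
    stop("hierarchy needs at least one category", call. = FALSE)

  cat_ids <- character(0)
  labels <- stats::setNames(goal_label, goal_id)
  children <- list()
  parent <- character(0)
  needs <- character(0)

  for (cat in categories) {
    if (is.null(cat$id) || is.null(cat$label))
      stop("every category needs an id and a label", call. = FALSE)
    kids <- cat$children
    if (length(kids) < 2L)
      stop("category '", cat$id, "' has fewer than 2 children; ",
           "a single-child category produces no pairwise comparisons",
           call. = FALSE)
    kid_ids <- vapply(kids, function(k) {
      if (is.null(k$id) || is.null(k$label))
        stop("every need under '", cat$id, "' requires an id and a label",
             call. = FALSE)
      if (!is.null(k$children) && length(k$children) > 0L)
        stop("need '", k$id, "' has children: hierarchies deeper than ",
             "goal/category/need are not supported", call. = FALSE)
      as.character(k$id)
    }, character(1))
    kid_labels <- vapply(kids, function(k) as.character(k$label), character(1))
    cat_ids <- c(cat_ids, as.character(cat$id))
    labels[as.character(cat$id)] <- as.character(cat$label)
    labels[kid_ids] <- kid_labels
    children[[as.character(cat$id)]] <- kid_ids
    parent[kid_ids] <- as.character(cat$id)
    needs <- c(needs, kid_ids)
  }

  all_ids <- c(goal_id, cat_ids, needs)
  dup <- all_ids[duplicated(all_ids)]
  if (length(dup) > 0L)
    stop("duplicate node id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)

  structure(
    list(goal = goal_id, labels = labels, categories = cat_ids,
         needs = needs, children = children, parent = parent),
    class = "ahp_hierarchy")
}

#' Load a hierarchy from a YAML or JSON config
#'
#' The document declares a `goal` label and an ordered `categories` list;
#' each category has `id`, `label` and an ordered `children` list of
#' `{id, label}` leaves. Document order is authoritative: questionnaire
#' schedules, weight tables and reports all follow it.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return An `ahp_hierarchy`; see [new_hierarchy()].
#' @examples
#' cfg <- system.file("extdata", "ct_hierarchy.yaml", package = "ahpelicit")
#' h <- load_hierarchy(cfg)
#' length(h$needs)  # 12
#' @export
load_hierarchy <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(doc$goal)) stop("config declares no goal", call. = FALSE)
  if (is.null(doc$categories)) stop("config declares no categories", call. = FALSE)
  new_hierarchy(goal_label = as.character(doc$goal),
                categories = doc$categories,
                goal_id = if (is.null(doc$goal_id)) "goal" else doc$goal_id)
}

#' Write a hierarchy back to YAML (canonical form)
#'
#' Round-trip companion of [load_hierarchy()]: `load(write(h))` reproduces
#' the identical ordered category and leaf ids.
#'
#' @param h an `ahp_hierarchy`.
#' @param path output file path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(h, path) {
  stopifnot(inherits(h, "ahp_hierarchy"))
  doc <- list(
    goal = unname(h$labels[h$goal]),
    goal_id = h$goal,
    categories = lapply(h$categories, function(cid) {
      list(id = cid, label = unname(h$labels[cid]),
           children = lapply(h$children[[cid]], function(nid) {
             list(id = nid, label = unname(h$labels[nid]))
           }))
    }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Comparison nodes of a hierarchy
#'
#' Every node at which pairwise comparisons are elicited: the goal (its
#' children are the categories) and each category (its children are needs).
#'
#' @param h an `ahp_hierarchy`.
#' @return Named list, node id -> ordered character vector of child ids.
#' @export
comparison_nodes <- function(h) {
  stopifnot(inherits(h, "ahp_hierarchy"))
  c(stats::setNames(list(h$categories), h$goal), h$children)
}

#' Advisory checks on hierarchy shape
#'
#' Flags nodes whose size works against reliable elicitation: more than four
#' elements under one node makes responders — especially those new to
#' pairwise comparison — noticeably less consistent. Breaches are advisories,
#' not errors: the hierarchy remains usable.
#'
#' @param h an `ahp_hierarchy`.
#' @param max_children advisory ceiling on children per node (default 4).
#' @return Data frame with columns `node_id`, `n_children`, `message`;
#'   zero rows when no node exceeds the ceiling.
#' @export
validate_advisories <- function(h, max_children = 4L) {
  stopifnot(inherits(h, "ahp_hierarchy"))
  nodes <- comparison_nodes(h)
  sizes <- lengths(nodes)
  bad <- sizes > max_children
  data.frame(
    node_id = names(nodes)[bad],
    n_children = unname(sizes[bad]),
    message = sprintf(
      "node '%s' has %d children; keeping nodes at %d or fewer elements improves responder consistency",
      names(nodes)[bad], unname(sizes[bad]), max_children),
    stringsAsFactors = FALSE)
}

#' @export
print.ahp_hierarchy <- function(x, ...) {
  cat("AHP hierarchy:", x$labels[x$goal], "\n")
  for (cid in x$categories) {
    cat("  [", cid, "] ", x$labels[cid], "\n", sep = "")
    for (nid in x$children[[cid]])
      cat("    - ", nid, ": ", x$labels[nid], "\n", sep = "")
  }
  invisible(x)
}
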