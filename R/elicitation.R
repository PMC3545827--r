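#' Verbal judgment scales
#'
#' A judgment scale maps ordered verbal grades to numeric importance ratios.
#' The default is the adapted five-anchor scale used in healthcare
#' elicitation with lay responders: equally important = 1, more important
#' = 3, much more important = 5, with reciprocals for the "less" side and
#' in-between grades for in-between judgments, giving the grid
#' {1/5, 1/4, 1/3, 1/2, 1, 2, 3, 4, 5}. The classic Saaty 1-9 scale is
#' available via `saaty_scale()`.
#'
#' Scales are symmetric by construction: `value(grade) * value(mirror)` is
#' exactly 1 because the "less" side is stored as `1 / value("more" side)`.
#'
#' @param values numeric values of the "more important" half, strictly
#'   increasing, starting above 1.
#' @param labels verbal labels of the "more important" half, same length,
#'   mildest first.
#' @param equal_label label of the neutral grade (value exactly 1).
#' @param less_prefix,more_prefix words substituted to build the mirrored
#'   "less important" labels from `labels`.
#' @return An object of class `ahp_scale`: data frame with columns `grade`
#'   (character) and `value` (numeric), ordered from strongest "less" to
#'   strongest "more".
#' @examples
#' s <- adapted_scale()
#' grade_to_value("much more important", s)  # 5
#' @export
judgment_scale <- function(values, labels, equal_label = "equally important",
                           less_prefix = "less", more_prefix = "more") {
  stopifnot(length(values) == length(labels), all(values > 1),
            !is.unsorted(values, strictly = TRUE))
  less_labels <- vapply(labels, function(l)
    sub(paste0("\\b", more_prefix, "\\b"), less_prefix, l), character(1))
  grades <- c(rev(less_labels), equal_label, labels)
  vals <- c(rev(1 / values), 1, values)
  if (anyDuplicated(grades))
    stop("grade labels are not unique", call. = FALSE)
  structure(data.frame(grade = grades, value = vals,
                       stringsAsFactors = FALSE),
            class = c("ahp_scale", "data.frame"))
}

#' @rdname judgment_scale
#' @export
adapted_scale <- function() {
  judgment_scale(
    values = c(2, 3, 4, 5),
    labels = c("slightly more important", "more important",
               "moderately more important", "much more important"))
}

#' @rdname judgment_scale
#' @export
saaty_scale <- function() {
  judgment_scale(
    values = 2:9,
    labels = c("2", "3", "4", "5", "6", "7", "8", "9"),
    equal_label = "1", less_prefix = "/", more_prefix = "")
}

#' Convert a verbal grade to its numeric ratio
#'
#' @param grade grade label (matched case-insensitively).
#' @param scale an `ahp_scale`; default [adapted_scale()].
#' @return The numeric ratio for the grade.
#' @export
grade_to_value <- function(grade, scale = adapted_scale()) {
  i <- match(tolower(trimws(grade)), tolower(scale$grade))
  if (anyNA(i))
    stop("unknown grade label(s): ",
         paste(grade[is.na(i)], collapse = ", "),
         "; scale vocabulary is: ", paste(scale$grade, collapse = " | "),
         call. = FALSE)
  scale$value[i]
}

#' Convert a ratio to the nearest verbal grade
#'
#' Snaps in log space so that a value and its reciprocal always map to
#' mirrored grades.
#'
#' @param value positive numeric ratio(s).
#' @param scale an `ahp_scale`.
#' @return Character vector of grade labels.
#' @export
value_to_grade <- function(value, scale = adapted_scale()) {
  stopifnot(all(value > 0))
  idx <- vapply(log(value), function(lv)
    which.min(abs(lv - log(scale$value))), integer(1))
  scale$grade[idx]
}

#' Mirror grade (reciprocal judgment)
#'
#' @param grade grade label(s).
#' @param scale an `ahp_scale`.
#' @return The label whose value is the exact reciprocal.
#' @export
mirror_grade <- function(grade, scale = adapted_scale()) {
  i <- match(tolower(trimws(grade)), tolower(scale$grade))
  if (anyNA(i)) stop("unknown grade label(s): ",
                     paste(grade[is.na(i)], collapse = ", "), call. = FALSE)
  scale$grade[nrow(scale) + 1L - i]
}

#' Build a balanced pairwise-comparison schedule for one node
#'
#' Emits every unordered pair of the node's children exactly once —
#' n(n-1)/2 questions — ordered and oriented so that each element appears on
#' the left and the right of the questionnaire as evenly as possible
#' (imbalance at most 1), which counteracts the left/top position bias of
#' responders reading left-to-right. For three children the schedule is the
#' cyclic triple (A,B), (B,C), (C,A): the third question is the redundant
#' transitivity probe implied by the first two.
#'
#' For n > 3, pairs are taken in lexicographic order of child positions and
#' each pair is oriented greedily, putting on the left the element with the
#' currently lower left-minus-right count (ties keep the earlier element
#' left). The schedule is deterministic: identical child order gives an
#' identical schedule.
#'
#' @param children ordered character vector of child ids (length >= 2).
#' @param node_id id of the node being compared (for labelling).
#' @return An object of class `ahp_schedule`: data frame with columns
#'   `node_id`, `left_id`, `right_id`; attribute `balance` holds the final
#'   left-minus-right count per element.
#' @export
build_schedule <- function(children, node_id = "node") {
  children <- as.character(children)
  n <- length(children)
  if (n < 2L)
    stop("node '", node_id, "' has fewer than 2 children; nothing to compare",
         call. = FALSE)
  if (anyDuplicated(children))
    stop("duplicate child ids in node '", node_id, "'", call. = FALSE)

  if (n == 3L) {
    pairs <- cbind(c(1L, 2L, 3L), c(2L, 3L, 1L))
  } else {
    idx <- utils::combn(n, 2L)
    d <- integer(n)  # left minus right appearances so far
    pairs <- matrix(0L, ncol(idx), 2L)
    for (r in seq_len(ncol(idx))) {
      a <- idx[1L, r]; b <- idx[2L, r]
      if (d[a] <= d[b]) {
        pairs[r, ] <- c(a, b); d[a] <- d[a] + 1L; d[b] <- d[b] - 1L
      } else {
        pairs[r, ] <- c(b, a); d[b] <- d[b] + 1L; d[a] <- d[a] - 1L
      }
    }
  }
  out <- data.frame(node_id = node_id,
                    left_id = children[pairs[, 1L]],
                    right_id = children[pairs[, 2L]],
                    stringsAsFactors = FALSE)
  left_n <- table(factor(out$left_id, levels = children))
  right_n <- table(factor(out$right_id, levels = children))
  attr(out, "balance") <- stats::setNames(as.integer(left_n - right_n), children)
  class(out) <- c("ahp_schedule", "data.frame")
  out
}

#' Schedules for every comparison node of a hierarchy
#'
#' @param h an `ahp_hierarchy`.
#' @return Named list of `ahp_schedule`, one per node (goal first).
#' @export
build_schedules <- function(h) {
  nodes <- comparison_nodes(h)
  stats::setNames(
    lapply(names(nodes), function(nid) build_schedule(nodes[[nid]], nid)),
    names(nodes))
}

#' Render a questionnaire from a schedule
#'
#' One row per question, with the standard elicitation stem. The default
#' stem matches a CT-scanner purchasing study; pass your own for other
#' devices.
#'
#' @param schedule an `ahp_schedule` (or the list from [build_schedules()]).
#' @param h an `ahp_hierarchy`, used to substitute human-readable labels.
#' @param stem question template with placeholders `{i}` and `{j}`.
#' @return Data frame with columns `node_id`, `left_id`, `right_id`,
#'   `question`.
#' @export
render_questionnaire <- function(schedule, h,
    stem = paste0("In the selection of a new CT scanner, according to your ",
                  "experience, how important do you consider {i} compared ",
                  "to {j}?")) {
  if (!inherits(schedule, "data.frame")) schedule <- do.call(rbind, schedule)
  q <- vapply(seq_len(nrow(schedule)), function(r) {
    li <- h$labels[schedule$left_id[r]]
    rj <- h$labels[schedule$right_id[r]]
    gsub("\\{j\\}", rj, gsub("\\{i\\}", li, stem))
  }, character(1))
  data.frame(node_id = schedule$node_id, left_id = schedule$left_id,
             right_id = schedule$right_id, question = q,
             stringsAsFactors = FALSE)
}

#' Ingest raw response rows against a schedule
#'
#' Accepts answers in either orientation: a row answering (B, A) when the
#' schedule asks (A, B) is stored under the scheduled orientation with the
#' mirrored grade. Every scheduled pair must be answered exactly once;
#' duplicate answers for one pair are an error (re-elicitation, not
#' averaging, is the remedy for contradictory answers).
#'
#' @param schedule an `ahp_schedule` for one node.
#' @param rows data frame with columns `left_id`, `right_id`, `grade`
#'   (extra columns ignored).
#' @param scale an `ahp_scale`.
#' @return An `ahp_responses` data frame: columns `node_id`, `left_id`,
#'   `right_id`, `grade`, `value`, keyed in schedule orientation and order.
#' @export
ingest_responses <- function(schedule, rows, scale = adapted_scale()) {
  stopifnot(is.data.frame(rows),
            all(c("left_id", "right_id", "grade") %in% names(rows)))
  key <- function(a, b) paste(a, b, sep = "\r")
  sched_keys <- key(schedule$left_id, schedule$right_id)

  grade <- rep(NA_character_, nrow(schedule))
  for (r in seq_len(nrow(rows))) {
    g <- as.character(rows$grade[r])
    grade_to_value(g, scale)  # validates the label
    i <- match(key(rows$left_id[r], rows$right_id[r]), sched_keys)
    if (is.na(i)) {
      i <- match(key(rows$right_id[r], rows$left_id[r]), sched_keys)
      if (is.na(i))
        stop("response (", rows$left_id[r], ", ", rows$right_id[r],
             ") matches no scheduled pair of node '",
             schedule$node_id[1], "'", call. = FALSE)
      g <- mirror_grade(g, scale)
    }
    if (!is.na(grade[i]) && tolower(grade[i]) != tolower(g))
      stop("contradictory duplicate answers for pair (",
           schedule$left_id[i], ", ", schedule$right_id[i],
           "); the responder should answer the questionnaire again",
           call. = FALSE)
    grade[i] <- g
  }
  missing <- is.na(grade)
  if (any(missing))
    stop("missing answer(s) for pair(s): ",
         paste(sprintf("(%s, %s)", schedule$left_id[missing],
                       schedule$right_id[missing]), collapse = ", "),
         call. = FALSE)
  out <- data.frame(node_id = schedule$node_id, left_id = schedule$left_id,
                    right_id = schedule$right_id, grade = grade,
                    value = grade_to_value(grade, scale),
                    stringsAsFactors = FALSE)
  class(out) <- c("ahp_responses", "data.frame")
  out
}

#' Build a reciprocal judgment matrix from a complete response set
#'
#' Entry a_ij > 1 means element i was judged more important than element j.
#' The lower triangle is set to exact reciprocals of the upper answers (one
#' float per pair, never two independently converted values), so
#' `A * t(A) == 1` holds exactly.
#'
#' @param responses an `ahp_responses` for one node (see
#'   [ingest_responses()]), or any data frame with `left_id`, `right_id`
#'   and `value` covering each unordered pair once.
#' @param children ordered child ids defining row/column order.
#' @param node_id node id for labelling.
#' @return An `ahp_judgment` matrix: positive reciprocal numeric matrix with
#'   dimnames `children` and attribute `node_id`.
#' @export
build_judgment_matrix <- function(responses, children, node_id = "node") {
  children <- as.character(children)
  n <- length(children)
  A <- diag(1, n)
  dimnames(A) <- list(children, children)
  seen <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(responses))) {
    i <- match(responses$left_id[r], children)
    j <- match(responses$right_id[r], children)
    if (is.na(i) || is.na(j))
      stop("response references unknown element(s) for node '", node_id, "'",
           call. = FALSE)
    v <- responses$value[r]
    A[i, j] <- v
    A[j, i] <- 1 / v
    seen[i, j] <- seen[j, i] <- TRUE
  }
  need <- upper.tri(seen) & !seen
  if (any(need)) {
    idx <- which(need, arr.ind = TRUE)
    stop("incomplete responses for node '", node_id, "': missing pair(s) ",
         paste(sprintf("(%s, %s)", children[idx[, 1]], children[idx[, 2]]),
               collapse = ", "), call. = FALSE)
  }
  structure(A, node_id = node_id, class = c("ahp_judgment", "matrix", "array"))
}

#' Validate judgment-matrix structure
#'
#' @param A numeric square matrix.
#' @param tol tolerance on reciprocity.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
check_judgment_matrix <- function(A, tol = 1e-12) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("judgment matrix must be square", call. = FALSE)
  if (any(A <= 0)) stop("judgment matrix entries must be positive", call. = FALSE)
  if (any(abs(diag(A) - 1) > tol))
    stop("judgment matrix diagonal must be 1", call. = FALSE)
  if (any(abs(A * t(A) - 1) > tol))
    stop("judgment matrix must be reciprocal: a_ji = 1/a_ij", call. = FALSE)
  invisible(TRUE)
}
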