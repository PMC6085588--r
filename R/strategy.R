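#' Per-class route click counts
#'
#' Attributes every selection toggle to the modal latent class of the step
#' in which it occurred. A step's toggles are the routes whose selection
#' state differs from the student's previous step; a student's first step
#' contributes its selected routes.
#'
#' @param data A \code{"process_data"} object.
#' @param modal_class Integer vector of modal classes per step (e.g. from a
#'   fitted model).
#' @param G Number of classes (default \code{max(modal_class)}).
#' @return A G x I matrix of click counts (classes in rows, routes in
#'   columns). Its grand total equals the dataset's total toggle count.
#' @export
class_click_counts <- function(data, modal_class, G = max(modal_class)) {
  sel <- data$selected
  sid <- data$steps$student_id
  first <- !duplicated(sid)
  toggles <- sel
  if (nrow(sel) > 1L) {
    prev <- rbind(sel[1L, ], sel[-nrow(sel), , drop = FALSE])
    d <- abs(sel - prev)
    toggles[!first, ] <- d[!first, , drop = FALSE]
  }
  counts <- matrix(0L, G, ncol(sel),
                   dimnames = list(paste0("class", seq_len(G)),
                                   colnames(sel)))
  for (g in seq_len(G)) {
    rows <- modal_class == g
    if (any(rows)) counts[g, ] <- colSums(toggles[rows, , drop = FALSE])
  }
  counts
}

#' Characteristic route signature of a latent class
#'
#' Selects the routes a class clicked more than others (above the class
#' mean click count, or a fixed top-k), orders them by descending clicks,
#' and prunes retained routes that share no endpoint with any other
#' retained route -- an isolated high-click route is noise relative to the
#' path-building strategy the class represents. A single retained route is
#' kept as the unique start route.
#'
#' @param counts Named numeric vector of click counts over routes for one
#'   class.
#' @param spec A [task_spec()] (supplies the map adjacency).
#' @param rule \code{"above_mean"} (default) or \code{"top_k"}.
#' @param k Number of routes when \code{rule = "top_k"}.
#' @param class_id Optional class label carried into the result.
#' @return An object of class \code{"class_signature"}: list with
#'   \code{class_id}, \code{click_counts}, \code{ranked_routes} (retained
#'   routes by descending clicks, before pruning) and \code{signature}
#'   (after pruning).
#' @export
class_signature <- function(counts, spec, rule = c("above_mean", "top_k"),
                            k = NULL, class_id = NA) {
  rule <- match.arg(rule)
  counts <- counts[spec$routes]
  if (all(counts == 0) || !length(counts)) {
    return(structure(list(class_id = class_id, click_counts = counts,
                          ranked_routes = character(),
                          signature = character()),
                     class = "class_signature"))
  }
  retained <- if (rule == "above_mean") names(counts)[counts > mean(counts)]
              else names(sort(counts, decreasing = TRUE))[seq_len(min(k, length(counts)))]
  ranked <- retained[order(-counts[retained])]
  adj <- route_adjacency(spec)
  keep <- if (length(ranked) == 1L) TRUE else
    vapply(ranked, function(r) any(adj[r, ranked]), TRUE)
  structure(list(class_id = class_id, click_counts = counts,
                 ranked_routes = ranked, signature = ranked[keep]),
            class = "class_signature")
}

#' @export
print.class_signature <- function(x, ...) {
  cat("Class", x$class_id, "signature:",
      if (length(x$signature)) paste(x$signature, collapse = "-") else "(empty)",
      "\n")
  pruned <- setdiff(x$ranked_routes, x$signature)
  if (length(pruned))
    cat("  pruned (no shared endpoint):", paste(pruned, collapse = ", "), "\n")
  invisible(x)
}

#' Strategy episodes and shift count of one modal-class sequence
#'
#' A student is considered to have employed a class's strategy when its
#' modal class occurs three or more times consecutively (the run-length
#' threshold). The qualifying runs, in order, form the student's episode
#' sequence; adjacent episodes with the same label separated only by
#' sub-threshold noise collapse into one (configurable). A student with no
#' qualifying run has an empty episode sequence ("class 0": no stable
#' strategy) and a shift count of 0; otherwise the shift count is the
#' number of episodes.
#'
#' @param modal_sequence Integer vector of per-step modal classes for one
#'   student, in step order.
#' @param threshold Minimum run length for an episode (default 3).
#' @param collapse_gaps Collapse adjacent identical episode labels
#'   (default \code{TRUE}).
#' @return List with \code{episodes} (integer vector, possibly empty) and
#'   \code{n_shifts}.
#' @export
strategy_trace <- function(modal_sequence, threshold = 3L,
                           collapse_gaps = TRUE) {
  stopifnot(length(modal_sequence) >= 1L)
  r <- rle(as.integer(modal_sequence))
  ep <- r$values[r$lengths >= threshold]
  if (collapse_gaps && length(ep) > 1L)
    ep <- ep[c(TRUE, ep[-1L] != ep[-length(ep)])]
  list(episodes = ep, n_shifts = length(ep))
}

#' Strategy traces for every student of a fitted model
#'
#' @param fit A fitted \code{"mmixirt"} model.
#' @param threshold,collapse_gaps Passed to [strategy_trace()].
#' @return A data frame with \code{student_id}, \code{episodes} (label
#'   string such as \code{"2>1"}, empty when no qualifying run) and
#'   \code{n_shifts}; the raw episode vectors are in attribute
#'   \code{"episode_list"}.
#' @export
strategy_traces <- function(fit, threshold = 3L, collapse_gaps = TRUE) {
  sid <- fit$data$steps$student_id
  traces <- lapply(fit$data$students, function(s)
    strategy_trace(fit$modal_class[sid == s], threshold, collapse_gaps))
  eps <- lapply(traces, `[[`, "episodes")
  structure(data.frame(
    student_id = fit$data$students,
    episodes = vapply(eps, paste, "", collapse = ">"),
    n_shifts = vapply(traces, `[[`, 0L, "n_shifts"),
    stringsAsFactors = FALSE), episode_list = eps)
}

#' Transition counts and shift-count summaries of strategy traces
#'
#' Tabulates (from, to) transitions over consecutive episode pairs of each
#' student's episode sequence, and summarises students by their number of
#' shifts: group sizes and, when per-student variables are supplied, their
#' means.
#'
#' @param traces Output of [strategy_traces()] (or a compatible data frame
#'   with attribute \code{"episode_list"}).
#' @param group Optional named vector (by student id) or vector aligned
#'   with \code{traces} assigning each student to a group (e.g.
#'   correct/wrong).
#' @param vars Optional per-student data frame (matched on
#'   \code{student_id}) of numeric variables to average per shift count,
#'   e.g. ability estimates and operational variables.
#' @return List with \code{transitions} (data frame \code{group},
#'   \code{from}, \code{to}, \code{n}; empty when every student has at most
#'   one episode) and \code{by_shifts} (per group and shift count:
#'   \code{n_students} and the means of \code{vars}).
#' @export
shift_summary <- function(traces, group = NULL, vars = NULL) {
  eps <- attr(traces, "episode_list")
  if (is.null(group)) group <- rep("all", nrow(traces))
  if (!is.null(names(group))) group <- group[traces$student_id]
  group <- as.character(group)

  pairs <- do.call(rbind, lapply(seq_along(eps), function(i) {
    e <- eps[[i]]
    if (length(e) < 2L) return(NULL)
    data.frame(group = group[i], from = e[-length(e)], to = e[-1L])
  }))
  transitions <- if (is.null(pairs))
    data.frame(group = character(), from = integer(), to = integer(),
               n = integer())
  else {
    agg <- stats::aggregate(list(n = rep(1L, nrow(pairs))),
                            pairs[c("group", "from", "to")], sum)
    agg[order(agg$group, agg$from, agg$to), , drop = FALSE]
  }

  key <- data.frame(group = group, n_shifts = traces$n_shifts)
  by_shifts <- stats::aggregate(list(n_students = rep(1L, nrow(key))), key,
                                sum)
  if (!is.null(vars)) {
    vars <- vars[match(traces$student_id, vars$student_id), , drop = FALSE]
    num <- vars[vapply(vars, is.numeric, TRUE)]
    means <- stats::aggregate(num, key, mean, na.rm = TRUE)
    by_shifts <- merge(by_shifts, means, by = c("group", "n_shifts"))
  }
  by_shifts <- by_shifts[order(by_shifts$group, by_shifts$n_shifts), ,
                         drop = FALSE]
  rownames(by_shifts) <- NULL
  list(transitions = transitions, by_shifts = by_shifts)
}
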