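#' Parse a PISA-dialect log table into ordered events
#'
#' Accepts the raw four-column log export (student id, event type, time in
#' seconds, event value) and returns validated events ordered by time within
#' student. Rows whose event type marks a full map state (\code{ACER_EVENT})
#' must carry a 0/1 state string of length equal to the number of routes,
#' optionally prefixed with an apostrophe as in the SPSS export; malformed
#' state rows are rejected with a diagnostic rather than silently dropped.
#'
#' @param log A data frame with columns (case-insensitive, common aliases
#'   accepted) \code{id}/\code{student_id}/\code{StIDStd}, \code{event},
#'   \code{time}, \code{event_value}.
#' @param spec A [task_spec()]; its route count fixes the state-string length.
#' @return An object of class \code{"log_events"}: a data frame with columns
#'   \code{student_id}, \code{event}, \code{time_s}, \code{event_value},
#'   ordered by student then time, with attribute \code{"rejected"} holding
#'   rejected rows and their diagnostics.
#' @export
parse_log <- function(log, spec) {
  log <- as.data.frame(log, stringsAsFactors = FALSE)
  nm <- tolower(names(log))
  pick <- function(aliases) {
    j <- which(nm %in% aliases)[1L]
    if (is.na(j)) stop("log table lacks a column named one of: ",
                       paste(aliases, collapse = ", "))
    log[[j]]
  }
  ev <- data.frame(
    student_id = as.character(pick(c("id", "student_id", "stidstd"))),
    event = as.character(pick("event")),
    time_s = as.numeric(pick(c("time", "time_s"))),
    event_value = as.character(pick(c("event_value", "value"))),
    stringsAsFactors = FALSE)
  ev$event_value[is.na(ev$event_value)] <- ""
  if (any(bad_t <- !is.finite(ev$time_s) | ev$time_s < 0)) {
    rej_t <- ev[bad_t, ]
    rej_t$reason <- "missing or negative time"
    ev <- ev[!bad_t, ]
  } else rej_t <- NULL

  is_state <- is_state_row(ev)
  val <- sub("^'", "", ev$event_value)
  ok <- !is_state | (nchar(val) == spec$n_routes & grepl("^[01]+$", val))
  rejected <- ev[!ok, ]
  if (nrow(rejected))
    rejected$reason <- sprintf(
      "state string of length %d with alphabet outside {0,1} (expected %d)",
      nchar(sub("^'", "", rejected$event_value)), spec$n_routes)
  rejected <- rbind(rej_t, rejected)
  ev <- ev[ok, ]
  ev <- ev[order(ev$student_id, ev$time_s), ]
  rownames(ev) <- NULL
  structure(ev, class = c("log_events", "data.frame"), rejected = rejected)
}

is_state_row <- function(ev) ev$event == "ACER_EVENT"

#' Read a log table from a delimited text export
#'
#' @param path Path to a CSV/TSV export of the log table.
#' @param spec A [task_spec()].
#' @param sep Field separator (default comma).
#' @return A \code{"log_events"} object, see [parse_log()].
#' @export
read_log <- function(path, spec, sep = ",") {
  parse_log(utils::read.table(path, header = TRUE, sep = sep,
                              colClasses = "character", quote = "\""),
            spec)
}

decode_state <- function(value, n_routes) {
  s <- sub("^'", "", value)
  m <- matrix(0L, length(s), n_routes)
  for (r in seq_along(s))
    m[r, ] <- as.integer(strsplit(s[r], "")[[1L]])
  m
}

encode_state <- function(selected, apostrophe = TRUE) {
  s <- apply(selected, 1L, paste, collapse = "")
  if (apostrophe) paste0("'", s) else s
}

#' Recode parsed log events into a step-by-route process dataset
#'
#' Retains only the full-state rows (one per effective step), decodes each
#' state string into a selected-route indicator vector, and applies the
#' scoring convention of [score_step()]. Click/double-click and
#' \code{hit_<segment>} highlight rows duplicate the state rows and are
#' dropped. Students with no retained state row (e.g. an open/close pair
#' with no action) are excluded and reported.
#'
#' @param events A \code{"log_events"} object from [parse_log()].
#' @param spec A [task_spec()].
#' @param collapse_consecutive Drop steps whose state repeats the previous
#'   state verbatim. Default \code{FALSE}: every retained state row is a step.
#' @return An object of class \code{"process_data"}: a list with
#'   \describe{
#'     \item{steps}{data frame \code{student_id}, \code{step} (1-based within
#'       student), \code{time_s};}
#'     \item{selected, scored}{integer matrices, one row per step, one column
#'       per route;}
#'     \item{students}{student ids with at least one step;}
#'     \item{final}{row index of each student's final step, named by student;}
#'     \item{excluded}{ids of students present in the log but without any
#'       retained step;}
#'     \item{spec}{the task specification.}
#'   }
#' @export
build_step_matrix <- function(events, spec, collapse_consecutive = FALSE) {
  st <- events[is_state_row(events), , drop = FALSE]
  all_students <- unique(events$student_id)
  excluded <- setdiff(all_students, unique(st$student_id))
  if (length(excluded))
    message(length(excluded), " student(s) with no retained state row excluded: ",
            paste(utils::head(excluded, 10L), collapse = ", "))
  selected <- decode_state(st$event_value, spec$n_routes)
  keep <- rep(TRUE, nrow(st))
  if (collapse_consecutive && nrow(st) > 1L) {
    same_student <- st$student_id[-1L] == st$student_id[-nrow(st)]
    same_state <- rowSums(abs(selected[-1L, , drop = FALSE] -
                              selected[-nrow(st), , drop = FALSE])) == 0L
    keep[-1L] <- !(same_student & same_state)
  }
  st <- st[keep, , drop = FALSE]
  selected <- selected[keep, , drop = FALSE]
  colnames(selected) <- spec$routes
  steps <- data.frame(student_id = st$student_id,
                      step = stats::ave(seq_len(nrow(st)), st$student_id,
                                        FUN = seq_along),
                      time_s = st$time_s, stringsAsFactors = FALSE)
  new_process_data(steps, selected, spec, excluded = excluded)
}

new_process_data <- function(steps, selected, spec, excluded = character()) {
  scored <- score_step(selected, spec)
  students <- unique(steps$student_id)
  final <- vapply(students, function(s) max(which(steps$student_id == s)), 0L)
  names(final) <- students
  structure(list(steps = steps, selected = selected, scored = scored,
                 students = students, final = final, excluded = excluded,
                 spec = spec),
            class = "process_data")
}

#' Scoring convention for a selection state
#'
#' A route indicator is recoded so that 1 always means the "good" state:
#' for routes on the correct path the score equals the selection indicator,
#' for routes off the correct path it is its complement. The map is an
#' involution: applying it twice recovers the selection vector, so the same
#' function converts scored responses back to selections.
#'
#' @param selected Binary vector of length \code{n_routes}, or a matrix with
#'   one row per step.
#' @param spec A [task_spec()].
#' @return Scored vector/matrix of the same shape.
#' @export
score_step <- function(selected, spec) {
  vec <- is.null(dim(selected))
  m <- if (vec) matrix(selected, 1L) else as.matrix(selected)
  if (ncol(m) != spec$n_routes)
    stop("selection vector length must equal the number of routes")
  wrong <- !(spec$routes %in% spec$correct_set)
  m[, wrong] <- 1L - m[, wrong]
  storage.mode(m) <- "integer"
  colnames(m) <- spec$routes
  if (vec) m[1L, ] else m
}

#' Per-student operational variables
#'
#' Computes, per student: the valid number of route clicks (toggles between
#' consecutive map states, the first state contributing its selected
#' routes), the number of resets (a one-event transition from a non-empty
#' selection to the all-clear state, plus any explicit \code{reset} event
#' rows), the response time (last minus first event time over all of the
#' student's log events), whether the final selection equals the correct
#' path, and the absolute difference in minutes between the travel time of
#' the final selection and the target time.
#'
#' @param events A \code{"log_events"} object (used for response time and
#'   explicit reset events).
#' @param data A \code{"process_data"} object from [build_step_matrix()].
#' @param spec A [task_spec()].
#' @return A data frame with one row per student in \code{data}:
#'   \code{student_id}, \code{n_route_clicks}, \code{n_resets},
#'   \code{response_time_s}, \code{final_correct}, \code{abs_time_diff}
#'   (\code{NA} when travel times are unavailable).
#' @export
operational_vars <- function(events, data, spec) {
  sel <- data$selected
  sid <- data$steps$student_id
  out <- lapply(data$students, function(s) {
    rows <- which(sid == s)
    m <- sel[rows, , drop = FALSE]
    nz <- rowSums(m) > 0L
    clicks <- sum(m[1L, ])
    resets <- 0L
    if (nrow(m) > 1L) {
      d <- abs(m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE])
      clicks <- clicks + sum(d)
      resets <- sum(nz[-length(nz)] & !nz[-1L])
    }
    tev <- events$time_s[events$student_id == s]
    resets <- resets + sum(events$event[events$student_id == s] == "reset")
    fin <- m[nrow(m), ]
    final_correct <- identical(spec$routes[fin == 1L], spec$correct_set) ||
      setequal(spec$routes[fin == 1L], spec$correct_set)
    atd <- if (is.null(spec$travel_time)) NA_real_ else
      abs(sum(spec$travel_time[fin == 1L]) - spec$target_time)
    data.frame(student_id = s, n_route_clicks = clicks, n_resets = resets,
               response_time_s = if (length(tev)) max(tev) - min(tev) else NA_real_,
               final_correct = final_correct, abs_time_diff = atd,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(spec$travel_time))
    warning("travel times missing from the task spec; abs_time_diff is NA")
  rownames(res) <- NULL
  res
}

#' @export
print.process_data <- function(x, ...) {
  cat("Process dataset:", nrow(x$selected), "steps from",
      length(x$students), "students over", x$spec$n_routes, "routes\n")
  J <- table(x$steps$student_id)
  cat(sprintf("  steps per student: mean %.1f, range %d-%d\n",
              mean(J), min(J), max(J)))
  if (length(x$excluded))
    cat("  excluded (no retained step):", length(x$excluded), "student(s)\n")
  invisible(x)
}

#' Tidy one-row-per-step view of a process dataset
#'
#' @param x A \code{"process_data"} object.
#' @param row.names,optional,... Passed through for S3 compatibility.
#' @return A data frame with \code{student_id}, \code{step}, \code{time_s},
#'   the selected indicators (route labels) and the scored indicators
#'   (route labels prefixed \code{"S_"}).
#' @export
as.data.frame.process_data <- function(x, row.names = NULL, optional = FALSE, ...) {
  scored <- x$scored
  colnames(scored) <- paste0("S_", x$spec$routes)
  cbind(x$steps, as.data.frame(x$selected), as.data.frame(scored))
}

#' Write a process dataset as a tidy CSV
#'
#' @param data A \code{"process_data"} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_process_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Number of level-1 units (steps)
#' @param data A \code{"process_data"} object.
#' @return Integer step count.
#' @export
n_steps <- function(data) nrow(data$selected)
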