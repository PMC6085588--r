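#' Task specification for a route-selection problem-solving item
#'
#' A task specification describes the map underlying a route-selection item:
#' the labelled routes, the node pair each route connects, per-route travel
#' times in minutes, the set of routes forming the correct path, and the
#' target travel time of that path.
#'
#' @param route_labels Character vector of unique route identifiers, in the
#'   order used by the log dialect's state strings (position \code{i} of a
#'   state string refers to \code{route_labels[i]}).
#' @param endpoints Two-column character matrix or data frame (one row per
#'   route) giving the unordered node pair each route connects.
#' @param travel_time Numeric vector of per-route travel times in minutes,
#'   or \code{NULL} if unknown (operational variables depending on travel
#'   times are then unavailable).
#' @param correct_set Character vector: the routes forming the correct path.
#' @param target_time Travel time in minutes of the correct path.
#'
#' @return An object of class \code{"task_spec"}: a list with elements
#'   \code{routes}, \code{endpoints} (data frame with columns \code{route},
#'   \code{from}, \code{to}), \code{travel_time} (named numeric or
#'   \code{NULL}), \code{correct_set}, \code{target_time}, \code{n_routes}.
#' @seealso [traffic_task()] for the bundled 23-route demonstration task.
#' @export
task_spec <- function(route_labels, endpoints, travel_time = NULL,
                      correct_set, target_time) {
  route_labels <- as.character(route_labels)
  if (anyDuplicated(route_labels))
    stop("route labels must be unique")
  endpoints <- as.data.frame(endpoints, stringsAsFactors = FALSE)
  if (nrow(endpoints) != length(route_labels) || ncol(endpoints) < 2L)
    stop("'endpoints' must have one row per route and two node columns")
  endpoints <- data.frame(route = route_labels,
                          from = as.character(endpoints[[1L]]),
                          to = as.character(endpoints[[2L]]),
                          stringsAsFactors = FALSE)
  correct_set <- as.character(correct_set)
  if (!all(correct_set %in% route_labels))
    stop("'correct_set' must be a subset of the route labels")
  if (!is.null(travel_time)) {
    travel_time <- as.numeric(travel_time)
    if (length(travel_time) != length(route_labels))
      stop("'travel_time' must have one entry per route")
    names(travel_time) <- route_labels
    tt <- sum(travel_time[correct_set])
    if (is.finite(tt) && abs(tt - target_time) > 1e-8)
      stop(sprintf(
        "travel times of the correct set sum to %g, not the target %g",
        tt, target_time))
  }
  spec <- structure(
    list(routes = route_labels, endpoints = endpoints,
         travel_time = travel_time, correct_set = correct_set,
         target_time = as.numeric(target_time),
         n_routes = length(route_labels)),
    class = "task_spec")
  if (!correct_set_is_path(spec))
    stop("the correct set must form a connected simple path on the map")
  spec
}

# The correct routes must chain into a simple path: in the subgraph induced
# by the correct set, exactly two nodes have degree 1, the rest degree 2,
# and the edges form one connected component.
correct_set_is_path <- function(spec) {
  ep <- spec$endpoints[spec$endpoints$route %in% spec$correct_set, ]
  if (nrow(ep) == 0L) return(FALSE)
  nodes <- unique(c(ep$from, ep$to))
  deg <- table(factor(c(ep$from, ep$to), levels = nodes))
  if (sum(deg == 1L) != 2L || any(deg > 2L)) return(FALSE)
  # connectivity by breadth-first search over correct edges
  reached <- nodes[1L]
  repeat {
    nxt <- unique(c(ep$to[ep$from %in% reached], ep$from[ep$to %in% reached]))
    nxt <- setdiff(nxt, reached)
    if (!length(nxt)) break
    reached <- c(reached, nxt)
  }
  length(reached) == length(nodes)
}

#' Routes adjacent to a given route on the map
#'
#' Two routes are adjacent when they share an endpoint node. Node names are
#' compared case-insensitively (log dialects are inconsistent about case).
#'
#' @param spec A [task_spec()].
#' @return A logical adjacency matrix over routes (diagonal \code{FALSE}).
#' @export
route_adjacency <- function(spec) {
  ep <- spec$endpoints
  from <- tolower(ep$from); to <- tolower(ep$to)
  n <- nrow(ep)
  adj <- matrix(FALSE, n, n, dimnames = list(ep$route, ep$route))
  for (a in seq_len(n)) {
    share <- (from == from[a] | from == to[a] | to == from[a] | to == to[a])
    adj[a, ] <- share
  }
  diag(adj) <- FALSE
  adj
}

#' The 23-route "Traffic" demonstration task
#'
#' The bundled demonstration map: 23 labelled routes (P1--P23) between named
#' suburbs, with the correct path Diamond--Nowhere--Sakharov--Market--Lee--
#' Mandela--Einstein (routes P1, P13, P17, P8, P5, P7) taking 31 minutes.
#' Per-route travel times are not part of the published item material; the
#' values bundled here are invented for demonstration, constrained so that
#' the correct path sums to the 31-minute target.
#'
#' @return A [task_spec()] with 23 routes.
#' @export
traffic_task <- function() {
  ep <- matrix(c(
    "Diamond",  "Nowhere",   # P1  (correct)
    "Diamond",  "Silver",    # P2
    "Emerald",  "Lincoln",   # P3
    "Emerald",  "Unity",     # P4
    "Lee",      "Mandela",   # P5  (correct)
    "Lincoln",  "Sato",      # P6
    "Mandela",  "Einstein",  # P7  (correct)
    "Market",   "Lee",       # P8  (correct)
    "Market",   "Park",      # P9
    "Nobel",    "Lee",       # P10
    "Nowhere",  "Einstein",  # P11
    "Nowhere",  "Emerald",   # P12
    "Nowhere",  "Sakharov",  # P13 (correct)
    "Nowhere",  "Unity",     # P14
    "Park",     "Mandela",   # P15
    "Park",     "Nowhere",   # P16
    "Sakharov", "Market",    # P17 (correct)
    "Sakharov", "Nobel",     # P18
    "Sato",     "Nowhere",   # P19
    "Silver",   "Market",    # P20
    "Silver",   "Nowhere",   # P21
    "Unity",    "Park",      # P22
    "Unity",    "Sato"       # P23
  ), ncol = 2L, byrow = TRUE)
  # invented travel times (minutes); correct path P1+P13+P17+P8+P5+P7 = 31
  tt <- c(4, 10, 8, 7, 6, 9, 5, 5, 7, 8, 22, 12, 6, 14, 9, 11, 5, 7, 13,
          12, 15, 8, 10)
  task_spec(route_labels = paste0("P", 1:23), endpoints = ep,
            travel_time = tt,
            correct_set = c("P1", "P5", "P7", "P8", "P13", "P17"),
            target_time = 31)
}

#' @export
print.task_spec <- function(x, ...) {
  cat("Task specification:", x$n_routes, "routes\n")
  cat("  correct path:", paste(x$correct_set, collapse = " "),
      sprintf("(%g min)\n", x$target_time))
  if (is.null(x$travel_time)) cat("  travel times: not specified\n")
  invisible(x)
}

#' Read or write a task specification as YAML
#'
#' The on-disk format is a YAML mapping with keys \code{routes} (list of
#' mappings \code{label}, \code{from}, \code{to}, optional \code{minutes}),
#' \code{correct_set} and \code{target_time}.
#'
#' @param path File path.
#' @return \code{read_task_spec} returns a [task_spec()];
#'   \code{write_task_spec} returns \code{path} invisibly.
#' @export
read_task_spec <- function(path) {
  y <- yaml::read_yaml(path)
  labs <- vapply(y$routes, `[[`, "", "label")
  ep <- cbind(vapply(y$routes, `[[`, "", "from"),
              vapply(y$routes, `[[`, "", "to"))
  tt <- vapply(y$routes, function(r)
    if (is.null(r$minutes)) NA_real_ else as.numeric(r$minutes), 0)
  if (all(is.na(tt))) tt <- NULL
  task_spec(labs, ep, tt, y$correct_set, y$target_time)
}

#' @rdname read_task_spec
#' @param spec A [task_spec()].
#' @export
write_task_spec <- function(spec, path) {
  routes <- lapply(seq_along(spec$routes), function(i) {
    r <- list(label = spec$routes[i], from = spec$endpoints$from[i],
              to = spec$endpoints$to[i])
    if (!is.null(spec$travel_time)) r$minutes <- unname(spec$travel_time[i])
    r
  })
  yaml::write_yaml(list(routes = routes, correct_set = spec$correct_set,
                        target_time = spec$target_time), path)
  invisible(path)
}
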