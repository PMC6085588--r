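task <- traffic_task()

# Selected-route sets of the published 14-step example for student 00017,
# written out independently of the state-string decoder.
student17_sets <- list(
  c("P2"),
  c("P1", "P2"),
  c("P1", "P2", "P13"),
  c("P1", "P2", "P13", "P18"),
  c("P1", "P2", "P10", "P13", "P18"),
  c("P1", "P2", "P10", "P13", "P18", "P20"),
  c("P1", "P2", "P10", "P18", "P20"),
  c("P2", "P10", "P18", "P20"),
  c("P2", "P10", "P20"),
  c("P2", "P20"),
  c("P2", "P10", "P20"),
  c("P2", "P20"),
  c("P2", "P9", "P20"),
  c("P2", "P9", "P16", "P20"))

sets_to_matrix <- function(sets, routes) {
  m <- matrix(0L, length(sets), length(routes),
              dimnames = list(NULL, routes))
  for (j in seq_along(sets)) m[j, sets[[j]]] <- 1L
  m
}

test_that("the student 00017 log excerpt reproduces the printed step matrix", {
  events <- read_log(fixture_path(), task)
  expect_s3_class(events, "log_events")
  # click/hit rows parsed but not retained as steps
  data <- build_step_matrix(events, task)
  expect_equal(nrow(data$selected), 14L)
  expect_equal(unname(data$selected),
               unname(sets_to_matrix(student17_sets, task$routes)))
  expect_equal(data$steps$step, 1:14)
  expect_equal(data$steps$time_s[1:2], c(837.6, 839.8))
  # N1 equals the number of retained full-state rows
  expect_equal(n_steps(data), sum(events$event == "ACER_EVENT"))
})

test_that("parse_log rejects malformed state strings with diagnostics", {
  log <- toy_log(c(strrep("0", 23), "0101"))  # second state string too short
  log$event_value[3] <- "0101"
  ev <- parse_log(log, task)
  rej <- attr(ev, "rejected")
  expect_equal(nrow(rej), 1L)
  expect_match(rej$reason, "state string")
  expect_equal(sum(ev$event == "ACER_EVENT"), 1L)

  bad <- toy_log(strrep("2", 23))             # alphabet outside {0,1}
  expect_equal(nrow(attr(parse_log(bad, task), "rejected")), 1L)
})

test_that("an empty log table yields an empty event list", {
  empty <- data.frame(id = character(), event = character(),
                      time = numeric(), event_value = character())
  ev <- parse_log(empty, task)
  expect_equal(nrow(ev), 0L)
})

test_that("events are ordered by time within student", {
  log <- rbind(toy_log(c("01000000000000000000000",
                         "11000000000000000000000"), id = "b"),
               toy_log(strrep("0", 23), id = "a"))
  log <- log[sample.int(nrow(log)), ]
  ev <- parse_log(log, task)
  expect_equal(unique(ev$student_id), c("a", "b"))
  expect_true(all(diff(ev$time_s[ev$student_id == "b"]) >= 0))
})

test_that("students with no retained state row are excluded and logged", {
  log <- rbind(toy_log("01000000000000000000000", id = "keep"),
               data.frame(id = "drop", event = c("start_item", "end_item"),
                          time = c(1, 2), event_value = ""))
  ev <- parse_log(log, task)
  expect_message(data <- build_step_matrix(ev, task), "excluded")
  expect_equal(data$students, "keep")
  expect_equal(data$excluded, "drop")
})

test_that("scoring follows the correct/incorrect recoding convention", {
  correct_only <- as.integer(task$routes %in% task$correct_set)
  expect_equal(unname(score_step(correct_only, task)),
               rep(1L, 23))
  # selecting only P2: 0 at the six correct routes and at P2, 1 elsewhere
  p2 <- as.integer(task$routes == "P2")
  sc <- score_step(p2, task)
  expect_equal(sum(sc), 16L)
  expect_equal(unname(sc[c(task$correct_set, "P2")]), rep(0L, 7))
  # selecting everything: 1 on the 6 correct routes, 0 on the 17 wrong ones
  all_sel <- rep(1L, 23)
  expect_equal(unname(score_step(all_sel, task)[task$correct_set]), rep(1L, 6))
  expect_equal(sum(score_step(all_sel, task)), 6L)
})

test_that("scoring is an involution and all-ones iff the correct set", {
  set.seed(7)
  for (r in 1:25) {
    sel <- rbinom(23, 1, 0.3)
    expect_equal(unname(score_step(score_step(sel, task), task)), sel)
    all_ones <- all(score_step(sel, task) == 1L)
    expect_equal(all_ones,
                 setequal(task$routes[sel == 1L], task$correct_set))
  }
})

test_that("consecutive duplicate states are kept unless collapsing is on", {
  states <- c("01000000000000000000000", "01000000000000000000000",
              "11000000000000000000000")
  ev <- parse_log(toy_log(states), task)
  expect_equal(n_steps(build_step_matrix(ev, task)), 3L)
  expect_equal(n_steps(build_step_matrix(ev, task,
                                         collapse_consecutive = TRUE)), 2L)
})

test_that("operational variables count toggles, resets, timing", {
  # script: select P1, then P1+P2, then all-clear, then the correct set
  correct_str <- paste(as.integer(task$routes %in% task$correct_set),
                       collapse = "")
  states <- c("10000000000000000000000", "11000000000000000000000",
              strrep("0", 23), correct_str)
  ev <- parse_log(toy_log(states), task)
  data <- build_step_matrix(ev, task)
  ov <- operational_vars(ev, data, task)
  expect_equal(ov$n_route_clicks, 1L + 1L + 2L + 6L)
  expect_equal(ov$n_resets, 1L)
  expect_true(ov$final_correct)
  expect_equal(ov$abs_time_diff, 0)
  expect_equal(ov$response_time_s, diff(range(ev$time_s)))

  # a student whose state never leaves all-zeros
  ev0 <- parse_log(toy_log(strrep("0", 23)), task)
  ov0 <- operational_vars(ev0, build_step_matrix(ev0, task), task)
  expect_equal(ov0$n_route_clicks, 0L)
  expect_equal(ov0$n_resets, 0L)
  expect_false(ov0$final_correct)
})

test_that("a scripted all-clear after five selections counts one reset", {
  states <- vapply(1:5, function(k)
    paste(c(rep(1L, k), rep(0L, 23 - k)), collapse = ""), "")
  states <- c(states, strrep("0", 23))
  ev <- parse_log(toy_log(states), task)
  ov <- operational_vars(ev, build_step_matrix(ev, task), task)
  expect_equal(ov$n_resets, 1L)
  expect_equal(ov$n_route_clicks, 5L + 5L)
})

test_that("the tidy CSV export carries selected and scored columns", {
  ev <- read_log(fixture_path(), task)
  data <- build_step_matrix(ev, task)
  df <- as.data.frame(data)
  expect_true(all(c("student_id", "step", "time_s", "P1", "S_P1") %in%
                  names(df)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_process_csv(data, path)
  back <- utils::read.csv(path, colClasses = c(student_id = "character"))
  expect_equal(back$P2, df$P2)
  expect_equal(back$S_P13, df$S_P13)
})
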