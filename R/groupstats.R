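#' Route selection proportions by group
#'
#' Percentage of steps (default) or students in which each route is
#' selected, per group (e.g. the correct-answer vs wrong-answer partition).
#' The per-student variant counts a route as selected when it appears in
#' any of the student's steps.
#'
#' @param data A \code{"process_data"} object.
#' @param group Vector assigning each student to a group; either named by
#'   student id or aligned with \code{data$students}.
#' @param by Denominator: \code{"steps"} (default) or \code{"students"}.
#' @return A data frame with \code{route} and one percentage column per
#'   group level (values in [0, 100]; \code{NA} for an empty group).
#' @export
selection_proportions <- function(data, group, by = c("steps", "students")) {
  by <- match.arg(by)
  if (!is.null(names(group))) group <- group[data$students]
  stopifnot(length(group) == length(data$students))
  group <- as.character(group)
  sid <- data$steps$student_id
  step_group <- group[match(sid, data$students)]
  out <- data.frame(route = data$spec$routes, stringsAsFactors = FALSE)
  for (lev in unique(group)) {
    if (by == "steps") {
      rows <- step_group == lev
      out[[lev]] <- if (any(rows))
        100 * colMeans(data$selected[rows, , drop = FALSE]) else NA_real_
    } else {
      studs <- data$students[group == lev]
      if (!length(studs)) { out[[lev]] <- NA_real_; next }
      ever <- t(vapply(studs, function(s)
        colSums(data$selected[sid == s, , drop = FALSE]) > 0L,
        logical(data$spec$n_routes)))
      out[[lev]] <- 100 * colMeans(ever)
    }
  }
  out
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson's chi-square test of homogeneity without continuity correction,
#' df = 1. A zero row or column marginal makes the statistic undefined.
#'
#' @param counts 2x2 matrix of non-negative counts.
#' @return List with \code{statistic}, \code{df}, \code{p_value} and
#'   \code{defined} (\code{FALSE}, with \code{NA} statistic, on a zero
#'   marginal).
#' @export
chisq_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2L), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    warning("zero marginal: chi-square statistic undefined")
    return(list(statistic = NA_real_, df = 1L, p_value = NA_real_,
                defined = FALSE))
  }
  ct <- stats::chisq.test(counts, correct = FALSE)
  list(statistic = unname(ct$statistic), df = 1L,
       p_value = unname(ct$p.value), defined = TRUE)
}

#' Pooled-variance two-sample t test
#'
#' Student's t test with pooled variance, df = n1 + n2 - 2, two-sided.
#'
#' @param x,y Numeric samples (each of size >= 2).
#' @param pooled Use the pooled-variance statistic (default \code{TRUE};
#'   \code{FALSE} gives Welch's test).
#' @return List with \code{statistic}, \code{df}, \code{p_value} and
#'   \code{defined} (\code{FALSE} when the pooled variance is zero).
#' @export
two_sample_t <- function(x, y, pooled = TRUE) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::var(x) + stats::var(y) == 0) {
    warning("zero pooled variance: t statistic undefined")
    return(list(statistic = NA_real_,
                df = if (pooled) length(x) + length(y) - 2L else NA_real_,
                p_value = NA_real_, defined = FALSE))
  }
  tt <- stats::t.test(x, y, var.equal = pooled)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = unname(tt$p.value), defined = TRUE)
}

#' Correlations between ability estimates and operational variables
#'
#' For each group (and overall), Pearson correlations of each operational
#' variable with the mean process-level ability and the student-level
#' ability, with two-sided significance stars at 0.05 / 0.01 / 0.001, plus
#' per-group means and SDs. Correlations involving a constant column are
#' undefined and reported as \code{NA}.
#'
#' @param vars Per-student data frame containing numeric columns
#'   \code{mean_process_ability} and \code{student_ability} plus the
#'   operational variables to correlate with them.
#' @param group Optional vector (aligned with rows of \code{vars}) of group
#'   labels; an \code{"all"} block is always appended when groups are given.
#' @return A data frame with columns \code{group}, \code{variable},
#'   \code{r_process}, \code{sig_process}, \code{r_student},
#'   \code{sig_student}, \code{mean}, \code{sd}.
#' @export
correlation_table <- function(vars, group = NULL) {
  stopifnot(all(c("mean_process_ability", "student_ability") %in% names(vars)))
  num <- vars[vapply(vars, is.numeric, TRUE)]
  blocks <- if (is.null(group)) list(all = rep(TRUE, nrow(num)))
  else {
    levs <- unique(as.character(group))
    c(stats::setNames(lapply(levs, function(l) group == l), levs),
      list(all = rep(TRUE, nrow(num))))
  }
  cor1 <- function(a, b) {
    ok <- stats::complete.cases(a, b)
    if (sum(ok) < 3L || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
      return(c(NA_real_, NA_real_))
    ct <- stats::cor.test(a[ok], b[ok])
    c(unname(ct$estimate), ct$p.value)
  }
  stars <- function(p) {
    if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.01) "**"
    else if (p < 0.05) "*" else ""
  }
  out <- do.call(rbind, lapply(names(blocks), function(bn) {
    rows <- blocks[[bn]]
    sub <- num[rows, , drop = FALSE]
    do.call(rbind, lapply(names(sub), function(v) {
      rp <- cor1(sub[[v]], sub$mean_process_ability)
      rs <- cor1(sub[[v]], sub$student_ability)
      data.frame(group = bn, variable = v,
                 r_process = if (v == "mean_process_ability") NA_real_ else rp[1L],
                 sig_process = if (v == "mean_process_ability") "" else stars(rp[2L]),
                 r_student = if (v == "student_ability") NA_real_ else rs[1L],
                 sig_student = if (v == "student_ability") "" else stars(rs[2L]),
                 mean = mean(sub[[v]], na.rm = TRUE),
                 sd = stats::sd(sub[[v]]),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Assemble the per-student analysis table of a fit
#'
#' Joins each student's mean process-level EAP ability, student-level EAP
#' ability and operational variables into the table consumed by
#' [correlation_table()] and [shift_summary()].
#'
#' @param fit A fitted \code{"mmixirt"} model.
#' @param opvars Output of [operational_vars()] for the same dataset.
#' @return Data frame keyed by \code{student_id}.
#' @export
student_table <- function(fit, opvars) {
  sid <- fit$data$steps$student_id
  mp <- vapply(fit$data$students, function(s)
    mean(fit$eap_process[sid == s]), 0)
  base <- data.frame(student_id = fit$data$students,
                     mean_process_ability = unname(mp),
                     student_ability = unname(fit$eap_student),
                     stringsAsFactors = FALSE)
  merge(base, opvars, by = "student_id", sort = FALSE)
}
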