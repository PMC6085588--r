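#' Deterministic well-separated example parameter bundle
#'
#' A reproducible parameter set for demonstrations and validation studies:
#' each class "prefers" a different block of routes (locations -1.5 vs
#' +1.5, so between-class location gaps of 3 on most routes), moderate
#' discriminations, unequal mixing proportions, all class ability
#' distributions standardized.
#'
#' @param I Number of routes.
#' @param G Number of classes (default 2).
#' @param separation Half-distance between the low and high route locations
#'   (default 1.5).
#' @return An [mmixirt_params()] bundle.
#' @export
example_params <- function(I, G = 2L, separation = 1.5) {
  alpha <- matrix(0.8 + 0.4 * ((seq_len(I) %% 3L) / 2), I, G)
  beta <- matrix(separation, I, G)
  m <- max(G, 2L)
  for (g in seq_len(G))
    beta[(seq_len(I) + g) %% m == 0L, g] <- -separation
  gamma <- (G:1 + 1) / sum(G:1 + 1)
  mmixirt_params(alpha, beta, gamma)
}

#' Simulate process data from the generative mixture model
#'
#' Draws, per student, a step count from a truncated Poisson distribution,
#' then per step a latent class from the mixing proportions, a process
#' ability from the class distribution, and scored route indicators from
#' the class-specific 2PL. The final step of each student is instead drawn
#' from the student-level 2PL with ability \code{theta_k ~ N(0, 1)} and the
#' (tied) student-level item parameters, so the final response pattern
#' carries the student-level signal. Selections are recovered from scores
#' by the involutive scoring convention, timestamps accumulate exponential
#' inter-event gaps, and optional all-clear "reset" steps are interleaved.
#'
#' @param spec A [task_spec()].
#' @param params An [mmixirt_params()] bundle (the truth).
#' @param n_students Number of students (default 406).
#' @param step_mean Mean of the Poisson step-count distribution (default
#'   39).
#' @param step_range Truncation bounds for step counts (default
#'   \code{c(1, 183)}).
#' @param reset_rate Probability of inserting an all-clear step after each
#'   process step (default 0).
#' @param gap_mean Mean inter-event gap in seconds (default 15).
#' @param seed Integer seed (mandatory; all randomness flows through it).
#' @return List with \code{data} (a \code{"process_data"} object) and
#'   \code{truth}: \code{steps} (per-step \code{student_id}, \code{step},
#'   \code{class}, \code{theta}, \code{is_reset}, \code{is_final};
#'   class/theta are \code{NA} on reset steps and \code{is_final} rows
#'   carry \code{theta_k}), \code{theta_k} (named per student) and
#'   \code{params}.
#' @export
simulate_mmixirt <- function(spec, params, n_students = 406L,
                             step_mean = 39, step_range = c(1L, 183L),
                             reset_rate = 0, gap_mean = 15, seed) {
  stopifnot(inherits(spec, "task_spec"), inherits(params, "mmixirt_params"),
            n_students >= 1L, reset_rate >= 0, reset_rate <= 1)
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  set.seed(seed)
  I <- spec$n_routes
  stopifnot(params$I == I)
  G <- params$G

  rtpois <- function(n) {
    out <- integer(n)
    for (i in seq_len(n)) {
      repeat {
        j <- stats::rpois(1L, step_mean)
        if (j >= step_range[1L] && j <= step_range[2L]) break
      }
      out[i] <- j
    }
    out
  }

  J <- rtpois(n_students)
  ids <- sprintf("S%04d", seq_len(n_students))
  theta_k <- stats::setNames(stats::rnorm(n_students), ids)

  rows <- list(); truth <- list(); t_clock <- 0
  for (k in seq_len(n_students)) {
    jk <- J[k]
    cls <- sample.int(G, jk, replace = TRUE, prob = params$gamma)
    th <- stats::rnorm(jk, params$mu[cls], params$sigma[cls])
    # final step: student-level machinery with tied item parameters
    cls[jk] <- NA_integer_; th[jk] <- theta_k[k]
    scored <- matrix(0L, jk, I)
    for (j in seq_len(jk)) {
      p <- if (j == jk)
        stats::plogis(params$alpha_B * th[j] - params$beta_B)
      else
        stats::plogis(params$alpha[, cls[j]] * th[j] - params$beta[, cls[j]])
      scored[j, ] <- stats::rbinom(I, 1L, p)
    }
    is_reset <- logical(jk)
    if (reset_rate > 0) {
      insert <- which(stats::runif(jk) < reset_rate)
      insert <- insert[insert < jk]        # keep the final step final
      if (length(insert)) {
        ord <- sort(c(seq_len(jk), insert + 0.5))
        reset_row <- score_step(integer(I), spec)
        scored2 <- matrix(0L, length(ord), I)
        scored2[ord %% 1 == 0, ] <- scored
        scored2[ord %% 1 != 0, ] <- matrix(reset_row, sum(ord %% 1 != 0), I,
                                           byrow = TRUE)
        scored <- scored2
        expand <- function(v, fill) {
          out <- rep(fill, length(ord)); out[ord %% 1 == 0] <- v; out
        }
        cls <- expand(cls, NA_integer_); th <- expand(th, NA_real_)
        is_reset <- ord %% 1 != 0
        jk <- length(ord)
      }
    }
    t0 <- t_clock + stats::rexp(1L, 1 / 60)
    times <- t0 + cumsum(stats::rexp(jk, 1 / gap_mean))
    t_clock <- times[jk]
    rows[[k]] <- data.frame(student_id = ids[k], step = seq_len(jk),
                            time_s = times, stringsAsFactors = FALSE)
    truth[[k]] <- data.frame(student_id = ids[k], step = seq_len(jk),
                             class = cls, theta = th, is_reset = is_reset,
                             is_final = seq_len(jk) == jk,
                             stringsAsFactors = FALSE)
    rows[[k]]$scored <- scored
  }
  steps <- do.call(rbind, lapply(rows, `[`, c("student_id", "step", "time_s")))
  scored_all <- do.call(rbind, lapply(rows, `[[`, "scored"))
  selected <- score_step(scored_all, spec)  # involution: scores -> selections
  data <- new_process_data(steps, selected, spec)
  list(data = data,
       truth = list(steps = do.call(rbind, truth), theta_k = theta_k,
                    params = params, seed = seed))
}

#' Serialize a process dataset in the PISA 2012 log dialect
#'
#' Emits one \code{ACER_EVENT} row per step with the apostrophe-prefixed
#' 0/1 state string over routes, bracketed by \code{start_item} /
#' \code{end_item} rows per student; optionally each state row is preceded
#' by a redundant \code{click} row in \code{hit_<route>} form (as real logs
#' carry), which [build_step_matrix()] must drop again.
#'
#' @param data A \code{"process_data"} object.
#' @param spec A [task_spec()].
#' @param hit_rows Also emit redundant \code{hit_<route>} click rows
#'   (default \code{FALSE}).
#' @return A data frame with columns \code{id}, \code{event}, \code{time},
#'   \code{event_value}, parseable by [parse_log()].
#' @export
emit_log <- function(data, spec, hit_rows = FALSE) {
  if (!length(data$students))
    return(data.frame(id = character(), event = character(),
                      time = numeric(), event_value = character(),
                      stringsAsFactors = FALSE))
  sid <- data$steps$student_id
  state <- encode_state(data$selected)
  out <- lapply(data$students, function(s) {
    rows <- which(sid == s)
    tms <- data$steps$time_s[rows]
    df <- data.frame(id = s, event = "ACER_EVENT", time = tms,
                     event_value = state[rows], stringsAsFactors = FALSE)
    if (hit_rows) {
      sel <- data$selected[rows, , drop = FALSE]
      prev <- rbind(0L, sel[-nrow(sel), , drop = FALSE])
      hit <- apply(abs(sel - prev), 1L, function(d)
        if (any(d == 1L)) paste0("hit_", tolower(spec$routes[which(d == 1L)[1L]]))
        else "")
      df2 <- data.frame(id = s, event = "click", time = tms,
                        event_value = hit, stringsAsFactors = FALSE)
      df <- rbind(df, df2)
    }
    rbind(data.frame(id = s, event = "start_item", time = min(tms) - 1,
                     event_value = "", stringsAsFactors = FALSE),
          df,
          data.frame(id = s, event = "end_item", time = max(tms) + 1,
                     event_value = "", stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$id, out$time), ]
  rownames(out) <- NULL
  out
}

# all permutations of 1:n (n small)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  unname(do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k)))))
}

#' Align fitted class labels with a reference bundle
#'
#' Finds the permutation of fitted classes minimizing the squared distance
#' of the standardized location matrices to the reference (truth), breaking
#' the label-switching indeterminacy of mixture fits.
#'
#' @param fitted,reference [mmixirt_params()] bundles with equal G.
#' @return Integer permutation \code{perm}: fitted class \code{f}
#'   corresponds to reference class \code{perm[f]}.
#' @export
align_classes <- function(fitted, reference) {
  stopifnot(fitted$G == reference$G)
  bf <- standardize_params(fitted)$beta
  br <- standardize_params(reference)$beta
  perms <- all_perms(fitted$G)
  costs <- apply(perms, 1L, function(p) sum((bf - br[, p, drop = FALSE])^2))
  perms[which.min(costs), ]
}

#' Parameter-recovery experiment
#'
#' Simulates a dataset from a known parameter bundle, fits the model at the
#' true number of classes, aligns labels, and reports recovery error on the
#' standardized within-class scale (the scale on which class-specific item
#' parameters are identified): RMSE of discriminations and locations,
#' largest absolute mixing-proportion error, and modal-class assignment
#' accuracy over non-final, non-reset steps.
#'
#' @param spec A [task_spec()].
#' @param true_params An [mmixirt_params()] bundle.
#' @param n_students,step_mean,seed Simulation design (see
#'   [simulate_mmixirt()]).
#' @param ... Passed to [mmixirt()] (e.g. \code{starts}, \code{quadrature}).
#' @return List with \code{rmse_alpha}, \code{rmse_beta},
#'   \code{gamma_max_err}, \code{accuracy}, \code{perm}, \code{fit},
#'   \code{sim}.
#' @export
recovery_experiment <- function(spec, true_params, n_students = 500L,
                                step_mean = 30, seed = 1L, ...) {
  sim <- simulate_mmixirt(spec, true_params, n_students = n_students,
                          step_mean = step_mean, seed = seed)
  fit <- mmixirt(sim$data, classes = true_params$G, seed = seed, ...)
  perm <- align_classes(fit$params, true_params)
  eh <- standardize_params(fit$params)
  et <- standardize_params(true_params)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  tr <- sim$truth$steps
  proc <- !tr$is_final & !tr$is_reset
  acc <- mean(perm[fit$modal_class[proc]] == tr$class[proc])
  list(rmse_alpha = rmse(eh$alpha, et$alpha[, perm, drop = FALSE]),
       rmse_beta = rmse(eh$beta, et$beta[, perm, drop = FALSE]),
       gamma_max_err = max(abs(fit$params$gamma - true_params$gamma[perm])),
       accuracy = acc, perm = perm, fit = fit, sim = sim)
}
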