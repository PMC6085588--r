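#' @export
print.mmixirt <- function(x, ...) {
  cat(sprintf("Multilevel mixture 2PL fit: %d class(es), %d routes\n",
              x$params$G, x$params$I))
  cat(sprintf("  %d steps from %d students; logLik %.3f (%d free parameters)\n",
              x$n_steps, x$n_students, x$loglik, x$n_params))
  cat(sprintf("  AIC %.3f  BIC %.3f  aBIC %.3f", x$ic[["AIC"]],
              x$ic[["BIC"]], x$ic[["aBIC"]]))
  if (!is.na(x$entropy)) cat(sprintf("  entropy %.3f", x$entropy))
  cat("\n  class proportions:",
      paste(sprintf("%.3f", x$params$gamma), collapse = " "), "\n")
  if (!x$converged) cat("  (EM not converged)\n")
  invisible(x)
}

#' @export
summary.mmixirt <- function(object, ...) {
  G <- object$params$G
  cls <- data.frame(
    class = seq_len(G),
    proportion = object$params$gamma,
    steps = as.vector(table(factor(object$modal_class, levels = seq_len(G)))),
    mean_eap = vapply(seq_len(G), function(g)
      mean(object$eap_process[object$modal_class == g]), 0))
  structure(list(fit = object, class_table = cls),
            class = "summary.mmixirt")
}

#' @export
print.summary.mmixirt <- function(x, ...) {
  print(x$fit)
  cat("\nModal class sizes and mean process-level EAP ability:\n")
  print(x$class_table, row.names = FALSE, digits = 3)
  cat("\nAverage posterior probability by modal class:\n")
  print(round(x$fit$avg_posterior, 3))
  invisible(x)
}

#' Extract model coefficients
#'
#' @param object A fitted \code{"mmixirt"} model.
#' @param level \code{"process"} (class-specific route parameters, mixing
#'   proportions and class moments) or \code{"student"} (final-step 2PL
#'   parameters).
#' @param ... Unused.
#' @return For \code{"process"}, a list with \code{alpha}, \code{beta}
#'   (I x G), \code{gamma}, \code{mu}, \code{sigma}; for \code{"student"},
#'   a two-column matrix of \code{alpha_B}, \code{beta_B}.
#' @export
coef.mmixirt <- function(object, level = c("process", "student"), ...) {
  level <- match.arg(level)
  p <- object$params
  if (level == "process")
    list(alpha = p$alpha, beta = p$beta, gamma = p$gamma,
         mu = p$mu, sigma = p$sigma)
  else cbind(alpha_B = p$alpha_B, beta_B = p$beta_B)
}

#' @export
logLik.mmixirt <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_steps,
            class = "logLik")
}

#' Posterior quantities for new process data
#'
#' @param object A fitted \code{"mmixirt"} model.
#' @param newdata A \code{"process_data"} object; default: the training data.
#' @param type \code{"posterior"} (steps x G matrix), \code{"class"} (modal
#'   class per step) or \code{"eap"} (list of process- and student-level
#'   EAP abilities).
#' @param ... Unused.
#' @export
predict.mmixirt <- function(object, newdata = NULL,
                            type = c("posterior", "class", "eap"), ...) {
  type <- match.arg(type)
  data <- newdata %||% object$data
  if (type == "eap")
    return(eap_abilities(data, object$params, object$quadrature))
  rule <- gh_rule(object$quadrature)
  par <- object$params
  scored <- data$scored; storage.mode(scored) <- "double"
  e <- e_step(scored, par, rule)
  Q <- length(rule$x)
  post <- sapply(seq_len(par$G), function(g)
    rowSums(e$W[, (g - 1L) * Q + seq_len(Q), drop = FALSE]))
  post <- matrix(post, nrow = nrow(scored),
                 dimnames = list(NULL, paste0("class", seq_len(par$G))))
  if (type == "posterior") post else max.col(post, ties.method = "first")
}

#' Pearson residuals of the scored responses
#'
#' Per step and route: \code{(w - phat) / sqrt(phat (1 - phat))} where
#' \code{phat} is the model-implied selection probability marginal over the
#' step's posterior class/ability distribution.
#'
#' @param object A fitted \code{"mmixirt"} model.
#' @param ... Unused.
#' @return A steps x routes matrix.
#' @export
residuals.mmixirt <- function(object, ...) {
  rule <- gh_rule(object$quadrature)
  par <- object$params
  scored <- object$data$scored; storage.mode(scored) <- "double"
  e <- e_step(scored, par, rule)
  Q <- length(rule$x)
  P <- matrix(0, par$I, par$G * Q)
  for (g in seq_len(par$G))
    P[, (g - 1L) * Q + seq_len(Q)] <-
      stats::plogis(outer(par$alpha[, g], rule$x) - par$beta[, g])
  phat <- e$W %*% t(P)
  phat <- pmin(pmax(phat, 1e-10), 1 - 1e-10)
  res <- (scored - phat) / sqrt(phat * (1 - phat))
  colnames(res) <- object$data$spec$routes
  res
}

#' Simulate datasets from a fitted model
#'
#' Draws new process datasets from the fitted parameter bundle with the
#' generative machinery of [simulate_mmixirt()].
#'
#' @param object A fitted \code{"mmixirt"} model.
#' @param nsim Number of datasets.
#' @param seed Integer seed.
#' @param n_students,step_mean,... Passed to [simulate_mmixirt()]; defaults
#'   mirror the training data.
#' @return A list of \code{nsim} simulation results (each with \code{data}
#'   and \code{truth}).
#' @export
simulate.mmixirt <- function(object, nsim = 1, seed = NULL,
                             n_students = NULL, step_mean = NULL, ...) {
  if (is.null(seed)) seed <- object$seed
  n_students <- n_students %||% object$n_students
  step_mean <- step_mean %||% max(1, round(object$n_steps / object$n_students))
  lapply(seq_len(nsim), function(r)
    simulate_mmixirt(object$data$spec, object$params,
                     n_students = n_students, step_mean = step_mean,
                     seed = seed + r - 1L, ...))
}

#' Plot class profiles of a fitted model
#'
#' Draws the model-implied probability of the "good" scored state per route
#' for each class, evaluated at the class ability mean, plus an inset
#' barplot of mixing proportions.
#'
#' @param x A fitted \code{"mmixirt"} model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.mmixirt <- function(x, ...) {
  p <- x$params
  prob <- sapply(seq_len(p$G), function(g)
    stats::plogis(p$alpha[, g] * p$mu[g] - p$beta[, g]))
  graphics::matplot(prob, type = "b", pch = as.character(seq_len(p$G)),
                    lty = 1, xlab = "route", xaxt = "n",
                    ylab = "P(scored response = 1) at class mean ability",
                    main = "Class route profiles", ...)
  graphics::axis(1, at = seq_len(p$I),
                 labels = p$routes %||% seq_len(p$I), las = 2, cex.axis = 0.7)
  graphics::legend("bottomright",
                   legend = sprintf("class %d (%.2f)", seq_len(p$G), p$gamma),
                   col = seq_len(p$G), lty = 1, cex = 0.8)
  invisible(x)
}
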