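#' Fit the multilevel mixture 2PL model to process data
#'
#' Maximizes the marginal likelihood of the scored step-by-route responses
#' under a process-level mixture of class-specific 2PL models (class
#' membership redrawn step by step, class ability distributions normal with
#' the reference class fixed at N(0,1)) by an EM algorithm on a fixed
#' Gauss-Hermite node grid. Student-level abilities are scored from each
#' student's final step under a 2PL whose item parameters are tied to the
#' reference class. Multiple random starts are run for a short burn-in and
#' the best start is iterated to convergence; classes are then relabelled
#' canonically (descending mixing proportion, ties by ascending ability
#' mean).
#'
#' Every M-step update is accepted only if it does not decrease its piece of
#' the expected complete-data log-likelihood, so the observed-data
#' log-likelihood trace is non-decreasing by construction (generalized EM).
#'
#' @param data A \code{"process_data"} object from [build_step_matrix()] or
#'   [simulate_mmixirt()].
#' @param classes Number of latent classes G (>= 1).
#' @param quadrature Number of Gauss-Hermite nodes (default 15).
#' @param starts Number of random starts (default 20), perturbed around
#'   method-of-moments initial values (locations from scored-proportion
#'   logits, unit discriminations).
#' @param seed Integer seed recorded in the result; all randomness in the
#'   fit flows through it.
#' @param max_iter,tol Convergence: stop when the relative log-likelihood
#'   change falls below \code{tol} (default \code{1e-6}) or after
#'   \code{max_iter} (default 500) iterations.
#' @param short_iter Burn-in EM iterations per random start before the best
#'   start is selected (default 30).
#' @param ic_n Sample size used in BIC/aBIC penalties: number of level-1
#'   steps (default, \code{"steps"}) or number of students
#'   (\code{"students"}).
#' @param verbose Print per-start progress.
#' @return An object of class \code{"mmixirt"}; see Details. Components
#'   include \code{params} ([mmixirt_params()]), \code{loglik},
#'   \code{n_params}, \code{n_steps}, \code{n_students}, \code{posteriors}
#'   (steps x G), \code{modal_class}, \code{eap_process},
#'   \code{eap_student}, \code{ic} (AIC/BIC/aBIC), \code{entropy},
#'   \code{avg_posterior}, \code{converged}, \code{n_iter},
#'   \code{ll_trace}, \code{boundary}, \code{seed}.
#' @examples
#' task <- traffic_task()
#' sim <- simulate_mmixirt(task, example_params(task$n_routes, 2),
#'                         n_students = 40, step_mean = 8, seed = 1)
#' fit <- mmixirt(sim$data, classes = 2, starts = 2, seed = 1)
#' fit
#' @export
mmixirt <- function(data, classes = 1L, quadrature = 15L, starts = 20L,
                    seed = NULL, max_iter = 500L, tol = 1e-6,
                    short_iter = 30L, ic_n = c("steps", "students"),
                    verbose = FALSE) {
  stopifnot(inherits(data, "process_data"), classes >= 1L, quadrature >= 5L)
  ic_n <- match.arg(ic_n)
  scored <- data$scored
  storage.mode(scored) <- "double"
  N1 <- nrow(scored)
  if (!N1) stop("empty process dataset")
  G <- as.integer(classes)
  rule <- gh_rule(quadrature)
  if (is.null(seed)) seed <- 20120601L
  rng <- local({ set.seed(seed); function(n, sd) stats::rnorm(n, 0, sd) })

  beta0 <- -stats::qlogis(pmin(pmax(colMeans(scored), 0.02), 0.98))
  make_start <- function() {
    list(alpha = matrix(exp(rng(data$spec$n_routes * G, 0.2)),
                        ncol = G),
         beta = beta0 + matrix(rng(length(beta0) * G, if (G > 1L) 0.7 else 0.2),
                               ncol = G),
         gamma = { g0 <- 0.5 + stats::runif(G); g0 / sum(g0) },
         mu = numeric(G), sigma = rep(1, G))
  }

  best <- NULL
  for (s in seq_len(starts)) {
    run <- em_run(scored, make_start(), rule,
                  max_iter = if (starts > 1L) short_iter else max_iter,
                  tol = tol)
    if (verbose)
      message(sprintf("start %d/%d: logLik %.3f after %d iter",
                      s, starts, run$loglik, run$n_iter))
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  if (starts > 1L)
    best <- em_run(scored, best$par, rule, max_iter = max_iter, tol = tol,
                   ll_trace = best$ll_trace)

  par <- best$par
  # canonical labels: descending class size, ties by ascending class mean
  perm <- order(-par$gamma, par$mu)
  par <- lapply_par(par, perm)
  reference <- which(perm == 1L)
  params <- mmixirt_params(par$alpha, par$beta, par$gamma, par$mu, par$sigma,
                           routes = data$spec$routes, reference = reference)

  e <- e_step(scored, par, rule)
  Q <- length(rule$x)
  post <- sapply(seq_len(G), function(g)
    rowSums(e$W[, (g - 1L) * Q + seq_len(Q), drop = FALSE]))
  post <- matrix(post, nrow = N1, dimnames = list(NULL, paste0("class", 1:G)))
  modal <- max.col(post, ties.method = "first")
  eap_p <- as.vector(e$W %*% rep(rule$x, G))
  eap_s <- eap_student(data, params, rule)

  p <- count_free_parameters(G, data$spec$n_routes)
  n_ic <- if (ic_n == "steps") N1 else length(data$students)
  fit <- structure(list(
    call = match.call(), params = params, loglik = best$loglik,
    n_params = p, n_steps = N1, n_students = length(data$students),
    posteriors = post, modal_class = modal,
    eap_process = eap_p, eap_student = eap_s,
    ic = information_criteria(best$loglik, p, n_ic),
    entropy = if (G >= 2L) entropy(post) else NA_real_,
    avg_posterior = average_posterior_matrix(post, modal),
    converged = best$converged, n_iter = best$n_iter,
    ll_trace = best$ll_trace, boundary = best$boundary,
    seed = seed, quadrature = quadrature, ic_n = ic_n,
    data = data), class = "mmixirt")
  if (best$boundary)
    warning("some item parameters reached the optimization bound; ",
            "estimates at the boundary (quasi-separation in the data)")
  if (!best$converged)
    warning("EM reached max_iter before the relative log-likelihood ",
            "change fell below tol; best solution returned")
  fit
}

lapply_par <- function(par, perm) {
  list(alpha = par$alpha[, perm, drop = FALSE],
       beta = par$beta[, perm, drop = FALSE],
       gamma = par$gamma[perm], mu = par$mu[perm], sigma = par$sigma[perm])
}

PARAM_CAP <- 30

e_step <- function(scored, par, rule) {
  Wn <- class_node_weights(rule, par$mu, par$sigma)
  Q <- length(rule$x)
  lw <- log(rep(pmax(par$gamma, 1e-300), each = Q)) + log(as.vector(Wn))
  ld <- sweep(step_log_density(scored, par, rule), 2L, lw, `+`)
  ll_by_step <- row_log_sum_exp(ld)
  list(W = exp(ld - ll_by_step), loglik = sum(ll_by_step))
}

em_run <- function(scored, par, rule, max_iter, tol, ll_trace = numeric()) {
  N1 <- nrow(scored); G <- length(par$gamma); Q <- length(rule$x)
  loglik <- -Inf; converged <- FALSE; boundary <- FALSE; floored <- FALSE
  iter <- 0L
  repeat {
    e <- e_step(scored, par, rule)
    ll_trace <- c(ll_trace, e$loglik)
    if (is.finite(loglik) &&
        (e$loglik - loglik) < tol * (abs(loglik) + 1e-3)) {
      loglik <- max(loglik, e$loglik)
      converged <- TRUE
      break
    }
    loglik <- e$loglik
    if (iter >= max_iter) break
    iter <- iter + 1L

    A <- matrix(colSums(e$W), nrow = Q)            # Q x G node masses
    gam <- colSums(A) / N1
    if (any(gam < 1e-4)) {
      gam <- pmax(gam, 1e-4); gam <- gam / sum(gam)
      if (!floored) {
        warning("a mixing proportion hit the 1e-4 floor (near-empty class)")
        floored <- TRUE
      }
    }
    par$gamma <- gam
    for (g in seq_len(G)) {
      Wg <- e$W[, (g - 1L) * Q + seq_len(Q), drop = FALSE]
      S <- crossprod(Wg, scored)                   # Q x I successes
      n_q <- A[, g]
      for (i in seq_len(ncol(scored))) {
        upd <- newton_2pl(rule$x, S[, i], n_q, par$alpha[i, g], par$beta[i, g])
        par$alpha[i, g] <- upd$a; par$beta[i, g] <- upd$b
      }
      if (g > 1L) {
        ms <- update_class_moments(A[, g], rule, par$mu[g], par$sigma[g])
        par$mu[g] <- ms$mu; par$sigma[g] <- ms$sigma
      }
    }
  }
  boundary <- any(abs(par$alpha) >= PARAM_DIVERGED) ||
    any(abs(par$beta) >= PARAM_DIVERGED)
  list(par = par, loglik = loglik, n_iter = iter, converged = converged,
       ll_trace = ll_trace, boundary = boundary)
}

# Weighted 2PL M-step for one route in one class: maximize
# sum_q s_q log p_q + (n_q - s_q) log(1 - p_q), p = plogis(a x - b),
# by damped Newton steps accepted only on ascent.
newton_2pl <- function(x, s, n, a, b, iters = 12L) {
  obj <- function(a, b) {
    eta <- a * x - b
    sum(s * stats::plogis(eta, log.p = TRUE) +
        (n - s) * stats::plogis(-eta, log.p = TRUE))
  }
  cur <- obj(a, b)
  for (it in seq_len(iters)) {
    p <- stats::plogis(a * x - b)
    r <- s - n * p
    g <- c(sum(r * x), -sum(r))
    w2 <- pmax(n * p * (1 - p), 1e-12)
    H <- matrix(c(sum(w2 * x^2), -sum(w2 * x), -sum(w2 * x), sum(w2)), 2L)
    d <- tryCatch(solve(H, g), error = function(e) g / (max(diag(H)) + 1e-8))
    step <- 1
    repeat {
      a2 <- clamp(a + step * d[1L]); b2 <- clamp(b + step * d[2L])
      val <- obj(a2, b2)
      if (val >= cur - 1e-12) break
      step <- step / 2
      if (step < 1e-6) { a2 <- a; b2 <- b; val <- cur; break }
    }
    done <- abs(val - cur) < 1e-10
    a <- a2; b <- b2; cur <- val
    if (done) break
  }
  list(a = a, b = b)
}

clamp <- function(v) pmin(pmax(v, -PARAM_CAP), PARAM_CAP)

# magnitude far outside the plausible logit range: treated as divergence
# (quasi-separation), reported via the boundary flag
PARAM_DIVERGED <- 15

# M-step for a non-reference class's ability moments: maximize the expected
# node-assignment log-likelihood sum_q A_q log w_q(mu, sigma) over the fixed
# grid; accepted only on improvement (the moments sit on a likelihood ridge
# with the class item parameters, so movements are typically small).
update_class_moments <- function(A, rule, mu, sigma) {
  obj <- function(p) {
    lw <- log(rule$w) + stats::dnorm(rule$x, p[1L], exp(p[2L]), log = TRUE) -
      stats::dnorm(rule$x, log = TRUE)
    sum(A * (lw - log_sum_exp(lw)))
  }
  cur <- obj(c(mu, log(sigma)))
  o <- tryCatch(
    stats::optim(c(mu, log(sigma)), function(p) -obj(p), method = "L-BFGS-B",
                 lower = c(-6, log(0.05)), upper = c(6, log(10)),
                 control = list(maxit = 25L)),
    error = function(e) NULL)
  if (!is.null(o) && -o$value > cur)
    list(mu = o$par[1L], sigma = exp(o$par[2L]))
  else list(mu = mu, sigma = sigma)
}

eap_student <- function(data, params, rule) {
  fs <- data$scored[data$final, , drop = FALSE]
  storage.mode(fs) <- "double"
  eta <- outer(params$alpha_B, rule$x) - params$beta_B
  lp <- stats::plogis(eta, log.p = TRUE)
  lq <- stats::plogis(-eta, log.p = TRUE)
  ld <- sweep(fs %*% lp + (1 - fs) %*% lq, 2L, log(rule$w), `+`)
  post <- exp(ld - row_log_sum_exp(ld))
  stats::setNames(as.vector(post %*% rule$x), data$students)
}

#' Information criteria for a fitted mixture model
#'
#' \code{AIC = -2 LL + 2p}, \code{BIC = -2 LL + p log(N)},
#' \code{aBIC = -2 LL + p log((N + 2) / 24)} (the sample-size-adjusted BIC),
#' with \code{N} the number of level-1 units (process steps by default).
#'
#' @param loglik Maximized marginal log-likelihood.
#' @param p Number of free parameters.
#' @param n1 Sample size entering the BIC/aBIC penalties.
#' @return Named numeric vector \code{c(AIC, BIC, aBIC)}.
#' @export
information_criteria <- function(loglik, p, n1) {
  stopifnot(n1 >= 1)
  c(AIC = -2 * loglik + 2 * p,
    BIC = -2 * loglik + p * log(n1),
    aBIC = -2 * loglik + p * log((n1 + 2) / 24))
}

#' Classification entropy of a mixture fit
#'
#' Normalized entropy \code{1 - sum_j sum_g (-p_jg log p_jg) / (N log G)},
#' in [0, 1]; 1 means every step is assigned to a class with certainty, 0
#' means posteriors are uniform.
#'
#' @param posteriors Steps x classes matrix of posterior class
#'   probabilities, rows summing to one.
#' @return Entropy in [0, 1]; \code{NA} for a single class.
#' @export
entropy <- function(posteriors) {
  posteriors <- as.matrix(posteriors)
  G <- ncol(posteriors)
  if (G < 2L) return(NA_real_)
  plogp <- posteriors * log(posteriors)
  plogp[posteriors == 0] <- 0
  1 - sum(-plogp) / (nrow(posteriors) * log(G))
}

#' Average posterior probabilities by modal class
#'
#' Entry (r, c) is the mean posterior probability of class c among the
#' steps whose modal (most likely) class is r; a well-separated solution
#' has a dominant diagonal. Rows of empty modal classes are \code{NA}.
#'
#' @param posteriors Steps x classes posterior matrix.
#' @param modal_class Integer vector of modal classes per step.
#' @return G x G matrix with rows summing to 1 where defined.
#' @export
average_posterior_matrix <- function(posteriors, modal_class) {
  posteriors <- as.matrix(posteriors)
  G <- ncol(posteriors)
  out <- matrix(NA_real_, G, G,
                dimnames = list(paste0("modal", 1:G), paste0("class", 1:G)))
  for (r in seq_len(G)) {
    rows <- modal_class == r
    if (any(rows)) out[r, ] <- colMeans(posteriors[rows, , drop = FALSE])
  }
  out
}

#' Expected a posteriori ability estimates
#'
#' Process-level EAP: posterior mean of the step ability given the step's
#' scored vector, marginal over classes. Student-level EAP: posterior mean
#' of the student ability given the final-step vector under the
#' student-level 2PL with N(0,1) prior.
#'
#' @param data A \code{"process_data"} object.
#' @param params An [mmixirt_params()] bundle.
#' @param quadrature Number of quadrature nodes.
#' @return List with \code{process} (per step) and \code{student} (named
#'   per student).
#' @export
eap_abilities <- function(data, params, quadrature = 15L) {
  rule <- gh_rule(quadrature)
  scored <- data$scored
  storage.mode(scored) <- "double"
  par <- list(alpha = params$alpha, beta = params$beta, gamma = params$gamma,
              mu = params$mu, sigma = params$sigma)
  e <- e_step(scored, par, rule)
  list(process = as.vector(e$W %*% rep(rule$x, params$G)),
       student = eap_student(data, params, rule))
}

#' Fit a sequence of class counts and tabulate model selection criteria
#'
#' Fits the model for each requested number of classes and assembles a
#' model-comparison table (class count, free parameters, log-likelihood,
#' AIC, BIC, aBIC, entropy).
#'
#' @param data A \code{"process_data"} object.
#' @param classes Integer vector of class counts to fit (e.g. \code{1:8}).
#' @param ... Passed to [mmixirt()].
#' @return A data frame of class \code{"mmixirt_selection"} with one row
#'   per class count and attribute \code{"fits"} holding the fitted models.
#' @export
select_classes <- function(data, classes = 1:4, ...) {
  fits <- lapply(classes, function(G) mmixirt(data, classes = G, ...))
  tab <- data.frame(
    classes = classes,
    n_params = vapply(fits, `[[`, 0L, "n_params"),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    AIC = vapply(fits, function(f) f$ic[["AIC"]], 0),
    BIC = vapply(fits, function(f) f$ic[["BIC"]], 0),
    aBIC = vapply(fits, function(f) f$ic[["aBIC"]], 0),
    entropy = vapply(fits, `[[`, 0, "entropy"))
  structure(tab, fits = fits, class = c("mmixirt_selection", "data.frame"))
}

#' @export
print.mmixirt_selection <- function(x, ...) {
  cat("Model selection over latent class counts (N1 =",
      attr(x, "fits")[[1L]]$n_steps, "steps)\n")
  print.data.frame(x, row.names = FALSE, digits = 8)
  invisible(x)
}
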