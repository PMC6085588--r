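#' Single-route selection probability (2PL)
#'
#' Probability that a scored route indicator equals 1 at ability
#' \code{theta}: \code{logistic(alpha * theta - beta)}. The location
#' \code{beta} lives on the logit scale (not the classical
#' \code{alpha * (theta - b)} form; see [location_to_difficulty()]).
#'
#' @param alpha Discrimination.
#' @param beta Location on the logit scale.
#' @param theta Ability.
#' @return Selection probability in (0, 1); vectorized over arguments.
#' @export
p_select <- function(alpha, beta, theta) stats::plogis(alpha * theta - beta)

#' Joint probability of one step's scored response vector
#'
#' Mixture of class-wise conditionally independent Bernoulli products:
#' \code{sum_g gamma_g prod_i p_ig^w_i (1-p_ig)^(1-w_i)} with
#' \code{p_ig = p_select(alpha[i,g], beta[i,g], theta[g])}.
#'
#' @param scored Binary vector of length I.
#' @param params An [mmixirt_params()] bundle (only \code{alpha},
#'   \code{beta}, \code{gamma} are used).
#' @param theta_by_class Ability value at which each class's product is
#'   evaluated, length G (recycled if scalar).
#' @return The joint probability.
#' @export
joint_step_prob <- function(scored, params, theta_by_class) {
  G <- params$G
  theta_by_class <- rep_len(theta_by_class, G)
  total <- 0
  for (g in seq_len(G)) {
    p <- p_select(params$alpha[, g], params$beta[, g], theta_by_class[g])
    total <- total + params$gamma[g] * prod(ifelse(scored == 1L, p, 1 - p))
  }
  total
}

#' Gauss-Hermite quadrature for a standard normal prior
#'
#' Nodes and weights such that \code{sum(w * f(x))} approximates
#' \code{E[f(Z)]} for \code{Z ~ N(0,1)}; weights sum to one.
#'
#' @param n Number of nodes (>= 5 recommended).
#' @return List with numeric \code{x} (nodes) and \code{w} (weights).
#' @export
gh_rule <- function(n) {
  gh <- pracma::gaussHermite(n)
  list(x = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}

# Per-class weights over the fixed standard-normal node grid. The reference
# class keeps the exact Gauss-Hermite weights; a class with moments
# (mu, sigma) reweights the same nodes by the density ratio
# dnorm(x; mu, sigma) / dnorm(x; 0, 1), renormalized. The model actually
# fitted is therefore a discrete-trait model on this grid, which makes the
# EM objective an exact function of the parameters.
class_node_weights <- function(rule, mu, sigma) {
  G <- length(mu)
  W <- matrix(0, length(rule$x), G)
  for (g in seq_len(G)) {
    if (abs(mu[g]) < 1e-12 && abs(sigma[g] - 1) < 1e-12) {
      W[, g] <- rule$w
    } else {
      lw <- log(rule$w) + stats::dnorm(rule$x, mu[g], sigma[g], log = TRUE) -
        stats::dnorm(rule$x, log = TRUE)
      W[, g] <- exp(lw - log_sum_exp(lw))
    }
  }
  W
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

row_log_sum_exp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Per-step log density log f(scored_j | class g, node q) for all (g, q),
# returned as an N x (G*Q) matrix (class-major blocks), plus the node grid.
step_log_density <- function(scored, params, rule) {
  Q <- length(rule$x); G <- ncol(params$alpha)
  out <- matrix(0, nrow(scored), G * Q)
  one_m <- 1 - scored
  for (g in seq_len(G)) {
    eta <- outer(params$alpha[, g], rule$x) - params$beta[, g]  # I x Q
    lp <- stats::plogis(eta, log.p = TRUE)
    lq <- stats::plogis(-eta, log.p = TRUE)
    out[, (g - 1L) * Q + seq_len(Q)] <- scored %*% lp + one_m %*% lq
  }
  out
}

#' Marginal log-likelihood of scored step responses
#'
#' For each step, the class-specific Bernoulli product is integrated over
#' the class ability distribution by Gauss-Hermite quadrature and summed
#' over classes with the mixing proportions; log-sum-exp is used throughout
#' so patterns of extreme probability do not underflow.
#'
#' @param scored Binary matrix (steps x routes) or a single vector.
#' @param params An [mmixirt_params()] bundle.
#' @param quadrature Number of quadrature nodes (default 15).
#' @return Total log-likelihood, with per-step values in attribute
#'   \code{"by_step"}.
#' @export
marginal_step_loglik <- function(scored, params, quadrature = 15L) {
  if (is.null(dim(scored))) scored <- matrix(scored, 1L)
  rule <- gh_rule(quadrature)
  W <- class_node_weights(rule, params$mu, params$sigma)
  Q <- length(rule$x)
  lw <- log(rep(params$gamma, each = Q) * as.vector(W))
  ld <- step_log_density(scored, params, rule)
  by_step <- row_log_sum_exp(sweep(ld, 2L, lw, `+`))
  structure(sum(by_step), by_step = by_step)
}

#' Marginal log-likelihood of final-step responses (student level)
#'
#' Plain 2PL marginal likelihood of each student's final-step scored vector
#' under ability prior N(0, 1) and the student-level item parameters.
#'
#' @param final_scored Binary matrix (students x routes) or vector.
#' @param params An [mmixirt_params()] bundle (uses \code{alpha_B},
#'   \code{beta_B}).
#' @param quadrature Number of quadrature nodes.
#' @return Total log-likelihood with per-student attribute \code{"by_student"}.
#' @export
student_loglik <- function(final_scored, params, quadrature = 15L) {
  if (is.null(dim(final_scored))) final_scored <- matrix(final_scored, 1L)
  rule <- gh_rule(quadrature)
  eta <- outer(params$alpha_B, rule$x) - params$beta_B
  lp <- stats::plogis(eta, log.p = TRUE)
  lq <- stats::plogis(-eta, log.p = TRUE)
  ld <- final_scored %*% lp + (1 - final_scored) %*% lq
  by_student <- row_log_sum_exp(sweep(ld, 2L, log(rule$w), `+`))
  structure(sum(by_student), by_student = by_student)
}

#' Number of free parameters of the mixture model
#'
#' Class-specific discriminations and locations for every class
#' (\code{2 * I * G}), plus, per non-reference class, one mixing logit and
#' a free ability mean and variance (\code{3 * (G - 1)}); the reference
#' class ability is fixed N(0,1) and the student-level item parameters are
#' tied to the reference class, contributing nothing.
#'
#' @param G Number of latent classes.
#' @param I Number of routes (default 23).
#' @param tie_between_to_reference If \code{FALSE}, adds \code{2 * I} for
#'   separate student-level item parameters.
#' @return Integer parameter count.
#' @export
count_free_parameters <- function(G, I = 23L, tie_between_to_reference = TRUE) {
  p <- 2L * I * G + 3L * (G - 1L)
  if (!tie_between_to_reference) p <- p + 2L * I
  as.integer(p)
}
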