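#' Parameter bundle for the multilevel mixture 2PL model
#'
#' Collects all free parameters: class-specific process-level discriminations
#' and locations (on the \code{alpha * theta - beta} logit scale), mixing
#' proportions, per-class ability means and standard deviations (the
#' reference class fixed at N(0,1) for identification), and the
#' student-level item parameters used to score final-step responses. By
#' default the student-level parameters are tied to the reference class.
#'
#' @param alpha,beta Numeric I x G matrices of process-level discriminations
#'   and locations (routes in rows, classes in columns).
#' @param gamma Mixing proportions, length G, non-negative, summing to 1.
#' @param mu,sigma Class ability means/SDs, length G; the reference class
#'   must be (0, 1) and all SDs positive.
#' @param alpha_B,beta_B Student-level item parameters, length I; default
#'   \code{NULL} ties them to the reference class columns of
#'   \code{alpha}/\code{beta}.
#' @param routes Optional route labels (row names).
#' @param reference Index of the reference class (default 1).
#' @return An object of class \code{"mmixirt_params"}.
#' @export
mmixirt_params <- function(alpha, beta, gamma, mu = NULL, sigma = NULL,
                           alpha_B = NULL, beta_B = NULL, routes = NULL,
                           reference = 1L) {
  alpha <- as.matrix(alpha); beta <- as.matrix(beta)
  G <- ncol(alpha); I <- nrow(alpha)
  stopifnot(all(dim(beta) == c(I, G)), length(gamma) == G)
  if (is.null(mu)) mu <- numeric(G)
  if (is.null(sigma)) sigma <- rep(1, G)
  stopifnot(length(mu) == G, length(sigma) == G, all(sigma > 0),
            all(gamma >= 0), abs(sum(gamma) - 1) < 1e-8,
            all(is.finite(alpha)), all(is.finite(beta)))
  if (abs(mu[reference]) > 1e-8 || abs(sigma[reference] - 1) > 1e-8)
    stop("the reference class ability distribution must be N(0, 1)")
  tied <- is.null(alpha_B)
  if (tied) { alpha_B <- alpha[, reference]; beta_B <- beta[, reference] }
  stopifnot(length(alpha_B) == I, length(beta_B) == I)
  if (!is.null(routes)) rownames(alpha) <- rownames(beta) <- routes
  structure(list(alpha = alpha, beta = beta, gamma = as.numeric(gamma),
                 mu = as.numeric(mu), sigma = as.numeric(sigma),
                 alpha_B = alpha_B, beta_B = beta_B,
                 tied = tied, reference = as.integer(reference),
                 G = G, I = I, routes = routes),
            class = "mmixirt_params")
}

#' @export
print.mmixirt_params <- function(x, ...) {
  cat(sprintf("mmixirt parameters: I = %d routes, G = %d class(es)\n",
              x$I, x$G))
  cat("  mixing proportions:", paste(sprintf("%.3f", x$gamma), collapse = " "),
      "\n")
  cat("  class ability: mu =", paste(sprintf("%.2f", x$mu), collapse = " "),
      "; sigma =", paste(sprintf("%.2f", x$sigma), collapse = " "), "\n")
  if (x$tied) cat("  student-level item parameters tied to class",
                  x$reference, "\n")
  invisible(x)
}

#' Convert a class to the standardized within-class ability scale
#'
#' With class-specific item parameters, each non-reference class's ability
#' mean and SD trade off against its discriminations and locations along a
#' likelihood ridge: \code{alpha * (mu + sigma * z) - beta} equals
#' \code{(alpha * sigma) * z - (beta - alpha * mu)}. This helper maps a
#' bundle onto the equivalent parameterization with every class N(0, 1),
#' the canonical scale used when comparing parameter sets.
#'
#' @param params An [mmixirt_params()] bundle.
#' @return An equivalent bundle with \code{mu = 0}, \code{sigma = 1}
#'   everywhere.
#' @export
standardize_params <- function(params) {
  a <- params$alpha; b <- params$beta
  for (g in seq_len(params$G)) {
    b[, g] <- b[, g] - a[, g] * params$mu[g]
    a[, g] <- a[, g] * params$sigma[g]
  }
  mmixirt_params(a, b, params$gamma, alpha_B = params$alpha_B,
                 beta_B = params$beta_B, routes = params$routes,
                 reference = params$reference)
}

#' Permute class labels of a parameter bundle
#'
#' @param params An [mmixirt_params()] bundle.
#' @param perm Permutation of \code{1:G}: new class \code{g} is old class
#'   \code{perm[g]}.
#' @return The relabelled bundle (reference index remapped).
#' @export
permute_classes <- function(params, perm) {
  mmixirt_params(params$alpha[, perm, drop = FALSE],
                 params$beta[, perm, drop = FALSE],
                 params$gamma[perm], params$mu[perm], params$sigma[perm],
                 alpha_B = params$alpha_B, beta_B = params$beta_B,
                 routes = params$routes,
                 reference = which(perm == params$reference))
}

#' Serialize a parameter bundle to JSON
#'
#' Writes a flat key-value representation with explicit class and route
#' labels, readable back with [read_params()].
#'
#' @param params An [mmixirt_params()] bundle.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_params <- function(params, path) {
  obj <- list(I = params$I, G = params$G,
              routes = params$routes %||% paste0("R", seq_len(params$I)),
              alpha = as.data.frame(params$alpha),
              beta = as.data.frame(params$beta),
              gamma = params$gamma, mu = params$mu, sigma = params$sigma,
              alpha_B = params$alpha_B, beta_B = params$beta_B,
              tied = params$tied, reference = params$reference)
  names(obj$alpha) <- names(obj$beta) <- paste0("class", seq_len(params$G))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  mmixirt_params(as.matrix(o$alpha), as.matrix(o$beta), o$gamma, o$mu,
                 o$sigma,
                 alpha_B = if (isTRUE(o$tied)) NULL else o$alpha_B,
                 beta_B = if (isTRUE(o$tied)) NULL else o$beta_B,
                 routes = o$routes, reference = o$reference)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert between logit-location and difficulty parameterizations
#'
#' The model is written as \code{logistic(alpha * theta - beta)}; classical
#' IRT difficulty is \code{b = beta / alpha}.
#'
#' @param alpha,beta Discrimination and location on the logit scale.
#' @return \code{location_to_difficulty} returns \code{b = beta/alpha};
#'   \code{difficulty_to_location} returns \code{beta = alpha * b}.
#' @export
location_to_difficulty <- function(alpha, beta) beta / alpha

#' @rdname location_to_difficulty
#' @param b Classical difficulty.
#' @export
difficulty_to_location <- function(alpha, b) alpha * b
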