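test_that("p_select evaluates the 2PL on the logit-location scale", {
  expect_equal(p_select(1, 0, 0), 0.5)
  expect_equal(p_select(0, 0, 1.7), 0.5)
  expect_equal(p_select(2, 0.5, 1), plogis(1.5))
  expect_equal(p_select(2, 0.5, 1), 0.8175745, tolerance = 1e-7)
  # strictly increasing in theta for positive discrimination
  th <- seq(-4, 4, by = 0.5)
  expect_true(all(diff(p_select(1.3, 0.2, th)) > 0))
})

test_that("joint_step_prob matches brute-force enumeration over classes", {
  p1 <- mmixirt_params(alpha = matrix(0, 4, 1), beta = matrix(0, 4, 1),
                       gamma = 1)
  expect_equal(joint_step_prob(c(1, 0, 1, 1), p1, 0), 0.5^4)

  a <- matrix(c(1, 0.5, 2, 0.7), 2, 2)
  b <- matrix(c(0.2, -0.4, 1, 0), 2, 2)
  p2 <- mmixirt_params(a, b, gamma = c(1, 0))
  th <- c(0.3, -0.2)
  w <- c(1, 0)
  only1 <- prod(plogis(a[, 1] * th[1] - b[, 1])^w *
                (1 - plogis(a[, 1] * th[1] - b[, 1]))^(1 - w))
  expect_equal(joint_step_prob(w, p2, th), only1)

  p3 <- mmixirt_params(a, b, gamma = c(0.6, 0.4))
  manual <- 0
  for (g in 1:2) {
    pr <- plogis(a[, g] * th[g] - b[, g])
    manual <- manual + p3$gamma[g] * prod(pr^w * (1 - pr)^(1 - w))
  }
  expect_equal(joint_step_prob(w, p3, th), manual)
})

test_that("joint_step_prob is a probability mass over response patterns", {
  set.seed(3)
  I <- 6
  pars <- mmixirt_params(matrix(runif(2 * I, 0.5, 2), I, 2),
                         matrix(rnorm(2 * I), I, 2), c(0.3, 0.7))
  th <- c(0.4, -1.1)
  patterns <- as.matrix(expand.grid(rep(list(0:1), I)))
  total <- sum(apply(patterns, 1, joint_step_prob, params = pars,
                     theta_by_class = th))
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("flat items make the marginal likelihood quadrature-free", {
  beta <- c(0.3, -0.7, 1.1)
  pars <- mmixirt_params(matrix(0, 3, 1), matrix(beta, 3, 1), 1)
  w <- c(1, 0, 1)
  closed <- sum(w * plogis(-beta, log.p = TRUE) +
                (1 - w) * log(1 - plogis(-beta)))
  for (Q in c(5, 15, 61))
    expect_equal(as.numeric(marginal_step_loglik(w, pars, Q)), closed,
                 tolerance = 1e-12)
})

test_that("quadrature refinement converges", {
  set.seed(11)
  pars <- mmixirt_params(matrix(runif(4, 0.5, 1.5), 2, 2),
                         matrix(rnorm(4, 0, 0.8), 2, 2), c(0.5, 0.5))
  w <- c(1, 0)
  l15 <- as.numeric(marginal_step_loglik(w, pars, 15))
  l61 <- as.numeric(marginal_step_loglik(w, pars, 61))
  l101 <- as.numeric(marginal_step_loglik(w, pars, 101))
  expect_equal(l15, l61, tolerance = 1e-6)
  expect_lt(abs(l61 - l101), 1e-9)
})

test_that("the marginal likelihood matches the dense-grid oracle", {
  set.seed(42)
  pars <- mmixirt_params(matrix(runif(6, 0.5, 2), 3, 2),
                         matrix(rnorm(6), 3, 2), c(0.6, 0.4))
  for (w in list(c(1, 0, 1), c(0, 0, 0), c(1, 1, 1))) {
    expect_lt(abs(as.numeric(marginal_step_loglik(w, pars, 61)) -
                  dense_marginal_ll(w, pars)), 1e-8)
  }
  # non-reference class with shifted, shrunk ability distribution
  pars2 <- mmixirt_params(pars$alpha, pars$beta, c(0.5, 0.5),
                          mu = c(0, 0.5), sigma = c(1, 0.8))
  expect_lt(abs(as.numeric(marginal_step_loglik(c(1, 1, 0), pars2, 61)) -
                dense_marginal_ll(c(1, 1, 0), pars2)), 1e-8)
})

test_that("the marginal likelihood is invariant to class relabelling", {
  set.seed(5)
  pars <- mmixirt_params(matrix(runif(9, 0.5, 2), 3, 3),
                         matrix(rnorm(9), 3, 3), c(0.5, 0.3, 0.2),
                         mu = c(0, 0.4, -0.6), sigma = c(1, 0.9, 1.2))
  w <- matrix(rbinom(9, 1, 0.5), 3, 3)
  base <- as.numeric(marginal_step_loglik(w, pars, 31))
  # move the reference class to position 2
  perm <- c(2L, 1L, 3L)
  expect_equal(as.numeric(marginal_step_loglik(w, permute_classes(pars, perm),
                                               31)),
               base, tolerance = 1e-12)
})

test_that("student-level marginal 2PL matches flat and grid oracles", {
  pars <- mmixirt_params(matrix(0, 2, 1), matrix(c(0.5, -0.2), 2, 1), 1)
  w <- c(1, 1)
  closed <- sum(plogis(-c(0.5, -0.2), log.p = TRUE))
  expect_equal(as.numeric(student_loglik(w, pars, 15)), closed,
               tolerance = 1e-12)

  pars2 <- mmixirt_params(matrix(c(1.2, 0.8), 2, 1),
                          matrix(c(0.3, -0.5), 2, 1), 1)
  expect_lt(abs(as.numeric(student_loglik(c(1, 0), pars2, 61)) -
                dense_marginal_ll(c(1, 0), pars2)), 1e-8)
  l15 <- as.numeric(student_loglik(c(1, 0), pars2, 15))
  expect_equal(l15, as.numeric(student_loglik(c(1, 0), pars2, 61)),
               tolerance = 1e-7)
})

test_that("free-parameter accounting reproduces the published counts", {
  expect_equal(vapply(1:8, count_free_parameters, 0L, I = 23L),
               c(46L, 95L, 144L, 193L, 242L, 291L, 340L, 389L))
  # untied student-level item parameters add 2I
  expect_equal(count_free_parameters(2, 23, tie_between_to_reference = FALSE),
               95L + 46L)
})

test_that("parameter bundles serialize losslessly to JSON", {
  pars <- example_params(23, 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_params(pars, path)
  back <- read_params(path)
  expect_equal(back$alpha, pars$alpha, ignore_attr = TRUE)
  expect_equal(back$beta, pars$beta, ignore_attr = TRUE)
  expect_equal(back$gamma, pars$gamma)
  expect_true(back$tied)
})

test_that("standardizing a class preserves the likelihood", {
  set.seed(9)
  pars <- mmixirt_params(matrix(runif(6, 0.5, 2), 3, 2),
                         matrix(rnorm(6), 3, 2), c(0.7, 0.3),
                         mu = c(0, 0.8), sigma = c(1, 0.6))
  std <- standardize_params(pars)
  expect_equal(std$mu, c(0, 0))
  expect_equal(std$sigma, c(1, 1))
  w <- c(1, 0, 1)
  expect_equal(as.numeric(marginal_step_loglik(w, std, 101)),
               as.numeric(marginal_step_loglik(w, pars, 101)),
               tolerance = 1e-4)
})
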