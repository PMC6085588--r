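task <- traffic_task()

test_that("information criteria implement AIC, BIC and the adjusted BIC", {
  ic <- information_criteria(-112745.581, 46, 15879)
  expect_equal(unname(ic["AIC"]), 225583.161, tolerance = 1e-8)
  expect_equal(unname(ic["BIC"]), 225936.108, tolerance = 1e-8)
  expect_equal(unname(ic["aBIC"]), 225789.923, tolerance = 1e-8)
  expect_equal(unname(information_criteria(0, 0, 100)), c(0, 0, 0))
})

test_that("entropy is 1 for crisp, 0 for uniform, and matches hand values", {
  crisp <- diag(3)[c(1, 2, 3, 1), ]
  expect_equal(entropy(crisp), 1)
  unif <- matrix(1 / 4, 5, 4)
  expect_equal(entropy(unif), 0)
  expect_equal(entropy(matrix(c(0.8, 0.2), 1)), 0.2780719,
               tolerance = 1e-6)
  expect_true(is.na(entropy(matrix(1, 4, 1))))
})

test_that("average posterior matrix averages within modal classes", {
  crisp <- diag(2)[c(1, 2, 2), ]
  expect_equal(unname(average_posterior_matrix(crisp, c(1, 2, 2))),
               diag(2))
  post <- rbind(c(0.7, 0.3), c(0.6, 0.4))
  m <- average_posterior_matrix(post, c(1, 1))
  expect_equal(unname(m[1, ]), c(0.65, 0.35))
  expect_true(all(is.na(m[2, ])))   # empty modal class
  expect_equal(sum(m[1, ]), 1)
})

test_that("EAP abilities collapse to the prior mean for flat items", {
  pars <- mmixirt_params(matrix(0, 23, 1), matrix(0, 23, 1), 1,
                         routes = task$routes)
  ev <- parse_log(toy_log(c("01000000000000000000000",
                            "11000000000000000000000")), task)
  data <- build_step_matrix(ev, task)
  eap <- eap_abilities(data, pars)
  expect_equal(eap$process, c(0, 0), tolerance = 1e-10)
  expect_equal(unname(eap$student), 0, tolerance = 1e-10)
})

test_that("one-item EAP matches the fine-grid posterior mean", {
  one <- task_spec("R1", rbind(c("A", "B")), 5, "R1", 5)
  pars <- mmixirt_params(matrix(1, 1, 1), matrix(0, 1, 1), 1)
  ev <- parse_log(toy_log("1", id = "s1"), one)
  data <- build_step_matrix(ev, one)
  eap <- eap_abilities(data, pars, quadrature = 61)
  th <- seq(-12, 12, length.out = 400001)
  post <- plogis(th) * dnorm(th)
  oracle <- pracma::trapz(th, th * post) / pracma::trapz(th, post)
  expect_equal(eap$process, oracle, tolerance = 1e-6)
  expect_equal(unname(eap$student), oracle, tolerance = 1e-6)
})

test_that("students sharing a final-step pattern get identical ability", {
  pars <- example_params(23, 1)
  states <- paste(as.integer(task$routes %in% task$correct_set),
                  collapse = "")
  log <- rbind(toy_log(c(strrep("0", 23), states), id = "a"),
               toy_log(states, id = "b", t0 = 500))
  data <- build_step_matrix(parse_log(log, task), task)
  eap <- eap_abilities(data, pars)
  expect_equal(unname(eap$student["a"]), unname(eap$student["b"]),
               tolerance = 1e-12)
})

test_that("the EM log-likelihood trace is monotone and the optimum is
           consistent with the marginal likelihood", {
  sim <- simulate_mmixirt(task, example_params(23, 2), n_students = 40,
                          step_mean = 8, seed = 3)
  fit <- mmixirt(sim$data, classes = 2, starts = 2, seed = 3)
  expect_true(all(diff(fit$ll_trace) >= -1e-8))
  # the fitted loglik equals the marginal likelihood of the relabelled
  # parameters (label permutation leaves the mixture invariant)
  ll <- as.numeric(marginal_step_loglik(sim$data$scored, fit$params,
                                        fit$quadrature))
  expect_equal(fit$loglik, ll, tolerance = 1e-10)
  expect_true(all(abs(rowSums(fit$posteriors) - 1) < 1e-10))
  expect_equal(fit$n_params, 95L)
})

test_that("label permutations leave the fit invariant up to relabelling", {
  sim <- simulate_mmixirt(task, example_params(23, 2), n_students = 60,
                          step_mean = 10, seed = 8)
  f1 <- mmixirt(sim$data, classes = 2, starts = 2, seed = 8)
  expect_true(all(diff(f1$params$gamma) <= 0))
  # swapping class labels changes nothing observable: same likelihood,
  # and the canonical order (descending gamma) restores the original bundle
  swapped <- permute_classes(f1$params, 2:1)
  expect_equal(as.numeric(marginal_step_loglik(sim$data$scored, swapped,
                                               f1$quadrature)),
               f1$loglik, tolerance = 1e-12)
  back <- permute_classes(swapped, order(-swapped$gamma, swapped$mu))
  expect_equal(back$alpha, f1$params$alpha, ignore_attr = TRUE)
  expect_equal(back$gamma, f1$params$gamma)
})

test_that("a well-separated three-class fit classifies crisply", {
  sim <- simulate_mmixirt(task, example_params(23, 3), n_students = 90,
                          step_mean = 12, seed = 21)
  fit <- mmixirt(sim$data, classes = 3, starts = 4, seed = 21)
  expect_gt(min(diag(fit$avg_posterior)), 0.9)
  expect_gt(fit$entropy, 0.8)
})

test_that("degenerate all-ones data drives locations to the boundary", {
  states <- paste(as.integer(task$routes %in% task$correct_set),
                  collapse = "")
  log <- do.call(rbind, lapply(1:8, function(k)
    toy_log(rep(states, 4), id = paste0("s", k), t0 = 100 * k)))
  data <- build_step_matrix(parse_log(log, task), task)
  expect_warning(fit <- mmixirt(data, classes = 1, starts = 1, seed = 1,
                                max_iter = 200),
                 "boundary")
  expect_true(fit$boundary)
  expect_lt(max(fit$params$beta), -5)
})

test_that("class-count selection assembles the comparison table", {
  sim <- simulate_mmixirt(task, example_params(23, 2), n_students = 50,
                          step_mean = 8, seed = 5)
  tab <- select_classes(sim$data, classes = 1:2, starts = 2, seed = 5)
  expect_equal(tab$classes, 1:2)
  expect_equal(tab$n_params, c(46L, 95L))
  expect_true(all(c("loglik", "AIC", "BIC", "aBIC", "entropy") %in%
                  names(tab)))
  expect_lt(tab$BIC[2], tab$BIC[1])
  expect_true(is.na(tab$entropy[1]))
  # IC are consistent with (loglik, p, N1) by formula
  expect_equal(tab$BIC[2],
               unname(information_criteria(tab$loglik[2], 95,
                                           n_steps(sim$data))["BIC"]))
})
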