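# Dense-grid (trapezoid) oracle for the marginal step log-likelihood:
# class-sum x brute-force integration, independent of the package's
# Gauss-Hermite path.
dense_marginal_ll <- function(w, params, n = 400001L, lim = 14) {
  th <- seq(-lim, lim, length.out = n)
  tot <- 0
  for (g in seq_len(params$G)) {
    f <- rep(1, n)
    for (i in seq_along(w)) {
      pi <- stats::plogis(params$alpha[i, g] * th - params$beta[i, g])
      f <- f * (if (w[i] == 1) pi else 1 - pi)
    }
    dens <- stats::dnorm(th, params$mu[g], params$sigma[g])
    tot <- tot + params$gamma[g] * pracma::trapz(th, f * dens)
  }
  log(tot)
}

# Small synthetic map for signature-pruning tests: R1-R2-R3 chain A-B-C-D
# (the correct path), R4 isolated (E-F), R5 isolated pair partner (F-G).
toy_task <- function() {
  task_spec(route_labels = paste0("R", 1:5),
            endpoints = rbind(c("A", "B"), c("B", "C"), c("C", "D"),
                              c("E", "F"), c("G", "H")),
            travel_time = c(2, 3, 5, 4, 6),
            correct_set = c("R1", "R2", "R3"),
            target_time = 10)
}

# Minimal hand-written log table in the PISA dialect.
toy_log <- function(states, id = "s1", t0 = 100) {
  n <- length(states)
  data.frame(
    id = id,
    event = c("start_item", rep("ACER_EVENT", n), "end_item"),
    time = c(t0 - 1, t0 + seq_len(n), t0 + n + 1),
    event_value = c("", paste0("'", states), ""),
    stringsAsFactors = FALSE)
}

fixture_path <- function() {
  system.file("extdata", "traffic_log_student17.csv", package = "mmixirt",
              mustWork = TRUE)
}
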