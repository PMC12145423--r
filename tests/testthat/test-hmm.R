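test_that("single-state model collapses to empirical presence frequencies", {
  set.seed(1)
  y <- matrix(rbinom(200 * 4, 1, c(0.1, 0.4, 0.7, 0.9)), ncol = 4,
              byrow = TRUE)
  calls <- make_calls(y)
  fit <- gp_fit(calls, k = 1, seed = 2)
  expect_equal(as.numeric(fit$emission), colMeans(y), tolerance = 1e-8)
  expect_equal(fit$transition, matrix(1, 1, 1))
  # closed-form independent-Bernoulli likelihood at the fitted parameters
  closed <- sum(dbinom(y, 1, rep(pmin(pmax(colMeans(y), 1e-6), 1 - 1e-6),
                                 each = nrow(y)), log = TRUE))
  expect_equal(gp_loglik(fit, calls), closed, tolerance = 1e-6)
})

test_that("posterior, likelihood and expected counts match path enumeration", {
  set.seed(33)
  for (case in 1:4) {
    k <- sample(2:3, 1)
    Tn <- sample(4:8, 1)
    D <- sample(1:3, 1)
    emission <- matrix(runif(k * D, 0.05, 0.95), k, D)
    transition <- matrix(rgamma(k * k, 2), k, k)
    transition <- transition / rowSums(transition)
    initial <- rgamma(k, 2); initial <- initial / sum(initial)
    y <- matrix(rbinom(Tn * D, 1, 0.5), Tn, D)
    oracle <- enum_hmm(y, emission, transition, initial)

    model <- make_model(emission, transition, initial,
                        marks = rep("m", D)[1])
    # D tracks of one mark: rebuild track frame consistent with y's columns
    calls <- make_calls(y)
    model$tracks <- calls$tracks
    colnames(model$emission) <- calls$tracks$track_id
    expect_equal(gp_loglik(model, calls), oracle$loglik, tolerance = 1e-10)
    post <- gp_posterior(model, calls)
    expect_equal(post, oracle$posterior, tolerance = 1e-10)
    expect_equal(rowSums(post), rep(1, Tn), tolerance = 1e-9)
    # E-step expected transition counts from the compiled kernel
    lb <- globpat:::emission_loglik(y, emission)
    fb <- globpat:::.fb_chain(lb, initial, transition)
    expect_equal(fb$xi, oracle$xi, tolerance = 1e-10)
  }
})

test_that("permuting state labels permutes posterior columns identically", {
  set.seed(5)
  emission <- matrix(runif(6, 0.1, 0.9), 3, 2)
  transition <- matrix(rgamma(9, 3), 3); transition <- transition / rowSums(transition)
  initial <- c(0.2, 0.3, 0.5)
  y <- matrix(rbinom(20, 1, 0.5), 10, 2)
  calls <- make_calls(y)
  m1 <- make_model(emission, transition, initial)
  m1$tracks <- calls$tracks; colnames(m1$emission) <- calls$tracks$track_id
  perm <- c(3, 1, 2)
  m2 <- make_model(emission[perm, ], transition[perm, perm], initial[perm])
  m2$tracks <- calls$tracks; colnames(m2$emission) <- calls$tracks$track_id
  expect_equal(gp_posterior(m2, calls), gp_posterior(m1, calls)[, perm],
               tolerance = 1e-12)
})

test_that("EM log-likelihood is non-decreasing and parameters stay stochastic", {
  cfg <- synth_config(n_individuals = 8, n_bins = 4000, n_chroms = 2,
                      n_states_true = 3, seed = 6)
  tr <- simulate_truth(cfg)
  sim <- simulate_counts(tr, cfg)
  calls <- binary_call_matrix(sim$presence, tr$bins,
                              tr$tracks[, c("individual", "mark")])
  fit <- gp_fit(calls, 3, seed = 4, tol = 1e-7)
  expect_true(all(diff(fit$trace) >= -1e-8 * abs(fit$trace[-1])))
  expect_equal(sum(fit$initial), 1, tolerance = 1e-9)
  expect_equal(rowSums(fit$transition), rep(1, 3), tolerance = 1e-9)
  expect_true(all(fit$emission >= 1e-6 & fit$emission <= 1 - 1e-6))
})

test_that("well-separated synthetic states are recovered", {
  arch <- emission_architecture(4, 12, "H3K27ac", p_on = 0.9, p_off = 0.05,
                                seed = 2)
  cfg <- synth_config(n_individuals = 12, n_bins = 2e4, n_chroms = 2,
                      n_states_true = 4, emission_arch = arch, seed = 10)
  tr <- simulate_truth(cfg)
  sim <- simulate_counts(tr, cfg)
  calls <- binary_call_matrix(sim$presence, tr$bins,
                              tr$tracks[, c("individual", "mark")])
  fit <- gp_fit(calls, 4, seed = 1, tol = 1e-6, restarts = 3)
  m <- match_to_truth(fit, tr)
  expect_lte(m$max_err, 0.05)
  ann <- gp_annotate(fit, calls)
  expect_gte(mean(m$perm[ann$state] == tr$state_path), 0.9)
})

test_that("fits with different seeds agree up to state relabeling", {
  arch <- emission_architecture(3, 10, "H3K27ac", p_on = 0.9, p_off = 0.05,
                                seed = 5)
  cfg <- synth_config(n_individuals = 10, n_bins = 1.5e4, n_chroms = 1,
                      n_states_true = 3, emission_arch = arch, seed = 3)
  tr <- simulate_truth(cfg)
  sim <- simulate_counts(tr, cfg)
  calls <- binary_call_matrix(sim$presence, tr$bins,
                              tr$tracks[, c("individual", "mark")])
  f1 <- gp_fit(calls, 3, seed = 101, tol = 1e-6, restarts = 2)
  f2 <- gp_fit(calls, 3, seed = 202, tol = 1e-6, restarts = 2)
  m <- greedy_match_states(f1, f2)
  expect_gte(min(m$pairs$rho), 0.99)
})

test_that("annotation is the posterior argmax with smallest-id tie-break", {
  # two identical states: posteriors tie, smaller id must win
  emission <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  y <- matrix(rbinom(16, 1, 0.5), 8, 2)
  calls <- make_calls(y)
  model <- make_model(emission)
  model$tracks <- calls$tracks; colnames(model$emission) <- calls$tracks$track_id
  ann <- gp_annotate(model, calls)
  expect_true(all(ann$state == 1L))
  # k = 1: everything state 1
  m1 <- gp_fit(calls, 1, seed = 1)
  expect_true(all(gp_annotate(m1, calls)$state == 1L))
  expect_true(all(gp_posterior(m1, calls) == 1))
})

test_that("high self-transition smooths identical observations into runs", {
  emission <- rbind(c(0.9, 0.9), c(0.1, 0.1))
  transition <- rbind(c(0.95, 0.05), c(0.05, 0.95))
  y <- rbind(matrix(1, 5, 2), matrix(0, 5, 2))
  calls <- make_calls(y)
  model <- make_model(emission, transition, c(0.5, 0.5))
  model$tracks <- calls$tracks; colnames(model$emission) <- calls$tracks$track_id
  ann <- gp_annotate(model, calls)
  expect_identical(ann$state, c(rep(1L, 5), rep(2L, 5)))
})

test_that("subset decoding with the full track set is the identity", {
  arch <- emission_architecture(3, 6, c("m1", "m2"), p_on = 0.9,
                                p_off = 0.05, seed = 7)
  cfg <- synth_config(n_individuals = 6, marks = c("m1", "m2"),
                      n_bins = 6000, n_chroms = 1, n_states_true = 3,
                      emission_arch = arch, seed = 2)
  tr <- simulate_truth(cfg)
  sim <- simulate_counts(tr, cfg)
  calls <- binary_call_matrix(sim$presence, tr$bins,
                              tr$tracks[, c("individual", "mark")])
  fit <- gp_fit(calls, 3, seed = 5, tol = 1e-6, restarts = 2)
  sd_full <- gp_subset_decode(fit, calls, seq_len(12))
  present <- sort(unique(gp_annotate(fit, calls)$state))
  expect_equal(diag(sd_full$confusion)[present], rep(1, length(present)),
               ignore_attr = TRUE)
  expect_equal(sd_full$recovery, 1)
  expect_error(gp_subset_decode(fit, calls, integer(0)), "nonempty")
})

test_that("dropping the only discriminating tracks spreads confusion mass", {
  # states 1 and 2 differ only in track 3
  emission <- rbind(c(0.9, 0.1, 0.9), c(0.9, 0.1, 0.05),
                    c(0.05, 0.9, 0.5))
  transition <- matrix(1 / 3, 3, 3)
  set.seed(9)
  state <- sample(1:3, 3000, replace = TRUE)
  y <- matrix(rbinom(3000 * 3, 1, emission[state, ]), 3000, 3)
  calls <- make_calls(y)
  model <- make_model(emission, transition)
  model$tracks <- calls$tracks; colnames(model$emission) <- calls$tracks$track_id
  sub <- gp_subset_decode(model, calls, 1:2)
  # the indistinct pair collapses onto the smaller state id (posterior ties
  # break to the smallest id); the distinct state stays recovered
  expect_gt(sub$confusion[1, 1] + sub$confusion[1, 2], 0.8)
  expect_gt(sub$confusion[2, 1] + sub$confusion[2, 2], 0.8)
  expect_lt(sub$confusion[2, 2], 0.2)
  expect_gt(sub$confusion[2, 1], 0.6)
  expect_gt(sub$confusion[3, 3], 0.9)
})

test_that("model serialization round-trips through TSV + JSON", {
  arch <- emission_architecture(2, 4, "H3K27ac", seed = 3)
  cfg <- synth_config(n_individuals = 4, n_bins = 1000, n_chroms = 1,
                      n_states_true = 2, emission_arch = arch, seed = 2)
  tr <- simulate_truth(cfg)
  sim <- simulate_counts(tr, cfg)
  calls <- binary_call_matrix(sim$presence, tr$bins,
                              tr$tracks[, c("individual", "mark")])
  fit <- gp_fit(calls, 2, seed = 1)
  prefix <- file.path(tempdir(), "gp_test")
  write_model(fit, prefix)
  back <- read_model(prefix, fit$tracks[, c("individual", "mark")])
  expect_equal(unname(back$emission), unname(fit$emission), tolerance = 1e-12)
  expect_equal(back$transition, unname(fit$transition), tolerance = 1e-12)
  expect_equal(back$initial, fit$initial, tolerance = 1e-12)
  expect_equal(back$loglik, fit$loglik, tolerance = 1e-9)
  # posteriors from the deserialized model are usable
  expect_equal(gp_posterior(back, calls), gp_posterior(fit, calls),
               tolerance = 1e-9)
})

test_that("simulate() draws data the model can be re-fit on", {
  emission <- rbind(c(0.9, 0.9, 0.1, 0.1), c(0.1, 0.1, 0.9, 0.9))
  transition <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  model <- make_model(emission, transition, c(0.5, 0.5))
  sim <- simulate(model, nsim = 5000, seed = 4)
  refit <- gp_fit(sim, 2, seed = 1, tol = 1e-6)
  m <- greedy_match_states(refit$emission, emission)
  expect_lte(max(abs(refit$emission[m$pairs$state_a, ] -
                     emission[m$pairs$state_b, ])), 0.05)
})

test_that("degenerate and invalid fits are handled", {
  y <- matrix(1L, 10, 2)
  calls <- make_calls(y)
  expect_warning(gp_fit(calls, 2, seed = 1), "duplicate states")
  expect_error(gp_fit(calls, 50, seed = 1), "exceeds")
  y2 <- matrix(rbinom(20, 1, 0.5), 10, 2)
  calls2 <- make_calls(y2)
  fit <- gp_fit(calls2, 2, seed = 1)
  bad <- make_calls(y2[, 1, drop = FALSE])
  expect_error(gp_posterior(fit, bad), "tracks")
})
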