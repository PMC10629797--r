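test_that("greedy optimization recovers the generating order (vs enumeration)", {
  set.seed(21)
  g <- event_grid(paste0("r", 1:3), z_events = 1, z_max = 5)  # E = 3
  s_true <- c(2L, 3L, 1L)
  # noise-free subjects spread over all stages
  G <- sustainr:::traj_matrix(s_true, g)
  X <- t(G[, rep(1:4, each = 50)])
  colnames(X) <- g$regions
  opt <- optimize_sequence(X, g, n_startpoints = 5)
  oracle <- oracle_best_sequence(X, g)
  expect_equal(opt$seq, oracle$seq)
  expect_equal(opt$seq, s_true)
  expect_equal(opt$loglik, oracle$loglik, tolerance = 1e-9)

  # flat landscape: a single stage-0 subject still returns a valid sequence
  opt0 <- optimize_sequence(matrix(0, 1, 3,
                                   dimnames = list(NULL, g$regions)), g,
                            n_startpoints = 3)
  expect_true(validate_sequence(opt0$seq, g))

  # determinism under the seed
  set.seed(5); a <- optimize_sequence(X, g, n_startpoints = 5)
  set.seed(5); b <- optimize_sequence(X, g, n_startpoints = 5)
  expect_identical(a, b)
})

test_that("fit_sustain reduces to optimize_sequence at C = 1", {
  set.seed(22)
  g <- event_grid(paste0("r", 1:3), z_events = 1, z_max = 5)
  sim <- simulate_zscores(100, g, list(c(1L, 2L, 3L)), 1, sigma_gen = 0.8)
  cfg <- run_config(n_startpoints = 10)
  set.seed(1); m <- fit_sustain(sim$z, g, 1, cfg)
  set.seed(1); opt <- optimize_sequence(sim$z, g, n_startpoints = 10)
  expect_equal(m$sequences[[1]], opt$seq)
  expect_equal(m$loglik, opt$loglik)
  expect_equal(m$f, 1)
})

test_that("single-sequence data yields a degenerate 2-subtype fit", {
  set.seed(23)
  g <- event_grid(paste0("r", 1:5), z_events = 1, z_max = 5)
  s <- random_valid_sequence(g)
  sim <- simulate_zscores(300, g, list(s), 1, sigma_gen = 0.5)
  m <- suppressMessages(fit_sustain(sim$z, g, 2, run_config(n_startpoints = 8)))
  # fractions collapse or the sequences duplicate
  tau <- kendall_tau(m$sequences[[1]], m$sequences[[2]])
  expect_true(min(m$f) < 0.15 || tau > 0.9)
})

test_that("two well-separated subtypes are recovered", {
  set.seed(24)
  g <- event_grid(paste0("r", 1:6), z_events = 1, z_max = 5)
  s1 <- c(1L, 2L, 3L, 4L, 5L, 6L)
  s2 <- c(6L, 5L, 4L, 3L, 2L, 1L)
  sim <- simulate_zscores(400, g, list(s1, s2), c(0.6, 0.4), sigma_gen = 0.8)
  m <- suppressMessages(fit_sustain(sim$z, g, 2, run_config(n_startpoints = 8)))
  mp <- match_subtypes(m$sequences, list(s1, s2))
  expect_true(all(abs(m$f[mp] - c(0.6, 0.4)) < 0.1))
  expect_gt(kendall_tau(m$sequences[[mp[1]]], s1), 0.8)
  expect_gt(kendall_tau(m$sequences[[mp[2]]], s2), 0.8)
})

test_that("EM refinement never decreases the dataset log-likelihood", {
  set.seed(25)
  g <- event_grid(paste0("r", 1:4), z_events = 1, z_max = 5)
  sim <- simulate_zscores(150, g,
                          list(c(1L, 2L, 3L, 4L), c(4L, 3L, 2L, 1L)),
                          c(0.5, 0.5), sigma_gen = 1)
  cfg <- run_config(n_startpoints = 5)
  m1 <- fit_sustain(sim$z, g, 1, cfg)
  m2 <- suppressMessages(fit_sustain(sim$z, g, 2, cfg))
  expect_gte(m2$loglik, m1$loglik - 1e-9)

  # label switching leaves the likelihood unchanged
  ll_a <- dataset_log_likelihood(sim$z, m2$sequences, m2$f, g)
  ll_b <- dataset_log_likelihood(sim$z, rev(m2$sequences), rev(m2$f), g)
  expect_equal(ll_a, ll_b, tolerance = 1e-12)
})

test_that("MCMC behaves: acceptance, PVD normalization, modal sequence", {
  set.seed(26)
  g <- event_grid(paste0("r", 1:3), z_events = 1, z_max = 5)
  s_true <- c(3L, 1L, 2L)
  sim <- simulate_zscores(500, g, list(s_true), 1, sigma_gen = 0.3)
  cfg <- run_config(n_startpoints = 5)
  m <- fit_sustain(sim$z, g, 1, cfg)
  m <- suppressMessages(mcmc_sample(sim$z, m, n_iter = 4000, config = cfg))

  expect_gt(m$samples$accept_rate_seq, 0)
  expect_lt(m$samples$accept_rate_seq, 1)
  P <- positional_variance(m)[[1]]
  expect_true(all(abs(rowSums(P) - 1) < 1e-12))

  # modal sampled sequence equals the enumeration argmax
  oracle <- oracle_best_sequence(sim$z, g)
  keys <- apply(m$samples$seq, 1, paste, collapse = "-")
  modal <- as.integer(strsplit(names(which.max(table(keys))), "-")[[1]])
  expect_equal(modal, oracle$seq)
  # and the PVD argmax positions reproduce the enumeration-optimal order
  expect_equal(order(apply(P, 1, which.max)), oracle$seq)

  expect_error(mcmc_sample(sim$z, m, n_iter = 50, config = cfg),
               "uninformative")
  expect_error(positional_variance(fit_sustain(sim$z, g, 1, cfg)),
               "no MCMC samples")
})

test_that("MCMC on zero-information data flattens the PVD", {
  # all subjects exactly at stage 0: every valid sequence has identical
  # likelihood, the chain accepts everything, and each PVD row approaches
  # the uniform distribution over positions (total variation < 0.1)
  set.seed(28)
  g <- event_grid(paste0("r", 1:3), z_events = 1, z_max = 5)
  X <- matrix(0, 50, 3, dimnames = list(NULL, g$regions))
  cfg <- run_config(n_startpoints = 3)
  m <- fit_sustain(X, g, 1, cfg)
  m <- suppressMessages(mcmc_sample(X, m, n_iter = 50000, config = cfg,
                                    store_samples = FALSE))
  expect_gt(m$samples$accept_rate_seq, 0.99)
  P <- positional_variance(m)[[1]]
  tv <- 0.5 * rowSums(abs(P - 1 / 3))
  expect_true(all(tv < 0.1))
})

test_that("subject posteriors: assignment rule, boundaries, stage zero", {
  set.seed(27)
  g <- event_grid(paste0("r", 1:4), z_events = 1, z_max = 5)
  s1 <- c(1L, 2L, 3L, 4L); s2 <- c(4L, 3L, 2L, 1L)
  model <- sustainr:::new_sustain_model(list(s1, s2), c(0.5, 0.5),
                                        NA_real_, g, 1)

  # deep subtype-2 subject is assigned subtype 2
  G2 <- sustainr:::traj_matrix(s2, g)
  deep <- matrix(G2[, 4], 1, dimnames = list(NULL, g$regions))
  p <- subject_posteriors(deep, model)
  expect_equal(p$assigned_subtype, 2L)
  expect_false(p$stage_zero)

  # exactly 0.5/0.5 membership stays unclassified (strict > cutoff)
  model_dup <- sustainr:::new_sustain_model(list(s1, s1), c(0.5, 0.5),
                                            NA_real_, g, 1)
  p2 <- subject_posteriors(deep, model_dup)
  expect_equal(p2$prob_subtype1, 0.5)
  expect_true(is.na(p2$assigned_subtype))

  # all-zero subject: stage-zero flag, unassigned
  zero <- matrix(0, 1, 4, dimnames = list(NULL, g$regions))
  p3 <- subject_posteriors(zero, model)
  expect_true(p3$stage_zero)
  expect_true(is.na(p3$assigned_subtype))
  expect_lt(p3$weighted_stage, 0.5)

  # weighted stage bounds and membership normalization on random data
  X <- matrix(rnorm(40, 1), 10, 4, dimnames = list(NULL, g$regions))
  p4 <- subject_posteriors(X, model)
  expect_true(all(p4$weighted_stage >= 0 & p4$weighted_stage <= g$E))
  expect_equal(p4$prob_subtype1 + p4$prob_subtype2, rep(1, 10),
               tolerance = 1e-12)
})
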