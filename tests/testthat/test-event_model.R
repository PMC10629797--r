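test_that("sequence validation matches brute-force enumeration", {
  g1 <- event_grid("r1", z_events = c(1, 2))
  expect_true(validate_sequence(c(1L, 2L), g1))     # z=1 before z=2
  expect_false(validate_sequence(c(2L, 1L), g1))    # higher threshold first
  expect_error(validate_sequence(c(1L, 1L), g1), "permutation")

  # 2 regions x 2 thresholds: exactly C(4,2) = 6 of the 24 permutations valid
  g2 <- event_grid(c("a", "b"), z_events = c(1, 2))
  valid <- all_valid_sequences(g2)
  expect_length(valid, 6)
  for (s in valid) expect_true(validate_sequence(s, g2))
})

test_that("random valid sequences are valid and cover the space", {
  set.seed(7)
  g <- event_grid(c("a", "b"), z_events = c(1, 2))
  draws <- replicate(300, paste(random_valid_sequence(g), collapse = "-"))
  for (s in unique(draws))
    expect_true(validate_sequence(as.integer(strsplit(s, "-")[[1]]), g))
  expect_equal(length(unique(draws)), 6)   # all linear extensions reached
})

test_that("trajectories interpolate through the event anchors", {
  g <- event_grid(c("a", "b"), z_events = c(1, 2), z_max = 5)  # E = 4
  # order: a_z1, a_z2, b_z1, b_z2 -> a's z=1 at position 1, z=2 at 2
  s <- c(1L, 2L, 3L, 4L)
  expect_equal(trajectory_value("a", 0, s, g), 0)   # baseline anchor
  expect_equal(trajectory_value("a", 1, s, g), 1)
  expect_equal(trajectory_value("a", 2, s, g), 2)
  expect_equal(trajectory_value("a", 4, s, g), 5)   # terminal anchor
  # b's z=1 sits at position 3: halfway there g = 0.5 at ... position 1.5;
  # integer stages: g(3) = 1, and between (0,0)-(3,1): g(1) = 1/3
  expect_equal(trajectory_value("b", 1, s, g), 1 / 3)
  expect_equal(trajectory_value("b", 3, s, g), 1)
  # region whose z=1 event is at position 2 in an E=4 grid: g(1) = 0.5
  g2 <- event_grid(c("a", "b"), z_events = 1, z_max = 5)
  g2b <- event_grid(c("a", "b", "c", "d"), z_events = 1, z_max = 5)
  s2 <- c(2L, 1L, 3L, 4L)                 # region a's event at position 2
  expect_equal(trajectory_value("a", 1, s2, g2b), 0.5)
  expect_equal(trajectory_value("a", 2, s2, g2b), 1)
  expect_error(trajectory_value("a", 5, s2, g2b), "outside")

  # matches the independent approx() oracle on random grids
  set.seed(8)
  for (rep in 1:5) {
    gg <- event_grid(paste0("r", 1:3), z_events = c(1, 2, 3), z_max = 5)
    s <- random_valid_sequence(gg)
    expect_equal(sustainr:::traj_matrix(s, gg), oracle_traj(s, gg),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("plateau anchor is dropped when the last event sits at stage E", {
  g <- event_grid("a", z_events = c(1, 2))  # E = 2; z=2 event at position E
  G <- sustainr:::traj_matrix(c(1L, 2L), g)
  expect_equal(unname(G[1, ]), c(0, 1, 2))  # ends at threshold, not z_max
})

test_that("stage likelihoods match a hand-computed oracle", {
  g <- event_grid(c("a", "b"), z_events = 1, z_max = 5)   # E = 2
  s <- c(1L, 2L)
  x <- c(0.4, -0.3)
  sl <- stage_likelihoods(x, s, g, sigma = 1)
  # independent arithmetic: anchors a: (0,0),(1,1),(2,5); b: (0,0),(2,1)
  G <- rbind(c(0, 1, 5), c(0, 0.5, 1))
  direct <- vapply(1:3, function(k)
    sum(dnorm(x, G[, k], 1, log = TRUE)), numeric(1))
  expect_equal(unname(sl$loglik), direct, tolerance = 1e-12)
  m <- max(direct)
  expect_equal(sl$marginal, m + log(sum(exp(direct - m))) - log(3),
               tolerance = 1e-12)
  expect_equal(sum(sl$posterior), 1, tolerance = 1e-12)

  # all-zero subject -> stage 0 is the mode
  expect_equal(which.max(stage_likelihoods(c(0, 0), s, g)$posterior), 1L)
  # subject on the terminal trajectory with small noise -> mass at stage E
  xe <- c(5, 1)
  post <- stage_likelihoods(xe, s, g, sigma = 0.1)$posterior
  expect_gt(post[3], 0.999)
  expect_error(stage_likelihoods(x, s, g, sigma = 0), "sigma")
})

test_that("dataset log-likelihood: collapse, invariance, exhaustive oracle", {
  set.seed(9)
  g <- event_grid(c("a", "b"), z_events = 1, z_max = 5)
  s1 <- c(1L, 2L); s2 <- c(2L, 1L)
  X <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))

  ll1 <- dataset_log_likelihood(X, list(s1), 1, g)
  # mixture with one component equals the plain sum of subject logliks
  expect_equal(ll1, sum(vapply(1:5, function(j)
    oracle_subject_loglik(X[j, ], s1, g), numeric(1))), tolerance = 1e-10)
  # duplicated subtype: any fractions give the single-subtype value
  expect_equal(dataset_log_likelihood(X, list(s1, s1), c(0.3, 0.7), g), ll1,
               tolerance = 1e-10)
  # full brute-force (sequence, stage) enumeration
  expect_equal(dataset_log_likelihood(X, list(s1, s2), c(0.4, 0.6), g),
               oracle_dataset_loglik(X, list(s1, s2), c(0.4, 0.6), g),
               tolerance = 1e-10)
  expect_error(dataset_log_likelihood(X, list(s1, s2), c(0.4, 0.4), g),
               "sum to 1")
})

test_that("model properties: normalization, monotonicity, equivariance, identifiability", {
  set.seed(10)
  g <- event_grid(paste0("r", 1:3), z_events = c(1, 2), z_max = 5)
  for (rep in 1:10) {
    s <- random_valid_sequence(g)
    x <- rnorm(3, sd = 3)
    expect_equal(sum(stage_likelihoods(x, s, g)$posterior), 1,
                 tolerance = 1e-12)
    G <- sustainr:::traj_matrix(s, g)
    expect_true(all(diff(t(G)) >= -1e-12))          # non-decreasing stages
  }

  # permutation equivariance: relabel regions and permute data columns
  s <- random_valid_sequence(g)
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, g$regions))
  perm <- c(3, 1, 2)
  g_p <- event_grid(g$regions[perm], z_events = c(1, 2), z_max = 5)
  # map each event to its new index under the region relabelling
  key <- paste(g$events$region, g$events$threshold)
  key_p <- paste(g_p$events$region, g_p$events$threshold)
  s_p <- match(key[s], key_p)
  expect_equal(dataset_log_likelihood(X, list(s), 1, g),
               dataset_log_likelihood(X[, perm], list(s_p), 1, g_p),
               tolerance = 1e-12)

  # noise-free identifiability: exact trajectory data recovers its stage
  G <- sustainr:::traj_matrix(s, g)
  for (k in 0:g$E) {
    post <- stage_likelihoods(G[, k + 1], s, g, sigma = 1)$posterior
    expect_equal(which.max(post) - 1L, k)
  }
})
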