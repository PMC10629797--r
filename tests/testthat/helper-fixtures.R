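# Shared fixtures and independent oracles. The enumeration oracle is pure
# R and independent of the greedy/MCMC code paths it is used to check.

# all valid sequences of a grid by brute-force permutation filtering
all_valid_sequences <- function(grid) {
  perms <- function(v) {
    if (length(v) <= 1) return(matrix(v, nrow = 1))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], perms(v[-i]))))
  }
  P <- perms(seq_len(grid$E))
  keep <- apply(P, 1, function(s) {
    pos <- integer(grid$E)
    pos[s] <- seq_len(grid$E)
    ok <- TRUE
    for (i in unique(grid$events$region_idx)) {
      idx <- which(grid$events$region_idx == i)
      if (is.unsorted(pos[idx], strictly = TRUE)) ok <- FALSE
    }
    ok
  })
  lapply(which(keep), function(r) as.integer(P[r, ]))
}

# independent piecewise-linear trajectory via stats::approx
oracle_traj <- function(s, grid) {
  E <- grid$E
  pos <- integer(E)
  pos[s] <- seq_len(E)
  t(vapply(seq_len(grid$n_regions), function(i) {
    idx <- which(grid$events$region_idx == i)      # ascending threshold
    xs <- c(0, pos[idx])
    ys <- c(0, grid$events$threshold[idx])
    if (max(xs) < E) { xs <- c(xs, E); ys <- c(ys, grid$z_max[i]) }
    approx(xs, ys, xout = 0:E)$y
  }, numeric(E + 1)))
}

# independent subject marginal loglik: direct dnorm sums over the stage grid
oracle_subject_loglik <- function(x, s, grid, sigma = 1) {
  G <- oracle_traj(s, grid)
  lk <- vapply(0:grid$E, function(k)
    sum(dnorm(x, G[, k + 1], sigma, log = TRUE)), numeric(1))
  m <- max(lk)
  m + log(sum(exp(lk - m))) - log(grid$E + 1)
}

# exhaustive mixture loglik over all (sequence, stage) combinations
oracle_dataset_loglik <- function(X, sequences, fractions, grid, sigma = 1) {
  sum(vapply(seq_len(nrow(X)), function(j) {
    lj <- vapply(seq_along(sequences), function(c)
      oracle_subject_loglik(X[j, ], sequences[[c]], grid, sigma), numeric(1))
    m <- max(lj + log(fractions))
    m + log(sum(exp(lj + log(fractions) - m)))
  }, numeric(1)))
}

# brute-force single-sequence maximum-likelihood ordering
oracle_best_sequence <- function(X, grid, sigma = 1) {
  cands <- all_valid_sequences(grid)
  ll <- vapply(cands, function(s)
    sum(vapply(seq_len(nrow(X)), function(j)
      oracle_subject_loglik(X[j, ], s, grid, sigma), numeric(1))),
    numeric(1))
  list(seq = cands[[which.max(ll)]], loglik = max(ll), all = ll,
       cands = cands)
}

kendall_tau <- function(a, b) cor(order(a), order(b), method = "kendall")

# match fitted subtypes to true ones by total Kendall tau of sequences
match_subtypes <- function(fit_seqs, true_seqs) {
  C <- length(true_seqs)
  perms <- sustainr:::all_permutations(C)
  tot <- apply(perms, 1, function(p)
    sum(vapply(seq_len(C), function(c)
      kendall_tau(fit_seqs[[p[c]]], true_seqs[[c]]), numeric(1))))
  perms[which.max(tot), ]                 # fitted index for each true c
}

# tiny ROI table writer for io tests
write_toy_roi <- function(path, n = 3, sep = ",",
                          dictionary = default_roi_dictionary(),
                          drop_cols = NULL, extra_cols = NULL) {
  set.seed(42)
  d <- data.frame(subject_id = paste0("S", seq_len(n)),
                  group = rep(c("patient", "control"), length.out = n),
                  scanner = "site1",
                  age = 30 + seq_len(n), sex = c("M", "F", "1")[seq_len(n) %% 3 + 1],
                  tiv = 1.5e6 + 1000 * seq_len(n))
  for (r in dictionary$region_name) d[[r]] <- round(runif(n, 2, 4), 3)
  if (!is.null(drop_cols)) d <- d[, setdiff(names(d), drop_cols)]
  if (!is.null(extra_cols)) for (nm in extra_cols) d[[nm]] <- 1
  write.table(d, path, sep = sep, quote = FALSE, row.names = FALSE)
  d
}
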