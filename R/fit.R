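# Subtype-and-stage fitting: multi-start greedy sequence optimization,
# hierarchical cluster splitting with EM over (sequences, fractions), and a
# Metropolis chain over event orderings for uncertainty quantification.

#' Multi-start greedy sequence optimization
#'
#' From each random valid start sequence, greedy coordinate ascent
#' repeatedly relocates each event to its best feasible position (respecting
#' the within-region threshold order) until no single move improves the
#' (optionally subject-weighted) log-likelihood; the best result across
#' starts is returned.
#'
#' @param X z-score matrix (subjects x regions) or `zmatrix`.
#' @param grid an [event_grid()].
#' @param n_startpoints number of random restarts (default 25).
#' @param sigma shared noise SD.
#' @param weights optional per-subject non-negative weights (EM
#'   responsibilities); default all 1.
#' @param init optional sequence used as one of the starts (warm restart).
#' @return list with `seq` (best sequence) and `loglik`.
#' @export
optimize_sequence <- function(X, grid, n_startpoints = 25, sigma = 1,
                              weights = NULL, init = NULL) {
  X <- as_z_input(X, grid)
  if (!nrow(X)) stop("X must be non-empty")
  if (is.null(weights)) weights <- rep(1, nrow(X))
  stopifnot(length(weights) == nrow(X), all(weights >= 0))
  best <- NULL
  starts <- if (is.null(init)) list() else list(as.integer(init))
  while (length(starts) < max(n_startpoints, length(starts)))
    starts[[length(starts) + 1]] <- random_valid_sequence(grid)
  lls <- numeric(0)
  for (s0 in starts) {
    res <- cpp_greedy_optimize(X, as.numeric(weights), as.integer(s0),
                               as.integer(grid$events$region_idx) - 1L,
                               as.numeric(grid$events$threshold),
                               as.numeric(grid$z_max), grid$n_regions,
                               sigma, 100L)
    lls <- c(lls, res$loglik)
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  # a flat landscape (all starts tie) usually means uninformative data
  if (length(lls) > 1 && diff(range(lls)) < 1e-9)
    sustain_log("optimize_sequence: flat likelihood landscape (all %d starts tie); sequence is arbitrary",
                length(lls))
  list(seq = as.integer(best$seq), loglik = best$loglik)
}

new_sustain_model <- function(sequences, f, loglik, grid, sigma) {
  structure(list(sequences = sequences, f = f, loglik = loglik,
                 grid = grid, sigma = sigma, C = length(sequences),
                 samples = NULL, pvd = NULL),
            class = "sustain_model")
}

#' @export
print.sustain_model <- function(x, ...) {
  cat(sprintf("sustain_model: %d subtype(s), E = %d events, loglik = %.3f\n",
              x$C, x$grid$E, x$loglik))
  cat("fractions:", sprintf("%.3f", x$f), "\n")
  if (!is.null(x$samples))
    cat(sprintf("MCMC: %d retained samples, acceptance %.3f\n",
                x$samples$n_kept, x$samples$accept_rate_seq))
  invisible(x)
}

# EM over (fractions, sequences) at fixed C, from given starting sequences.
# Two guards interrupt plain coordinate ascent, both re-seeding a cluster
# from the worst-fit subjects: an empty cluster, and a cluster whose
# sequence has collapsed onto another's (a symmetric fixed point plain EM
# cannot leave). The best state seen is returned, so a re-seed can only
# help.
run_em <- function(X, grid, sequences, f, sigma, config,
                   reopt_startpoints = 1) {
  n <- nrow(X)
  C <- length(sequences)
  L <- subject_loglik_matrix(X, sequences, grid, sigma)
  ll <- cpp_mixture_loglik(L, f)
  best <- list(sequences = sequences, f = f, loglik = ll)
  reseeds <- 0
  for (round in seq_len(config$em_max_rounds)) {
    # E-step: responsibilities
    A <- sweep(L, 2, log(f), "+")
    m <- apply(A, 1, max)
    R <- exp(A - m)
    R <- R / rowSums(R)
    mix_ll <- m + log(rowSums(exp(A - m)))   # per-subject fit
    reseed <- function(c) {
      worst <- order(mix_ll)[seq_len(max(2, floor(n / (4 * C))))]
      R[worst, ] <<- 0
      R[worst, c] <<- 1
      R <<- R / rowSums(R)
      opt <- optimize_sequence(X, grid, n_startpoints = 3, sigma = sigma,
                               weights = R[, c])
      sequences[[c]] <<- opt$seq
      reseeds <<- reseeds + 1
    }
    for (c in seq_len(C)) {
      if (sum(R[, c]) < 1e-8 && reseeds < 3) {
        reseed(c)
        sustain_log("EM: re-seeded empty cluster %d", c)
      }
    }
    if (C > 1 && reseeds < 3) {
      for (c in 2:C) for (c2 in seq_len(c - 1)) {
        if (identical(sequences[[c]], sequences[[c2]]) && reseeds < 3) {
          dup <- if (f[c] <= f[c2]) c else c2
          reseed(dup)
          sustain_log("EM: re-seeded duplicated cluster %d", dup)
        }
      }
    }
    # M-step
    f <- colMeans(R)
    for (c in seq_len(C)) {
      opt <- optimize_sequence(X, grid, n_startpoints = reopt_startpoints,
                               sigma = sigma, weights = R[, c],
                               init = sequences[[c]])
      sequences[[c]] <- opt$seq
    }
    L <- subject_loglik_matrix(X, sequences, grid, sigma)
    new_ll <- cpp_mixture_loglik(L, f)
    if (new_ll > best$loglik)
      best <- list(sequences = sequences, f = f, loglik = new_ll)
    if (abs(new_ll - ll) < config$em_tol && new_ll >= ll) break
    ll <- new_ll
  }
  best
}

#' Fit a subtype-and-stage model with C subtypes
#'
#' `C = 1` is plain multi-start sequence optimization. For `C > 1` the model
#' is grown hierarchically: each existing cluster's subjects are randomly
#' bipartitioned, sequences re-optimized within the halves, the best-
#' likelihood split kept, then fractions and sequences are refined by EM
#' (responsibility-weighted fraction update alternating with per-cluster
#' weighted sequence re-optimization) until the log-likelihood improvement
#' falls below `em_tol` or `em_max_rounds` is reached.
#'
#' @param X z-score matrix (subjects x regions) or `zmatrix`.
#' @param grid an [event_grid()].
#' @param C_target number of subtypes to fit.
#' @param config a [run_config()].
#' @param sigma shared noise SD; defaults to `config$sigma`.
#' @return A `sustain_model` (no MCMC samples yet; see [mcmc_sample()]).
#' @export
fit_sustain <- function(X, grid, C_target, config = run_config(),
                        sigma = config$sigma) {
  X <- as_z_input(X, grid)
  if (C_target < 1 || C_target > config$max_subtypes)
    stop("C_target must be in 1..max_subtypes")
  n <- nrow(X)

  opt <- optimize_sequence(X, grid, n_startpoints = config$n_startpoints,
                           sigma = sigma)
  sequences <- list(opt$seq)
  f <- 1
  loglik <- opt$loglik

  short_cfg <- config
  short_cfg$em_max_rounds <- 3
  split_tries <- max(3, ceiling(config$n_startpoints / 3))
  split_starts <- max(2, ceiling(config$n_startpoints / 5))

  for (C in seq_len(C_target)[-1]) {
    L <- subject_loglik_matrix(X, sequences, grid, sigma)
    A <- sweep(L, 2, log(f), "+")
    hard <- max.col(A)
    best <- NULL
    for (c in seq_along(sequences)) {
      members <- which(hard == c)
      if (length(members) < 4) next
      # several random bipartitions, each refined by a short EM; the best
      # candidate gets the full EM below
      for (try in seq_len(split_tries)) {
        half <- sample(c(TRUE, FALSE), length(members), replace = TRUE)
        if (all(half) || all(!half)) half[1] <- !half[1]
        s_a <- optimize_sequence(X[members[half], , drop = FALSE], grid,
                                 n_startpoints = split_starts, sigma = sigma)
        s_b <- optimize_sequence(X[members[!half], , drop = FALSE], grid,
                                 n_startpoints = split_starts, sigma = sigma)
        cand_seqs <- c(sequences[-c], list(s_a$seq, s_b$seq))
        cand_f <- c(f[-c], f[c] * mean(half), f[c] * mean(!half))
        cand_f <- cand_f / sum(cand_f)
        em <- run_em(X, grid, cand_seqs, cand_f, sigma, short_cfg)
        if (is.null(best) || em$loglik > best$loglik) best <- em
      }
    }
    if (is.null(best))
      stop("no cluster large enough to split at C = ", C)
    em <- run_em(X, grid, best$sequences, best$f, sigma, config)
    sequences <- em$sequences
    f <- em$f
    loglik <- em$loglik
  }
  new_sustain_model(sequences, f, loglik, grid, sigma)
}

#' Sample sequence and fraction uncertainty by MCMC
#'
#' Metropolis chain started at the fitted model: each iteration relocates
#' one uniformly chosen event of one uniformly chosen subtype to a
#' uniformly chosen valid position, then (unless fractions are frozen)
#' jointly perturbs the fractions with a Dirichlet proposal centred at the
#' current value; both moves accept with `min(1, exp(delta loglik))` under
#' flat priors. The first `burn_frac` of the chain is discarded;
#' positional-variance diagrams are computed from all retained samples.
#'
#' @param X z-score matrix or `zmatrix` used for the fit.
#' @param model a fitted `sustain_model`.
#' @param n_iter chain length (>= 100).
#' @param config a [run_config()]; uses `burn_frac`, `sample_fractions`,
#'   `dirichlet_scale`.
#' @param store_samples keep the raw retained samples (needed for
#'   [export_results()] sample tables; PVDs are accumulated either way).
#' @return The model with `samples` (chain summary) and `pvd` attached, and
#'   `f`/`loglik` updated to the final chain state's maximum-likelihood
#'   values left intact.
#' @export
mcmc_sample <- function(X, model, n_iter = NULL, config = run_config(),
                        store_samples = TRUE) {
  stopifnot(inherits(model, "sustain_model"))
  if (is.null(n_iter)) n_iter <- config$n_mcmc_iter
  if (n_iter < 100) stop("n_iter < 100 gives an uninformative chain")
  X <- as_z_input(X, model$grid)
  grid <- model$grid
  seqs <- do.call(cbind, model$sequences)
  res <- cpp_mcmc(X, seqs, as.numeric(model$f), as.integer(n_iter),
                  config$burn_frac,
                  as.integer(grid$events$region_idx) - 1L,
                  as.numeric(grid$events$threshold),
                  as.numeric(grid$z_max), grid$n_regions, model$sigma,
                  isTRUE(config$sample_fractions), config$dirichlet_scale,
                  isTRUE(store_samples))
  sustain_log("MCMC: %d iterations, %d retained, acceptance %.3f (sequences)%s",
              n_iter, res$n_kept, res$accept_rate_seq,
              if (isTRUE(config$sample_fractions) && model$C > 1)
                sprintf(" / %.3f (fractions)", res$accept_rate_f) else "")
  pvd <- lapply(res$pvd, function(P) {
    dimnames(P) <- list(grid$events$event_name,
                        paste0("position_", seq_len(grid$E)))
    P
  })
  model$samples <- list(
    seq = res$samples_seq, f = res$samples_f,
    loglik_trace = res$loglik_trace, n_kept = res$n_kept,
    accept_rate_seq = res$accept_rate_seq,
    accept_rate_f = res$accept_rate_f,
    final_seqs = res$final_seqs, final_f = res$final_f)
  model$pvd <- pvd
  model
}

#' Positional-variance diagrams
#'
#' `P_c[event, position]` = fraction of retained MCMC samples in which the
#' event occupies that position in subtype `c`'s sequence; each row sums
#' to 1.
#'
#' @param model a `sustain_model` with MCMC samples.
#' @return list of event x position matrices, one per subtype.
#' @export
positional_variance <- function(model) {
  stopifnot(inherits(model, "sustain_model"))
  if (is.null(model$pvd))
    stop("model has no MCMC samples; run mcmc_sample() first")
  model$pvd
}

#' Per-subject subtype probabilities, staging and assignment
#'
#' Subtype membership `p(c | x_j)` is proportional to
#' `f_c exp(l_j(S_c))`; the weighted stage is the posterior-mean stage
#' averaged over subtype membership,
#' `w_j = sum_c p(c|x_j) sum_k k p(k|x_j, c)`. Subjects whose z-scores show
#' no abnormality (weighted stage below 0.5) are flagged `stage_zero` and
#' left unassigned; otherwise a subject is assigned to the subtype with the
#' highest membership only when that membership strictly exceeds the
#' cut-off (default `> 0.5`), ties above the cut-off resolved to the lowest
#' subtype index.
#'
#' @param X z-score matrix or `zmatrix`.
#' @param model a fitted `sustain_model`.
#' @param cutoff assignment cut-off in (0, 1).
#' @return data frame with one row per subject: membership probabilities,
#'   `weighted_stage`, `assigned_subtype` (`NA` when unclassified) and
#'   `stage_zero`; per-subtype stage posteriors in
#'   `attr(, "stage_posteriors")`.
#' @export
subject_posteriors <- function(X, model, cutoff = 0.5) {
  stopifnot(inherits(model, "sustain_model"))
  ids <- if (inherits(X, "zmatrix")) X$subject_id else rownames(as.matrix(X))
  X <- as_z_input(X, model$grid)
  n <- nrow(X)
  if (is.null(ids)) ids <- sprintf("subject_%03d", seq_len(n))
  grid <- model$grid
  E <- grid$E
  C <- model$C

  L <- subject_loglik_matrix(X, model$sequences, grid, model$sigma)
  A <- sweep(L, 2, log(model$f), "+")
  m <- apply(A, 1, max)
  P <- exp(A - m)
  P <- P / rowSums(P)                      # p(c | x_j)

  stage_post <- array(NA_real_, c(n, E + 1, C))
  mean_stage <- matrix(NA_real_, n, C)
  for (c in seq_len(C)) {
    SL <- cpp_stage_loglik(X, traj_matrix(model$sequences[[c]], grid),
                           model$sigma)
    mm <- apply(SL, 1, max)
    Q <- exp(SL - mm)
    Q <- Q / rowSums(Q)
    stage_post[, , c] <- Q
    mean_stage[, c] <- Q %*% (0:E)
  }
  w <- rowSums(P * mean_stage)

  stage_zero <- w < 0.5
  assigned <- rep(NA_integer_, n)
  top <- apply(P, 1, max)
  ok <- !stage_zero & top > cutoff
  assigned[ok] <- apply(P[ok, , drop = FALSE], 1, which.max)

  out <- data.frame(subject_id = ids, P,
                    weighted_stage = w, assigned_subtype = assigned,
                    stage_zero = stage_zero, stringsAsFactors = FALSE)
  names(out)[1 + seq_len(C)] <- paste0("prob_subtype", seq_len(C))
  rownames(out) <- NULL
  attr(out, "stage_posteriors") <- stage_post
  out
}
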