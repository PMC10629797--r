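# Cross-validated choice of the number of subtypes. The information
# criterion is the held-out deviance CIC(C) = -2 * sum over folds of the
# out-of-fold dataset log-likelihood; smaller is better, and a smaller C
# within parsimony_delta of the minimum is preferred.

#' K-fold cross-validation over the number of subtypes
#'
#' Subjects are split into seeded random folds; for each fold and each
#' `C = 1..max_subtypes` a model is fitted on the training split and the
#' held-out dataset log-likelihood is evaluated on the test split. When
#' `similarity_mcmc_iter > 0`, each fold's model at every C also gets a
#' short MCMC pass so cross-fold similarity can be computed.
#'
#' @param X z-score matrix (subjects x regions) or `zmatrix`.
#' @param grid an [event_grid()].
#' @param config a [run_config()]; uses `cv_folds`, `max_subtypes`,
#'   `n_startpoints`, `sigma`.
#' @param similarity_mcmc_iter MCMC iterations per fold model for PVDs
#'   (0 = skip; similarity then unavailable).
#' @return A `cv_report`: `cic` (one value per C), `fold_loglik`
#'   (folds x C), `folds` (assignment), `fold_models` (per C, list of fold
#'   models), `chosen` from [select_n_subtypes()].
#' @export
crossval <- function(X, grid, config = run_config(),
                     similarity_mcmc_iter = 0) {
  X <- as_z_input(X, grid)
  n <- nrow(X)
  k <- config$cv_folds
  if (n < 2 * k)
    stop("need at least 2 subjects per fold; reduce cv_folds")
  fold <- sample(rep(seq_len(k), length.out = n))
  if (min(table(fold)) < 2)
    stop("a fold has fewer than 2 subjects; reduce cv_folds")

  Cs <- seq_len(config$max_subtypes)
  fold_ll <- matrix(NA_real_, k, length(Cs),
                    dimnames = list(NULL, paste0("C", Cs)))
  fold_models <- lapply(Cs, function(C) vector("list", k))
  for (fi in seq_len(k)) {
    train <- X[fold != fi, , drop = FALSE]
    test <- X[fold == fi, , drop = FALSE]
    for (C in Cs) {
      m <- fit_sustain(train, grid, C, config)
      fold_ll[fi, C] <- dataset_log_likelihood(test, m$sequences, m$f,
                                               grid, m$sigma)
      if (similarity_mcmc_iter > 0)
        m <- mcmc_sample(train, m, n_iter = similarity_mcmc_iter,
                         config = config, store_samples = FALSE)
      fold_models[[C]][[fi]] <- m
    }
    sustain_log("crossval: fold %d/%d done", fi, k)
  }
  cic <- -2 * colSums(fold_ll)
  rep <- structure(list(cic = cic, fold_loglik = fold_ll, folds = fold,
                        fold_models = fold_models,
                        max_subtypes = config$max_subtypes,
                        parsimony_delta = config$parsimony_delta),
                   class = "cv_report")
  rep$chosen <- select_n_subtypes(rep)
  rep
}

#' Choose the number of subtypes from a cross-validation report
#'
#' `C* = argmin CIC`, except that the smallest C whose CIC lies within
#' `parsimony_delta` (default 6) of the minimum is preferred.
#'
#' @param report a `cv_report` (or plain numeric CIC vector).
#' @return Chosen number of subtypes.
#' @export
select_n_subtypes <- function(report) {
  cic <- if (inherits(report, "cv_report")) report$cic else as.numeric(report)
  delta <- if (inherits(report, "cv_report")) report$parsimony_delta else 6
  cstar <- which.min(cic)
  within <- which(cic - min(cic) < delta)
  chosen <- min(within)
  if (chosen != cstar)
    sustain_log("parsimony rule: C=%d within %.1f of minimum at C=%d; choosing C=%d",
                chosen, delta, cstar, chosen)
  chosen
}

# overlap similarity of two positional-variance rows/matrices:
# mean over events of sum_k min(P[e,k], Q[e,k]) -- 1 for identical
# distributions, 0 for disjoint support
pvd_overlap <- function(P, Q) {
  stopifnot(all(dim(P) == dim(Q)))
  mean(rowSums(pmin(P, Q)))
}

#' Cross-validation similarity of progression subtypes
#'
#' Each fold's subtypes are matched one-to-one to the reference model's
#' subtypes by the permutation maximizing total positional-variance
#' overlap; the similarity of a matched pair is the mean over events of the
#' summed element-wise minimum of their PVD rows (1 = identical orderings,
#' 0 = disjoint). Reports per-subtype mean and percentile 95% CI over
#' folds.
#'
#' @param fold_models list of fitted `sustain_model`s (one per fold, each
#'   with MCMC samples), all with the same number of subtypes.
#' @param reference reference `sustain_model` with MCMC samples.
#' @return list with `mean`, `ci_low`, `ci_high` (length C) and the
#'   folds x C similarity matrix `per_fold`.
#' @export
cv_similarity <- function(fold_models, reference) {
  stopifnot(inherits(reference, "sustain_model"))
  Pref <- positional_variance(reference)
  C <- length(Pref)
  if (any(vapply(fold_models, function(m) m$C, 0L) != C))
    stop("fold models and reference disagree on the number of subtypes")
  perms <- all_permutations(C)
  per_fold <- t(vapply(fold_models, function(m) {
    Pf <- positional_variance(m)
    sim <- matrix(0, C, C)   # sim[a, b] = overlap(fold subtype a, ref b)
    for (a in seq_len(C)) for (b in seq_len(C))
      sim[a, b] <- pvd_overlap(Pf[[a]], Pref[[b]])
    tot <- vapply(seq_len(nrow(perms)), function(p)
      sum(sim[cbind(perms[p, ], seq_len(C))]), 0)
    best <- perms[which.max(tot), ]
    sim[cbind(best, seq_len(C))]
  }, numeric(C)))
  per_fold <- matrix(per_fold, ncol = C)
  ci <- apply(per_fold, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  list(mean = colMeans(per_fold), ci_low = ci[1, ], ci_high = ci[2, ],
       per_fold = per_fold)
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
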