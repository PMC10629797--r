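# Clinical characterization of subtypes: correlation-matrix PCA with Kaiser
# retention, bootstrap Spearman correlations, chi-squared and
# Kruskal-Wallis tests, and a combined subtype report. The paper-level
# convention of unadjusted p-values is kept (a Benjamini-Hochberg switch is
# available in characterize_subtypes but off by default).

#' Severity PCA on clinical features
#'
#' Correlation-matrix PCA (features standardized) on complete cases.
#' Components with eigenvalue > 1 are retained (Kaiser rule); each retained
#' loading vector's sign is fixed so its largest-magnitude loading is
#' positive.
#'
#' @param features data frame of numeric clinical features (for the focal
#'   cohort convention: convulsions in prior year, seizure frequency, ASM
#'   count, duration; the generalized convention drops seizure frequency).
#' @return A `pca_result`: `loadings` (all components), `eigenvalues`,
#'   `retained` (indices with eigenvalue > 1), `scores` (complete-case
#'   subjects x retained components), `explained_variance`, `complete_rows`.
#' @export
pca_severity <- function(features) {
  stopifnot(is.data.frame(features) || is.matrix(features))
  X <- as.matrix(features)
  cc <- complete.cases(X)
  X <- X[cc, , drop = FALSE]
  if (nrow(X) < 3) stop("fewer than 3 complete cases")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) stop("zero-variance feature: ",
                          paste(colnames(X)[sds == 0], collapse = ", "))
  Xs <- scale(X)
  eg <- eigen(cor(X), symmetric = TRUE)
  V <- eg$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(colnames(X), paste0("PC", seq_len(ncol(V))))
  retained <- which(eg$values > 1)
  if (!length(retained))
    sustain_log("PCA: no component has eigenvalue > 1; nothing retained")
  scores <- Xs %*% V[, retained, drop = FALSE]
  structure(list(loadings = V, eigenvalues = eg$values,
                 retained = retained, scores = scores,
                 explained_variance = eg$values / ncol(X),
                 complete_rows = which(cc)),
            class = "pca_result")
}

#' Spearman correlation with bootstrap confidence interval
#'
#' Spearman's rho on average ranks, two-tailed p from the t approximation,
#' and a percentile CI from paired resamples.
#'
#' @param x,y paired numeric vectors (pairs with missing values dropped;
#'   at least 10 complete pairs required).
#' @param reps bootstrap resamples (default 5000).
#' @param seed optional integer seed for the resampling.
#' @param conf confidence level (default 0.95).
#' @return An `association_result` list: `rho`, `p`, `ci` (length 2),
#'   `n`, `reps`.
#' @export
spearman_bootstrap <- function(x, y, reps = 5000, seed = NULL, conf = 0.95) {
  ok <- complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 10) stop("need at least 10 paired complete observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant vector: Spearman's rho undefined")
  if (!is.null(seed)) set.seed(seed)
  rho <- cor(rank(x), rank(y))
  tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), n - 2)
  boot <- vapply(seq_len(reps), function(r) {
    i <- sample.int(n, n, replace = TRUE)
    if (sd(x[i]) == 0 || sd(y[i]) == 0) return(NA_real_)
    cor(rank(x[i]), rank(y[i]))
  }, numeric(1))
  boot <- boot[!is.na(boot)]
  a <- (1 - conf) / 2
  ci <- quantile(boot, c(a, 1 - a), names = FALSE)
  structure(list(rho = rho, p = p, ci = ci, n = n, reps = reps),
            class = "association_result")
}

#' Pearson chi-squared test on a contingency table
#'
#' Without continuity correction; `df = (r - 1)(c - 1)`. Warns (and
#' proceeds) when any expected cell count is below 1.
#'
#' @param tab counts matrix, at least 2 x 2.
#' @return list with `chisq`, `df`, `p`, `expected`.
#' @export
contingency_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("need at least a 2x2 table")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1))
    warning("expected cell count < 1; consider an exact test (not implemented)")
  chisq <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(chisq = chisq, df = df, p = pchisq(chisq, df, lower.tail = FALSE),
       expected = expected)
}

#' Kruskal-Wallis test of an ordinal outcome across groups
#'
#' Tie-corrected H statistic (wraps the standard rank-sum machinery).
#'
#' @param values numeric/ordinal outcome.
#' @param groups group labels.
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_by_group <- function(values, groups) {
  ok <- complete.cases(values, groups)
  kt <- kruskal.test(values[ok], factor(groups[ok]))
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Clinical characterization of fitted subtypes
#'
#' Joins subject posteriors to the clinical table and computes: the
#' per-subtype prevalence table (and cross-cohort prevalence chi-squared
#' when a `cohort` column is present), bootstrap Spearman correlations of
#' weighted stage with duration, onset age and seizure frequency, the
#' convulsion-by-subtype chi-squared, seizure frequency across subtypes by
#' Kruskal-Wallis, and (when a [pca_severity()] result is supplied)
#' Spearman correlations of each subtype's expression probability with each
#' retained component score.
#'
#' @param posteriors [subject_posteriors()] output.
#' @param clinical clinical table with `subject_id`.
#' @param pca optional `pca_result` computed on the same clinical rows.
#' @param reps bootstrap resamples for the Spearman CIs.
#' @param seed optional integer seed.
#' @param bh apply Benjamini-Hochberg correction across the report's
#'   p-values (off by default, matching unadjusted reporting).
#' @return A `subtype_report` list.
#' @export
characterize_subtypes <- function(posteriors, clinical, pca = NULL,
                                  reps = 5000, seed = NULL, bh = FALSE) {
  d <- merge(posteriors, clinical, by = "subject_id")
  if (nrow(d) < 10) stop("join produced fewer than 10 rows")
  if (!is.null(seed)) set.seed(seed)
  C <- sum(grepl("^prob_subtype", names(posteriors)))

  prevalence <- table(factor(ifelse(is.na(d$assigned_subtype), "unclassified",
                                    d$assigned_subtype),
                             levels = c(seq_len(C), "unclassified")))
  cohort_chisq <- NULL
  if ("cohort" %in% names(d)) {
    tab <- table(d$cohort, ifelse(is.na(d$assigned_subtype), "unclassified",
                                  d$assigned_subtype))
    cohort_chisq <- contingency_test(tab)
  }

  stage_cor <- list(
    duration = spearman_bootstrap(d$weighted_stage, d$duration_years,
                                  reps = reps),
    onset_age = spearman_bootstrap(d$weighted_stage, d$onset_age_years,
                                   reps = reps),
    seizure_frequency = spearman_bootstrap(d$weighted_stage,
                                           d$seizure_frequency, reps = reps))

  assigned <- !is.na(d$assigned_subtype)
  convulsion_chisq <- NULL
  frequency_kruskal <- NULL
  if (length(unique(d$assigned_subtype[assigned])) >= 2) {
    tab <- table(d$assigned_subtype[assigned],
                 d$convulsions_prior_year[assigned])
    if (all(dim(tab) >= 2)) convulsion_chisq <- contingency_test(tab)
    frequency_kruskal <- kruskal_by_group(d$seizure_frequency[assigned],
                                          d$assigned_subtype[assigned])
  }

  pc_cor <- NULL
  if (!is.null(pca) && length(pca$retained)) {
    rows <- pca$complete_rows
    pc_cor <- list()
    for (c in seq_len(C)) for (j in seq_along(pca$retained)) {
      nm <- sprintf("subtype%d_PC%d", c, j)
      pc_cor[[nm]] <- spearman_bootstrap(
        d[rows, paste0("prob_subtype", c)], pca$scores[, j], reps = reps)
    }
  }

  report <- list(n = nrow(d), prevalence = prevalence,
                 cohort_chisq = cohort_chisq, stage_cor = stage_cor,
                 convulsion_chisq = convulsion_chisq,
                 frequency_kruskal = frequency_kruskal, pc_cor = pc_cor)
  if (bh) {
    ps <- c(vapply(stage_cor, `[[`, 0, "p"),
            if (!is.null(pc_cor)) vapply(pc_cor, `[[`, 0, "p"))
    report$bh_adjusted_p <- stats::p.adjust(ps, method = "BH")
  }
  class(report) <- "subtype_report"
  report
}
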