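# Control-referenced adjustment and z-scoring. Each regional measure is
# modelled in the control group as a conjugate Bayesian linear regression on
# intercept, TIV, sex, age and age^2 (age centred at the stratum control
# mean before squaring, for conditioning). With a vague prior (precision
# prior_precision * I) the posterior mean is ridge-regularized least
# squares. Subjects are z-scored against their own scanner stratum and the
# sign is flipped once, so positive z* means more atrophy.

design_matrix <- function(df, age_center, include_tiv) {
  a <- df$age - age_center
  X <- cbind(intercept = 1,
             tiv = if (include_tiv) df$tiv else 0,
             sex = df$sex, age = a, age2 = a^2)
  if (!include_tiv) X <- X[, colnames(X) != "tiv", drop = FALSE]
  X
}

#' Fit the control normalization model
#'
#' @param controls ROI measurement table rows with `group == "control"`.
#' @param dictionary ROI dictionary naming the measure columns.
#' @param config a [run_config()]; uses `min_controls`, `prior_precision`
#'   and `include_tiv`.
#' @return A `control_norm_model`: per scanner stratum, per-region posterior
#'   mean coefficients and control residual mean/SD.
#' @export
fit_control_model <- function(controls, dictionary = default_roi_dictionary(),
                              config = run_config()) {
  stopifnot(is.data.frame(controls))
  controls <- controls[controls$group == "control", , drop = FALSE]
  if (!nrow(controls)) stop("no control rows supplied")
  regions <- intersect(dictionary$region_name, names(controls))
  if (!length(regions)) stop("no dictionary regions found in controls")

  strata <- sort(unique(controls$scanner))
  fit <- list()
  for (s in strata) {
    cs <- controls[controls$scanner == s, , drop = FALSE]
    if (nrow(cs) < config$min_controls)
      stop(sprintf(
        "stratum '%s' has %d controls, below the floor of %d; pool strata or lower min_controls",
        s, nrow(cs), config$min_controls))
    age_center <- mean(cs$age)
    X <- design_matrix(cs, age_center, config$include_tiv)
    # column scaling before the solve: TIV is ~1e6 while sex is 0/1, and an
    # unscaled cross-product looks singular to rcond purely from units
    cs_scale <- pmax(apply(abs(X), 2, max), .Machine$double.eps)
    Xs <- sweep(X, 2, cs_scale, "/")
    XtX <- crossprod(Xs) + config$prior_precision * diag(ncol(X))
    if (rcond(XtX) < 1e-12) stop("singular design in stratum ", s)
    Y <- as.matrix(cs[, regions, drop = FALSE])
    beta <- solve(XtX, crossprod(Xs, Y)) / cs_scale  # p x R posterior means
    res <- Y - X %*% beta
    rmean <- colMeans(res)
    rsd <- apply(res, 2, sd)
    # numerically-zero residual SD (constant measure) is degenerate; the
    # floor is relative to the measure's own scale so vague-prior shrinkage
    # residue on an exactly-constant column still trips it
    floor_sd <- 1e-8 + 1e-4 * abs(colMeans(Y))
    bad <- !is.finite(rsd) | rsd <= floor_sd
    if (any(bad))
      stop("degenerate residual SD (~0) in stratum ", s,
           " for region(s): ", paste(regions[bad], collapse = ", "))
    fit[[s]] <- list(beta = beta, resid_mean = rmean, resid_sd = rsd,
                     age_center = age_center, n_controls = nrow(cs))
  }
  structure(list(strata = fit, regions = regions,
                 include_tiv = config$include_tiv),
            class = "control_norm_model")
}

#' Compute sign-flipped regional z-scores
#'
#' `z = (observed - predicted - residual_mean) / residual_SD` against the
#' subject's own scanner stratum, then flipped (`z* = -z`) so that larger
#' values mean more atrophy. Fitting controls come out with per-region mean
#' 0 and SD 1 by construction.
#'
#' @param subjects ROI measurement table (patients and/or controls).
#' @param model a [fit_control_model()] result.
#' @return A `zmatrix`: list with the subjects x regions matrix `z`
#'   (already flipped), `subject_id`, `group`, `stratum` and `flipped`.
#' @export
compute_zscores <- function(subjects, model) {
  stopifnot(inherits(model, "control_norm_model"))
  unknown <- setdiff(unique(subjects$scanner), names(model$strata))
  if (length(unknown))
    stop("unknown scanner stratum: ", paste(unknown, collapse = ", "))
  regions <- model$regions
  Z <- matrix(NA_real_, nrow(subjects), length(regions),
              dimnames = list(subjects$subject_id, regions))
  for (s in names(model$strata)) {
    idx <- which(subjects$scanner == s)
    if (!length(idx)) next
    m <- model$strata[[s]]
    X <- design_matrix(subjects[idx, , drop = FALSE], m$age_center,
                       model$include_tiv)
    pred <- X %*% m$beta
    obs <- as.matrix(subjects[idx, regions, drop = FALSE])
    z <- sweep(sweep(obs - pred, 2, m$resid_mean, "-"), 2, m$resid_sd, "/")
    Z[idx, ] <- -z                       # single sign flip: z* = -z
  }
  structure(list(z = Z, subject_id = subjects$subject_id,
                 group = subjects$group, stratum = subjects$scanner,
                 flipped = TRUE),
            class = "zmatrix")
}

#' Regroup left/right regions as ipsilateral/contralateral
#'
#' Keeps only patients with a proven lateralized seizure focus
#' (`laterality` of `left` or `right`); for right-focus subjects the left
#' and right columns are swapped, then columns are renamed `ipsi_*` /
#' `contra_*`. Bilateral/undetermined subjects are excluded with a logged
#' count.
#'
#' @param z a `zmatrix` of patients.
#' @param clinical clinical table with `subject_id` and `laterality`.
#' @return A `zmatrix` restricted to lateralized subjects with
#'   ipsi/contra column names.
#' @export
regroup_ipsi_contra <- function(z, clinical) {
  stopifnot(inherits(z, "zmatrix"))
  lat <- clinical$laterality[match(z$subject_id, clinical$subject_id)]
  keep <- which(!is.na(lat) & lat %in% c("left", "right"))
  dropped <- length(z$subject_id) - length(keep)
  if (dropped > 0)
    sustain_log("excluded %d subject(s) without a lateralized focus", dropped)
  if (!length(keep)) stop("no subjects with a lateralized seizure focus")

  cols <- colnames(z$z)
  left_cols <- grep("^left_", cols, value = TRUE)
  right_cols <- paste0("right_", sub("^left_", "", left_cols))
  if (!all(right_cols %in% cols)) stop("left/right columns are not paired")

  Z <- z$z[keep, , drop = FALSE]
  lat <- lat[keep]
  swap <- lat == "right"
  if (any(swap)) {
    tmp <- Z[swap, left_cols, drop = FALSE]
    Z[swap, left_cols] <- Z[swap, right_cols, drop = FALSE]
    Z[swap, right_cols] <- tmp
  }
  colnames(Z)[match(left_cols, colnames(Z))] <-
    paste0("ipsi_", sub("^left_", "", left_cols))
  colnames(Z)[match(right_cols, colnames(Z))] <-
    paste0("contra_", sub("^right_", "", right_cols))

  structure(list(z = Z, subject_id = z$subject_id[keep],
                 group = z$group[keep], stratum = z$stratum[keep],
                 flipped = z$flipped, laterality = lat),
            class = "zmatrix")
}
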