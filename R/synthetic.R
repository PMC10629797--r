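# Synthetic cohorts with known ground truth. Patients are drawn from the
# piecewise-linear z-score model itself (latent subtype, latent integer
# stage, Gaussian noise around the subtype trajectory); raw measures are
# produced by inverting the control normalization at plausible regional
# scales (thickness ~2-4 mm, volumes ~1e3-1e4 mm^3) so the full
# adjust -> fit path is exercised. Every dataset ships its generating
# truth, and regeneration from (config, seed) is bit-identical.

# deterministic per-region raw-unit scales for the default dictionary;
# generic/unknown regions fall back to thickness-like scales
region_scales <- function(regions, dictionary = NULL) {
  base_vol <- c(hippocampus = 3500, amygdala = 1600, thalamus = 7000,
                caudate = 3600, pallidum = 1700, putamen = 4800)
  out <- data.frame(region = regions, intercept = NA_real_,
                    beta_tiv = NA_real_, beta_sex = NA_real_,
                    beta_age = NA_real_, beta_age2 = NA_real_,
                    resid_sd = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(regions)) {
    b <- roi_base_name(regions[i])
    if (b %in% names(base_vol)) {
      sc <- base_vol[[b]]
      out$intercept[i] <- 0.6 * sc
      out$beta_tiv[i] <- 0.4 * sc / 1.5e6
      out$beta_sex[i] <- 0.03 * sc
      out$beta_age[i] <- -0.002 * sc
      out$beta_age2[i] <- -2e-5 * sc
      out$resid_sd[i] <- 0.05 * sc
    } else {
      # cortical thickness in mm; mild deterministic variation across rows
      out$intercept[i] <- 2.6 + 0.02 * (i %% 7)
      out$beta_tiv[i] <- 2e-8
      out$beta_sex[i] <- 0.04
      out$beta_age[i] <- -0.005
      out$beta_age2[i] <- -5e-5
      out$resid_sd[i] <- 0.12
    }
  }
  out
}

draw_stage <- function(n, E, stage_dist) {
  if (is.function(stage_dist)) return(stage_dist(n, E))
  if (identical(stage_dist, "uniform")) return(sample(0:E, n, replace = TRUE))
  if (is.numeric(stage_dist) && length(stage_dist) == 1)
    return(rep(as.integer(stage_dist), n))           # point mass
  if (is.numeric(stage_dist) && length(stage_dist) == 2)  # beta(a, b) option
    return(round(E * rbeta(n, stage_dist[1], stage_dist[2])))
  stop("stage_dist must be 'uniform', a point mass, beta parameters, or a function")
}

#' Simulate a cohort with known subtype/stage ground truth
#'
#' Draws `K` subtype sequences (uniform over valid orderings unless
#' supplied), assigns each patient a subtype from `fractions` and an
#' integer stage from `stage_dist` (default uniform on `0..E`), sets the
#' latent z-scores to the subtype trajectory plus `Normal(0, sigma_gen)`
#' noise, and back-maps everything to raw units through a known control
#' model (controls are drawn at `z* ~ Normal(0, 1)`, defining the reference
#' distribution).
#'
#' @param n_patients,n_controls cohort sizes (defaults 400 / 100).
#' @param regions region names; default the 40-region dictionary.
#' @param K number of latent subtypes.
#' @param fractions subtype fractions (simplex, length K).
#' @param z_events,z_max event grid parameters (defaults `c(1,2,3)` / 5).
#' @param stage_dist `"uniform"`, a single stage (point mass), `c(a, b)`
#'   beta parameters (rounded to integer stages), or `function(n, E)`.
#' @param sigma_gen patient noise SD around the trajectory (default 1).
#' @param sequences optional list of K generating sequences.
#' @param distinct require the K drawn sequences to be distinct.
#' @param scanners scanner labels to spread subjects over (default one).
#' @param seed optional integer seed (`set.seed` is called when given).
#' @return list with `roi` (measurement table in [load_cohort_tables()]
#'   format) and `truth` (a `synthetic_truth`: sequences, fractions,
#'   per-subject subtype/stage, control coefficients, grid, parameters).
#' @export
simulate_cohort <- function(n_patients = 400, n_controls = 100,
                            regions = default_roi_dictionary()$region_name,
                            K = 2, fractions = c(0.6, 0.4),
                            z_events = c(1, 2, 3), z_max = 5,
                            stage_dist = "uniform", sigma_gen = 1,
                            sequences = NULL, distinct = TRUE,
                            scanners = "site1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (K < 1) stop("K must be >= 1")
  if (length(fractions) != K || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be a length-K simplex")
  grid <- event_grid(regions, z_events = z_events, z_max = z_max)
  E <- grid$E

  if (is.null(sequences)) {
    sequences <- list()
    for (tries in seq_len(100 * K)) {
      s <- random_valid_sequence(grid)
      if (!distinct || !any(vapply(sequences, identical, TRUE, y = s)))
        sequences[[length(sequences) + 1]] <- s
      if (length(sequences) == K) break
    }
    if (length(sequences) < K)
      stop("could not draw ", K, " distinct valid sequences")
  } else {
    stopifnot(length(sequences) == K)
    for (s in sequences)
      if (!validate_sequence(s, grid)) stop("supplied sequence is invalid")
  }

  lat <- simulate_zscores(n_patients, grid, sequences, fractions,
                          stage_dist, sigma_gen)

  # known control model at plausible raw scales
  sc <- region_scales(regions)
  n <- n_patients + n_controls
  subj <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    group = rep(c("patient", "control"), c(n_patients, n_controls)),
    scanner = sample(scanners, n, replace = TRUE),
    age = pmin(pmax(rnorm(n, 35, 12), 18), 70),
    sex = rbinom(n, 1, 0.5),
    tiv = rnorm(n, 1.5e6, 1.2e5),
    stringsAsFactors = FALSE)

  Zstar <- rbind(lat$z,
                 matrix(rnorm(n_controls * grid$n_regions), n_controls))
  age_center <- 35                      # truth model centre (known)
  a <- subj$age - age_center
  raw <- matrix(NA_real_, n, grid$n_regions, dimnames = list(NULL, regions))
  for (i in seq_len(grid$n_regions)) {
    pred <- sc$intercept[i] + sc$beta_tiv[i] * subj$tiv +
      sc$beta_sex[i] * subj$sex + sc$beta_age[i] * a + sc$beta_age2[i] * a^2
    raw[, i] <- pred - Zstar[, i] * sc$resid_sd[i]
  }
  roi <- cbind(subj, as.data.frame(raw))

  truth <- structure(list(
    sequences = sequences, fractions = fractions,
    subtype = lat$subtype, stage = lat$stage,
    subject_id = subj$subject_id[seq_len(n_patients)],
    age = subj$age[seq_len(n_patients)],
    grid = grid, sigma_gen = sigma_gen,
    control_coefficients = sc, age_center = age_center,
    z_patients = lat$z, seed = seed),
    class = "synthetic_truth")
  list(roi = roi, truth = truth)
}

#' Simulate latent z-scores only (no raw-unit back-mapping)
#'
#' Fast path for model-level simulations: patients drawn directly from the
#' piecewise-linear z-score model.
#'
#' @param n number of patients.
#' @param grid an [event_grid()].
#' @param sequences list of generating sequences.
#' @param fractions subtype fractions.
#' @param stage_dist as in [simulate_cohort()].
#' @param sigma_gen noise SD.
#' @return list with matrix `z` (n x regions), `subtype`, `stage`.
#' @export
simulate_zscores <- function(n, grid, sequences, fractions,
                             stage_dist = "uniform", sigma_gen = 1) {
  K <- length(sequences)
  subtype <- sample.int(K, n, replace = TRUE, prob = fractions)
  stage <- draw_stage(n, grid$E, stage_dist)
  G <- lapply(sequences, traj_matrix, grid = grid)
  Z <- matrix(NA_real_, n, grid$n_regions,
              dimnames = list(NULL, grid$regions))
  for (j in seq_len(n))
    Z[j, ] <- G[[subtype[j]]][, stage[j] + 1]
  Z <- Z + matrix(rnorm(n * grid$n_regions, 0, sigma_gen), n)
  list(z = Z, subtype = subtype, stage = stage)
}

#' Reconstruct the exact generating control model
#'
#' Returns the generator's own coefficients as a `control_norm_model`, so
#' that [compute_zscores()] inverts the simulation exactly (used for
#' noise-free round-trip checks; real analyses fit the model from controls
#' instead).
#'
#' @param truth a `synthetic_truth`.
#' @param scanners scanner labels to register the model under.
#' @return A `control_norm_model`.
#' @export
control_model_from_truth <- function(truth, scanners = "site1") {
  sc <- truth$control_coefficients
  beta <- rbind(intercept = sc$intercept, tiv = sc$beta_tiv,
                sex = sc$beta_sex, age = sc$beta_age, age2 = sc$beta_age2)
  colnames(beta) <- sc$region
  strata <- setNames(lapply(scanners, function(s)
    list(beta = beta, resid_mean = setNames(rep(0, nrow(sc)), sc$region),
         resid_sd = setNames(sc$resid_sd, sc$region),
         age_center = truth$age_center, n_controls = NA_integer_)),
    scanners)
  structure(list(strata = strata, regions = sc$region, include_tiv = TRUE),
            class = "control_norm_model")
}

#' Simulate a clinical table linked to the latent truth
#'
#' Encodes the associations the analysis stage should re-detect: epilepsy
#' duration increases with true stage
#' (`duration = a * (stage/E) * 30 + Normal(0, s)`, truncated at 0;
#' defaults a = 1, s = 5, giving Table-1-scale durations around 15 (SD ~9)
#' years at uniform stages); convulsions in the prior year are Bernoulli
#' with log-odds `b0 + b1 * [subtype == designated]`; seizure frequency is
#' a proportional-odds ordinal (0-4) shifted by `freq_beta` for the
#' designated subtype; lifetime ASM count is Poisson with rate increasing
#' in frequency.
#'
#' @param truth a `synthetic_truth`.
#' @param params named overrides: `duration_slope` (a), `duration_sd` (s),
#'   `b0`, `b1`, `designated_subtype`, `freq_beta`, `freq_cutpoints`,
#'   `asm_base`, `asm_per_freq`, `lat_probs`, `surgery_rate`.
#' @param seed optional integer seed.
#' @return A clinical data frame in [load_cohort_tables()] format.
#' @export
simulate_clinical <- function(truth, params = list(), seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!is.null(seed)) set.seed(seed)
  p <- list(duration_slope = 1, duration_sd = 5, b0 = -0.7, b1 = 2,
            designated_subtype = length(truth$fractions),
            freq_beta = 1.5, freq_cutpoints = c(-2, -0.5, 1, 2.5),
            asm_base = 0.5, asm_per_freq = 0.25,
            lat_probs = c(left = 0.4, right = 0.4, bilateral = 0.1,
                          undetermined = 0.1),
            surgery_rate = 0.25)
  p[names(params)] <- params

  n <- length(truth$stage)
  E <- truth$grid$E
  k <- truth$stage
  cj <- truth$subtype
  desig <- as.numeric(cj == p$designated_subtype)

  duration <- pmax(0, p$duration_slope * (k / E) * 30 +
                     rnorm(n, 0, p$duration_sd))
  onset <- pmax(truth$age - duration, 1)
  convulsions <- rbinom(n, 1, stats::plogis(p$b0 + p$b1 * desig))
  lat_freq <- p$freq_beta * desig + rlogis(n)
  frequency <- rowSums(outer(lat_freq, p$freq_cutpoints, ">"))
  asm <- rpois(n, exp(p$asm_base + p$asm_per_freq * frequency))
  laterality <- sample(names(p$lat_probs), n, replace = TRUE,
                       prob = p$lat_probs)
  surgery <- ifelse(runif(n) < p$surgery_rate,
                    sample(1:4, n, replace = TRUE), NA_integer_)

  data.frame(subject_id = truth$subject_id,
             duration_years = duration, onset_age_years = onset,
             seizure_frequency = frequency,
             convulsions_prior_year = convulsions,
             asm_count = asm, laterality = laterality,
             surgery_outcome = surgery, stringsAsFactors = FALSE)
}
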