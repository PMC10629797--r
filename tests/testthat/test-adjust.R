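# helpers building small control tables with known generating coefficients
make_controls <- function(n, scanner = "s1", intercept = 2.5,
                          b_age = -0.01, noise = 0.1, region = "left_hippocampus") {
  d <- data.frame(subject_id = paste0(scanner, "_", seq_len(n)),
                  group = "control", scanner = scanner,
                  age = runif(n, 20, 60), sex = rbinom(n, 1, 0.5),
                  tiv = rnorm(n, 1.5e6, 1e5))
  d[[region]] <- intercept + b_age * d$age + rnorm(n, 0, noise)
  d
}

toy_dict <- function(region = "left_hippocampus") {
  roi_dictionary(data.frame(region_name = c(region, sub("^left", "right", region)),
                            hemisphere = c("left", "right"),
                            tissue_class = "subcortical_volume"))
}

test_that("control model recovers generating coefficients", {
  set.seed(101)
  d <- make_controls(200)
  d$right_hippocampus <- 3 - 0.02 * d$age + rnorm(200, 0, 0.1)
  m <- fit_control_model(d, toy_dict(), run_config())
  expect_lt(abs(m$strata$s1$beta["age", "left_hippocampus"] - (-0.01)), 0.002)
  expect_lt(abs(m$strata$s1$beta["age", "right_hippocampus"] - (-0.02)), 0.002)
  # residual mean over fitting controls is ~0 (vague-prior shrinkage only),
  # residual SD close to the generating noise
  expect_lt(abs(m$strata$s1$resid_mean[["left_hippocampus"]]), 1e-6)
  expect_lt(abs(m$strata$s1$resid_sd[["left_hippocampus"]] - 0.1), 0.02)
})

test_that("degenerate and under-sized inputs error", {
  set.seed(102)
  d <- make_controls(50, noise = 0)
  d$left_hippocampus <- 2.5                  # constant, zero noise
  d$right_hippocampus <- 3
  expect_error(fit_control_model(d, toy_dict(), run_config()),
               "residual SD")
  d2 <- make_controls(10)
  d2$right_hippocampus <- 1
  expect_error(fit_control_model(d2, toy_dict(), run_config()),
               "below the floor")
})

test_that("two strata recover their intercepts independently", {
  set.seed(103)
  d <- rbind(make_controls(150, "old", intercept = 2.5),
             make_controls(150, "new", intercept = 3.5))
  d$right_hippocampus <- d$left_hippocampus
  m <- fit_control_model(d, toy_dict(), run_config())
  # intercept is at the stratum age centre: truth = a + b_age * mean(age)
  for (s in c("old", "new")) {
    ages <- d$age[d$scanner == s]
    truth <- ifelse(s == "old", 2.5, 3.5) - 0.01 * mean(ages)
    expect_equal(unname(m$strata[[s]]$beta["intercept", "left_hippocampus"]),
                 truth, tolerance = 0.05)
  }
  expect_error(compute_zscores(make_controls(5, "unknown_site"), m),
               "unknown scanner stratum")
})

test_that("z-scores are control-normalized and sign-flipped", {
  set.seed(104)
  sim <- simulate_cohort(n_patients = 50, n_controls = 120,
                         regions = paste0("left_r", 1:4), K = 1,
                         fractions = 1, z_events = 1, sigma_gen = 1)
  # synthetic left-only scheme: bypass the constructor's pairing check
  dict <- structure(data.frame(
    region_name = paste0("left_r", 1:4), hemisphere = "left",
    tissue_class = "cortical_thickness"),
    class = c("roi_dictionary", "data.frame"))
  controls <- sim$roi[sim$roi$group == "control", ]
  m <- fit_control_model(controls, dict, run_config())
  z <- compute_zscores(sim$roi, m)
  zc <- z$z[z$group == "control", ]
  expect_true(all(abs(colMeans(zc)) < 1e-6))
  expect_true(all(abs(apply(zc, 2, sd) - 1) < 1e-6))
  expect_true(z$flipped)

  # a subject exactly at the model prediction gets z* = 0; one 2 control-SD
  # below prediction gets z* = +2 (atrophy positive)
  tm <- control_model_from_truth(sim$truth)
  s <- sim$roi[1, ]
  a <- s$age - sim$truth$age_center
  sc <- sim$truth$control_coefficients
  for (i in 1:4) {
    s[[sc$region[i]]] <- sc$intercept[i] + sc$beta_tiv[i] * s$tiv +
      sc$beta_sex[i] * s$sex + sc$beta_age[i] * a + sc$beta_age2[i] * a^2 -
      2 * sc$resid_sd[i]
  }
  z1 <- compute_zscores(s, tm)
  expect_equal(unname(z1$z[1, ]), rep(2, 4), tolerance = 1e-9)
})

test_that("adjustment is idempotent and affine-invariant", {
  set.seed(105)
  d <- make_controls(200)
  d$right_hippocampus <- 3 - 0.02 * d$age + rnorm(200, 0, 0.1)
  m <- fit_control_model(d, toy_dict(), run_config())
  z <- compute_zscores(d, m)

  # refit on the adjusted values: slopes collapse to ~0
  d2 <- d
  d2$left_hippocampus <- -z$z[, "left_hippocampus"]
  d2$right_hippocampus <- -z$z[, "right_hippocampus"]
  m2 <- fit_control_model(d2, toy_dict(), run_config())
  expect_lt(abs(m2$strata$s1$beta["age", "left_hippocampus"]), 0.01)

  # rescaling a raw column leaves z* untouched
  d3 <- d
  d3$left_hippocampus <- 1000 * d3$left_hippocampus
  m3 <- fit_control_model(d3, toy_dict(), run_config())
  z3 <- compute_zscores(d3, m3)
  expect_equal(z3$z[, "left_hippocampus"], z$z[, "left_hippocampus"],
               tolerance = 1e-9)
})

test_that("ipsi/contra regrouping swaps and filters correctly", {
  set.seed(106)
  dict <- default_roi_dictionary()
  n <- 10
  d <- data.frame(subject_id = paste0("P", 1:n), group = "patient",
                  scanner = "s1", age = 30, sex = 0, tiv = 1.5e6)
  Z <- matrix(rnorm(n * 40), n, 40, dimnames = list(NULL, dict$region_name))
  z <- structure(list(z = Z, subject_id = d$subject_id, group = d$group,
                      stratum = d$scanner, flipped = TRUE), class = "zmatrix")
  clin <- data.frame(subject_id = paste0("P", 1:n),
                     laterality = rep(c("left", "right", "bilateral"),
                                      c(4, 4, 2)))
  out <- suppressMessages(regroup_ipsi_contra(z, clin))
  expect_equal(nrow(out$z), 8)
  expect_true(all(grepl("^(ipsi|contra)_", colnames(out$z))))
  # left focus: left_hippocampus -> ipsi_hippocampus
  expect_equal(unname(out$z["P1" == out$subject_id, "ipsi_hippocampus"]),
               unname(Z[1, "left_hippocampus"]))
  # right focus: left_hippocampus -> contra_hippocampus
  expect_equal(unname(out$z["P5" == out$subject_id, "contra_hippocampus"]),
               unname(Z[5, "left_hippocampus"]))
  expect_equal(unname(out$z["P5" == out$subject_id, "ipsi_hippocampus"]),
               unname(Z[5, "right_hippocampus"]))

  clin_none <- data.frame(subject_id = paste0("P", 1:n),
                          laterality = "bilateral")
  expect_error(suppressMessages(regroup_ipsi_contra(z, clin_none)),
               "no subjects")
})
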