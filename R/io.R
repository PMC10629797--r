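# Cohort table I/O. Dialect: UTF-8, separator auto-detected from the header
# line (tab if present, otherwise comma); all outputs are TSV with fixed
# %.9f float formatting so re-exports are byte-identical and round-trips
# hold to 1e-9.

REQUIRED_ROI_COVARIATES <- c("subject_id", "group", "scanner", "age", "sex", "tiv")
REQUIRED_CLINICAL_COLS <- c("subject_id", "duration_years", "onset_age_years",
                            "seizure_frequency", "convulsions_prior_year",
                            "asm_count", "laterality")

detect_sep <- function(path) {
  hdr <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
}

normalize_names <- function(x) gsub("[ .\\-]+", "_", tolower(trimws(x)))

coerce_sex <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA_real_, length(key))
  out[key %in% c("m", "male", "0")] <- 0
  out[key %in% c("f", "female", "1")] <- 1
  out
}

#' Load and validate cohort tables
#'
#' Reads the ROI measurement table (one row per subject: id, group,
#' scanner, age, sex, total intracranial volume, and one column per
#' dictionary region) and, optionally, the clinical table. Headers are
#' matched case-insensitively with separators normalized to underscores.
#' Rows with missing required fields are dropped with a logged count;
#' clinical rows whose id is not a patient id in the ROI table are dropped
#' with a logged count.
#'
#' @param roi_path path to the ROI CSV/TSV.
#' @param clinical_path optional path to the clinical CSV/TSV.
#' @param dictionary an [roi_dictionary()]; defaults to the 40-region scheme.
#' @return list with elements `roi` (validated measurement table) and
#'   `clinical` (validated clinical table or `NULL`).
#' @export
load_cohort_tables <- function(roi_path, clinical_path = NULL,
                               dictionary = default_roi_dictionary()) {
  if (!file.exists(roi_path)) stop("ROI file not found: ", roi_path)
  roi <- read.table(roi_path, header = TRUE, sep = detect_sep(roi_path),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(roi) <- normalize_names(names(roi))

  for (col in REQUIRED_ROI_COVARIATES)
    if (!col %in% names(roi)) stop("required covariate absent: ", col)

  regions <- dictionary$region_name
  missing_regions <- setdiff(regions, names(roi))
  if (length(missing_regions))
    stop("required region column absent: ",
         paste(missing_regions, collapse = ", "))
  extra <- setdiff(names(roi),
                   c(REQUIRED_ROI_COVARIATES, regions, "syndrome"))
  if (length(extra)) {
    warning("ignoring unknown region column(s): ",
            paste(extra, collapse = ", "))
    roi <- roi[, setdiff(names(roi), extra), drop = FALSE]
  }

  roi$sex <- coerce_sex(roi$sex)
  roi$group <- tolower(trimws(roi$group))
  if (!all(roi$group %in% c("patient", "control")))
    stop("group must be 'patient' or 'control'")
  roi$subject_id <- as.character(roi$subject_id)
  roi$scanner <- as.character(roi$scanner)

  need <- c(REQUIRED_ROI_COVARIATES, regions)
  keep <- complete.cases(roi[, need])
  if (any(!keep))
    sustain_log("dropped %d ROI row(s) with missing required fields",
                sum(!keep))
  roi <- roi[keep, , drop = FALSE]
  if (anyDuplicated(roi$subject_id))
    stop("duplicated subject_id in ROI table")
  if (any(roi$age <= 0) || any(roi$tiv <= 0))
    stop("age and tiv must be positive")
  rownames(roi) <- NULL

  clinical <- NULL
  if (!is.null(clinical_path)) {
    if (!file.exists(clinical_path))
      stop("clinical file not found: ", clinical_path)
    clinical <- read.table(clinical_path, header = TRUE,
                           sep = detect_sep(clinical_path),
                           stringsAsFactors = FALSE, check.names = FALSE)
    names(clinical) <- normalize_names(names(clinical))
    for (col in REQUIRED_CLINICAL_COLS)
      if (!col %in% names(clinical)) stop("required covariate absent: ", col)
    clinical$subject_id <- as.character(clinical$subject_id)
    patient_ids <- roi$subject_id[roi$group == "patient"]
    unmatched <- !(clinical$subject_id %in% patient_ids)
    if (any(unmatched))
      sustain_log("dropped %d clinical row(s) with no matching patient id",
                  sum(unmatched))
    clinical <- clinical[!unmatched, , drop = FALSE]
    ok_lat <- c("left", "right", "bilateral", "undetermined", "not_applicable")
    if (!all(clinical$laterality %in% ok_lat))
      stop("laterality values must be one of: ", paste(ok_lat, collapse = ", "))
    sf <- clinical$seizure_frequency
    if (any(!is.na(sf) & (sf < 0 | sf > 4)))
      stop("seizure_frequency must be an ordinal in 0..4")
    if (any(!is.na(clinical$duration_years) & clinical$duration_years < 0))
      stop("duration_years must be >= 0")
    rownames(clinical) <- NULL
  }
  list(roi = roi, clinical = clinical)
}

fixed_num <- function(x) sprintf("%.9f", x)

write_tsv_fixed <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fixed_num)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Export fitted model and per-subject results as TSV
#'
#' Writes, with deterministic row/column order and fixed float precision:
#' one positional-variance TSV per subtype (rows sum to 1), the maximum-
#' likelihood event sequences with subtype fractions, per-subject subtype
#' probabilities / weighted stage / assignment, and per-subtype severity
#' bands (the band 0 = unaffected, 1 = z in \[1,2), 2 = z in \[2,3),
#' 3 = z >= 3 reached by each region at each stage).
#'
#' @param model fitted `sustain_model` (with MCMC samples for the PVDs).
#' @param posteriors `subject_posteriors()` output.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the written file paths.
#' @export
export_results <- function(model, posteriors, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, 2) != 0) stop("unwritable directory: ", out_dir)
  grid <- model$grid
  E <- grid$E
  paths <- character(0)

  pvds <- positional_variance(model)
  for (c in seq_along(pvds)) {
    P <- pvds[[c]]
    df <- data.frame(event = grid$events$event_name,
                     as.data.frame(P), check.names = FALSE)
    names(df) <- c("event", paste0("position_", seq_len(E)))
    p <- file.path(out_dir, sprintf("pvd_subtype%d.tsv", c))
    paths <- c(paths, write_tsv_fixed(df, p))
  }

  seq_df <- do.call(rbind, lapply(seq_along(model$sequences), function(c) {
    data.frame(subtype = c, fraction = model$f[c],
               position = seq_len(E),
               event = grid$events$event_name[model$sequences[[c]]],
               stringsAsFactors = FALSE)
  }))
  paths <- c(paths, write_tsv_fixed(seq_df,
                                    file.path(out_dir, "sequences.tsv")))

  post <- posteriors
  post$assigned_subtype <- ifelse(is.na(post$assigned_subtype),
                                  "unclassified",
                                  as.character(post$assigned_subtype))
  paths <- c(paths, write_tsv_fixed(
    post, file.path(out_dir, "subject_posteriors.tsv")))

  bands <- do.call(rbind, lapply(seq_along(model$sequences), function(c) {
    G <- traj_matrix(model$sequences[[c]], grid)
    B <- (G >= 1) + (G >= 2) + (G >= 3)
    df <- data.frame(subtype = c, region = grid$regions,
                     as.data.frame(B), check.names = FALSE)
    names(df) <- c("subtype", "region", paste0("stage_", 0:E))
    df
  }))
  paths <- c(paths, write_tsv_fixed(
    bands, file.path(out_dir, "severity_bands.tsv")))

  sustain_log("exported %d result file(s) to %s", length(paths), out_dir)
  invisible(paths)
}
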