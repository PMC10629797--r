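#' Default run configuration
#'
#' Central knobs of the pipeline with the conventions used throughout:
#' z-score events at thresholds 1, 2, 3 per region with a plateau at
#' `z_max = 5`; 25 optimizer start points; one million MCMC iterations at
#' production scale (override for tests); at most 4 subtypes; 10-fold
#' cross-validation; a strict `> 0.5` subtype-assignment cut-off; 5000
#' bootstrap resamples for Spearman confidence intervals.
#'
#' @param ... named overrides of any default field.
#' @return A validated `run_config` list.
#' @export
#' @examples
#' cfg <- run_config(n_mcmc_iter = 10000, rng_seed = 1)
run_config <- function(...) {
  cfg <- list(
    z_events = c(1, 2, 3),
    z_max = 5,
    n_startpoints = 25,
    n_mcmc_iter = 1e6,
    max_subtypes = 4,
    cv_folds = 10,
    rng_seed = NULL,
    subtype_assignment_cutoff = 0.5,
    bootstrap_reps = 5000,
    sigma = 1,
    min_controls = 20,
    prior_precision = 1e-6,
    include_tiv = TRUE,
    sample_fractions = TRUE,
    em_tol = 1e-6,
    em_max_rounds = 100,
    burn_frac = 0.1,
    dirichlet_scale = 100,
    parsimony_delta = 6)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  z <- cfg$z_events
  if (length(z) < 1 || any(diff(z) <= 0))
    stop("z_events must be strictly increasing")
  if (max(z) >= cfg$z_max)
    stop("z_events must all be below z_max")
  if (cfg$cv_folds < 2) stop("cv_folds must be >= 2")
  co <- cfg$subtype_assignment_cutoff
  if (co <= 0 || co >= 1) stop("subtype_assignment_cutoff must be in (0,1)")
  if (cfg$max_subtypes < 1) stop("max_subtypes must be >= 1")
  class(cfg) <- "run_config"
  cfg
}

#' Read a flat TOML-style configuration file
#'
#' Parses a minimal TOML subset: `key = value` lines, `#` comments, quoted
#' strings, booleans, numbers and flat numeric arrays `[1, 2, 3]`. Section
#' headers are flattened as prefixes (`[mcmc]` + `iters` -> `mcmc.iters`),
#' but the default configuration uses top-level keys only.
#'
#' @param path configuration file.
#' @return A `run_config` built from defaults overridden by the file.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  vals <- list()
  section <- ""
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- paste0(gsub("^\\[|\\]$", "", ln), ".")
      next
    }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed config line: ", ln)
    key <- paste0(section, trimws(substr(ln, 1, eq - 1)))
    raw <- trimws(substr(ln, eq + 1, nchar(ln)))
    vals[[key]] <- parse_toml_value(raw)
  }
  do.call(run_config, vals)
}

parse_toml_value <- function(raw) {
  if (grepl("^\".*\"$", raw)) return(gsub("^\"|\"$", "", raw))
  if (raw %in% c("true", "false")) return(raw == "true")
  if (grepl("^\\[.*\\]$", raw)) {
    inner <- trimws(strsplit(gsub("^\\[|\\]$", "", raw), ",")[[1]])
    inner <- inner[inner != ""]
    return(as.numeric(gsub("_", "", inner)))
  }
  num <- suppressWarnings(as.numeric(gsub("_", "", raw)))
  if (is.na(num)) stop("cannot parse config value: ", raw)
  num
}
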