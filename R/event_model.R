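# The piecewise-linear z-score event model. An event is one region crossing
# one z threshold; a sequence is a permutation of all events in which each
# region crosses its thresholds in increasing order. A region's expected
# trajectory interpolates linearly through (0, 0), (pos(z_1), z_1), ...,
# (E, z_max); if the region's last threshold event sits at position E the
# plateau anchor is dropped (no zero-length segment). Stages are the
# integers 0..E with a uniform prior; measurement noise is Gaussian with a
# shared SD (default 1, since inputs are control-referenced z-scores).

#' Build an event grid
#'
#' @param regions character vector of region names (the z-matrix columns).
#' @param z_events vector of strictly increasing z thresholds applied to
#'   every region (default `c(1, 2, 3)`).
#' @param z_max plateau z reached at the final stage (default 5).
#' @return An `event_grid`: events table (region, threshold), `E`, `z_max`.
#' @export
#' @examples
#' g <- event_grid(c("hippocampus", "thalamus"), z_events = c(1, 2))
#' g$E  # 4 events
event_grid <- function(regions, z_events = c(1, 2, 3), z_max = 5) {
  stopifnot(length(regions) >= 1, !anyDuplicated(regions))
  if (any(diff(z_events) <= 0) || length(z_events) < 1)
    stop("z_events must be strictly increasing")
  if (z_max <= max(z_events)) stop("z_max must exceed max(z_events)")
  events <- expand.grid(threshold = z_events,
                        region_idx = seq_along(regions),
                        KEEP.OUT.ATTRS = FALSE)
  events <- events[order(events$region_idx, events$threshold), ]
  events <- data.frame(
    region_idx = events$region_idx,
    region = regions[events$region_idx],
    threshold = events$threshold,
    event_name = sprintf("%s_z%g", regions[events$region_idx],
                         events$threshold),
    stringsAsFactors = FALSE)
  rownames(events) <- NULL
  structure(list(regions = regions, events = events,
                 E = nrow(events), n_regions = length(regions),
                 z_max = rep(z_max, length(regions))),
            class = "event_grid")
}

#' Check that a sequence respects the within-region threshold order
#'
#' @param s integer permutation of `1:grid$E` (event indices in order).
#' @param grid an [event_grid()].
#' @return `TRUE` iff every region crosses its thresholds in increasing
#'   order along `s`.
#' @export
validate_sequence <- function(s, grid) {
  stopifnot(inherits(grid, "event_grid"))
  if (length(s) != grid$E || !setequal(s, seq_len(grid$E)))
    stop("sequence is not a permutation of the grid events")
  pos <- integer(grid$E)
  pos[s] <- seq_len(grid$E)
  ev <- grid$events
  for (i in unique(ev$region_idx)) {
    idx <- which(ev$region_idx == i)          # ascending threshold order
    if (is.unsorted(pos[idx], strictly = TRUE)) return(FALSE)
  }
  TRUE
}

#' Draw a uniformly random valid event sequence
#'
#' Random-keys construction: draw one uniform key per event, sort each
#' region's keys so ascending thresholds get ascending keys, then order all
#' events by key. This samples uniformly from the valid orderings (linear
#' extensions of the per-region chains).
#'
#' @param grid an [event_grid()].
#' @return Integer event sequence.
#' @export
random_valid_sequence <- function(grid) {
  u <- runif(grid$E)
  for (i in unique(grid$events$region_idx)) {
    idx <- which(grid$events$region_idx == i)
    u[idx] <- sort(u[idx])
  }
  order(u)
}

# region x (E+1) matrix of expected z at stages 0..E
traj_matrix <- function(s, grid) {
  G <- cpp_traj_matrix(as.integer(s), as.integer(grid$events$region_idx) - 1L,
                       as.numeric(grid$events$threshold),
                       as.numeric(grid$z_max), grid$n_regions)
  dimnames(G) <- list(grid$regions, paste0("stage_", 0:grid$E))
  G
}

#' Expected z of one region at one stage
#'
#' @param region region name or index.
#' @param t integer stage in `0..E`.
#' @param s valid event sequence.
#' @param grid an [event_grid()].
#' @return The piecewise-linear trajectory value `g_region(t)`.
#' @export
trajectory_value <- function(region, t, s, grid) {
  if (any(t < 0 | t > grid$E)) stop("stage t outside 0..E")
  if (is.character(region)) region <- match(region, grid$regions)
  if (any(is.na(region))) stop("unknown region")
  G <- traj_matrix(s, grid)
  G[region, t + 1]
}

#' Per-stage likelihoods and marginal log-likelihood for one subject
#'
#' `L(k) = prod_i Normal(x_i; g_i(k), sigma)` for stages `k = 0..E`,
#' computed in log space, and the marginal
#' `log( (1/(E+1)) * sum_k L(k) )` under the uniform stage prior.
#'
#' @param x numeric vector, one z-score per grid region.
#' @param s valid event sequence.
#' @param grid an [event_grid()].
#' @param sigma shared Gaussian noise SD (> 0).
#' @return list with `loglik` (length `E+1`), `posterior` (normalized stage
#'   posterior) and `marginal` (scalar log marginal).
#' @export
stage_likelihoods <- function(x, s, grid, sigma = 1) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (length(x) != grid$n_regions)
    stop("x must have one value per region")
  L <- cpp_stage_loglik(matrix(as.numeric(x), nrow = 1),
                        traj_matrix(s, grid), sigma)[1, ]
  m <- max(L)
  post <- exp(L - m)
  post <- post / sum(post)
  marg <- m + log(sum(exp(L - m))) - log(grid$E + 1)
  list(loglik = L, posterior = post, marginal = marg)
}

# n x C matrix of per-subject marginal logliks, one column per sequence
subject_loglik_matrix <- function(X, sequences, grid, sigma = 1) {
  X <- as_z_input(X, grid)
  L <- vapply(sequences, function(s)
    cpp_seq_subject_loglik(X, as.integer(s),
                           as.integer(grid$events$region_idx) - 1L,
                           as.numeric(grid$events$threshold),
                           as.numeric(grid$z_max), grid$n_regions, sigma),
    numeric(nrow(X)))
  matrix(L, nrow = nrow(X))
}

# accept a zmatrix or a plain matrix; order columns by grid regions
as_z_input <- function(X, grid) {
  if (inherits(X, "zmatrix")) X <- X$z
  X <- as.matrix(X)
  if (!is.null(colnames(X))) {
    if (!all(grid$regions %in% colnames(X)))
      stop("z matrix lacks grid region column(s)")
    X <- X[, grid$regions, drop = FALSE]
  } else if (ncol(X) != grid$n_regions) {
    stop("z matrix has ", ncol(X), " columns; grid expects ",
         grid$n_regions)
  }
  X
}

#' Mixture log-likelihood of a dataset under subtype sequences
#'
#' `sum_j log sum_c f_c exp(l_j(S_c))`, log-sum-exp stabilized, where
#' `l_j(S_c)` is the subject's stage-marginalized log-likelihood under
#' sequence `S_c`.
#'
#' @param X z-score matrix (subjects x regions) or `zmatrix`.
#' @param sequences list of valid event sequences.
#' @param fractions subtype fractions on the simplex.
#' @param grid an [event_grid()].
#' @param sigma shared noise SD.
#' @return Scalar total log-likelihood.
#' @export
dataset_log_likelihood <- function(X, sequences, fractions, grid, sigma = 1) {
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be non-negative and sum to 1")
  if (length(sequences) != length(fractions))
    stop("one fraction per sequence required")
  L <- subject_loglik_matrix(X, sequences, grid, sigma)
  cpp_mixture_loglik(L, as.numeric(fractions))
}
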