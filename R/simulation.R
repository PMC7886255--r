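#' Generate a random attractor set
#'
#' Draws every bit independently and equiprobably (0/1), resampling
#' until all states across the set are pairwise distinct. Cyclic
#' attractors are random distinct state lists, not cycles of an actual
#' Boolean network: the observability analysis depends only on the
#' states, and this mirrors how synthetic attractor sets are used in the
#' sensitivity experiments. Uses the current RNG state; call
#' [set.seed()] for reproducibility.
#'
#' @param n gene count.
#' @param m attractor count (>= 2).
#' @param period attractor period(s): a single value for all attractors
#'   or a length-m vector (1 = singleton).
#' @return an [attractor_set()]; attribute `resamples` counts rejection
#'   rounds due to duplicate states.
#' @export
random_attractor_set <- function(n, m, period = 1L) {
  stopifnot(n >= 1L, m >= 2L)
  periods <- as.integer(rep_len(period, m))
  stopifnot(all(periods >= 1L))
  total <- sum(periods)
  if (2^n < total)
    stop(sprintf("cannot draw %d distinct states from a 2^%d state space",
                 total, n))
  resamples <- 0L
  repeat {
    bits <- matrix(sample(0:1, total * n, replace = TRUE), total, n)
    if (!anyDuplicated(apply(bits, 1L, paste0, collapse = ""))) break
    resamples <- resamples + 1L
    if (resamples > 1000L) stop("too many resampling rounds; state space too small")
  }
  idx <- split(seq_len(total), rep(seq_len(m), periods))
  out <- attractor_set(lapply(idx, function(i) bits[i, , drop = FALSE]))
  attr(out, "resamples") <- resamples
  out
}

#' Run a repeated-trials observability experiment
#'
#' Draws `trials` independent random attractor sets with the given
#' dimensions, solves each, and summarizes the minimal consecutive-node
#' count (numNode) across trials.
#'
#' @param n gene count.
#' @param m attractor count.
#' @param period attractor period (1 for singleton experiments).
#' @param trials number of independent repetitions (>= 1).
#' @param seed optional RNG seed applied before the first trial.
#' @return list with `num_node` (per-trial minima), `mean_num_node`,
#'   and the configuration (`n`, `m`, `period`, `trials`, `seed`).
#' @examples
#' run_experiment(n = 50, m = 4, period = 1, trials = 5, seed = 1)$mean_num_node
#' @export
run_experiment <- function(n, m, period = 1L, trials = 10L, seed = NULL) {
  stopifnot(trials >= 1L)
  if (!is.null(seed)) set.seed(seed)
  vals <- vapply(seq_len(trials), function(i) {
    s <- random_attractor_set(n, m, period)
    as.numeric(ao_solve(s, report_windows = FALSE)$min_length)
  }, 0)
  list(num_node = vals, mean_num_node = mean(vals),
       n = n, m = m, period = period, trials = trials, seed = seed)
}

#' Sensitivity sweep over gene count or attractor count
#'
#' Repeats [run_experiment()] along a grid of either `n` or `m` values,
#' holding the other fixed, and returns the per-trial numNode values at
#' every grid point — the raw material for the distribution histograms
#' of the sensitivity analyses.
#'
#' @param axis `"n"` or `"m"`: which dimension varies.
#' @param values grid values for the varying dimension.
#' @param fixed the value of the non-varying dimension.
#' @param period attractor period (default 1).
#' @param trials repetitions per grid point.
#' @param seed optional RNG seed applied once before the sweep.
#' @return a data.frame with columns `n`, `m`, `period`, `trial`,
#'   `num_node`, one row per trial per grid point.
#' @export
ao_sweep <- function(axis = c("n", "m"), values, fixed, period = 1L,
                     trials = 10L, seed = NULL) {
  axis <- match.arg(axis)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(values, function(v) {
    n <- if (axis == "n") v else fixed
    m <- if (axis == "m") v else fixed
    ex <- run_experiment(n, m, period, trials, seed = NULL)
    data.frame(n = n, m = m, period = period,
               trial = seq_len(trials), num_node = ex$num_node)
  })
  do.call(rbind, out)
}
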