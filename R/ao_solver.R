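#' Minimum window length needed information-theoretically
#'
#' \eqn{m} distinct binary patterns need at least \eqn{\lceil \log_2 m
#' \rceil} bits, so no window shorter than that can discriminate
#' \eqn{m} attractors. This is both the run-length threshold of the
#' zero-run analysis and the global lower bound on the answer.
#'
#' @param m attractor count (>= 1).
#' @return non-negative integer; 0 for m = 1.
#' @export
ao_threshold <- function(m) {
  stopifnot(m >= 1)
  as.integer(ceiling(log2(m)))
}

# Decode combination index (1-based, attractor 1 slowest-varying) into a
# phase choice vector.
.phase_choice <- function(periods, idx) {
  m <- length(periods)
  choice <- integer(m)
  idx <- idx - 1L
  for (i in m:1) {
    choice[i] <- idx %% periods[i] + 1L
    idx <- idx %/% periods[i]
  }
  choice
}

# Materialize the m x n matrix for one phase choice.
.combination_matrix <- function(aset, choice) {
  A <- t(vapply(seq_len(aset$m),
                function(i) aset$attractors[[i]][choice[i], ],
                integer(aset$n)))
  attr(A, "phase_choice") <- choice
  A
}

#' Enumerate all phase combinations of an attractor set
#'
#' A phase combination picks one global state (phase) from each of the m
#' attractors, giving an m x n binary matrix; there are
#' \eqn{L = l_1 l_2 \cdots l_m} combinations. They are returned in
#' lexicographic order of the phase choice, attractor 1 slowest-varying,
#' so that cyclic attractors later in the set cycle fastest.
#'
#' @param aset an [attractor_set()].
#' @return list of L integer matrices, each with a `phase_choice` attribute.
#' @export
enumerate_combinations <- function(aset) {
  stopifnot(inherits(aset, "attractor_set"))
  lapply(seq_len(aset$L),
         function(i) .combination_matrix(aset, .phase_choice(aset$periods, i)))
}

#' Pairwise XOR (difference) matrix of a phase combination
#'
#' For each unordered attractor pair (i, k), i < k, in lexicographic
#' order, the row is the elementwise XOR of rows i and k of the
#' combination matrix: a 0 marks a column where the two attractors
#' agree, so a window of columns fails to separate the pair exactly when
#' it falls inside a run of 0's of that row.
#'
#' @param A an m x n 0/1 matrix (one phase combination).
#' @return a C(m,2) x n 0/1 integer matrix with attribute `pair_index`,
#'   a 2-column matrix of the (i, k) labels per row.
#' @export
pair_xor_matrix <- function(A) {
  A <- as.matrix(A)
  m <- nrow(A)
  if (m < 2L) stop("need at least two attractors to form pairs")
  pairs <- which(upper.tri(diag(m)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  bi <- matrix(0L, nrow(pairs), ncol(A))
  for (r in seq_len(nrow(pairs)))
    bi[r, ] <- bitwXor(A[pairs[r, 1L], ], A[pairs[r, 2L], ])
  dimnames(pairs) <- list(NULL, c("i", "k"))
  attr(bi, "pair_index") <- pairs
  bi
}

#' Find qualifying zero runs in a pairwise difference matrix
#'
#' Scans every row for maximal runs of consecutive 0's of length at
#' least `threshold` and pools them (duplicates across rows are
#' retained). Any candidate window lying inside one of these runs fails
#' to separate the corresponding attractor pair.
#'
#' @param bi a pairwise difference matrix ([pair_xor_matrix()]).
#' @param threshold minimum run length to record (>= 1); the solver uses
#'   [ao_threshold()] of the attractor count.
#' @return a run table: list with `runs` (2-column matrix of closed
#'   1-based `[start, end]` intervals), `covered` (sorted union of run
#'   columns), `pruned` (`NULL` until [prune_runs()]), `threshold`, `n`.
#' @export
find_zero_runs <- function(bi, threshold) {
  stopifnot(threshold >= 1)
  bi <- as.matrix(bi)
  n <- ncol(bi)
  starts <- integer(0); ends <- integer(0)
  for (r in seq_len(nrow(bi))) {
    rl <- rle(bi[r, ] == 0L)
    e <- cumsum(rl$lengths)
    s <- e - rl$lengths + 1L
    keep <- rl$values & rl$lengths >= threshold
    starts <- c(starts, s[keep]); ends <- c(ends, e[keep])
  }
  runs <- cbind(start = starts, end = ends)
  covered <- if (nrow(runs) == 0L) integer(0) else
    sort(unique(unlist(lapply(seq_len(nrow(runs)),
                              function(j) runs[j, 1L]:runs[j, 2L]))))
  list(runs = runs, covered = covered, pruned = NULL,
       threshold = as.integer(threshold), n = n)
}

#' Columns not covered by any qualifying zero run
#'
#' Returns \eqn{U \setminus B_{uni}} where U = 1..n. A nonempty result
#' certifies that the minimum for this combination equals the
#' information-theoretic threshold: any threshold-length window
#' containing an uncovered column separates all pairs.
#'
#' @param rt a run table from [find_zero_runs()].
#' @param n gene count (defaults to the run table's own).
#' @return integer vector of uncovered columns (possibly empty).
#' @export
coverage_gap <- function(rt, n = rt$n) {
  setdiff(seq_len(n), rt$covered)
}

#' Sort and prune the zero-run list
#'
#' Runs are sorted by start column; among runs sharing a start only the
#' longest is kept, and any run strictly contained in another run is
#' removed as well (a contained run constrains no window that the
#' containing run does not). The result has strictly increasing starts
#' and strictly increasing ends.
#'
#' @param rt a run table from [find_zero_runs()].
#' @return the run table with `pruned` populated.
#' @export
prune_runs <- function(rt) {
  runs <- rt$runs
  if (nrow(runs) == 0L) { rt$pruned <- runs; return(rt) }
  runs <- runs[order(runs[, 1L], -runs[, 2L]), , drop = FALSE]
  # keep a run only if its end exceeds every end seen at an earlier or
  # equal start: removes same-start duplicates and contained runs alike
  keep <- runs[, 2L] > c(-1L, cummax(runs[, 2L]))[seq_len(nrow(runs))]
  rt$pruned <- runs[keep, , drop = FALSE]
  rt
}

#' Per-combination minimum window length from the pruned runs
#'
#' When every column is covered by some qualifying run, the minimum
#' window length for the combination is
#' \deqn{\max\{\min_j [B_{ni}(j,2) - B_{ni}(j+1,1) + 3],\ \lceil \log_2 m \rceil\}}
#' over adjacent pruned-run pairs j: the inner expression is the length
#' of the shortest window that pokes one column past the end of run j
#' and one column before the start of run j+1, which no pooled run can
#' contain. A single pruned run spanning all of 1..n means some
#' attractor pair agrees everywhere: the combination is infeasible and
#' `Inf` is returned.
#'
#' @param rt a run table with `pruned` populated ([prune_runs()]).
#' @param m attractor count.
#' @return positive integer, or `Inf` when indistinguishable.
#' @export
min_window_length <- function(rt, m) {
  if (is.null(rt$pruned)) stop("run table has not been pruned; see prune_runs()")
  pr <- rt$pruned
  thr <- ao_threshold(m)
  if (nrow(pr) == 1L && pr[1L, 1L] == 1L && pr[1L, 2L] == rt$n)
    return(Inf)
  if (nrow(pr) < 2L)
    stop("pruned run table inconsistent with full coverage")
  j <- seq_len(nrow(pr) - 1L)
  cand <- min(pr[j, 2L] - pr[j + 1L, 1L] + 3L)
  max(cand, thr)
}

#' Windows of a given length that distinguish all rows
#'
#' Recovery pass used to report achieving windows: all start positions a
#' such that the row restrictions of `A` to columns `[a, a + w - 1]` are
#' pairwise distinct. Windows are linear (no wrap-around).
#'
#' @param A an m x n 0/1 matrix (one phase combination).
#' @param w window length (>= 1).
#' @return 2-column integer matrix of `[start, end]` windows, ascending
#'   by start; zero rows when none qualifies.
#' @export
recover_windows <- function(A, w) {
  A <- as.matrix(A)
  n <- ncol(A)
  stopifnot(w >= 1)
  if (w > n) return(cbind(start = integer(0), end = integer(0)))
  ok <- logical(n - w + 1L)
  for (a in seq_len(n - w + 1L)) {
    cols <- a:(a + w - 1L)
    codes <- if (w <= 50L)
      as.vector(A[, cols, drop = FALSE] %*% 2^(seq_len(w) - 1L))
    else
      apply(A[, cols, drop = FALSE], 1L, paste0, collapse = "")
    ok[a] <- !anyDuplicated(codes)
  }
  starts <- which(ok)
  cbind(start = starts, end = starts + w - 1L)
}

# Run the zero-run analysis on one combination matrix; returns minL
# (integer or Inf).
.combination_min <- function(A, m) {
  thr <- ao_threshold(m)
  bi <- pair_xor_matrix(A)
  rt <- find_zero_runs(bi, max(thr, 1L))
  if (length(coverage_gap(rt)) > 0L) return(thr)
  min_window_length(prune_runs(rt), m)
}

#' Solve the attractor-observability problem
#'
#' Finds the minimum number of consecutive nodes whose joint state
#' discriminates every attractor from every other, over all phase
#' combinations of the set. For each combination the pairwise XOR matrix
#' is analyzed via its qualifying zero runs: an uncovered column
#' certifies the information-theoretic minimum outright, otherwise the
#' pruned-run formula of [min_window_length()] applies. The overall
#' answer is the minimum across combinations; a window is deemed
#' sufficient if *some* phase assignment makes the patterns distinct.
#'
#' By default the scan stops early once a combination attains the lower
#' bound \eqn{\lceil \log_2 m \rceil}; with `exhaustive = TRUE` every
#' combination is evaluated and the per-combination minima are reported.
#'
#' @param aset an [attractor_set()].
#' @param exhaustive evaluate all L combinations (default `FALSE`:
#'   early termination).
#' @param report_windows recover and report all achieving windows
#'   (default `TRUE`).
#' @return an object of class `ao_result`: list with `min_length`
#'   (integer, 0 for m = 1, `Inf` if infeasible), `feasible`, `windows`
#'   (data.frame `combination`, `start`, `end`, 1-based inclusive),
#'   `per_combination` (numeric vector of minL over all L combinations;
#'   only with `exhaustive = TRUE`), `threshold`, `m`, `n`, `L`,
#'   `evaluated` (number of combinations examined).
#' @examples
#' s <- attractor_set(list(c(0,0,1,1,0,1,1), c(1,1,0,0,0,1,0),
#'                         rbind(c(1,1,0,1,0,1,0), c(0,0,1,1,1,0,0)),
#'                         rbind(c(0,0,1,0,0,1,1), c(1,1,0,1,1,1,0))))
#' ao_solve(s)
#' @export
ao_solve <- function(aset, exhaustive = FALSE, report_windows = TRUE) {
  stopifnot(inherits(aset, "attractor_set"))
  m <- aset$m; n <- aset$n; L <- aset$L
  thr <- ao_threshold(m)
  empty_windows <- data.frame(combination = integer(0), start = integer(0),
                              end = integer(0))
  if (m == 1L) {
    return(structure(list(min_length = 0L, feasible = TRUE,
                          windows = empty_windows,
                          per_combination = if (exhaustive) rep(0, L),
                          threshold = 0L, m = m, n = n, L = L, evaluated = 0L),
                     class = "ao_result"))
  }
  minL <- rep(NA_real_, L)
  best <- Inf
  evaluated <- 0L
  for (i in seq_len(L)) {
    A <- .combination_matrix(aset, .phase_choice(aset$periods, i))
    minL[i] <- .combination_min(A, m)
    evaluated <- i
    best <- min(best, minL[i])
    if (!exhaustive && best == thr) break
  }
  feasible <- is.finite(best)
  windows <- empty_windows
  if (report_windows && feasible) {
    hit <- which(!is.na(minL) & minL == best)
    wins <- lapply(hit, function(i) {
      A <- .combination_matrix(aset, .phase_choice(aset$periods, i))
      w <- recover_windows(A, best)
      if (nrow(w) == 0L) NULL else
        data.frame(combination = i, start = w[, 1L], end = w[, 2L])
    })
    wins <- wins[!vapply(wins, is.null, TRUE)]
    if (length(wins) > 0L) {
      windows <- do.call(rbind, wins)
      windows <- windows[order(windows$combination, windows$start), ]
      rownames(windows) <- NULL
    }
  }
  structure(list(
    min_length = if (feasible) as.integer(best) else Inf,
    feasible = feasible, windows = windows,
    per_combination = if (exhaustive) minL,
    threshold = thr, m = m, n = n, L = L, evaluated = evaluated),
    class = "ao_result")
}

#' @rdname ao_solve
#' @param a an [attractor_set()] (for the `solve` method).
#' @param b unused, for generic consistency.
#' @param ... passed on to [ao_solve()].
#' @export
solve.attractor_set <- function(a, b, ...) ao_solve(a, ...)

#' @export
print.ao_result <- function(x, ...) {
  cat("Attractor observability\n")
  cat(sprintf("  m = %d attractors, n = %d genes, L = %d phase combination%s (%d evaluated)\n",
              x$m, x$n, x$L, if (x$L == 1L) "" else "s", x$evaluated))
  if (!x$feasible) {
    cat("  INFEASIBLE: some attractor pair agrees on every node in every phase combination\n")
    return(invisible(x))
  }
  cat(sprintf("  minimum consecutive nodes: %d (lower bound ceil(log2 m) = %d)\n",
              x$min_length, x$threshold))
  if (nrow(x$windows) > 0L) {
    lab <- sprintf("[%d,%d]", x$windows$start, x$windows$end)
    cat(sprintf("  achieving windows (combination: columns): %s\n",
                paste(sprintf("%d: %s", x$windows$combination, lab),
                      collapse = "; ")))
  }
  invisible(x)
}

#' @export
summary.ao_result <- function(object, ...) {
  print(object)
  if (!is.null(object$per_combination)) {
    cat("  per-combination minima:",
        paste(ifelse(is.finite(object$per_combination),
                     object$per_combination, "Inf"), collapse = ", "), "\n")
  }
  invisible(object)
}
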