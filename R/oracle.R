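#' Does a window of consecutive nodes distinguish all rows?
#'
#' Direct check of the observability definition for one phase
#' combination: restrict every row of `A` to the columns
#' `[start, start + w - 1]` and test whether the restrictions are
#' pairwise distinct.
#'
#' @param A an m x n 0/1 matrix (one phase combination).
#' @param start first column of the window (1-based).
#' @param w window length.
#' @return `TRUE` iff all m restricted patterns differ.
#' @export
window_distinguishes <- function(A, start, w) {
  A <- as.matrix(A)
  n <- ncol(A)
  if (start < 1L || w < 1L || start + w - 1L > n)
    stop(sprintf("window [%d,%d] out of range 1..%d", start, start + w - 1L, n))
  cols <- start:(start + w - 1L)
  keys <- do.call(paste0, lapply(cols, function(j) A[, j]))
  !anyDuplicated(keys)
}

#' Brute-force minimal distinguishing window
#'
#' Reference solver used to validate the zero-run algorithm: scans
#' window lengths in ascending order and, for each, every phase
#' combination and every start position, using only the direct
#' definition ([window_distinguishes()]). The first length with an
#' achieving window is minimal by construction. Exponential in the
#' number of cyclic attractors via L; intended for small instances.
#'
#' @param aset an [attractor_set()].
#' @param budget refuse when `L * n^2 * m^2` exceeds this (default 1e8).
#' @return list with `min_length` (integer, 0 for m = 1, `Inf` when even
#'   full-length windows fail everywhere) and `windows` (data.frame
#'   `combination`, `start`, `end` of all achievers at the minimum).
#' @export
brute_force_min <- function(aset, budget = 1e8) {
  stopifnot(inherits(aset, "attractor_set"))
  m <- aset$m; n <- aset$n; L <- aset$L
  if (L * n^2 * m^2 > budget)
    stop(sprintf("instance size L*n^2*m^2 = %.3g exceeds oracle budget %.3g",
                 L * n^2 * m^2, budget))
  empty <- data.frame(combination = integer(0), start = integer(0),
                      end = integer(0))
  if (m == 1L) return(list(min_length = 0L, windows = empty))
  # own combination enumeration: cartesian product of phase indices,
  # attractor 1 slowest-varying to match the solver's reporting order
  grid <- rev(expand.grid(rev(lapply(aset$periods, seq_len))))
  combos <- lapply(seq_len(nrow(grid)), function(g) {
    t(vapply(seq_len(m),
             function(i) aset$attractors[[i]][grid[g, i], ], integer(n)))
  })
  for (w in seq_len(n)) {
    hits <- empty
    for (g in seq_along(combos)) {
      for (a in seq_len(n - w + 1L)) {
        if (window_distinguishes(combos[[g]], a, w))
          hits <- rbind(hits, data.frame(combination = g, start = a,
                                         end = a + w - 1L))
      }
    }
    if (nrow(hits) > 0L) {
      rownames(hits) <- NULL
      return(list(min_length = w, windows = hits))
    }
  }
  list(min_length = Inf, windows = empty)
}
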