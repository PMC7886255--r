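#' Construct an attractor set
#'
#' An attractor set holds the \eqn{m} singleton or cyclic attractors of a
#' Boolean network over a shared gene count \eqn{n}. Each attractor is an
#' ordered cyclic list of global states (Gene Activity Profiles); a
#' period-1 attractor is a fixed point, period \eqn{p \ge 2} a cycle.
#'
#' All global states across the whole set must be pairwise distinct: two
#' attractors of a deterministic synchronous network can never share a
#' state, and the observability problem is ill-posed otherwise.
#'
#' @param attractors a list of 0/1 matrices (one row per state, one column
#'   per gene) or 0/1 vectors (singleton attractors). All must have the
#'   same number of columns.
#' @return an object of class `attractor_set` with elements `attractors`
#'   (list of integer matrices), `m`, `n`, `periods`, `L` (the number of
#'   phase combinations \eqn{L = l_1 l_2 \cdots l_m}).
#' @examples
#' s <- attractor_set(list(c(0, 1, 0), rbind(c(1, 1, 0), c(0, 0, 1))))
#' s$periods
#' @export
attractor_set <- function(attractors) {
  if (!is.list(attractors) || length(attractors) == 0L)
    stop("'attractors' must be a non-empty list of 0/1 matrices or vectors")
  mats <- lapply(unname(attractors), function(a) {
    if (is.null(dim(a))) a <- matrix(a, nrow = 1L)
    a <- as.matrix(a)
    storage.mode(a) <- "integer"
    if (!all(a %in% c(0L, 1L))) stop("attractor states must be 0/1")
    a
  })
  n <- ncol(mats[[1L]])
  if (n < 1L) stop("attractors must have at least one gene")
  if (any(vapply(mats, ncol, 0L) != n))
    stop("all attractors must share the same gene count")
  keys <- unlist(lapply(mats, function(a) apply(a, 1L, paste0, collapse = "")))
  if (anyDuplicated(keys))
    stop("global states must be pairwise distinct across the attractor set")
  periods <- vapply(mats, nrow, 0L)
  structure(
    list(attractors = mats, m = length(mats), n = n,
         periods = periods, L = prod(periods)),
    class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
  cat(sprintf("Attractor set: m = %d attractors over n = %d genes\n", x$m, x$n))
  cat(sprintf("  periods: %s (max P = %d); phase combinations L = %d\n",
              paste(x$periods, collapse = ", "), max(x$periods), x$L))
  invisible(x)
}

#' @export
format.attractor_set <- function(x, ...) {
  sprintf("<attractor_set: m=%d, n=%d, L=%d>", x$m, x$n, x$L)
}

#' Build an attractor set of singletons from the rows of a matrix
#'
#' @param mat a 0/1 matrix; each row becomes one singleton attractor.
#' @return an `attractor_set` with `m = nrow(mat)` period-1 attractors.
#' @export
singleton_attractors <- function(mat) {
  mat <- as.matrix(mat)
  attractor_set(lapply(seq_len(nrow(mat)), function(i) mat[i, ]))
}

#' Read an attractor set from a TSV file
#'
#' The file has columns `attractor_id`, `phase`, then either a single
#' `state` column of n-character binary strings or one 0/1 column per
#' gene. Phases are the within-attractor state order (1-based).
#'
#' @param path file path.
#' @return an `attractor_set`.
#' @seealso [write_attractors()]
#' @export
read_attractors <- function(path) {
  first <- readLines(path, n = 50L)
  first <- first[nzchar(first) & !startsWith(first, "#")][1L]
  hdr <- strsplit(first, "\t", fixed = TRUE)[[1L]]
  cls <- if ("state" %in% hdr) c(state = "character") else NA
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          colClasses = cls)
  need <- c("attractor_id", "phase")
  if (!all(need %in% names(df)))
    stop("attractor TSV must have columns 'attractor_id' and 'phase'")
  if ("state" %in% names(df)) {
    states <- as.character(df$state)
    if (length(unique(nchar(states))) != 1L)
      stop("all state strings must have equal length")
    if (!all(grepl("^[01]+$", states)))
      stop("state strings must be binary (0/1 characters only)")
    bits <- t(vapply(strsplit(states, ""),
                     function(s) as.integer(s), integer(nchar(states[1L]))))
  } else {
    gene_cols <- setdiff(names(df), need)
    if (length(gene_cols) == 0L) stop("no gene columns found")
    bits <- as.matrix(df[, gene_cols, drop = FALSE])
    storage.mode(bits) <- "integer"
    dimnames(bits) <- NULL
    if (!all(bits %in% c(0L, 1L))) stop("gene columns must be 0/1")
  }
  ord <- order(match(df$attractor_id, unique(df$attractor_id)), df$phase)
  bits <- bits[ord, , drop = FALSE]
  id <- df$attractor_id[ord]
  attractor_set(lapply(unique(id), function(a) bits[id == a, , drop = FALSE]))
}

#' Write an attractor set to a TSV file
#'
#' Inverse of [read_attractors()]: columns `attractor_id`, `phase`, then
#' `v1..vn` gene columns.
#'
#' @param aset an `attractor_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_attractors <- function(aset, path) {
  stopifnot(inherits(aset, "attractor_set"))
  rows <- do.call(rbind, aset$attractors)
  colnames(rows) <- paste0("v", seq_len(aset$n))
  df <- data.frame(
    attractor_id = rep(seq_len(aset$m), aset$periods),
    phase = unlist(lapply(aset$periods, seq_len)),
    rows, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
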