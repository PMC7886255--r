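# Bundled worked examples and the Drosophila segment-polarity application.

.fixture_names <- c("example1_bn", "example2_first", "example2_second",
                    "seven_gene_attractors", "example3_attractors",
                    "drosophila")

.parse_state_strings <- function(strings) {
  t(vapply(strsplit(strings, ""), as.integer, integer(nchar(strings[1L]))))
}

#' Load a bundled fixture
#'
#' Small worked instances shipped with the package:
#' \describe{
#'   \item{`example1_bn`}{3-node Boolean network with one singleton and
#'     one period-2 attractor (a `boolean_network`).}
#'   \item{`example2_first`}{4 singleton attractors over 6 genes; the
#'     zero-run union leaves column 4 uncovered, so the minimum equals
#'     the threshold 2 with windows \[3,4\] and \[4,5\].}
#'   \item{`example2_second`}{4 singleton attractors over 6 genes where
#'     every column is covered and the pruned-run formula applies
#'     (minimum 2, window \[2,3\]).}
#'   \item{`seven_gene_attractors`}{2 singleton + 2 period-2 attractors
#'     over 7 genes; nodes 3–4 suffice to tell them apart.}
#'   \item{`example3_attractors`}{2 singleton + 2 period-2 attractors
#'     over 6 genes; per-combination minima 4, 6, 3, 2.}
#'   \item{`drosophila`}{the ten 60-variable steady states of the
#'     Drosophila segment-polarity Boolean model, as 10 singleton
#'     attractors (see [drosophila_gene_map()]).}
#' }
#'
#' @param name one of the fixture ids above.
#' @return a `boolean_network` for `example1_bn`, otherwise an
#'   [attractor_set()].
#' @export
load_fixture <- function(name) {
  if (!is.character(name) || length(name) != 1L || !(name %in% .fixture_names))
    stop("unknown fixture; available: ", paste(.fixture_names, collapse = ", "))
  switch(name,
    example1_bn = read_boolean_rules(
      system.file("extdata", "example1_network.txt", package = "aobn",
                  mustWork = TRUE)),
    example2_first = singleton_attractors(.parse_state_strings(
      c("010101", "101000", "010010", "111110"))),
    example2_second = singleton_attractors(.parse_state_strings(
      c("100101", "011011", "101010", "010001"))),
    seven_gene_attractors = attractor_set(list(
      c(0L, 0L, 1L, 1L, 0L, 1L, 1L),
      c(1L, 1L, 0L, 0L, 0L, 1L, 0L),
      .parse_state_strings(c("1101010", "0011100")),
      .parse_state_strings(c("0010011", "1101110")))),
    example3_attractors = attractor_set(list(
      c(0L, 1L, 0L, 1L, 1L, 0L),
      c(0L, 0L, 1L, 0L, 1L, 0L),
      .parse_state_strings(c("001011", "110101")),
      .parse_state_strings(c("010010", "101010")))),
    drosophila = {
      path <- system.file("extdata", "drosophila_steady_states.txt",
                          package = "aobn", mustWork = TRUE)
      lines <- readLines(path, warn = FALSE)
      lines <- trimws(lines[nzchar(lines) & !startsWith(lines, "#")])
      if (length(lines) != 10L || any(nchar(lines) != 60L) ||
          !all(grepl("^[01]{60}$", lines)))
        stop("corrupt Drosophila steady-state file")
      singleton_attractors(.parse_state_strings(lines))
    })
}

#' Variable-to-gene map of the Drosophila segment-polarity model
#'
#' The 60 Boolean variables of the four-compartment segment-polarity
#' model are, compartment by compartment, the genes/proteins SLP, wg,
#' WG, en, EN, hh, HH, ptc, PTC, PH, SMO, ci, CI, CIA, CIR (lowercase =
#' mRNA, uppercase = protein).
#'
#' @return a data.frame with columns `column` (1..60), `compartment`
#'   (1..4), `symbol`, `label` ("compartment c SYMBOL").
#' @export
drosophila_gene_map <- function() {
  path <- system.file("extdata", "drosophila_gene_map.tsv",
                      package = "aobn", mustWork = TRUE)
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  map$label <- sprintf("compartment %d %s", map$compartment, map$symbol)
  map
}

#' Gene labels for a window of columns
#'
#' Translates a 1-based inclusive column window into the ordered gene /
#' protein labels of a variable map such as [drosophila_gene_map()].
#'
#' @param window length-2 integer vector `c(start, end)`.
#' @param map data.frame with columns `column` and `label` (and
#'   optionally `compartment`, `symbol`).
#' @return character vector of labels, one per column in the window.
#' @export
name_window <- function(window, map) {
  stopifnot(length(window) == 2L, window[1L] <= window[2L])
  if (is.null(map) || nrow(map) == 0L) stop("empty gene-name map")
  cols <- window[1L]:window[2L]
  hit <- match(cols, map$column)
  if (anyNA(hit))
    stop(sprintf("window [%d,%d] outside the map's column range",
                 window[1L], window[2L]))
  map$label[hit]
}
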