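#' Write an observability result to a report file
#'
#' Serializes an [ao_solve()] result to JSON (schema version 1) or TSV.
#' All column indices are 1-based inclusive. When a gene-name map is
#' supplied, each window additionally carries the ordered gene/protein
#' labels of its columns.
#'
#' @param result an `ao_result`.
#' @param path output file path.
#' @param map optional variable map (see [drosophila_gene_map()]).
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, map = NULL, format = c("json", "tsv")) {
  stopifnot(inherits(result, "ao_result"))
  format <- match.arg(format)
  if (format == "json") {
    windows <- if (nrow(result$windows) == 0L) list() else
      lapply(seq_len(nrow(result$windows)), function(r) {
        w <- list(combination = result$windows$combination[r],
                  start = result$windows$start[r],
                  end = result$windows$end[r])
        if (!is.null(map))
          w$labels <- name_window(c(w$start, w$end), map)
        w
      })
    doc <- list(
      schema = "aobn-report/1",
      min_length = if (result$feasible) result$min_length else NULL,
      feasible = result$feasible,
      threshold = result$threshold,
      m = result$m, n = result$n, L = result$L,
      evaluated = result$evaluated,
      windows = windows)
    if (!is.null(result$per_combination))
      doc$per_combination <- ifelse(is.finite(result$per_combination),
                                    result$per_combination, NA)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                         null = "null", na = "null", digits = NA)
  } else {
    header <- c(
      sprintf("# aobn-report/1  feasible=%s  min_length=%s  threshold=%d  m=%d  n=%d  L=%d",
              result$feasible,
              if (result$feasible) result$min_length else "Inf",
              result$threshold, result$m, result$n, result$L))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    df <- result$windows
    if (!is.null(map) && nrow(df) > 0L)
      df$labels <- vapply(seq_len(nrow(df)), function(r)
        paste(name_window(c(df$start[r], df$end[r]), map), collapse = ","), "")
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
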