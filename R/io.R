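# Plain-TSV round-tripping for count and score tables. All core formats are
# single-header TSV; JSON is used for summaries and run manifests.

.SCORE_REQUIRED <- c("position", "wt_aa", "alt_aa", "var_class", "score")
.COUNT_REQUIRED <- c(
  "position", "wt_aa", "alt_aa", "var_class", "tile", "replicate",
  "condition", "count", "depth"
)

#' Write a table as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path,
    sep = "\t", quote = FALSE, row.names = FALSE, na = "NA"
  )
  invisible(path)
}

#' Read / write variant score tables
#'
#' Score tables are TSV with one header line. `read_score_table()` accepts
#' either explicit `position`/`wt_aa`/`alt_aa` key columns or a protein
#' HGVS key column (`hgvs_pro`), which is parsed with [parse_pro_hgvs()];
#' a `var_class` column is derived from the keys when absent. Missing
#' required columns are reported exhaustively in one message.
#'
#' @param path File path.
#' @return A score tibble.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("score table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  has_keys <- all(c("position", "wt_aa", "alt_aa") %in% names(df))
  if (!has_keys && "hgvs_pro" %in% names(df)) {
    parsed <- tryCatch(parse_pro_hgvs(df$hgvs_pro), error = function(e) {
      stop("while parsing hgvs_pro in ", path, ": ", conditionMessage(e))
    })
    df$position <- parsed$position
    df$wt_aa <- parsed$wt_aa
    df$alt_aa <- parsed$alt_aa
  }
  if (!"var_class" %in% names(df) &&
    all(c("position", "wt_aa", "alt_aa") %in% names(df))) {
    df$var_class <- dplyr::case_when(
      df$alt_aa == "*" ~ "nonsense",
      df$alt_aa == df$wt_aa ~ "synonymous",
      TRUE ~ "missense"
    )
  }
  missing_cols <- setdiff(.SCORE_REQUIRED, names(df))
  if (length(missing_cols) > 0L) {
    stop(
      "score table ", path, " is missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      " (or an hgvs_pro column to derive the variant keys from)"
    )
  }
  tibble::as_tibble(df)
}

#' @rdname read_score_table
#' @param x Score tibble (e.g. from [score_counts()]).
#' @export
write_score_table <- function(x, path) {
  missing_cols <- setdiff(.SCORE_REQUIRED, names(x))
  if (length(missing_cols) > 0L) {
    stop("score table is missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"hgvs_pro" %in% names(x)) {
    x$hgvs_pro <- format_pro_hgvs(x$position, x$wt_aa, x$alt_aa)
  }
  write_tsv_table(x, path)
}

#' Read / write tile-seq count tables
#'
#' @param path File path.
#' @return A count tibble with the [simulate_counts()] schema.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing_cols <- setdiff(.COUNT_REQUIRED, names(df))
  if (length(missing_cols) > 0L) {
    stop(
      "count table ", path, " is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    )
  }
  bad <- setdiff(unique(df$condition), c("pre", "post", "wtctrl"))
  if (length(bad) > 0L) {
    stop("count table has unknown condition value(s): ", paste(bad, collapse = ", "))
  }
  tibble::as_tibble(df)
}

#' @rdname read_count_table
#' @param x Count tibble.
#' @export
write_count_table <- function(x, path) {
  missing_cols <- setdiff(.COUNT_REQUIRED, names(x))
  if (length(missing_cols) > 0L) {
    stop("count table is missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  write_tsv_table(x, path)
}
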