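# TSV interchange: matrix TSV (first column feature id, remaining columns
# sample ids) plus a sample-sheet TSV (sample_id, condition, zt_time, day,
# replicate). Decimal point '.', missing values "NA", gzip accepted
# transparently (readr). Output tables carry '#'-prefixed metadata header
# lines (version, seed, thresholds), which readers skip as comments.

# Base R parser: strtod is correctly rounded, so %.17g output from
# write_tsv_meta() round-trips bit-exactly. '#' lines are skipped; .gz is
# decompressed transparently.
read_tsv_plain <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else path
  df <- utils::read.delim(con, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "NA")
  tibble::as_tibble(df)
}

parse_zt <- function(x) {
  # accepts decimal hours or the "ZT02" label dialect
  if (is.numeric(x)) return(as.numeric(x))
  as.numeric(sub("^ZT", "", toupper(trimws(as.character(x)))))
}

#' Read a feature-by-sample matrix TSV and its sample sheet
#'
#' The matrix TSV has a header row of sample ids and a first column of
#' feature ids; the sample sheet TSV has columns `sample_id`, `condition`,
#' `zt_time` (decimal hours or "ZT02"-style labels), `day`, `replicate`.
#' Every matrix sample must be described in the sheet.
#'
#' @param matrix_path Path to the matrix TSV (optionally gzipped).
#' @param samples_path Path to the sample-sheet TSV.
#' @return A long time-course tibble (`feature_id`, `sample_id`, `value`,
#'   `condition`, `zt`, `day`, `replicate`).
#' @export
read_timecourse <- function(matrix_path, samples_path) {
  mat <- read_tsv_plain(matrix_path)
  if (nrow(mat) == 0L || ncol(mat) < 2L) {
    abort(sprintf("Empty or header-only matrix file: %s.", matrix_path))
  }
  names(mat)[1L] <- "feature_id"
  mat$feature_id <- as.character(mat$feature_id)
  if (anyDuplicated(mat$feature_id)) {
    dups <- unique(mat$feature_id[duplicated(mat$feature_id)])
    abort(sprintf("Duplicate feature id(s): %s.",
                  paste(head(dups, 5L), collapse = ", ")))
  }
  value_cols <- names(mat)[-1L]
  bad <- value_cols[!vapply(mat[value_cols], is.numeric, logical(1))]
  for (cl in bad) {
    v <- suppressWarnings(as.numeric(mat[[cl]]))
    nn <- which(is.na(v) & !is.na(mat[[cl]]) & mat[[cl]] != "NA")
    if (length(nn) > 0L) {
      abort(sprintf("Non-numeric value in column '%s', row %d: '%s'.",
                    cl, nn[1L], as.character(mat[[cl]][nn[1L]])))
    }
    mat[[cl]] <- v  # all-NA column read as logical
  }
  sheet <- read_tsv_plain(samples_path)
  needed <- c("sample_id", "condition", "zt_time", "day", "replicate")
  missing_cols <- setdiff(needed, names(sheet))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Sample sheet is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  orphans <- setdiff(value_cols, sheet$sample_id)
  if (length(orphans) > 0L) {
    abort(sprintf("Sample(s) in matrix but not in sheet: %s.",
                  paste(head(orphans, 10L), collapse = ", ")))
  }
  sheet$zt <- parse_zt(sheet$zt_time)
  long <- tidyr::pivot_longer(mat, -"feature_id", names_to = "sample_id",
                              values_to = "value")
  out <- dplyr::left_join(
    long,
    dplyr::select(sheet, "sample_id", "condition", "zt", "day", "replicate"),
    by = "sample_id")
  check_timecourse(out)
  out
}

#' Write a time course as matrix + sample-sheet TSVs
#'
#' @param data Long time-course tibble.
#' @param matrix_path,samples_path Output paths.
#' @param meta Optional named list written as `# key: value` header lines.
#' @return Invisibly, the two paths.
#' @export
write_timecourse <- function(data, matrix_path, samples_path, meta = NULL) {
  check_timecourse(data)
  wide <- tidyr::pivot_wider(
    dplyr::select(data, "feature_id", "sample_id", "value"),
    names_from = "sample_id", values_from = "value")
  sheet <- dplyr::distinct(data, .data$sample_id, .data$condition,
                           zt_time = .data$zt, .data$day, .data$replicate)
  write_tsv_meta(wide, matrix_path, meta)
  write_tsv_meta(sheet, samples_path, meta)
  invisible(c(matrix_path, samples_path))
}

#' Write a table as TSV with a commented metadata header
#'
#' @param x Data frame (list-columns are dropped with a note).
#' @param path Output path.
#' @param meta Named list of metadata, written as `# key: value` lines.
#' @return Invisibly, `path`.
#' @export
write_tsv_meta <- function(x, path, meta = NULL) {
  is_list_col <- vapply(x, is.list, logical(1))
  if (any(is_list_col)) x <- x[, !is_list_col, drop = FALSE]
  # %.17g guarantees the printed decimal parses back to the same double
  x <- dplyr::mutate(x, dplyr::across(
    dplyr::where(is.double),
    function(v) ifelse(is.na(v), NA_character_, sprintf("%.17g", v))))
  header <- character(0)
  if (!is.null(meta) && length(meta) > 0L) {
    header <- sprintf("# %s: %s", names(meta),
                      vapply(meta, function(v) paste(format(v), collapse = ","),
                             character(1)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header) > 0L) writeLines(header, con)
  cat(readr::format_tsv(x), file = con, sep = "")
  invisible(path)
}
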