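#' Read a BED file into an interval tibble
#'
#' Accepts BED3+ (three or more whitespace/tab-delimited columns); columns
#' beyond the third are ignored. BED coordinates are 0-based half-open, which
#' is also the package's internal convention, so no shifting occurs.
#'
#' @param path Path to a BED file. An empty file yields an empty set.
#' @param merge If `TRUE`, overlapping records are merged on read. Default
#'   `FALSE`: records are preserved (but validated).
#' @return An interval tibble (see [interval_tbl()]).
#' @export
read_bed <- function(path, merge = FALSE) {
  if (!file.exists(path)) rlang::abort(sprintf("BED file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(interval_tbl())
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    rlang::abort(sprintf("BED '%s': fewer than 3 columns at line %d",
                         path, lineno[which(nf < 3)[1]]))
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "BED '%s': invalid coordinates (need 0 <= start < end) at line %d",
      path, lineno[bad[1]]
    ))
  }
  x <- interval_tbl(chrom, start, end)
  if (merge) interval_merge(x) else x
}

#' Write an interval tibble to a BED3 file
#'
#' Records are emitted in deterministic order: chromosome (lexicographic),
#' then start. Coordinates are written as-is (0-based half-open).
#'
#' @param x An interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  x <- dplyr::arrange(x, .data$chrom, .data$start, .data$end)
  readr::write_tsv(x[, c("chrom", "start", "end")], path, col_names = FALSE)
  invisible(path)
}
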