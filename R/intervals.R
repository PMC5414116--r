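#' Construct an interval tibble
#'
#' Genomic intervals are represented throughout the package as tibbles with
#' columns `chrom`, `start` and `end` in 0-based half-open coordinates
#' (`start` inclusive, `end` exclusive), the convention BED files use.
#' Conversion to and from 1-based systems happens only at I/O boundaries.
#'
#' @param chrom Character vector of sequence names.
#' @param start Integer vector of 0-based inclusive start offsets.
#' @param end Integer vector of 0-based exclusive end offsets.
#' @return A tibble with columns `chrom`, `start`, `end`, sorted by
#'   chromosome (lexicographic) then start.
#' @examples
#' interval_tbl("chr1", 10, 20)
#' @export
interval_tbl <- function(chrom = character(), start = integer(), end = integer()) {
  x <- tibble::tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end)
  )
  validate_intervals(x)
  dplyr::arrange(x, .data$chrom, .data$start, .data$end)
}

#' Validate an interval tibble
#'
#' Checks the structural invariants every interval set must satisfy:
#' required columns, non-negative starts, and `start < end` for every row.
#'
#' @param x A tibble with columns `chrom`, `start`, `end`.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_intervals <- function(x) {
  if (!all(c("chrom", "start", "end") %in% names(x))) {
    rlang::abort("interval tibble must have columns `chrom`, `start`, `end`")
  }
  if (any(is.na(x$chrom)) || any(is.na(x$start)) || any(is.na(x$end))) {
    rlang::abort("interval tibble contains missing values")
  }
  bad <- which(x$start < 0 | x$start >= x$end)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "invalid intervals (need 0 <= start < end) at rows: %s",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  invisible(x)
}

# GRanges bridge: internal coordinates are 0-based half-open, IRanges is
# 1-based closed, so start+1 on the way in and start-1 on the way out.
as_granges <- function(x, seqlevels = NULL) {
  lv <- sort(unique(c(seqlevels, x$chrom)))
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = lv),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

as_interval_tbl <- function(gr) {
  x <- tibble::tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr)
  )
  dplyr::arrange(x, .data$chrom, .data$start, .data$end)
}

shared_levels <- function(a, b) sort(unique(c(a$chrom, b$chrom)))

#' Merge overlapping or bookended intervals
#'
#' Returns the minimal sorted set of non-overlapping intervals covering the
#' same bases as the input (per chromosome). Idempotent.
#'
#' @param x An interval tibble.
#' @return A normalized interval tibble.
#' @examples
#' interval_merge(interval_tbl("chr1", c(10, 15), c(20, 30)))
#' @export
interval_merge <- function(x) {
  validate_intervals(x)
  as_interval_tbl(GenomicRanges::reduce(as_granges(x)))
}

#' Intersect two interval sets
#'
#' Base-exact intersection: a base is in the result iff it is covered by both
#' `a` and `b`. Output is normalized (merged, sorted).
#'
#' @param a,b Interval tibbles.
#' @return A normalized interval tibble.
#' @examples
#' interval_intersect(interval_tbl("chr1", 0, 10), interval_tbl("chr1", 5, 15))
#' @export
interval_intersect <- function(a, b) {
  validate_intervals(a)
  validate_intervals(b)
  lv <- shared_levels(a, b)
  as_interval_tbl(GenomicRanges::intersect(as_granges(a, lv), as_granges(b, lv)))
}

#' Subtract one interval set from another
#'
#' Base-exact difference: bases of `a` not covered by `b`. Output is
#' normalized. Together with [interval_intersect()] this partitions
#' `interval_merge(a)`.
#'
#' @param a,b Interval tibbles.
#' @return A normalized interval tibble.
#' @export
interval_subtract <- function(a, b) {
  validate_intervals(a)
  validate_intervals(b)
  lv <- shared_levels(a, b)
  as_interval_tbl(GenomicRanges::setdiff(as_granges(a, lv), as_granges(b, lv)))
}

#' Total footprint of an interval set in base pairs
#'
#' The number of distinct bases covered; overlapping records are counted once
#' (the set is merged before summing).
#'
#' @param x An interval tibble.
#' @return A single integer (double if > 2^31).
#' @export
interval_total_bp <- function(x) {
  m <- interval_merge(x)
  sum(as.numeric(m$end - m$start))
}

# Overlap in bp of each row of `query` with the merged `reference` set.
interval_overlap_bp <- function(query, reference) {
  validate_intervals(query)
  validate_intervals(reference)
  if (nrow(query) == 0) return(integer(0))
  lv <- shared_levels(query, reference)
  gq <- as_granges(query, lv)
  gr <- GenomicRanges::reduce(as_granges(reference, lv))
  hits <- GenomicRanges::findOverlaps(gq, gr)
  out <- integer(nrow(query))
  if (length(hits) > 0) {
    w <- BiocGenerics::width(GenomicRanges::pintersect(
      gq[S4Vectors::queryHits(hits)], gr[S4Vectors::subjectHits(hits)]
    ))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    out[as.integer(names(agg))] <- as.integer(agg)
  }
  out
}

# Complement of an interval set over chromosomes of the given lengths
# (named vector). Plain-R sweep, used on hot simulation paths.
complement_intervals <- function(x, chrom_lens) {
  out <- vector("list", length(chrom_lens))
  for (k in seq_along(chrom_lens)) {
    ch <- names(chrom_lens)[k]
    L <- chrom_lens[[k]]
    sub <- x[x$chrom == ch, ]
    if (nrow(sub) == 0) {
      out[[k]] <- data.frame(chrom = ch, start = 0L, end = as.integer(L))
      next
    }
    o <- order(sub$start)
    s <- sub$start[o]; e <- cummax(sub$end[o])
    # merge overlapping/adjacent runs
    brk <- c(TRUE, s[-1] > e[-length(e)])
    ms <- s[brk]
    me <- c(e[which(brk[-1])], e[length(e)])
    gs <- c(0L, me)
    ge <- c(ms, as.integer(L))
    keep <- gs < ge
    out[[k]] <- data.frame(chrom = ch, start = gs[keep], end = ge[keep])
  }
  tibble::as_tibble(do.call(rbind, out))
}

# For 0-based point positions (tibble chrom/pos), TRUE if the base lies
# inside the merged interval set.
points_in_intervals <- function(chrom, pos0, intervals) {
  if (length(chrom) == 0) return(logical(0))
  pts <- tibble::tibble(chrom = as.character(chrom),
                        start = as.integer(pos0), end = as.integer(pos0) + 1L)
  lv <- sort(unique(c(pts$chrom, intervals$chrom)))
  gp <- as_granges(pts, lv)
  gi <- GenomicRanges::reduce(as_granges(intervals, lv))
  GenomicRanges::countOverlaps(gp, gi) > 0
}
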