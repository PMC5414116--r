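#' Category labels for differential 5hmC/5mC loci
#'
#' The three-way partition of classified loci: `"no_change"` (5hmC peak in
#' both conditions, no 5mC change — sites whose oxidation does not depend on
#' TET2), `"hmc_loss_or_mc_gain"` (5hmC peak lost, or 5mC peak gained, in the
#' knockout — sites where TET2 performs the first oxidation step), and
#' `"hmc_gain"` (5hmC peak present only in the knockout — sites where TET2
#' normally oxidizes 5hmC further).
#'
#' @return Character vector of the three category labels, in precedence order
#'   (lowest to highest).
#' @export
dhmr_categories <- function() c("no_change", "hmc_loss_or_mc_gain", "hmc_gain")

#' Label a peak set with its condition and mark
#'
#' A light wrapper pairing an interval tibble with its experimental labels,
#' used by [classify_loci()] to catch mislabelled inputs.
#'
#' @param peaks An interval tibble.
#' @param condition `"WT"` or `"KO"`.
#' @param mark `"5hmC"` or `"5mC"`.
#' @return An object of class `mark_peaks`.
#' @export
mark_peaks <- function(peaks, condition = c("WT", "KO"), mark = c("5hmC", "5mC")) {
  validate_intervals(peaks)
  structure(list(peaks = interval_merge(peaks),
                 condition = match.arg(condition),
                 mark = match.arg(mark)),
            class = "mark_peaks")
}

check_mark <- function(x, condition, mark, arg) {
  if (inherits(x, "mark_peaks")) {
    if (x$condition != condition || x$mark != mark) {
      rlang::abort(sprintf(
        "`%s` is labelled %s/%s but %s/%s was expected", arg,
        x$condition, x$mark, condition, mark
      ))
    }
    return(x$peaks)
  }
  validate_intervals(x)
  interval_merge(x)
}

#' Compare two peak sets at the whole-peak level
#'
#' A query peak is "gained" if its overlap with the (merged) reference set is
#' below `min_overlap_fraction` of its own length; with the default fraction
#' of 0 any overlap at all disqualifies it, so only fully reference-free
#' peaks count as gained. "Lost" applies the symmetric rule to reference
#' peaks against the query set. "Shared" is the base-level intersection.
#'
#' @param reference,query Interval tibbles (normalized internally).
#' @param min_overlap_fraction Number in \[0, 1\].
#' @return A list with interval tibbles `gained`, `lost` and `shared`.
#' @export
diff_peaks <- function(reference, query, min_overlap_fraction = 0) {
  f <- min_overlap_fraction
  if (!is.numeric(f) || length(f) != 1 || is.na(f) || f < 0 || f > 1) {
    rlang::abort("`min_overlap_fraction` must be a single number in [0, 1]")
  }
  reference <- interval_merge(reference)
  query <- interval_merge(query)
  pick <- function(a, b) {
    if (nrow(a) == 0) return(a)
    ov <- interval_overlap_bp(a, b)
    len <- a$end - a$start
    a[ov == 0 | ov < f * len, , drop = FALSE]
  }
  list(gained = pick(query, reference),
       lost = pick(reference, query),
       shared = interval_intersect(reference, query))
}

#' Classify loci by differential 5hmC/5mC peak dynamics
#'
#' Partitions the genome into the three categories of [dhmr_categories()]
#' from four peak sets: 5hmC and 5mC, each in wild-type (reference) and
#' knockout (query) conditions. Gain/loss is judged at the whole-peak level
#' (see [diff_peaks()]) and then reduced to base-level footprints; to
#' guarantee base-level disjointness, higher-precedence categories
#' (`hmc_gain` > `hmc_loss_or_mc_gain` > `no_change`) are subtracted from
#' lower ones. 5mC peak *loss* is deliberately not a category; such regions
#' fall out of the classification, as does all remaining background.
#'
#' @param hmc_wt,hmc_ko 5hmC peak sets (interval tibbles or [mark_peaks()]
#'   objects labelled WT/5hmC and KO/5hmC).
#' @param mc_wt,mc_ko 5mC peak sets (WT and KO).
#' @param min_overlap_fraction Passed to [diff_peaks()].
#' @return A tibble with columns `chrom`, `start`, `end`, `category`
#'   (factor over [dhmr_categories()]); category footprints are pairwise
#'   disjoint at base level.
#' @export
classify_loci <- function(hmc_wt, hmc_ko, mc_wt, mc_ko, min_overlap_fraction = 0) {
  hmc_wt <- check_mark(hmc_wt, "WT", "5hmC", "hmc_wt")
  hmc_ko <- check_mark(hmc_ko, "KO", "5hmC", "hmc_ko")
  mc_wt <- check_mark(mc_wt, "WT", "5mC", "mc_wt")
  mc_ko <- check_mark(mc_ko, "KO", "5mC", "mc_ko")

  d_hmc <- diff_peaks(hmc_wt, hmc_ko, min_overlap_fraction)
  d_mc <- diff_peaks(mc_wt, mc_ko, min_overlap_fraction)

  gain <- interval_merge(d_hmc$gained)
  loss <- interval_subtract(
    interval_merge(dplyr::bind_rows(d_hmc$lost, d_mc$gained)), gain
  )
  no_change <- interval_subtract(interval_subtract(d_hmc$shared, gain), loss)

  out <- dplyr::bind_rows(
    dplyr::mutate(no_change, category = "no_change"),
    dplyr::mutate(loss, category = "hmc_loss_or_mc_gain"),
    dplyr::mutate(gain, category = "hmc_gain")
  )
  out$category <- factor(out$category, levels = dhmr_categories())
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Per-category footprint of classified loci
#'
#' @param loci A classification tibble from [classify_loci()].
#' @return A tibble with one row per category (all three always present) and
#'   columns `category`, `footprint_bp`.
#' @export
category_footprints <- function(loci) {
  loci <- dplyr::arrange(loci, .data$chrom, .data$start)
  fp <- vapply(dhmr_categories(), function(cat) {
    sub <- loci[loci$category == cat, c("chrom", "start", "end")]
    if (nrow(sub) < 2 ||
        all(sub$start[-1] >= sub$end[-nrow(sub)] |
              sub$chrom[-1] != sub$chrom[-nrow(sub)])) {
      sum(as.numeric(sub$end - sub$start))  # already disjoint: sum directly
    } else {
      interval_total_bp(sub)
    }
  }, numeric(1))
  tibble::tibble(category = factor(dhmr_categories(), levels = dhmr_categories()),
                 footprint_bp = as.numeric(fp))
}

#' Write one BED file per category plus a footprint summary
#'
#' @param loci A classification tibble from [classify_loci()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_categorized_loci <- function(loci, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (cat in dhmr_categories()) {
    p <- file.path(dir, paste0("loci_", cat, ".bed"))
    write_bed(loci[loci$category == cat, c("chrom", "start", "end")], p)
    paths[cat] <- p
  }
  sm <- file.path(dir, "category_footprints.tsv")
  readr::write_tsv(category_footprints(loci), sm)
  paths["summary"] <- sm
  invisible(paths)
}
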