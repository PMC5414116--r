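#' Attach a DhMR category to each variant
#'
#' Each variant is represented by its assigned base (see [variant_pos0()]):
#' the substituted base for an SNV, the first changed base for an indel.
#' Because category footprints are disjoint a variant maps to at most one
#' category; variants outside all categories get `NA`.
#'
#' @param variants A variant tibble.
#' @param loci A classification tibble from [classify_loci()].
#' @return `variants` with an added `category` factor column.
#' @export
variant_categories <- function(variants, loci) {
  # loci footprints are disjoint, so a sorted findInterval lookup suffices
  loci <- dplyr::arrange(loci, .data$chrom, .data$start)
  cat <- rep(NA_character_, nrow(variants))
  pos0 <- variant_pos0(variants)
  for (ch in unique(variants$chrom)) {
    li <- loci[loci$chrom == ch, ]
    if (nrow(li) == 0) next
    i <- which(variants$chrom == ch)
    j <- findInterval(pos0[i], li$start)
    hit <- j >= 1 & pos0[i] < li$end[pmax(j, 1L)]
    cat[i[hit]] <- as.character(li$category[j[hit]])
  }
  dplyr::mutate(variants,
                category = factor(cat, levels = dhmr_categories()))
}

#' Count variants per DhMR category
#'
#' Produces the per-category counts, footprints and mutation rates used by
#' [enrichment_test()]. Variants outside all categories appear in an
#' `unassigned` row (footprint and rate `NA`); they are reported but excluded
#' from the three-way test.
#'
#' @param variants A variant tibble.
#' @param loci A classification tibble from [classify_loci()].
#' @return A tibble with columns `category`, `n_variants`, `footprint_bp` and
#'   `rate_per_mb` (variants per megabase of footprint).
#' @export
assign_variants <- function(variants, loci) {
  av <- variant_categories(variants, loci)
  fp <- category_footprints(loci)
  counts <- dplyr::count(dplyr::filter(av, !is.na(.data$category)),
                         .data$category, .drop = FALSE, name = "n_variants")
  out <- dplyr::left_join(fp, counts, by = "category")
  out$n_variants[is.na(out$n_variants)] <- 0L
  out$rate_per_mb <- ifelse(out$footprint_bp > 0,
                            out$n_variants / (out$footprint_bp / 1e6), NA_real_)
  unassigned <- tibble::tibble(
    category = factor("unassigned", levels = c(dhmr_categories(), "unassigned")),
    footprint_bp = NA_real_,
    n_variants = sum(is.na(av$category)),
    rate_per_mb = NA_real_
  )
  out$category <- factor(as.character(out$category),
                         levels = c(dhmr_categories(), "unassigned"))
  dplyr::bind_rows(out, unassigned)[, c("category", "n_variants",
                                        "footprint_bp", "rate_per_mb")]
}

#' Footprint-normalized enrichment test across categories
#'
#' Chi-squared goodness-of-fit of the per-category variant counts against
#' expected counts proportional to category footprint in bp — the null of a
#' uniform per-base-pair mutation rate. Unassigned (background) variants and
#' empty-footprint categories are excluded.
#'
#' @param counts A counts tibble from [assign_variants()].
#' @return An object of class `enrichment_result` with elements `counts`
#'   (the input) and `test` (a test-result tibble).
#' @export
enrichment_test <- function(counts) {
  use <- counts[!is.na(counts$footprint_bp) & counts$footprint_bp > 0, ]
  if (nrow(use) < 2) {
    rlang::abort("need at least 2 categories with positive footprint")
  }
  test <- chisq_goodness_of_fit(use$n_variants, use$footprint_bp)
  structure(list(counts = counts, test = test), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Footprint-normalized mutation enrichment\n")
  print(x$counts)
  cat(sprintf("%s: X-squared = %.4g, df = %d, p = %.4g\n",
              x$test$method, x$test$statistic, x$test$df, x$test$p_value))
  invisible(x)
}

#' Keep only C-to-T (or G-to-A) substitutions
#'
#' Restricts a variant tibble to SNVs of the collapsed C>T class, the class
#' expected from deamination-type events at methylated/hydroxymethylated
#' cytosines.
#'
#' @param variants A variant tibble.
#' @return The filtered variant tibble.
#' @export
filter_c_to_t <- function(variants) {
  dplyr::filter(variants, .data$kind == "SNV",
                (.data$ref == "C" & .data$alt == "T") |
                  (.data$ref == "G" & .data$alt == "A"))
}

#' TET2-binding coverage of each DhMR category
#'
#' For every category, counts the bases of its footprint covered versus not
#' covered by TET2-binding peaks, and tests homogeneity of coverage across
#' categories with a chi-squared test of independence on the category x
#' covered/uncovered table (base-level units).
#'
#' @param tet2_peaks Interval tibble of TET2-binding peaks.
#' @param loci A classification tibble from [classify_loci()].
#' @return An object of class `binding_enrichment`: list with `coverage`
#'   (tibble: `category`, `covered_bp`, `uncovered_bp`, `fraction`) and
#'   `test` (test-result tibble).
#' @export
binding_enrichment <- function(tet2_peaks, loci) {
  fp <- category_footprints(loci)
  if (all(fp$footprint_bp == 0)) rlang::abort("all category footprints are empty")
  keep <- fp$footprint_bp > 0
  covered <- unname(vapply(dhmr_categories(), function(cat) {
    interval_total_bp(interval_intersect(
      tet2_peaks, loci[loci$category == cat, c("chrom", "start", "end")]
    ))
  }, numeric(1)))
  coverage <- dplyr::mutate(fp,
    covered_bp = covered,
    uncovered_bp = .data$footprint_bp - covered,
    fraction = ifelse(.data$footprint_bp > 0, covered / .data$footprint_bp, NA_real_)
  )[, c("category", "covered_bp", "uncovered_bp", "fraction")]
  tab <- as.matrix(coverage[keep, c("covered_bp", "uncovered_bp")])
  test <- chisq_independence(tab)
  structure(list(coverage = coverage, test = test), class = "binding_enrichment")
}

#' @export
print.binding_enrichment <- function(x, ...) {
  cat("TET2-binding coverage by DhMR category\n")
  print(x$coverage)
  cat(sprintf("%s: X-squared = %.4g, df = %d, p = %.4g\n",
              x$test$method, x$test$statistic, x$test$df, x$test$p_value))
  invisible(x)
}

#' Overlap of in-locus mutations with TET2-binding peaks
#'
#' Counts how many variants (already restricted to classified loci) have
#' their assigned base strictly inside a TET2-binding peak.
#'
#' @param variants A variant tibble, typically pre-filtered to DhMR loci.
#' @param tet2_peaks Interval tibble of TET2-binding peaks.
#' @return A one-row tibble: `n_overlapping`, `n_total`, `fraction`.
#' @export
binding_mutation_overlap <- function(variants, tet2_peaks) {
  n_total <- nrow(variants)
  n_overlapping <- if (n_total == 0 || nrow(tet2_peaks) == 0) 0L else {
    sum(points_in_intervals(variants$chrom, variant_pos0(variants), tet2_peaks))
  }
  tibble::tibble(n_overlapping = as.integer(n_overlapping),
                 n_total = as.integer(n_total),
                 fraction = ifelse(n_total > 0, n_overlapping / n_total, NA_real_))
}

#' Fold enrichment of peaks in a genomic feature
#'
#' Ratio of the observed fraction of peaks overlapping a feature (by at
#' least 1 bp) to the fraction expected by chance from the feature's genomic
#' coverage (`feature_bp / genome_bp`).
#'
#' @param peaks Interval tibble of peaks.
#' @param feature Interval tibble of the feature (e.g. exons, CpG islands).
#' @param genome_bp Total genome size in bp; must be at least the feature
#'   footprint.
#' @return A single number: observed/expected fold change.
#' @export
feature_fold_enrichment <- function(peaks, feature, genome_bp) {
  feature_bp <- interval_total_bp(feature)
  if (feature_bp <= 0) rlang::abort("feature has zero footprint")
  if (genome_bp < feature_bp) rlang::abort("genome_bp must be >= feature footprint")
  peaks <- interval_merge(peaks)
  if (nrow(peaks) == 0) rlang::abort("peak set is empty")
  frac <- mean(interval_overlap_bp(peaks, feature) > 0)
  frac / (feature_bp / genome_bp)
}
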