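#' Run the full locus-classification and mutation analysis
#'
#' Orchestrates the core pipeline: classify loci by differential 5hmC/5mC
#' peaks, assign variants to categories, run the footprint-normalized
#' enrichment test (for all variants and for the collapsed C>T subset),
#' summarize the mutation spectrum, compute CpG proximity against the
#' spacing null, and — when TET2-binding peaks are supplied — their
#' per-category coverage and overlap with in-locus mutations.
#'
#' @param genome A genome (see [as_genome()]).
#' @param hmc_wt,hmc_ko,mc_wt,mc_ko Peak interval tibbles.
#' @param variants A variant tibble (possibly empty).
#' @param tet2_peaks Optional interval tibble of TET2-binding peaks.
#' @param min_overlap_fraction Passed to [classify_loci()].
#' @param window_bp CpG-proximity window (default 30 bp).
#' @param cpg_mean_spacing_bp Mean CpG spacing for the proximity null
#'   (default 100 bp).
#' @return An object of class `tetmut_report`: a named list with elements
#'   `loci`, `footprints`, `counts`, `enrichment`, `enrichment_c_to_t`,
#'   `spectrum`, `cpg_proximity`, `expected_cpg_fraction`,
#'   `binding` and `binding_overlap` (the last two `NULL` without TET2
#'   peaks; the test elements are `NULL` with a note when variants are
#'   absent), plus `params`.
#' @export
run_analysis <- function(genome, hmc_wt, hmc_ko, mc_wt, mc_ko, variants,
                         tet2_peaks = NULL, min_overlap_fraction = 0,
                         window_bp = 30, cpg_mean_spacing_bp = 100) {
  genome <- as_genome(genome)
  chroms <- names(genome)
  check_chroms <- function(x, what) {
    bad <- setdiff(unique(x$chrom), chroms)
    if (length(bad) > 0) {
      rlang::abort(sprintf("%s uses chromosome(s) absent from the genome: %s",
                           what, paste(bad, collapse = ", ")))
    }
  }
  for (nm in c("hmc_wt", "hmc_ko", "mc_wt", "mc_ko")) {
    check_chroms(get(nm), nm)
  }
  check_chroms(variants, "variants")
  if (!is.null(tet2_peaks)) check_chroms(tet2_peaks, "tet2_peaks")

  loci <- classify_loci(hmc_wt, hmc_ko, mc_wt, mc_ko,
                        min_overlap_fraction = min_overlap_fraction)
  footprints <- category_footprints(loci)
  counts <- assign_variants(variants, loci)
  have_variants <- nrow(variants) > 0
  testable <- sum(footprints$footprint_bp > 0) >= 2

  enr <- if (have_variants && testable) enrichment_test(counts) else NULL
  ctt <- filter_c_to_t(variants)
  enr_ctt <- if (nrow(ctt) > 0 && testable) {
    enrichment_test(assign_variants(ctt, loci))
  } else NULL
  spec <- if (have_variants) summarize_spectrum(variants) else NULL
  prox <- if (have_variants) cpg_proximity(variants, genome, window_bp) else NULL

  binding <- NULL; binding_overlap <- NULL
  if (!is.null(tet2_peaks)) {
    binding <- if (any(footprints$footprint_bp > 0)) {
      binding_enrichment(tet2_peaks, loci)
    } else NULL
    in_loci <- dplyr::filter(variant_categories(variants, loci),
                             !is.na(.data$category))
    binding_overlap <- binding_mutation_overlap(in_loci, tet2_peaks)
  }

  structure(list(
    loci = loci,
    footprints = footprints,
    counts = counts,
    enrichment = enr,
    enrichment_c_to_t = enr_ctt,
    spectrum = spec,
    cpg_proximity = prox,
    expected_cpg_fraction = expected_cpg_fraction(
      window_bp = window_bp, mean_spacing_bp = cpg_mean_spacing_bp),
    binding = binding,
    binding_overlap = binding_overlap,
    n_variants = nrow(variants),
    params = list(min_overlap_fraction = min_overlap_fraction,
                  window_bp = window_bp,
                  cpg_mean_spacing_bp = cpg_mean_spacing_bp)
  ), class = "tetmut_report")
}

#' @export
print.tetmut_report <- function(x, ...) {
  cat("tetmut analysis report\n")
  cat(sprintf("  %d variants; category footprints (bp): %s\n", x$n_variants,
              paste(sprintf("%s=%g", x$footprints$category,
                            x$footprints$footprint_bp), collapse = ", ")))
  if (!is.null(x$enrichment)) {
    cat(sprintf("  enrichment: X-squared = %.4g, df = %d, p = %.4g\n",
                x$enrichment$test$statistic, x$enrichment$test$df,
                x$enrichment$test$p_value))
  } else cat("  enrichment: not applicable (no variants or < 2 categories)\n")
  if (!is.null(x$cpg_proximity)) {
    cat(sprintf("  CpG proximity: %d/%d (%.1f%%) within %d bp; null expectation %.1f%%\n",
                x$cpg_proximity$n_proximal, x$cpg_proximity$n_total,
                100 * x$cpg_proximity$fraction, x$cpg_proximity$window_bp,
                100 * x$expected_cpg_fraction))
  }
  if (!is.null(x$binding_overlap)) {
    cat(sprintf("  TET2 overlap: %d of %d in-locus mutations inside binding peaks\n",
                x$binding_overlap$n_overlapping, x$binding_overlap$n_total))
  }
  invisible(x)
}

#' Run the analysis from files
#'
#' File-based wrapper around [run_analysis()]: reads FASTA, the four mark
#' BEDs, a site-only VCF and an optional TET2-binding BED, and optionally
#' writes per-category BEDs, a counts TSV and a JSON report to `out_dir`.
#'
#' @param fasta,hmc_wt_bed,hmc_ko_bed,mc_wt_bed,mc_ko_bed,vcf,tet2_bed File
#'   paths (`tet2_bed` optional).
#' @param out_dir Optional output directory.
#' @param ... Passed to [run_analysis()].
#' @return A `tetmut_report`.
#' @export
analyze_files <- function(fasta, hmc_wt_bed, hmc_ko_bed, mc_wt_bed, mc_ko_bed,
                          vcf, tet2_bed = NULL, out_dir = NULL, ...) {
  genome <- read_fasta(fasta)
  report <- run_analysis(
    genome,
    hmc_wt = read_bed(hmc_wt_bed), hmc_ko = read_bed(hmc_ko_bed),
    mc_wt = read_bed(mc_wt_bed), mc_ko = read_bed(mc_ko_bed),
    variants = read_vcf(vcf, genome = genome),
    tet2_peaks = if (is.null(tet2_bed)) NULL else read_bed(tet2_bed),
    ...
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_categorized_loci(report$loci, out_dir)
    readr::write_tsv(report$counts, file.path(out_dir, "category_counts.tsv"))
    write_report(report, file.path(out_dir, "report.json"))
  }
  report
}

#' Serialize a report to JSON
#'
#' Deterministic (no timestamps): identical inputs produce byte-identical
#' files.
#'
#' @param report A `tetmut_report`, `burden_result` or fluctuation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  to_plain <- function(x) {
    if (inherits(x, c("enrichment_result", "binding_enrichment",
                      "burden_result", "locus_fisher", "spectrum_summary"))) {
      lapply(unclass(x)[setdiff(names(unclass(x)), "data")], to_plain)
    } else if (is.data.frame(x)) {
      as.data.frame(x)
    } else if (is.list(x)) {
      lapply(x, to_plain)
    } else x
  }
  x <- if (inherits(x <- report, "tetmut_report")) {
    unclass(report)[setdiff(names(unclass(report)), "loci")]
  } else report
  jsonlite::write_json(to_plain(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, factor = "string", na = "null")
  invisible(path)
}

#' Cohort analysis from a table or file
#'
#' @param cohort A cohort tibble (`sample_id`, `tet2_status`, `n_mutations`)
#'   or the path of a TSV with those columns.
#' @return A `burden_result` (see [burden_compare()]).
#' @export
run_cohort <- function(cohort) {
  if (is.character(cohort)) {
    cohort <- readr::read_tsv(cohort, show_col_types = FALSE)
  }
  burden_compare(cohort)
}

#' Fluctuation-assay analysis from a table or file
#'
#' @param assay An assay tibble (see [fluctuation_analysis()]) or a TSV path.
#' @param ... Passed to [fluctuation_analysis()].
#' @return A result tibble.
#' @export
run_assay <- function(assay, ...) {
  if (is.character(assay)) {
    assay <- readr::read_tsv(assay, show_col_types = FALSE)
  }
  fluctuation_analysis(assay, ...)
}
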