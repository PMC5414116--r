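#' Per-locus Fisher tests of single-cell mutation frequencies
#'
#' For a panel of loci with mutant/total cell counts in two groups, runs a
#' two-sided Fisher's exact test per locus and reports the number of loci
#' significant at `alpha`, the minimum per-locus p-value, and a pooled test
#' on counts summed across loci. No multiple-testing correction is applied
#' by default; Bonferroni or Benjamini-Hochberg can be requested.
#'
#' @param data Long tibble with columns `locus_id`, `group`,
#'   `n_mutant_cells`, `n_total_cells` — exactly two rows (groups) per locus.
#' @param alpha Significance threshold (default 0.05).
#' @param correction `"none"` (default), `"bonferroni"` or `"BH"`; applied to
#'   the per-locus p-values before thresholding.
#' @return An object of class `locus_fisher`: list with `per_locus` (tibble:
#'   `locus_id`, per-group counts, `p_value`, `p_adjusted`, `significant`),
#'   `n_significant`, `min_p`, `pooled` (test-result tibble on summed
#'   counts) and `alpha`.
#' @export
per_locus_fisher <- function(data, alpha = 0.05,
                             correction = c("none", "bonferroni", "BH")) {
  correction <- match.arg(correction)
  need <- c("locus_id", "group", "n_mutant_cells", "n_total_cells")
  if (!all(need %in% names(data))) {
    rlang::abort(sprintf("locus table must have columns: %s", paste(need, collapse = ", ")))
  }
  if (any(data$n_mutant_cells > data$n_total_cells)) {
    rlang::abort("n_mutant_cells cannot exceed n_total_cells")
  }
  groups <- sort(unique(as.character(data$group)))
  if (length(groups) != 2) rlang::abort("exactly two groups are required")

  wide <- tidyr::pivot_wider(tibble::as_tibble(data),
                             id_cols = "locus_id", names_from = "group",
                             values_from = c("n_mutant_cells", "n_total_cells"))
  m1 <- wide[[paste0("n_mutant_cells_", groups[1])]]
  t1 <- wide[[paste0("n_total_cells_", groups[1])]]
  m2 <- wide[[paste0("n_mutant_cells_", groups[2])]]
  t2 <- wide[[paste0("n_total_cells_", groups[2])]]
  usable <- t1 > 0 & t2 > 0
  if (any(!usable)) {
    rlang::warn(sprintf("skipping locus/loci with zero total cells: %s",
                        paste(wide$locus_id[!usable], collapse = ", ")))
  }
  p <- rep(NA_real_, nrow(wide))
  for (i in which(usable)) {
    p[i] <- fisher_exact_two_sided(
      contingency_2x2(m1[i], t1[i] - m1[i], m2[i], t2[i] - m2[i]))$p_value
  }
  p_adj <- p
  p_adj[usable] <- stats::p.adjust(p[usable], method = switch(correction,
    none = "none", bonferroni = "bonferroni", BH = "BH"))
  per_locus <- tibble::tibble(
    locus_id = wide$locus_id,
    n_mutant_1 = m1, n_total_1 = t1, n_mutant_2 = m2, n_total_2 = t2,
    p_value = p, p_adjusted = p_adj,
    significant = !is.na(p_adj) & p_adj < alpha
  )
  pooled <- fisher_exact_two_sided(contingency_2x2(
    sum(m1[usable]), sum(t1[usable]) - sum(m1[usable]),
    sum(m2[usable]), sum(t2[usable]) - sum(m2[usable])))
  structure(list(per_locus = per_locus,
                 n_significant = sum(per_locus$significant),
                 min_p = suppressWarnings(min(p, na.rm = TRUE)),
                 pooled = pooled, alpha = alpha, groups = groups),
            class = "locus_fisher")
}

#' @export
print.locus_fisher <- function(x, ...) {
  cat(sprintf("Per-locus Fisher tests (%s vs %s): %d of %d loci significant at alpha = %g\n",
              x$groups[1], x$groups[2], x$n_significant, nrow(x$per_locus), x$alpha))
  cat(sprintf("min per-locus p = %.4g; pooled p = %.4g\n", x$min_p, x$pooled$p_value))
  invisible(x)
}

#' Compare mutational burden between two cohorts
#'
#' Two-sided Wilcoxon rank-sum test on per-sample (nonsynonymous) mutation
#' counts between samples with and without a mutation in the gene of
#' interest, with box-plot summaries (median and quartiles) per group.
#'
#' @param cohort Tibble with columns `sample_id`, `tet2_status` (two levels,
#'   e.g. `"mutated"` / `"wild_type"`) and `n_mutations`.
#' @return An object of class `burden_result`: list with `test` (test-result
#'   tibble), `group_stats` (tibble: `tet2_status`, `n`, `median`, `q25`,
#'   `q75`) and `data` (the input).
#' @export
burden_compare <- function(cohort) {
  need <- c("sample_id", "tet2_status", "n_mutations")
  if (!all(need %in% names(cohort))) {
    rlang::abort(sprintf("cohort table must have columns: %s", paste(need, collapse = ", ")))
  }
  if (any(cohort$n_mutations < 0)) rlang::abort("mutation counts must be >= 0")
  groups <- sort(unique(as.character(cohort$tet2_status)))
  if (length(groups) != 2) rlang::abort("cohort must contain exactly two groups")
  x <- cohort$n_mutations[cohort$tet2_status == groups[1]]
  y <- cohort$n_mutations[cohort$tet2_status == groups[2]]
  test <- wilcoxon_rank_sum_two_sided(x, y)
  group_stats <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(cohort), .data$tet2_status),
    n = dplyr::n(),
    median = stats::median(.data$n_mutations),
    q25 = stats::quantile(.data$n_mutations, 0.25),
    q75 = stats::quantile(.data$n_mutations, 0.75),
    .groups = "drop"
  )
  structure(list(test = test, group_stats = group_stats,
                 data = tibble::as_tibble(cohort)),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat("Cohort mutational-burden comparison\n")
  print(x$group_stats)
  cat(sprintf("%s: p = %.4g\n", x$test$method, x$test$p_value))
  invisible(x)
}

#' Lineage proportions of a cohort
#'
#' Percentages of each malignancy type (or any labelled count), rounded
#' half-up to one decimal, or to whole percent once at or above 10%.
#'
#' @param counts Named numeric vector of non-negative counts, or a tibble
#'   with columns `label` and `count`.
#' @return A tibble with columns `label`, `count`, `percentage`.
#' @examples
#' lineage_proportions(c(T_cell = 7, B_cell = 9, myeloid = 182))
#' @export
lineage_proportions <- function(counts) {
  if (is.data.frame(counts)) {
    labels <- as.character(counts$label)
    n <- as.numeric(counts$count)
  } else {
    labels <- names(counts)
    n <- as.numeric(counts)
  }
  if (any(n < 0)) rlang::abort("counts must be non-negative")
  total <- sum(n)
  if (total <= 0) rlang::abort("total count must be > 0")
  pct <- 100 * n / total
  rounded <- ifelse(pct >= 10, round_half_up(pct, 0), round_half_up(pct, 1))
  tibble::tibble(label = labels, count = n, percentage = rounded)
}

# round-half-up (round() would round half to even)
round_half_up <- function(x, digits) {
  floor(x * 10^digits + 0.5 + 1e-9) / 10^digits
}
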