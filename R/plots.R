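#' Plot per-category mutation rates
#'
#' Bar chart of variants per Mb of footprint for each locus category
#' (unassigned background excluded).
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  d <- dplyr::filter(object$counts, !is.na(.data$rate_per_mb))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$rate_per_mb)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "SNVs/indels per Mb",
                  subtitle = sprintf("chi-squared p = %.3g", object$test$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot a mutation spectrum
#'
#' Proportions of transitions, transversions and indel components, with the
#' six collapsed substitution classes alongside.
#'
#' @param object A `spectrum_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spectrum_summary
#' @export
autoplot.spectrum_summary <- function(object, ...) {
  d <- dplyr::bind_rows(
    dplyr::mutate(object$components, panel = "components",
                  label = as.character(.data$component)),
    dplyr::mutate(object$class_counts, panel = "substitution classes",
                  label = as.character(.data$class))
  )
  d$label <- factor(d$label, levels = unique(d$label))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$proportion)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "proportion of variants") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot cohort burden distributions
#'
#' Box plots of per-sample mutation counts by group, whiskers at 1.5 IQR.
#'
#' @param object A `burden_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot burden_result
#' @export
autoplot.burden_result <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$tet2_status, y = .data$n_mutations)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "nonsynonymous mutations per sample",
                  subtitle = sprintf("Wilcoxon rank-sum p = %.3g",
                                     object$test$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot per-locus Fisher results
#'
#' -log10 p-value per locus with the significance threshold marked.
#'
#' @param object A `locus_fisher`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot locus_fisher
#' @export
autoplot.locus_fisher <- function(object, ...) {
  d <- dplyr::filter(object$per_locus, !is.na(.data$p_value))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$locus_id),
                                  y = -log10(.data$p_value),
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(object$alpha), linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey60"),
                               guide = "none") +
    ggplot2::labs(x = "locus", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}
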