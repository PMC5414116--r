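#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname enrichment_test
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) x$counts

#' @rdname enrichment_test
#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) x$test

#' @rdname binding_enrichment
#' @param x A `binding_enrichment`.
#' @param ... Unused.
#' @method tidy binding_enrichment
#' @export
tidy.binding_enrichment <- function(x, ...) x$coverage

#' @rdname binding_enrichment
#' @method glance binding_enrichment
#' @export
glance.binding_enrichment <- function(x, ...) x$test

#' @rdname summarize_spectrum
#' @param x A `spectrum_summary`.
#' @param ... Unused.
#' @method tidy spectrum_summary
#' @export
tidy.spectrum_summary <- function(x, ...) x$components

#' @rdname summarize_spectrum
#' @method glance spectrum_summary
#' @export
glance.spectrum_summary <- function(x, ...) {
  tibble::tibble(n_total = x$n_total,
                 prop_transitions = x$components$proportion[1],
                 prop_transversions = x$components$proportion[2],
                 prop_indels = sum(x$components$proportion[3:5]))
}

#' @rdname burden_compare
#' @param x A `burden_result`.
#' @param ... Unused.
#' @method tidy burden_result
#' @export
tidy.burden_result <- function(x, ...) x$group_stats

#' @rdname burden_compare
#' @method glance burden_result
#' @export
glance.burden_result <- function(x, ...) x$test

#' @rdname per_locus_fisher
#' @param x A `locus_fisher`.
#' @param ... Unused.
#' @method tidy locus_fisher
#' @export
tidy.locus_fisher <- function(x, ...) x$per_locus

#' @rdname per_locus_fisher
#' @method glance locus_fisher
#' @export
glance.locus_fisher <- function(x, ...) {
  tibble::tibble(n_loci = nrow(x$per_locus),
                 n_significant = x$n_significant,
                 min_p = x$min_p,
                 pooled_p = x$pooled$p_value,
                 alpha = x$alpha)
}
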