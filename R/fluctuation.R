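#' Plating efficiency
#'
#' Fraction of cells plated without selection that form colonies. Values
#' above 1 (more colonies than cells plated) trigger a warning, not an
#' error, since miscounting can produce them.
#'
#' @param colonies_pe Colonies formed without 6-TG (> 0; a zero plating
#'   count makes the downstream mutation frequency undefined).
#' @param cells_plated_pe Cells plated without 6-TG (> 0).
#' @return Plating efficiency (colonies per plated cell). Vectorized.
#' @examples
#' plating_efficiency(250, 500)
#' @export
plating_efficiency <- function(colonies_pe, cells_plated_pe) {
  if (any(cells_plated_pe <= 0)) rlang::abort("cells_plated_pe must be > 0")
  if (any(colonies_pe <= 0)) {
    rlang::abort("zero colonies in the plating-efficiency dish: mutation frequency undefined")
  }
  pe <- colonies_pe / cells_plated_pe
  if (any(pe > 1)) rlang::warn("plating efficiency > 1; check colony counts")
  pe
}

#' 6-TG mutation frequency
#'
#' The forward-mutation frequency of the HPRT 6-thioguanine assay: resistant
#' colonies per plated cell, normalized by the plating efficiency,
#' `f = (colonies_6tg / cells_plated_selection) / plating_efficiency`.
#' The estimate is invariant to how cells are split across dishes when
#' totals are pooled.
#'
#' @param colonies_6tg Resistant colonies under 6-TG selection (>= 0).
#' @param cells_plated_selection Total cells plated under selection (> 0),
#'   summed over replicate dishes.
#' @param pe Plating efficiency in (0, 1+] (see [plating_efficiency()]).
#' @return Mutation frequency (mutants per plated viable cell). Vectorized.
#' @examples
#' mutation_frequency(24, 1.5e6, 0.5)
#' @export
mutation_frequency <- function(colonies_6tg, cells_plated_selection, pe) {
  if (any(cells_plated_selection <= 0)) rlang::abort("cells_plated_selection must be > 0")
  if (any(pe <= 0)) rlang::abort("plating efficiency must be > 0")
  if (any(colonies_6tg < 0)) rlang::abort("colony counts must be >= 0")
  (colonies_6tg / cells_plated_selection) / pe
}

#' Fold change between two mutation frequencies
#'
#' @param freq_test,freq_control Mutation frequencies; the control must be
#'   positive.
#' @return `freq_test / freq_control`.
#' @export
fold_change <- function(freq_test, freq_control) {
  if (any(freq_control <= 0)) rlang::abort("control frequency must be > 0")
  freq_test / freq_control
}

#' Analyse a fluctuation-assay table
#'
#' Takes one row per condition (or per dish, see `mode`) with columns
#' `condition`, `cells_plated_selection`, `colonies_6tg`, `cells_plated_pe`,
#' `colonies_pe`, and returns plating efficiency, mutation frequency and the
#' fold change of each condition relative to a named control.
#'
#' With `mode = "pooled"` (default) replicate rows of a condition are pooled
#' (colonies and cells summed) before the frequency is computed; with
#' `mode = "per_dish"` a frequency is computed per row and the per-condition
#' mean and standard deviation are reported alongside.
#'
#' @param data A tibble/data frame as described above.
#' @param control Name of the control condition for fold changes (default:
#'   first condition); `NULL` suppresses fold changes.
#' @param mode `"pooled"` or `"per_dish"`.
#' @return A tibble with one row per condition: `condition`,
#'   `cells_plated_selection`, `colonies_6tg`, `plating_efficiency`,
#'   `mutation_frequency`, `fold_change` (and `frequency_sd`, `n_dishes` in
#'   per-dish mode).
#' @export
fluctuation_analysis <- function(data, control = NULL,
                                 mode = c("pooled", "per_dish")) {
  mode <- match.arg(mode)
  need <- c("condition", "cells_plated_selection", "colonies_6tg",
            "cells_plated_pe", "colonies_pe")
  if (!all(need %in% names(data))) {
    rlang::abort(sprintf("assay table must have columns: %s",
                         paste(need, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)
  if (mode == "pooled") {
    out <- dplyr::summarise(
      dplyr::group_by(data, .data$condition),
      cells_plated_selection = sum(.data$cells_plated_selection),
      colonies_6tg = sum(.data$colonies_6tg),
      cells_plated_pe = .data$cells_plated_pe[1],
      colonies_pe = .data$colonies_pe[1],
      .groups = "drop"
    )
    out$plating_efficiency <- plating_efficiency(out$colonies_pe, out$cells_plated_pe)
    out$mutation_frequency <- mutation_frequency(
      out$colonies_6tg, out$cells_plated_selection, out$plating_efficiency)
    out$frequency_sd <- NA_real_
    out$n_dishes <- as.integer(table(data$condition)[as.character(out$condition)])
  } else {
    data$plating_efficiency <- plating_efficiency(data$colonies_pe, data$cells_plated_pe)
    data$freq <- mutation_frequency(data$colonies_6tg, data$cells_plated_selection,
                                    data$plating_efficiency)
    out <- dplyr::summarise(
      dplyr::group_by(data, .data$condition),
      cells_plated_selection = sum(.data$cells_plated_selection),
      colonies_6tg = sum(.data$colonies_6tg),
      plating_efficiency = .data$plating_efficiency[1],
      mutation_frequency = mean(.data$freq),
      frequency_sd = stats::sd(.data$freq),
      n_dishes = dplyr::n(),
      .groups = "drop"
    )
  }
  if (is.null(control)) control <- as.character(out$condition[1])
  if (!is.na(control) && control %in% as.character(out$condition)) {
    f0 <- out$mutation_frequency[as.character(out$condition) == control][1]
    out$fold_change <- if (f0 > 0) fold_change(out$mutation_frequency, f0) else NA_real_
  } else {
    rlang::abort(sprintf("control condition '%s' not found in the table", control))
  }
  out[, c("condition", "cells_plated_selection", "colonies_6tg",
          "plating_efficiency", "mutation_frequency", "frequency_sd",
          "n_dishes", "fold_change")]
}
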