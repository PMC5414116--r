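#' The six pyrimidine-collapsed substitution classes
#'
#' @return Character vector: "C>A", "C>G", "C>T", "T>A", "T>C", "T>G".
#' @export
substitution_classes <- function() c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Classify a single-base substitution
#'
#' Substitutions are collapsed onto the pyrimidine reference: a purine
#' reference pair is replaced by its reverse complement, so G>A becomes C>T,
#' A>C becomes T>G, and so on. C>T and T>C are the transitions; the other
#' four classes are transversions. Vectorized over `ref`/`alt`.
#'
#' @param ref,alt Single reference and alternate bases in {A,C,G,T}.
#' @return A tibble with columns `class` (factor over
#'   [substitution_classes()]) and `is_transition`.
#' @examples
#' classify_substitution(c("C", "G", "A"), c("T", "A", "C"))
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(ok)) rlang::abort("ref and alt must be single bases in {A,C,G,T}")
  if (any(ref == alt)) rlang::abort("ref and alt must differ")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  purine <- ref %in% c("A", "G")
  r <- ifelse(purine, comp[ref], ref)
  a <- ifelse(purine, comp[alt], alt)
  cls <- factor(paste0(r, ">", a), levels = substitution_classes())
  tibble::tibble(class = cls, is_transition = cls %in% c("C>T", "T>C"))
}

#' Summarize a mutation spectrum
#'
#' Splits variants into transitions, transversions, +1 insertions, -1
#' deletions and other indels, with per-class counts for the six
#' pyrimidine-collapsed substitution classes. Proportions are over all
#' variants and sum to 1.
#'
#' @param variants A non-empty variant tibble.
#' @return An object of class `spectrum_summary`: list with `n_total`,
#'   `class_counts` (tibble `class`, `count`, `proportion` — proportion over
#'   all variants) and `components` (tibble `component`, `count`,
#'   `proportion` over the five components).
#' @export
summarize_spectrum <- function(variants) {
  if (nrow(variants) == 0) rlang::abort("cannot summarize an empty variant set")
  n <- nrow(variants)
  snv <- variants[variants$kind == "SNV", ]
  cls <- if (nrow(snv) > 0) classify_substitution(snv$ref, snv$alt)$class else
    factor(character(), levels = substitution_classes())
  class_counts <- tibble::tibble(
    class = factor(substitution_classes(), levels = substitution_classes()),
    count = as.integer(table(cls)[substitution_classes()])
  )
  class_counts$proportion <- class_counts$count / n

  indel_size <- nchar(variants$alt) - nchar(variants$ref)
  comp_counts <- c(
    transitions = sum(cls %in% c("C>T", "T>C")),
    transversions = sum(!cls %in% c("C>T", "T>C")),
    plus1_insertions = sum(variants$kind == "insertion" & indel_size == 1),
    minus1_deletions = sum(variants$kind == "deletion" & indel_size == -1),
    other_indels = sum(variants$kind %in% c("insertion", "deletion", "other") &
                         abs(indel_size) != 1 |
                         variants$kind == "other" & abs(indel_size) == 1)
  )
  components <- tibble::tibble(
    component = factor(names(comp_counts), levels = names(comp_counts)),
    count = as.integer(comp_counts),
    proportion = as.numeric(comp_counts) / n
  )
  structure(list(n_total = n, class_counts = class_counts,
                 components = components),
            class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("Mutation spectrum over %d variants\n", x$n_total))
  print(x$components)
  invisible(x)
}

#' CpG proximity of mutations
#'
#' A variant is proximal if its assigned base lies within `window_bp` of
#' either base of a CpG dinucleotide (inclusive distance, measured to the C
#' or the G).
#'
#' @param variants A variant tibble.
#' @param genome A genome (see [as_genome()]).
#' @param window_bp Window in bp (>= 0); a window of 0 keeps only variants
#'   falling exactly on a CpG base.
#' @return A one-row tibble: `window_bp`, `n_total`, `n_proximal`, `fraction`.
#' @export
cpg_proximity <- function(variants, genome, window_bp = 30) {
  if (window_bp < 0) rlang::abort("window_bp must be >= 0")
  cpg <- find_cpg_sites(genome)
  pos0 <- variant_pos0(variants)
  prox <- logical(nrow(variants))
  for (ch in unique(variants$chrom)) {
    i <- which(variants$chrom == ch)
    cp <- cpg$pos[cpg$chrom == ch]
    prox[i] <- positions_near_cpg(pos0[i], cp, window_bp)
  }
  tibble::tibble(window_bp = as.integer(window_bp),
                 n_total = nrow(variants),
                 n_proximal = as.integer(sum(prox)),
                 fraction = ifelse(nrow(variants) > 0,
                                   sum(prox) / nrow(variants), NA_real_))
}

# For 0-based positions and sorted 0-based C offsets of CpGs, TRUE if within
# `window` of the C (cp) or the G (cp + 1) of any CpG. Equivalent to falling
# inside [cp - window, cp + 1 + window].
positions_near_cpg <- function(pos0, cp, window) {
  if (length(pos0) == 0) return(logical(0))
  if (length(cp) == 0) return(rep(FALSE, length(pos0)))
  i <- findInterval(pos0, cp)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(cp))
  d_lo <- ifelse(i >= 1, pmin(abs(pos0 - cp[lo]), abs(pos0 - (cp[lo] + 1L))), Inf)
  d_hi <- ifelse(i < length(cp), pmin(abs(pos0 - cp[hi]), abs(pos0 - (cp[hi] + 1L))), Inf)
  pmin(d_lo, d_hi) <= window
}

#' Expected fraction of mutations proximal to a CpG under a spacing null
#'
#' Null models for the fraction of uniformly placed mutations expected to
#' fall within `window_bp` of a CpG dinucleotide when CpGs have a given mean
#' spacing:
#'
#' * `"exponential_gap"` — CpGs placed by a Poisson process with mean
#'   inter-CpG spacing `mean_spacing_bp`. A uniformly placed mutation is
#'   proximal when a window of `2 * window_bp + 2` bases (the CpG occupies
#'   2 bp) contains a CpG, giving the closed form
#'   `1 - exp(-(2 * window_bp + 2) / mean_spacing_bp)`.
#' * `"fixed_spacing"` — perfectly regular spacing:
#'   `min(1, (2 * window_bp + 2) / mean_spacing_bp)`.
#' * `"empirical_shuffle"` — Monte-Carlo estimate from uniform random
#'   positions on a supplied genome.
#'
#' @param window_bp Window in bp (>= 0).
#' @param mean_spacing_bp Mean distance between CpG sites (> 0).
#' @param model One of `"exponential_gap"` (default), `"fixed_spacing"`,
#'   `"empirical_shuffle"`.
#' @param genome Genome for the empirical model.
#' @param n_positions Number of random positions for the empirical model.
#' @return Expected proximal fraction in \[0, 1\].
#' @examples
#' expected_cpg_fraction(window_bp = 30, mean_spacing_bp = 100)
#' @export
expected_cpg_fraction <- function(window_bp = 30, mean_spacing_bp = 100,
                                  model = c("exponential_gap", "fixed_spacing",
                                            "empirical_shuffle"),
                                  genome = NULL, n_positions = 1e5) {
  model <- match.arg(model)
  if (mean_spacing_bp <= 0) rlang::abort("mean_spacing_bp must be > 0")
  if (window_bp < 0) rlang::abort("window_bp must be >= 0")
  span <- 2 * window_bp + 2
  switch(model,
    exponential_gap = 1 - exp(-span / mean_spacing_bp),
    fixed_spacing = min(1, span / mean_spacing_bp),
    empirical_shuffle = {
      if (is.null(genome)) rlang::abort("empirical_shuffle requires a genome")
      genome <- as_genome(genome)
      lens <- genome_lengths(genome)
      ch <- sample(names(lens), n_positions, replace = TRUE,
                   prob = lens / sum(lens))
      pos0 <- floor(stats::runif(n_positions) * lens[ch])
      cpg <- find_cpg_sites(genome)
      prox <- logical(n_positions)
      for (cc in unique(ch)) {
        i <- which(ch == cc)
        prox[i] <- positions_near_cpg(pos0[i], cpg$pos[cpg$chrom == cc], window_bp)
      }
      mean(prox)
    }
  )
}
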