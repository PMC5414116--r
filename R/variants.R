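#' Construct a variant tibble
#'
#' Variants are represented as tibbles with columns `chrom`, `pos` (1-based,
#' the VCF convention), `ref`, `alt` and a derived `kind` column. `kind` is
#' one of `"SNV"` (both alleles single bases), `"insertion"` (`ref` a proper
#' prefix of `alt`), `"deletion"` (`alt` a proper prefix of `ref`) or
#' `"other"`. Indels are expected in left-aligned anchor-base style.
#'
#' @param chrom Character vector of sequence names.
#' @param pos Integer vector of 1-based positions.
#' @param ref,alt Allele strings over {A,C,G,T}.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `kind`.
#' @examples
#' variant_tbl("chr1", 5, "C", "T")
#' variant_tbl("chr1", 5, "CA", "C")  # -1 deletion
#' @export
variant_tbl <- function(chrom = character(), pos = integer(),
                        ref = character(), alt = character()) {
  x <- tibble::tibble(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt))
  )
  if (any(x$pos < 1, na.rm = TRUE)) rlang::abort("variant positions must be >= 1 (1-based)")
  if (any(grepl("[^ACGT]", x$ref)) || any(grepl("[^ACGT]", x$alt))) {
    rlang::abort("variant alleles must be strings over {A,C,G,T}")
  }
  if (any(x$ref == x$alt)) rlang::abort("ref and alt alleles must differ")
  x$kind <- variant_kind(x$ref, x$alt)
  x
}

#' Classify a ref/alt allele pair
#'
#' @param ref,alt Allele strings.
#' @return Character vector: `"SNV"`, `"insertion"`, `"deletion"` or `"other"`.
#' @export
variant_kind <- function(ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  dplyr::case_when(
    nr == 1 & na == 1 ~ "SNV",
    na > nr & substr(alt, 1, nr) == ref ~ "insertion",
    nr > na & substr(ref, 1, na) == alt ~ "deletion",
    TRUE ~ "other"
  )
}

#' 0-based assigned base of each variant
#'
#' The single base that represents a variant in all interval assignments:
#' for an SNV, the substituted base itself; for an insertion or deletion,
#' the first changed base (the base after the anchor). For `"other"` records
#' the first reference base is used.
#'
#' @param variants A variant tibble.
#' @return Integer vector of 0-based offsets.
#' @export
variant_pos0 <- function(variants) {
  ifelse(variants$kind %in% c("insertion", "deletion"),
         variants$pos, variants$pos - 1L)
}

#' Check variant reference alleles against a genome
#'
#' @param variants A variant tibble.
#' @param genome A genome (see [as_genome()]).
#' @return `variants`, invisibly, if every `ref` matches the genome at `pos`;
#'   otherwise an error listing the offending records.
#' @export
check_variants_ref <- function(variants, genome) {
  genome <- as_genome(genome)
  missing_chrom <- setdiff(unique(variants$chrom), names(genome))
  if (length(missing_chrom) > 0) {
    rlang::abort(sprintf("variant chromosome(s) absent from genome: %s",
                         paste(missing_chrom, collapse = ", ")))
  }
  obs <- character(nrow(variants))
  for (ch in unique(variants$chrom)) {
    i <- which(variants$chrom == ch)
    s <- as.character(genome[[ch]])
    obs[i] <- substring(s, variants$pos[i],
                        variants$pos[i] + nchar(variants$ref[i]) - 1L)
  }
  bad <- which(obs != variants$ref)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "REF allele mismatch with genome at: %s",
      paste(sprintf("%s:%d (%s vs genome %s)", variants$chrom[bad],
                    variants$pos[bad], variants$ref[bad], obs[bad])[
                      seq_len(min(5, length(bad)))], collapse = "; ")
    ))
  }
  invisible(variants)
}
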