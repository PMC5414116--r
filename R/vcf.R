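#' Read a site-only VCF into a variant tibble
#'
#' Parses the fixed columns of a VCF v4.x file (via \pkg{vcfR}); genotype
#' columns, INFO semantics and symbolic alleles are out of scope.
#' Multi-allelic records are split into one row per ALT allele. Positions
#' stay 1-based as in the file.
#'
#' @param path Path to an uncompressed VCF file.
#' @param genome Optional genome; if supplied, every REF allele is checked
#'   against it and mismatches raise a validation error.
#' @return A variant tibble (see [variant_tbl()]).
#' @export
read_vcf <- function(path, genome = NULL) {
  if (!file.exists(path)) rlang::abort(sprintf("VCF file not found: %s", path))
  n_body <- sum(!startsWith(readLines(path), "#"))
  if (n_body == 0) {
    v <- variant_tbl()
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- tibble::as_tibble(vcfR::getFIX(vcf))
    fix <- tidyr::separate_rows(fix, "ALT", sep = ",")
    v <- variant_tbl(fix$CHROM, as.integer(fix$POS), fix$REF, fix$ALT)
  }
  if (!is.null(genome)) check_variants_ref(v, genome)
  v
}

#' Write a variant tibble to a site-only VCF file
#'
#' Emits a minimal VCF v4.2 header and the fixed columns, with records in
#' deterministic order (chromosome lexicographic, then position).
#'
#' @param variants A variant tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  v <- dplyr::arrange(variants, .data$chrom, .data$pos, .data$ref, .data$alt)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=tetmut",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", sep = "\t")
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", v$chrom, v$pos, v$ref, v$alt)
  writeLines(c(header, body), path)
  invisible(path)
}
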