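#' Read a reference genome from a FASTA file
#'
#' Sequences are folded to upper case and validated against the alphabet
#' {A, C, G, T, N}. The returned object is a [Biostrings::DNAStringSet], the
#' standard in-memory container for reference sequences.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A named `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("FASTA file not found: %s", path))
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) rlang::abort(sprintf("malformed FASTA '%s': %s", path, conditionMessage(e)))
  )
  if (length(seqs) == 0) rlang::abort(sprintf("FASTA '%s' contains no records", path))
  chars <- toupper(as.character(seqs))
  bad <- which(grepl("[^ACGTN]", chars))
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "FASTA '%s': characters outside {A,C,G,T,N,a..} in record(s): %s",
      path, paste(utils::head(names(seqs)[bad], 5), collapse = ", ")
    ))
  }
  # keep only the first whitespace-delimited token of each header
  names(chars) <- sub("\\s.*$", "", names(seqs))
  Biostrings::DNAStringSet(chars)
}

#' Write a genome to a FASTA file
#'
#' Records are written in the order given; `write_fasta(read_fasta(f), g)`
#' reproduces the sequences of `f` exactly.
#'
#' @param genome A `DNAStringSet` or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(genome, filepath = path, width = 70L)
  invisible(path)
}

#' Coerce to a genome object
#'
#' @param x A `DNAStringSet` or a named character vector of sequences.
#' @return A `DNAStringSet`.
#' @export
as_genome <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x)) {
    if (is.null(names(x))) rlang::abort("character genome must be named by chromosome")
    return(Biostrings::DNAStringSet(toupper(x)))
  }
  rlang::abort("cannot coerce object to a genome (need DNAStringSet or named character)")
}

#' Locate CpG dinucleotides
#'
#' Returns the 0-based offset of the C of every "CG" dinucleotide per
#' chromosome. Positions involving N never match.
#'
#' @param genome A genome (see [as_genome()]).
#' @return A tibble with columns `chrom` and `pos` (0-based offset of the C),
#'   sorted within chromosome.
#' @examples
#' find_cpg_sites(c(chr1 = "ACGCGT"))
#' @export
find_cpg_sites <- function(genome) {
  genome <- as_genome(genome)
  res <- purrr::map2(names(genome), seq_along(genome), function(nm, i) {
    m <- Biostrings::matchPattern("CG", genome[[i]])
    tibble::tibble(chrom = nm, pos = BiocGenerics::start(m) - 1L)
  })
  dplyr::arrange(dplyr::bind_rows(res), .data$chrom, .data$pos)
}

# Chromosome lengths as a named numeric vector.
genome_lengths <- function(genome) {
  genome <- as_genome(genome)
  stats::setNames(BiocGenerics::width(genome), names(genome))
}

# Total non-N genome size in bp.
genome_bp <- function(genome) sum(genome_lengths(genome))

# Character vector of single bases for one chromosome (1-based indexing).
chrom_chars <- function(genome, chrom) {
  genome <- as_genome(genome)
  strsplit(as.character(genome[[chrom]]), "", fixed = TRUE)[[1]]
}
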