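#' Build a validated allele catalog
#'
#' An allele catalog holds the unique nucleotide sequences of the amplified
#' MHC alleles (one fixed-length fragment, e.g. the 184-nt exon-2 fragment
#' spanning the peptide-binding region) together with their conceptual
#' translations. Sequences must be equal-length, unambiguous (A/C/G/T only)
#' and stop-codon free after applying the reading-frame offset; a trailing
#' incomplete codon is silently trimmed before translation.
#'
#' @param sequences named character vector of uppercase nucleotide sequences;
#'   names are allele identifiers (e.g. `"DRB*04"`).
#' @param frame_offset integer 0-2, number of bases skipped before the first
#'   complete codon. The reading frame of an amplicon fragment is a property
#'   of the primer design and must be supplied explicitly.
#' @return An object of class `allele_catalog`: a list with elements
#'   `sequences`, `peptides` (named character, derived) and `frame_offset`.
#' @examples
#' cat6 <- allele_catalog(c(a1 = "ATGGCA", a2 = "ATGGCC"))
#' cat6$peptides
#' @export
allele_catalog <- function(sequences, frame_offset = 0L) {
  if (length(sequences) == 0L) stop("allele catalog is empty")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("every allele sequence must be named with an allele id")
  dup <- unique(names(sequences)[duplicated(names(sequences))])
  if (length(dup))
    stop("duplicate allele ids: ", paste(dup, collapse = ", "))
  frame_offset <- as.integer(frame_offset)
  if (frame_offset < 0L || frame_offset > 2L)
    stop("frame_offset must be 0, 1 or 2")
  sequences <- toupper(sequences)
  bad <- names(sequences)[grepl("[^ACGT]", sequences)]
  if (length(bad))
    stop("non-ACGT characters in: ", paste(bad, collapse = ", "))
  len <- unique(nchar(sequences))
  if (length(len) != 1L) {
    tab <- table(nchar(sequences))
    minority <- names(sequences)[nchar(sequences) != as.integer(names(tab)[which.max(tab)])]
    stop("sequences differ in length (",
         paste(names(tab), collapse = " vs "), " nt); offending records: ",
         paste(minority, collapse = ", "))
  }
  n_codons <- (len - frame_offset) %/% 3L
  if (n_codons < 1L) stop("sequences too short to contain one codon")
  coding <- substr(sequences, frame_offset + 1L, frame_offset + 3L * n_codons)
  pep <- as.character(Biostrings::translate(Biostrings::DNAStringSet(coding)))
  names(pep) <- names(sequences)
  with_stop <- names(pep)[grepl("\\*", pep)]
  if (length(with_stop))
    stop("stop codon in translated sequence of: ",
         paste(with_stop, collapse = ", "))
  structure(
    list(sequences = sequences, peptides = pep,
         frame_offset = frame_offset),
    class = "allele_catalog"
  )
}

#' @export
print.allele_catalog <- function(x, ...) {
  cat("Allele catalog:", length(x$sequences), "alleles of",
      nchar(x$sequences[[1L]]), "nt; frame offset", x$frame_offset,
      "; peptide length", nchar(x$peptides[[1L]]), "aa\n")
  invisible(x)
}

#' @export
length.allele_catalog <- function(x) length(x$sequences)

#' Allele identifiers of a catalog
#' @param catalog an [allele_catalog].
#' @return Character vector of allele ids in catalog order.
#' @export
allele_ids <- function(catalog) names(catalog$sequences)

#' Read an allele catalog from a FASTA file
#'
#' @param path FASTA file of allele nucleotide sequences.
#' @inheritParams allele_catalog
#' @return An [allele_catalog].
#' @export
read_allele_fasta <- function(path, frame_offset = 0L) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no FASTA records in ", path)
  v <- as.character(seqs)
  # keep only the id token of the description line
  names(v) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  allele_catalog(v, frame_offset = frame_offset)
}

#' Write an allele catalog to FASTA
#' @param catalog an [allele_catalog].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_allele_fasta <- function(catalog, path) {
  x <- Biostrings::DNAStringSet(catalog$sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
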