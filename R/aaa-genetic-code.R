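# Frozen copies of the standard genetic code so that profile layouts, codon
# ordering and synonym sets are stable package constants.

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

STOP_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE == "*"]

#' The 61 sense codons of the standard genetic code
#'
#' Alphabetically sorted DNA codons, excluding the three stop codons. All
#' codon-level tables in the package (usage profiles, CSC tables, tAI tables)
#' carry exactly these 61 codons in this order.
#'
#' @return Character vector of length 61.
#' @export
#' @examples
#' head(sense_codons())
sense_codons <- function() SENSE_CODONS

SENSE_CODONS <- sort(names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"])

# codon -> encoded amino acid, for the 61 sense codons
CODON_AA <- GENETIC_CODE_TABLE[SENSE_CODONS]

#' The 20 canonical amino acids
#'
#' @return Character vector of one-letter codes, alphabetically sorted.
#' @export
amino_acids <- function() AMINO_ACIDS

AMINO_ACIDS <- sort(unique(unname(CODON_AA)))

# amino acids encoded by two or more synonymous codons (18: all but M, W)
MULTI_CODON_AAS <- names(which(table(unname(CODON_AA)) >= 2L))

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.revcomp2 <- function(codon12) {
  # reverse complement of a 2-mer, vectorized
  paste0(.complement[substr(codon12, 2L, 2L)], .complement[substr(codon12, 1L, 1L)])
}

# Split a sequence into complete triplets for a given reading frame offset
# (0, 1 or 2 skipped leading nucleotides); trailing partial codon dropped.
chop_codons <- function(seq, frame = 0L) {
  stopifnot(frame %in% 0:2)
  n <- nchar(seq)
  starts <- seq.int(1L + frame, by = 3L, length.out = max(0L, (n - frame) %/% 3L))
  if (length(starts) == 0L) return(character(0))
  substring(seq, starts, starts + 2L)
}

.is_cds_tbl <- function(x) {
  is.data.frame(x) && all(c("id", "seq") %in% names(x))
}

# Coerce a CDS input (tibble with id/seq, or a possibly named character
# vector of sequences) into a canonical two-column tibble.
as_cds_tbl <- function(cds) {
  if (.is_cds_tbl(cds)) {
    return(tibble::tibble(id = as.character(cds$id), seq = toupper(cds$seq)))
  }
  if (is.character(cds)) {
    ids <- names(cds)
    if (is.null(ids)) ids <- paste0("seq", seq_along(cds))
    return(tibble::tibble(id = ids, seq = toupper(unname(cds))))
  }
  stop("`cds` must be a data frame with columns `id` and `seq`, ",
       "or a character vector of sequences.", call. = FALSE)
}
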