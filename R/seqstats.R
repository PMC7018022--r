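#' Read coding sequences from a FASTA file
#'
#' Reads a multi-record FASTA of coding sequences and applies the standard
#' CDS hygiene filters: one (longest) sequence per transcript identifier and
#' retention of ATG-initiated records only. IUPAC ambiguity codes other than
#' A/C/G/T are collapsed to N.
#'
#' @param path Path to a FASTA file (wrapped or single-line records).
#' @param require_atg Drop records whose sequence does not begin with "ATG".
#'   The number of dropped records is reported with a message.
#' @param longest_per_id Keep only the longest sequence per identifier
#'   (identifier = first whitespace-delimited token of the header); ties are
#'   broken by the lexicographically smallest sequence.
#' @return A tibble with columns `id`, `seq` and `length` (nucleotides).
#'   The count of records dropped by the ATG filter is attached as attribute
#'   `n_dropped_atg`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1", "ATGGTGTAA", ">t2", "ATGAAA"), fa)
#' read_cds_fasta(fa)
read_cds_fasta <- function(path, require_atg = TRUE, longest_per_id = TRUE) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  seqs <- unname(gsub("[^ACGT]", "N", seqs))
  out <- tibble::tibble(id = ids, seq = seqs, length = nchar(seqs))

  if (longest_per_id) {
    out <- out |>
      dplyr::arrange(.data$id, dplyr::desc(.data$length), .data$seq) |>
      dplyr::distinct(.data$id, .keep_all = TRUE)
  }

  n_dropped <- 0L
  if (require_atg) {
    keep <- out$length >= 3L & startsWith(out$seq, "ATG")
    n_dropped <- sum(!keep)
    if (n_dropped > 0L) {
      message(n_dropped, " record(s) dropped: sequence does not start with ATG")
    }
    out <- out[keep, , drop = FALSE]
  }
  if (nrow(out) == 0L) {
    warning("no coding sequences retained after filtering", call. = FALSE)
  }
  attr(out, "n_dropped_atg") <- n_dropped
  out
}

#' Write coding sequences to a FASTA file
#'
#' @param cds A CDS tibble (columns `id`, `seq`) or named character vector.
#' @param path Output file path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path, width = 70L) {
  cds <- as_cds_tbl(cds)
  lines <- unlist(purrr::map2(cds$id, cds$seq, function(id, s) {
    starts <- seq.int(1L, nchar(s), by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Codon usage frequencies of coding sequences
#'
#' Counts non-overlapping triplets of each sequence in the requested reading
#' frame (frames +1/+2 skip one/two leading nucleotides) and normalizes to
#' the number of counted codons. Triplets containing N and stop triplets are
#' excluded from both numerator and denominator, so frequencies are over the
#' 61 sense codons and sum to 1 for every transcript. The initiator ATG is
#' included in the counts.
#'
#' @param cds A CDS tibble (columns `id`, `seq`) or character vector of
#'   sequences.
#' @param frame Reading frame: 0 (annotated), 1 or 2 (frameshifted).
#' @return A long tibble with columns `transcript_id`, `frame`, `codon`,
#'   `freq`; exactly 61 rows per transcript (zero frequencies included).
#' @export
#' @examples
#' codon_frequencies(c(t1 = "ATGGTGGTG")) |> dplyr::filter(freq > 0)
codon_frequencies <- function(cds, frame = 0L) {
  cds <- as_cds_tbl(cds)
  frame <- as.integer(frame)
  stopifnot(frame %in% 0:2)
  counts <- vapply(cds$seq, function(s) {
    cod <- chop_codons(s, frame)
    cod <- cod[cod %in% SENSE_CODONS]
    tabulate(factor(cod, levels = SENSE_CODONS), nbins = 61L)
  }, integer(61L))
  totals <- colSums(counts)
  if (any(totals == 0L)) {
    stop("no countable sense codons in frame ", frame, " for: ",
         paste(utils::head(cds$id[totals == 0L], 5L), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    transcript_id = rep(cds$id, each = 61L),
    frame = frame,
    codon = rep(SENSE_CODONS, times = nrow(cds)),
    freq = as.vector(sweep(counts, 2L, totals, "/"))
  )
}

#' Translate coding sequences
#'
#' Standard genetic code translation of the frame-0 codonization. Codons
#' containing N translate to "X"; stop codons (internal or terminal)
#' translate to "*" and do not abort translation, so frameshifted sequences
#' can be translated too. A trailing partial codon is dropped.
#'
#' @inheritParams codon_frequencies
#' @param frame Reading frame (0, 1 or 2).
#' @return A tibble with columns `transcript_id` and `protein`.
#' @export
#' @examples
#' translate_cds(c(a = "ATGGTGTAA"))  # "MV*"
translate_cds <- function(cds, frame = 0L) {
  cds <- as_cds_tbl(cds)
  prot <- vapply(cds$seq, function(s) {
    cod <- chop_codons(s, frame)
    if (length(cod) == 0L) return("")
    aa <- GENETIC_CODE_TABLE[cod]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1L))
  tibble::tibble(transcript_id = cds$id, protein = unname(prot))
}

as_protein_tbl <- function(protein) {
  if (is.data.frame(protein) && all(c("transcript_id", "protein") %in% names(protein))) {
    return(tibble::tibble(transcript_id = as.character(protein$transcript_id),
                          protein = protein$protein))
  }
  if (is.character(protein)) {
    ids <- names(protein)
    if (is.null(ids)) ids <- paste0("seq", seq_along(protein))
    return(tibble::tibble(transcript_id = ids, protein = unname(protein)))
  }
  stop("`protein` must be a data frame with columns `transcript_id` and ",
       "`protein`, or a character vector.", call. = FALSE)
}

#' Amino acid usage frequencies
#'
#' Per-protein frequencies over the 20 canonical residues. Stop symbols "*"
#' are excluded from both numerator and denominator; unknown residues "X"
#' are excluded from the 20 frequencies but tracked as `x_fraction`, so that
#' the 20 frequencies plus `x_fraction` sum to 1 over translated positions.
#'
#' @param protein A tibble with columns `transcript_id`, `protein` (as
#'   returned by [translate_cds()]) or a character vector of amino acid
#'   strings.
#' @return A long tibble with columns `transcript_id`, `aa`, `freq`,
#'   `x_fraction`; 20 rows per protein.
#' @export
#' @examples
#' aa_frequencies(c(p = "MV*")) |> dplyr::filter(freq > 0)
aa_frequencies <- function(protein) {
  protein <- as_protein_tbl(protein)
  res <- vapply(protein$protein, function(p) {
    ch <- strsplit(p, "", fixed = TRUE)[[1L]]
    ch <- ch[ch != "*"]
    n_x <- sum(ch == "X")
    counts <- tabulate(factor(ch, levels = AMINO_ACIDS), nbins = 20L)
    denom <- sum(counts) + n_x
    if (denom == 0L) {
      stop("no canonical residues to count (string of only '*'/'X')",
           call. = FALSE)
    }
    c(counts / denom, n_x / denom)
  }, numeric(21L))
  tibble::tibble(
    transcript_id = rep(protein$transcript_id, each = 20L),
    aa = rep(AMINO_ACIDS, times = nrow(protein)),
    freq = as.vector(res[1:20, , drop = FALSE]),
    x_fraction = rep(unname(res[21L, ]), each = 20L)
  )
}

#' GC content and GC3 frequency of coding sequences
#'
#' `gc_content` is (G+C)/(A+C+G+T) over the whole sequence (N excluded);
#' `gc3_frequency` is the fraction of frame-0 sense codons whose third
#' nucleotide is G or C. Stop and N-containing codons are excluded from the
#' GC3 universe, matching the 61-codon convention used throughout.
#'
#' @inheritParams codon_frequencies
#' @return A tibble with columns `transcript_id`, `gc_content`,
#'   `gc3_frequency`.
#' @export
#' @examples
#' composition_stats(c(x = "ATGGCC"))  # gc3 = 1
composition_stats <- function(cds) {
  cds <- as_cds_tbl(cds)
  res <- vapply(cds$seq, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    n_acgt <- sum(ch %in% c("A", "C", "G", "T"))
    if (n_acgt == 0L) stop("sequence contains no unambiguous bases", call. = FALSE)
    gc <- sum(ch %in% c("G", "C")) / n_acgt
    cod <- chop_codons(s, 0L)
    cod <- cod[cod %in% SENSE_CODONS]
    if (length(cod) == 0L) stop("no frame-0 sense codons", call. = FALSE)
    gc3 <- mean(substr(cod, 3L, 3L) %in% c("G", "C"))
    c(gc, gc3)
  }, numeric(2L))
  tibble::tibble(
    transcript_id = cds$id,
    gc_content = unname(res[1L, ]),
    gc3_frequency = unname(res[2L, ])
  )
}

#' Find homopolymeric amino acid repeats
#'
#' Locates all maximal runs of identical canonical residues of at least
#' `min_length` in each protein. Coordinates are 1-based residue positions,
#' inclusive. Runs of "*" or "X" are never reported.
#'
#' @inheritParams aa_frequencies
#' @param min_length Minimum run length to report (default 5).
#' @return A tibble with columns `gene_id`, `amino_acid`, `length`, `start`.
#' @export
#' @examples
#' find_homopolymer_repeats(c(g = "MVVVVVK"))
find_homopolymer_repeats <- function(protein, min_length = 5L) {
  protein <- as_protein_tbl(protein)
  purrr::map2_dfr(protein$transcript_id, protein$protein, function(id, p) {
    if (nchar(p) == 0L) return(NULL)
    r <- rle(strsplit(p, "", fixed = TRUE)[[1L]])
    ends <- cumsum(r$lengths)
    keep <- r$lengths >= min_length & r$values %in% AMINO_ACIDS
    if (!any(keep)) return(NULL)
    tibble::tibble(
      gene_id = id,
      amino_acid = r$values[keep],
      length = r$lengths[keep],
      start = (ends - r$lengths + 1L)[keep]
    )
  })
}

#' Keep the longest repeat per gene and amino acid
#'
#' Companion reducer for [find_homopolymer_repeats()]: for genes carrying
#' more than one run of the same residue, retains only the longest run
#' (ties broken by first occurrence).
#'
#' @param repeats A tibble as returned by [find_homopolymer_repeats()].
#' @return A tibble with the same columns, at most one row per
#'   (gene, amino acid).
#' @export
longest_repeats <- function(repeats) {
  repeats |>
    dplyr::arrange(.data$gene_id, .data$amino_acid,
                   dplyr::desc(.data$length), .data$start) |>
    dplyr::distinct(.data$gene_id, .data$amino_acid, .keep_all = TRUE)
}
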