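# Pearson correlation with two-sided p and Fisher-z 95% CI, returning NA
# cleanly for zero-variance input (cor.test would error).
.safe_pearson <- function(x, y, conf_level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || sd(x) == 0 || sd(y) == 0) {
    return(c(r = NA_real_, p = NA_real_, lo = NA_real_, hi = NA_real_))
  }
  ct <- cor.test(x, y, method = "pearson", conf.level = conf_level)
  ci <- if (!is.null(ct$conf.int)) ct$conf.int else c(NA_real_, NA_real_)
  c(r = unname(ct$estimate), p = ct$p.value, lo = ci[1L], hi = ci[2L])
}

.join_halflives <- function(profiles, halflives, id_col = "transcript_id") {
  stopifnot(all(c("transcript_id", "half_life") %in% names(halflives)))
  if (any(halflives$half_life <= 0, na.rm = TRUE)) {
    stop("half-lives must be > 0", call. = FALSE)
  }
  n_prof <- dplyr::n_distinct(profiles[[id_col]])
  joined <- dplyr::inner_join(profiles,
                              halflives[, c("transcript_id", "half_life")],
                              by = stats::setNames("transcript_id", id_col))
  n_kept <- dplyr::n_distinct(joined[[id_col]])
  dropped <- n_prof - n_kept
  if (dropped > 0L) {
    message(dropped, " transcript(s) without a matching half-life dropped")
  }
  if (n_kept < 3L) {
    stop("need at least 3 transcripts present in both inputs", call. = FALSE)
  }
  joined
}

.tier <- function(r, p, p_sig) {
  dplyr::case_when(
    is.na(r) | is.na(p) ~ NA_character_,
    p < p_sig & r > 0 ~ "stabilizing",
    p < p_sig & r < 0 ~ "destabilizing",
    .default = "ns"
  )
}

#' Codon stability coefficients (CSC)
#'
#' For each of the 61 sense codons, the Pearson correlation coefficient
#' between the codon's length-normalized frequency across transcripts and
#' transcript half-life, with two-sided p-value and 95% confidence interval
#' (Fisher z-transform). Codons significant at `p_sig` are tiered
#' stabilizing (R > 0) or destabilizing (R < 0); `genome_wide` flags
#' p < `p_genome`. Transcripts absent from either input are dropped (inner
#' join, with a message). A codon with zero frequency variance yields NA,
#' never a silent zero.
#'
#' @param profiles Long codon-usage tibble from [codon_frequencies()].
#' @param halflives Tibble with columns `transcript_id`, `half_life`
#'   (hours, > 0).
#' @param p_sig Significance threshold for the tier call (default 0.01).
#' @param p_genome Genome-wide significance threshold (default 5e-8).
#' @return A 61-row tibble of class `csc_table` with columns `codon`,
#'   `amino_acid`, `csc`, `p_value`, `ci_low`, `ci_high`, `tier`,
#'   `genome_wide`; the number of transcripts used is attached as attribute
#'   `n_transcripts`.
#' @export
compute_csc <- function(profiles, halflives, p_sig = 0.01, p_genome = 5e-8) {
  stopifnot(all(c("transcript_id", "codon", "freq") %in% names(profiles)))
  joined <- .join_halflives(profiles, halflives)
  out <- joined |>
    dplyr::summarise(
      res = list(.safe_pearson(.data$freq, .data$half_life)),
      .by = "codon"
    ) |>
    tidyr::unnest_wider("res") |>
    dplyr::rename(csc = "r", p_value = "p", ci_low = "lo", ci_high = "hi")
  out <- tibble::tibble(codon = SENSE_CODONS) |>
    dplyr::left_join(out, by = "codon") |>
    dplyr::mutate(
      amino_acid = unname(CODON_AA[.data$codon]),
      tier = .tier(.data$csc, .data$p_value, p_sig),
      genome_wide = !is.na(.data$p_value) & .data$p_value < p_genome,
      .after = "codon"
    )
  attr(out, "n_transcripts") <- dplyr::n_distinct(joined$transcript_id)
  class(out) <- c("csc_table", class(out))
  out
}

#' Amino acid stabilization coefficients (AASC)
#'
#' The amino-acid analogue of [compute_csc()]: for each of the 20 canonical
#' residues, the Pearson correlation between amino acid frequency and
#' transcript half-life. The default tier threshold is p < 0.001.
#'
#' @param aa_profiles Long amino-acid usage tibble from [aa_frequencies()].
#' @inheritParams compute_csc
#' @return A 20-row tibble of class `aasc_table` with columns `aa`, `aasc`,
#'   `p_value`, `ci_low`, `ci_high`, `tier`, `genome_wide`.
#' @export
compute_aasc <- function(aa_profiles, halflives, p_sig = 0.001, p_genome = 5e-8) {
  stopifnot(all(c("transcript_id", "aa", "freq") %in% names(aa_profiles)))
  joined <- .join_halflives(aa_profiles, halflives)
  out <- joined |>
    dplyr::summarise(
      res = list(.safe_pearson(.data$freq, .data$half_life)),
      .by = "aa"
    ) |>
    tidyr::unnest_wider("res") |>
    dplyr::rename(aasc = "r", p_value = "p", ci_low = "lo", ci_high = "hi")
  out <- tibble::tibble(aa = AMINO_ACIDS) |>
    dplyr::left_join(out, by = "aa") |>
    dplyr::mutate(
      tier = .tier(.data$aasc, .data$p_value, p_sig),
      genome_wide = !is.na(.data$p_value) & .data$p_value < p_genome
    )
  attr(out, "n_transcripts") <- dplyr::n_distinct(joined$transcript_id)
  class(out) <- c("aasc_table", class(out))
  out
}

#' Transcript-level average stability scores
#'
#' Frequency-weighted sums of per-codon and per-amino-acid coefficients over
#' each transcript's frame-0 ORF:
#' avg CSC = sum over the 61 sense codons of freq(codon) x CSC(codon), and
#' analogously for avg AASC over the 20 amino acids. NA coefficients are
#' excluded and the remaining weights renormalized; the number of excluded
#' terms actually present in the transcript is reported. GC content and GC3
#' frequency are included for downstream half-life modeling.
#'
#' @inheritParams codon_frequencies
#' @param csc A `csc_table` from [compute_csc()].
#' @param aasc An `aasc_table` from [compute_aasc()].
#' @return A tibble with columns `transcript_id`, `avg_csc`, `avg_aasc`,
#'   `gc3_frequency`, `gc_content`, `n_excluded_codons`, `n_excluded_aas`.
#' @export
transcript_scores <- function(cds, csc, aasc) {
  stopifnot(inherits(csc, "csc_table"), inherits(aasc, "aasc_table"))
  cds <- as_cds_tbl(cds)
  prof <- codon_frequencies(cds, frame = 0L)
  aaprof <- aa_frequencies(translate_cds(cds))

  csc_scores <- prof |>
    dplyr::left_join(csc[, c("codon", "csc")], by = "codon") |>
    dplyr::summarise(
      avg_csc = {
        ok <- !is.na(.data$csc)
        w <- sum(.data$freq[ok])
        if (w == 0) NA_real_ else sum(.data$freq[ok] * .data$csc[ok]) / w
      },
      n_excluded_codons = sum(is.na(.data$csc) & .data$freq > 0),
      .by = "transcript_id"
    )
  aasc_scores <- aaprof |>
    dplyr::left_join(stats::setNames(aasc[, c("aa", "aasc")], c("aa", "aasc")),
                     by = "aa") |>
    dplyr::summarise(
      avg_aasc = {
        ok <- !is.na(.data$aasc)
        w <- sum(.data$freq[ok])
        if (w == 0) NA_real_ else sum(.data$freq[ok] * .data$aasc[ok]) / w
      },
      n_excluded_aas = sum(is.na(.data$aasc) & .data$freq > 0),
      .by = "transcript_id"
    )
  composition_stats(cds) |>
    dplyr::inner_join(csc_scores, by = "transcript_id") |>
    dplyr::inner_join(aasc_scores, by = "transcript_id") |>
    dplyr::select("transcript_id", "avg_csc", "avg_aasc",
                  "gc3_frequency", "gc_content",
                  "n_excluded_codons", "n_excluded_aas")
}

#' Partition amino acids by the strength of their stability effect
#'
#' Amino acids with |AASC| > `threshold` and p < `p_threshold` have
#' "extreme" effects on stability; the rest (including NA coefficients) are
#' "moderate". Codons inherit the class of the amino acid they encode.
#'
#' @param aasc An `aasc_table`.
#' @param threshold Absolute AASC cutoff (default 0.10).
#' @param p_threshold P-value cutoff (default 1e-30).
#' @return A list with elements `extreme` and `moderate` (character vectors
#'   of one-letter codes) and `codons` (61-row tibble with columns `codon`,
#'   `amino_acid`, `class`).
#' @export
amino_acid_effect_partition <- function(aasc, threshold = 0.10,
                                        p_threshold = 1e-30) {
  stopifnot(inherits(aasc, "aasc_table"))
  extreme <- aasc$aa[!is.na(aasc$aasc) & !is.na(aasc$p_value) &
                       abs(aasc$aasc) > threshold & aasc$p_value < p_threshold]
  codons <- tibble::tibble(
    codon = SENSE_CODONS,
    amino_acid = unname(CODON_AA),
    class = ifelse(unname(CODON_AA) %in% extreme, "extreme", "moderate")
  )
  list(extreme = extreme,
       moderate = setdiff(AMINO_ACIDS, extreme),
       codons = codons)
}

#' Amino acids with sign-consistent synonymous CSCs
#'
#' Among the 18 amino acids encoded by two or more synonymous codons,
#' returns those whose codons are exclusively stabilizing (all CSC > 0) or
#' exclusively destabilizing (all CSC < 0). Amino acids with any NA or
#' exactly-zero CSC are not exclusive.
#'
#' @param csc A `csc_table`.
#' @return Character vector of one-letter codes.
#' @export
exclusive_amino_acids <- function(csc) {
  stopifnot(inherits(csc, "csc_table"))
  by_aa <- split(csc$csc, csc$amino_acid)[MULTI_CODON_AAS]
  keep <- vapply(by_aa, function(v) {
    !anyNA(v) && (all(v > 0) || all(v < 0))
  }, logical(1L))
  names(by_aa)[keep]
}

#' Count amino acids with sign-consistent synonymous CSCs
#'
#' @inheritParams exclusive_amino_acids
#' @return Integer count (out of the 18 multi-codon amino acids).
#' @export
count_exclusive_amino_acids <- function(csc) {
  length(exclusive_amino_acids(csc))
}
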