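#' Default wobble pairing penalties
#'
#' Selective-constraint values for the codon:anticodon wobble pairs used in
#' classical tAI calculations (Watson-Crick pairs carry no penalty). Each row
#' gives the anticodon position-34 base, the codon third base it can read,
#' and the penalty `s` in \[0, 1\]; the decoding contribution of an anticodon
#' is weighted by `1 - s`. Position-34 A is treated as inosine (reads C and,
#' very weakly, A).
#'
#' @return A tibble with columns `anticodon_base`, `codon_base`, `s`.
#' @export
#' @examples
#' default_wobble_weights()
default_wobble_weights <- function() {
  tibble::tibble(
    anticodon_base = c("A", "C", "G", "T", "G", "A", "A", "T"),
    codon_base     = c("T", "G", "C", "A", "T", "C", "A", "G"),
    s = c(0, 0, 0, 0, 0.41, 0.28, 0.9999, 0.68)
  )
}

# codon -> decoding anticodons under a wobble table:
# anticodon (5'->3') = base34 + revcomp(codon positions 1-2); base34 pairs
# with the codon third base.
decoding_table <- function(wobble_weights = default_wobble_weights()) {
  stopifnot(all(c("anticodon_base", "codon_base", "s") %in% names(wobble_weights)))
  stopifnot(all(wobble_weights$s >= 0 & wobble_weights$s <= 1))
  tibble::tibble(codon = SENSE_CODONS,
                 codon_base = substr(SENSE_CODONS, 3L, 3L),
                 stem = .revcomp2(substr(SENSE_CODONS, 1L, 2L))) |>
    dplyr::inner_join(wobble_weights, by = "codon_base",
                      relationship = "many-to-many") |>
    dplyr::mutate(anticodon = paste0(.data$anticodon_base, .data$stem),
                  weight = 1 - .data$s) |>
    dplyr::select("codon", "anticodon", "s", "weight")
}

#' tRNA adaptation index (tAI) from tRNA-seq counts
#'
#' Aggregates per-gene tRNA-seq read counts by anticodon, converts them to
#' reads per million (RPM), and computes for each of the 61 sense codons the
#' wobble-weighted availability W = sum over decoding anticodons of
#' (1 - s) * RPM. tAI = W / max(W), so the best-decoded codon scores exactly
#' 1. Codons with tAI strictly greater than the median of the 61 values are
#' called optimal.
#'
#' Selenocysteine and initiator-methionine tRNA genes are excluded before
#' RPM computation (by matching `exclude_genes` against the gene id), as
#' their reads do not report on elongator decoding of sense codons.
#' Isodecoder genes are aggregated by anticodon after per-gene counting.
#'
#' @param counts A tibble with columns `trna_gene_id`, `anticodon` (DNA
#'   3-mer, position 34 first) and `read_count`.
#' @param wobble_weights Wobble penalty table; see
#'   [default_wobble_weights()].
#' @param exclude_genes Regular expression (case-insensitive) matched
#'   against `trna_gene_id` to drop Sec/iMet genes.
#' @return A tibble of class `tai_table` with columns `codon`,
#'   `amino_acid`, `tai`, `optimal`; the median tAI is attached as attribute
#'   `median`.
#' @export
tai_from_counts <- function(counts,
                            wobble_weights = default_wobble_weights(),
                            exclude_genes = "iMet|SeC|SelCys|Und") {
  stopifnot(all(c("trna_gene_id", "anticodon", "read_count") %in% names(counts)))
  if (any(counts$read_count < 0)) {
    stop("negative read counts are not allowed", call. = FALSE)
  }
  bad <- !grepl("^[ACGT]{3}$", counts$anticodon)
  if (any(bad)) {
    stop("invalid anticodon string(s): ",
         paste(unique(counts$anticodon[bad]), collapse = ", "), call. = FALSE)
  }
  counts <- counts[!grepl(exclude_genes, counts$trna_gene_id, ignore.case = TRUE), ]
  total <- sum(counts$read_count)
  if (nrow(counts) == 0L || total == 0) {
    stop("no usable tRNA reads after exclusions (all-zero counts?)", call. = FALSE)
  }
  rpm <- counts |>
    dplyr::summarise(rpm = sum(.data$read_count) / total * 1e6,
                     .by = "anticodon")
  w <- decoding_table(wobble_weights) |>
    dplyr::left_join(rpm, by = "anticodon") |>
    dplyr::mutate(rpm = dplyr::coalesce(.data$rpm, 0)) |>
    dplyr::summarise(w = sum(.data$weight * .data$rpm), .by = "codon")
  if (max(w$w) == 0) {
    stop("no sense codon is decoded by the supplied anticodons", call. = FALSE)
  }
  tai <- w$w / max(w$w)
  med <- median(tai)
  out <- tibble::tibble(
    codon = w$codon,
    amino_acid = unname(CODON_AA[w$codon]),
    tai = tai,
    optimal = tai > med
  )
  attr(out, "median") <- med
  class(out) <- c("tai_table", class(out))
  out
}

#' Construct a tAI table from precomputed tAI values
#'
#' For workflows where per-codon tAI values are already available (e.g. a
#' published vector) rather than raw tRNA-seq counts. Values are rescaled so
#' the maximum is 1 and optimality is called by the strict-median rule.
#'
#' @param tai Named numeric vector (names = the 61 sense codons) or tibble
#'   with columns `codon`, `tai`.
#' @return A `tai_table`, as from [tai_from_counts()].
#' @export
as_tai_table <- function(tai) {
  if (is.data.frame(tai)) tai <- setNames(tai$tai, tai$codon)
  missing <- setdiff(SENSE_CODONS, names(tai))
  if (length(missing) > 0L) {
    stop("tAI values missing for codon(s): ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  v <- unname(tai[SENSE_CODONS]) / max(tai, na.rm = TRUE)
  med <- median(v)
  out <- tibble::tibble(codon = SENSE_CODONS,
                        amino_acid = unname(CODON_AA),
                        tai = v,
                        optimal = v > med)
  attr(out, "median") <- med
  class(out) <- c("tai_table", class(out))
  out
}

#' Classify codons as optimal or non-optimal
#'
#' Strict median rule: codons with tAI strictly greater than the median of
#' the 61 sense-codon values are optimal; codons at or below the median are
#' non-optimal. Row order of the input does not affect the calls.
#'
#' @param tai A `tai_table` from [tai_from_counts()] or [as_tai_table()].
#' @return A tibble with columns `codon`, `amino_acid`, `call`
#'   ("optimal"/"non-optimal"); exactly 61 rows.
#' @export
classify_optimal <- function(tai) {
  stopifnot(inherits(tai, "tai_table"))
  med <- median(tai$tai)
  tibble::tibble(
    codon = tai$codon,
    amino_acid = tai$amino_acid,
    call = ifelse(tai$tai > med, "optimal", "non-optimal")
  )
}

#' Percent optimal codons of coding sequences
#'
#' 100 times the fraction of frame-0 sense codons classified optimal under
#' the supplied tAI table, reported to one decimal place. Stop and
#' N-containing codons are excluded from the denominator.
#'
#' @inheritParams codon_frequencies
#' @param tai A `tai_table`.
#' @return A tibble with columns `transcript_id`, `percent_optimal`.
#' @export
percent_optimal <- function(cds, tai) {
  stopifnot(inherits(tai, "tai_table"))
  cds <- as_cds_tbl(cds)
  opt <- tai$codon[tai$optimal]
  pct <- vapply(cds$seq, function(s) {
    cod <- chop_codons(s, 0L)
    cod <- cod[cod %in% SENSE_CODONS]
    if (length(cod) == 0L) stop("no frame-0 sense codons", call. = FALSE)
    round(100 * mean(cod %in% opt), 1L)
  }, numeric(1L))
  tibble::tibble(transcript_id = cds$id, percent_optimal = unname(pct))
}

#' Achievable optimality range of an encoded protein
#'
#' Theoretical minimum and maximum percent optimal codons reachable by
#' synonymous substitution alone: amino acids whose synonym sets are all
#' optimal (or all non-optimal) bound the range.
#'
#' @param seq A single nucleotide sequence.
#' @param tai A `tai_table`.
#' @return Named numeric vector `c(min = , max = )` in percent.
#' @export
optimality_range <- function(seq, tai) {
  stopifnot(inherits(tai, "tai_table"))
  opt_codons <- tai$codon[tai$optimal]
  cod <- chop_codons(toupper(seq), 0L)
  sense <- cod[cod %in% SENSE_CODONS]
  if (length(sense) == 0L) stop("no frame-0 sense codons", call. = FALSE)
  aa <- unname(CODON_AA[sense])
  aa_can_opt <- vapply(AMINO_ACIDS, function(a)
    any(SENSE_CODONS[CODON_AA == a] %in% opt_codons), logical(1L))
  can_opt <- aa_can_opt[aa]
  must_opt <- !vapply(AMINO_ACIDS, function(a)
    any(!SENSE_CODONS[CODON_AA == a] %in% opt_codons), logical(1L))[aa]
  c(min = round(100 * mean(must_opt), 1L),
    max = round(100 * mean(can_opt), 1L))
}

#' Design a reporter by randomly flipping synonymous codons
#'
#' Rewrites a coding sequence toward a target percent-optimal composition by
#' randomly "flipping" synonymous codons from optimal to non-optimal (or
#' vice versa), maximizing sequence similarity to the input: only as many
#' codons as needed are altered and the encoded protein is unchanged.
#'
#' Eligible positions (codons whose amino acid has a synonym on the desired
#' side of the median) are shuffled once with the seeded generator and
#' consumed until the running optimality crosses the target; the flip count
#' stopping on whichever side is nearer the target is kept. Replacement
#' synonyms are drawn uniformly among the synonyms on the desired side.
#' Single-codon amino acids (Met, Trp) are never flipped. Stop and
#' N-containing codons are left untouched.
#'
#' @param cds A single-row CDS tibble, or a single (optionally named)
#'   sequence string.
#' @param tai A `tai_table`.
#' @param target Target percent optimal codons, within the achievable range
#'   (see [optimality_range()]).
#' @param seed Integer seed for the flip randomization (the global RNG state
#'   is left untouched).
#' @return A one-row tibble with columns `id`, `seq`, `percent_optimal`,
#'   `n_flips`.
#' @export
flip_to_target_optimality <- function(cds, tai, target, seed = 1L) {
  stopifnot(inherits(tai, "tai_table"))
  cds <- as_cds_tbl(cds)
  if (nrow(cds) != 1L) stop("`cds` must contain exactly one sequence", call. = FALSE)
  seq <- cds$seq
  cod <- chop_codons(seq, 0L)
  is_sense <- cod %in% SENSE_CODONS
  n_sense <- sum(is_sense)
  if (n_sense == 0L) stop("no frame-0 sense codons", call. = FALSE)

  rng <- optimality_range(seq, tai)
  if (target < rng["min"] - 1e-9 || target > rng["max"] + 1e-9) {
    stop(sprintf(paste0("target %.1f%% outside the achievable range ",
                        "[%.1f%%, %.1f%%] for this protein"),
                 target, rng["min"], rng["max"]), call. = FALSE)
  }

  opt_codons <- tai$codon[tai$optimal]
  is_opt <- is_sense & cod %in% opt_codons
  target_count <- target / 100 * n_sense
  current <- sum(is_opt)

  synonyms <- split(SENSE_CODONS, unname(CODON_AA))
  new_cod <- cod
  n_flips <- 0L

  if (abs(current - target_count) > 0.5) {
    up <- target_count > current # need more optimal codons
    withr::with_seed(seed, {
      # positions flippable in the needed direction
      cand <- which(is_sense & (is_opt != up) & vapply(cod, function(cc) {
        if (!cc %in% SENSE_CODONS) return(FALSE)
        syn <- synonyms[[CODON_AA[cc]]]
        any((syn %in% opt_codons) == up)
      }, logical(1L)))
      cand <- cand[sample.int(length(cand))]
      count <- current
      for (i in cand) {
        step <- if (up) 1L else -1L
        # stop on whichever side of the target is nearer
        if (abs(count + step - target_count) >= abs(count - target_count)) break
        syn <- synonyms[[CODON_AA[new_cod[i]]]]
        pool <- syn[(syn %in% opt_codons) == up]
        new_cod[i] <- pool[sample.int(length(pool), 1L)]
        count <- count + step
        n_flips <- n_flips + 1L
      }
    })
  }

  new_seq <- paste(new_cod, collapse = "")
  # carry over any trailing partial codon unchanged
  tail_len <- nchar(seq) %% 3L
  if (tail_len > 0L) {
    new_seq <- paste0(new_seq, substr(seq, nchar(seq) - tail_len + 1L, nchar(seq)))
  }
  realized <- round(100 * sum(new_cod[is_sense] %in% opt_codons) / n_sense, 1L)
  tibble::tibble(id = cds$id, seq = new_seq,
                 percent_optimal = realized, n_flips = n_flips)
}
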