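#' Simulation configuration for the synthetic-data generator
#'
#' Bundles every knob of the synthetic pipeline with defaults chosen to
#' emulate the structure of a metabolic-labeling half-life study: an
#' ATG-initiated transcriptome with Dirichlet-distributed per-transcript
#' codon usage, right-skewed (log-linear) half-lives with optional planted
#' per-codon and per-amino-acid effects, a 10-timepoint decay chase with
#' growth dilution, spike-in distortion and multiplicative noise, and
#' tRNA-seq counts consistent with a known tAI vector. All randomness is
#' driven by `seed` (R's default Mersenne-Twister generator with inversion
#' sampling); regenerating with the same config reproduces outputs exactly.
#'
#' @param n_transcripts Number of transcripts (>= 3).
#' @param length_meanlog,length_sdlog Lognormal parameters of ORF length in
#'   codons (exclusive of the initiator ATG; minimum 10).
#' @param codon_alpha Dirichlet concentration over the 61 sense codons
#'   (length 1 or 61); larger values give more uniform per-transcript usage.
#' @param beta_codon Named numeric vector of planted per-codon half-life
#'   effects on the log scale (names = codons; missing codons get 0).
#' @param beta_aa Named numeric vector of planted per-amino-acid effects.
#' @param halflife_sigma Lognormal noise SD of half-lives.
#' @param halflife_median Target median half-life in hours.
#' @param timepoints Chase timepoints in hours (must start at 0).
#' @param doubling_time Cell doubling time in hours used for dilution.
#' @param spike_distortion_sd Lognormal SD of the per-timepoint spike-in
#'   distortion factor (0 = undistorted).
#' @param noise_sigma Lognormal SD of multiplicative FPKM noise.
#' @param t0_fpkm_meanlog,t0_fpkm_sdlog Lognormal parameters of raw t0
#'   FPKM.
#' @param trna_depth Total tRNA-seq read depth.
#' @param seed Master seed (integer).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 200L,
                       length_meanlog = log(180), length_sdlog = 0.25,
                       codon_alpha = 5,
                       beta_codon = NULL, beta_aa = NULL,
                       halflife_sigma = 0.25, halflife_median = 4,
                       timepoints = c(0, 0.5, 1, 2, 3, 4, 6, 8, 10, 12),
                       doubling_time = 15,
                       spike_distortion_sd = 0.2, noise_sigma = 0.1,
                       t0_fpkm_meanlog = log(50), t0_fpkm_sdlog = 1,
                       trna_depth = 1e6, seed = 1L) {
  stopifnot(n_transcripts >= 3L, halflife_sigma >= 0, noise_sigma >= 0,
            spike_distortion_sd >= 0, timepoints[1L] == 0,
            !is.unsorted(timepoints, strictly = TRUE))
  if (length(codon_alpha) == 1L) codon_alpha <- rep(codon_alpha, 61L)
  stopifnot(length(codon_alpha) == 61L, all(codon_alpha > 0))
  bc <- setNames(numeric(61L), SENSE_CODONS)
  if (!is.null(beta_codon)) {
    stopifnot(all(names(beta_codon) %in% SENSE_CODONS))
    bc[names(beta_codon)] <- beta_codon
  }
  ba <- setNames(numeric(20L), AMINO_ACIDS)
  if (!is.null(beta_aa)) {
    stopifnot(all(names(beta_aa) %in% AMINO_ACIDS))
    ba[names(beta_aa)] <- beta_aa
  }
  structure(list(
    n_transcripts = as.integer(n_transcripts),
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    codon_alpha = codon_alpha, beta_codon = bc, beta_aa = ba,
    halflife_sigma = halflife_sigma, halflife_median = halflife_median,
    timepoints = timepoints, doubling_time = doubling_time,
    spike_distortion_sd = spike_distortion_sd, noise_sigma = noise_sigma,
    t0_fpkm_meanlog = t0_fpkm_meanlog, t0_fpkm_sdlog = t0_fpkm_sdlog,
    trna_depth = trna_depth, seed = as.integer(seed)
  ), class = "sim_config")
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic transcriptome
#'
#' Draws per-transcript codon compositions from a Dirichlet over the 61
#' sense codons, samples ORFs codon-by-codon and prepends the initiator
#' ATG. Because only sense codons are sampled, sequences have no internal
#' stop in frame 0; every length is divisible by 3.
#'
#' @param config A [sim_config()].
#' @return A list with elements `cds` (tibble `id`, `seq`), `profiles`
#'   (frame-0 usage from [codon_frequencies()], the generative truth as
#'   realized) and `composition` (61 x n matrix of the drawn Dirichlet
#'   weights).
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, {
    n <- config$n_transcripts
    lens <- pmax(10L, round(rlnorm(n, config$length_meanlog, config$length_sdlog)))
    comp <- vapply(seq_len(n), function(i) .rdirichlet1(config$codon_alpha),
                   numeric(61L))
    rownames(comp) <- SENSE_CODONS
    seqs <- vapply(seq_len(n), function(i) {
      paste0("ATG", paste(sample(SENSE_CODONS, lens[i], replace = TRUE,
                                 prob = comp[, i]), collapse = ""))
    }, character(1L))
    cds <- tibble::tibble(id = sprintf("txn%04d", seq_len(n)), seq = seqs)
  })
  colnames(comp) <- cds$id
  list(cds = cds, profiles = codon_frequencies(cds, frame = 0L),
       composition = comp)
}

#' Generate synthetic half-lives with planted composition effects
#'
#' Half-lives follow a log-linear model of the realized frame-0 codon and
#' amino acid frequencies: eta = sum(beta_codon * freq) +
#' sum(beta_aa * aa_freq) + Normal(0, sigma), and
#' half_life = exp(eta - median(eta)) * halflife_median. Exponentiation
#' guarantees positivity and a right-skewed distribution; the planted
#' linear effects make coefficient sign recovery by [compute_csc()]
#' well-defined.
#'
#' @param transcriptome Result of [generate_transcriptome()].
#' @param config The same [sim_config()].
#' @return A tibble with `transcript_id`, `half_life`; the noiseless linear
#'   predictor is attached as attribute `eta`.
#' @export
generate_halflives <- function(transcriptome, config) {
  stopifnot(inherits(config, "sim_config"))
  prof <- transcriptome$profiles |>
    tidyr::pivot_wider(id_cols = "transcript_id", names_from = "codon",
                       values_from = "freq")
  fmat <- as.matrix(prof[, SENSE_CODONS])
  eta_codon <- drop(fmat %*% config$beta_codon[SENSE_CODONS])
  aaprof <- aa_frequencies(translate_cds(transcriptome$cds)) |>
    tidyr::pivot_wider(id_cols = "transcript_id", names_from = "aa",
                       values_from = "freq")
  amat <- as.matrix(aaprof[, AMINO_ACIDS])
  eta_aa <- drop(amat %*% config$beta_aa[AMINO_ACIDS])
  stopifnot(identical(prof$transcript_id, aaprof$transcript_id))
  eta <- eta_codon + eta_aa
  withr::with_seed(config$seed + 2L, {
    noise <- rnorm(length(eta), 0, config$halflife_sigma)
  })
  e <- eta + noise
  hl <- exp(e - median(e)) * config$halflife_median
  out <- tibble::tibble(transcript_id = prof$transcript_id, half_life = hl)
  attr(out, "eta") <- setNames(eta, prof$transcript_id)
  out
}

#' Generate a synthetic decay timecourse
#'
#' Each transcript decays as t0_fpkm * exp(-(ln2/half_life +
#' ln2/doubling_time) * t). A per-timepoint spike-in distortion factor
#' (lognormal, 1 at t0) multiplies every column, and the spike-in read
#' counts are generated proportionally so that [spike_in_normalize()] can
#' undo the distortion exactly; multiplicative lognormal noise is applied
#' last. Spike read counts are expected (real-valued) counts so the
#' noiseless round trip is exact.
#'
#' @param halflives Tibble with `transcript_id`, `half_life`.
#' @param config A [sim_config()].
#' @return A list with `fpkm` (long tibble `transcript_id`, `time`,
#'   `fpkm`), `spikes` (tibble `time`, `luc_reads`, `lysa_reads`,
#'   `total_reads`) and `truth` (list: `spike_distortion`, `t0_fpkm`,
#'   `half_life`).
#' @export
generate_timecourse <- function(halflives, config) {
  stopifnot(inherits(config, "sim_config"))
  stopifnot(all(halflives$half_life > 0))
  tp <- config$timepoints
  n <- nrow(halflives)
  withr::with_seed(config$seed + 3L, {
    t0_fpkm <- rlnorm(n, config$t0_fpkm_meanlog, config$t0_fpkm_sdlog)
    d <- c(1, rlnorm(length(tp) - 1L, 0, config$spike_distortion_sd))
    noise <- matrix(rlnorm(n * length(tp), 0, config$noise_sigma),
                    nrow = n)
  })
  rate <- log(2) / halflives$half_life + log(2) / config$doubling_time
  signal <- outer(t0_fpkm, rep(1, length(tp))) *
    exp(-outer(rate, tp))
  observed <- signal * rep(d, each = n) * noise
  fpkm <- tibble::tibble(
    transcript_id = rep(halflives$transcript_id, times = length(tp)),
    time = rep(tp, each = n),
    fpkm = as.vector(observed)
  )
  total <- 5e7
  base_frac <- 1e-3
  spikes <- tibble::tibble(
    time = tp,
    luc_reads = total * base_frac * d * 1.05,
    lysa_reads = total * base_frac * d * 0.95,
    total_reads = total
  )
  list(fpkm = fpkm, spikes = spikes,
       truth = list(spike_distortion = setNames(d, tp),
                    t0_fpkm = setNames(t0_fpkm, halflives$transcript_id),
                    half_life = setNames(halflives$half_life,
                                         halflives$transcript_id)))
}

#' Generate synthetic tRNA-seq counts consistent with a tAI vector
#'
#' If `true_tai` is supplied, solves for non-negative anticodon abundances
#' whose wobble-weighted codon availabilities reproduce it (non-negative
#' least squares; an unrealizable vector raises a feasibility error), then
#' draws multinomial read counts at the requested depth. Without
#' `true_tai`, anticodon abundances are drawn lognormal and the implied tAI
#' is returned as the truth.
#'
#' @param true_tai Optional named numeric vector of per-codon tAI values
#'   (names = the 61 sense codons, max 1).
#' @param depth Total read depth.
#' @param seed Seed for the count draw.
#' @param wobble_weights Wobble penalty table.
#' @param abundance_sdlog Lognormal SD of drawn anticodon abundances (used
#'   only when `true_tai` is NULL).
#' @param sampling If `FALSE`, expected (real-valued) read counts are
#'   returned instead of a multinomial draw — the infinite-depth limit,
#'   useful for exact round-trip checks.
#' @return A tibble with columns `trna_gene_id`, `anticodon`,
#'   `read_count`; the generating tAI vector is attached as attribute
#'   `true_tai` and the anticodon abundances as `abundance`.
#' @export
generate_trna_counts <- function(true_tai = NULL, depth = 1e6, seed = 1L,
                                 wobble_weights = default_wobble_weights(),
                                 abundance_sdlog = 1, sampling = TRUE) {
  dec <- decoding_table(wobble_weights)
  anticodons <- sort(unique(dec$anticodon))
  M <- matrix(0, nrow = 61L, ncol = length(anticodons),
              dimnames = list(SENSE_CODONS, anticodons))
  M[cbind(dec$codon, dec$anticodon)] <- dec$weight

  if (is.null(true_tai)) {
    withr::with_seed(seed, {
      abund <- setNames(rlnorm(length(anticodons), 0, abundance_sdlog),
                        anticodons)
    })
  } else {
    stopifnot(setequal(names(true_tai), SENSE_CODONS))
    target <- unname(true_tai[SENSE_CODONS])
    sol <- pracma::lsqnonneg(M, target)
    if (sqrt(sol$resid.norm) > 1e-6 * max(1, sqrt(sum(target^2)))) {
      stop("tAI vector is not realizable by non-negative anticodon ",
           "abundances under the wobble model", call. = FALSE)
    }
    abund <- setNames(sol$x, anticodons)
  }
  w <- drop(M %*% abund)
  tai <- w / max(w)

  keep <- abund > 0
  probs <- abund[keep] / sum(abund[keep])
  if (sampling) {
    withr::with_seed(seed + 1L, {
      counts <- drop(rmultinom(1L, size = depth, prob = probs))
    })
  } else {
    counts <- depth * probs
  }
  out <- tibble::tibble(
    trna_gene_id = paste0("tRNA-", names(probs), "-1"),
    anticodon = names(probs),
    read_count = counts
  )
  attr(out, "true_tai") <- setNames(tai, SENSE_CODONS)
  attr(out, "abundance") <- abund
  out
}
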