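# Independent oracles, small fixture builders, and shared heavy fixtures.
# Helpers are sourced once per run, so expensive simulations live here and
# are reused by module and acceptance tests alike.

# -- textbook Pearson correlation from sums (no cor()) ------------------------
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# -- closed-form OLS via the normal equations ---------------------------------
ols_oracle <- function(X, y) drop(solve(t(X) %*% X, t(X) %*% y))

# -- two-sided Fisher exact p by full hypergeometric enumeration --------------
fisher_enum_oracle <- function(tab) {
  m <- sum(tab[1L, ]); n <- sum(tab[2L, ]); k <- sum(tab[, 1L])
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(tab[1L, 1L], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# -- exact two-sided rank-sum p by enumerating all group assignments ----------
wilcox_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n)])
  combs <- utils::combn(length(pooled), n)
  stats <- apply(combs, 2L, function(ix) sum(r[ix]))
  mu <- n * (length(pooled) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# -- Kruskal-Wallis H from the rank-sum formula with tie correction -----------
kruskal_oracle <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) sum(ri)^2 / length(ri))) -
    3 * (N + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# -- random CDS strings (plain base R, independent of the simulator) ----------
random_cds <- function(n, len_nt = 300L, alphabet = c("A", "C", "G", "T"),
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    paste0("ATG", paste(sample(alphabet, len_nt - 3L, replace = TRUE),
                        collapse = ""))
  }, character(1L))
  names(seqs) <- paste0("rnd", seq_len(n))
  seqs
}

# -- hand-built coefficient tables for unit tests -----------------------------
make_csc_table <- function(values, p = 0.5) {
  stopifnot(setequal(names(values), sense_codons()))
  v <- unname(values[sense_codons()])
  out <- tibble::tibble(
    codon = sense_codons(),
    amino_acid = vapply(sense_codons(), function(cc)
      as.character(Biostrings::GENETIC_CODE[cc]), character(1L)),
    csc = v, p_value = rep_len(p, 61L),
    ci_low = v - 0.05, ci_high = v + 0.05,
    tier = "ns", genome_wide = FALSE
  )
  class(out) <- c("csc_table", class(out))
  out
}

make_aasc_table <- function(values, p_values = NULL) {
  stopifnot(setequal(names(values), amino_acids()))
  v <- unname(values[amino_acids()])
  p <- if (is.null(p_values)) rep(0.5, 20L) else unname(p_values[amino_acids()])
  out <- tibble::tibble(
    aa = amino_acids(), aasc = v, p_value = p,
    ci_low = v - 0.05, ci_high = v + 0.05,
    tier = "ns", genome_wide = FALSE
  )
  class(out) <- c("aasc_table", class(out))
  out
}

# -- shared heavy fixtures (one computation per run) --------------------------

# transcriptome with planted codon effects, n = 2000
planted <- local({
  cfg <- sim_config(
    n_transcripts = 2000L,
    beta_codon = c(GTG = 4, GCT = 3, AGT = -4, TCG = -3),
    seed = 11L
  )
  tx <- generate_transcriptome(cfg)
  hl <- generate_halflives(tx, cfg)
  csc <- suppressMessages(compute_csc(tx$profiles, hl))
  csc_f1 <- suppressMessages(compute_csc(codon_frequencies(tx$cds, 1L), hl))
  aasc <- suppressMessages(
    compute_aasc(aa_frequencies(translate_cds(tx$cds)), hl))
  scores <- transcript_scores(tx$cds, csc, aasc)
  list(cfg = cfg, tx = tx, hl = hl, csc = csc, csc_f1 = csc_f1,
       aasc = aasc, scores = scores)
})

# 500 noisy decay trajectories with known half-lives in [0.5, 12] h
recovery <- local({
  cfg <- sim_config(n_transcripts = 500L, noise_sigma = 0.1, seed = 21L)
  set.seed(1021L)
  truth <- tibble::tibble(
    transcript_id = sprintf("t%03d", 1:500),
    half_life = stats::runif(500L, 0.5, 12)
  )
  tc <- generate_timecourse(truth, cfg)
  ntc <- spike_in_normalize(tc$fpkm, tc$spikes)
  est <- fit_halflives(ntc)
  rel_err <- abs(est$half_life -
                   truth$half_life[match(est$transcript_id, truth$transcript_id)]) /
    truth$half_life[match(est$transcript_id, truth$transcript_id)]
  list(truth = truth, est = est, median_rel_err = stats::median(rel_err))
})
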