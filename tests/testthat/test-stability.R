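test_that("CSC is the Pearson correlation of codon frequency with half-life", {
  profiles <- tibble::tibble(
    transcript_id = rep(paste0("t", 1:4), each = 2L),
    frame = 0L,
    codon = rep(c("GTG", "AAA"), 4L),
    freq = c(0.1, 0.9, 0.2, 0.8, 0.3, 0.7, 0.4, 0.6)
  )
  hl <- tibble::tibble(transcript_id = paste0("t", 1:4), half_life = 1:4)
  csc <- compute_csc(profiles, hl)
  expect_equal(nrow(csc), 61L)
  expect_equal(csc$csc[csc$codon == "GTG"], 1)
  expect_equal(csc$csc[csc$codon == "AAA"], -1)
  # reversed half-lives flip the sign
  hl_rev <- dplyr::mutate(hl, half_life = rev(half_life))
  expect_equal(compute_csc(profiles, hl_rev)$csc[csc$codon == "GTG"], -1)
  # zero-variance frequency gives NA, never zero
  profiles_const <- dplyr::mutate(profiles,
                                  freq = ifelse(codon == "AAA", 0.5, freq))
  csc_const <- compute_csc(profiles_const, hl)
  expect_true(is.na(csc_const$csc[csc_const$codon == "AAA"]))
})

test_that("CSC and AASC agree with the covariance oracle on a synthetic cohort", {
  cfg <- sim_config(n_transcripts = 200L, seed = 41L, halflife_sigma = 0.4)
  tx <- generate_transcriptome(cfg)
  hl <- generate_halflives(tx, cfg)
  csc <- compute_csc(tx$profiles, hl)
  wide <- tidyr::pivot_wider(tx$profiles, id_cols = "transcript_id",
                             names_from = "codon", values_from = "freq")
  h <- hl$half_life[match(wide$transcript_id, hl$transcript_id)]
  for (cod in sense_codons()) {
    expect_equal(csc$csc[csc$codon == cod], pearson_oracle(wide[[cod]], h),
                 tolerance = 1e-9)
  }
  aap <- aa_frequencies(translate_cds(tx$cds))
  aasc <- compute_aasc(aap, hl)
  wide_aa <- tidyr::pivot_wider(aap, id_cols = "transcript_id",
                                names_from = "aa", values_from = "freq")
  h2 <- hl$half_life[match(wide_aa$transcript_id, hl$transcript_id)]
  for (aa in amino_acids()) {
    expect_equal(aasc$aasc[aasc$aa == aa], pearson_oracle(wide_aa[[aa]], h2),
                 tolerance = 1e-9)
  }
})

test_that("AASC handles proportional and constant frequencies", {
  aap <- tibble::tibble(
    transcript_id = rep(paste0("t", 1:5), each = 2L),
    aa = rep(c("V", "S"), 5L),
    freq = c(0.1, 0.3, 0.2, 0.3, 0.3, 0.3, 0.4, 0.3, 0.5, 0.3),
    x_fraction = 0
  )
  hl <- tibble::tibble(transcript_id = paste0("t", 1:5), half_life = 1:5)
  aasc <- compute_aasc(aap, hl)
  expect_equal(aasc$aasc[aasc$aa == "V"], 1)
  expect_true(is.na(aasc$aasc[aasc$aa == "S"]))
})

test_that("inner-join attrition is reported, and too-small overlap errors", {
  profiles <- codon_frequencies(random_cds(5L, seed = 42L))
  hl <- tibble::tibble(transcript_id = paste0("rnd", 1:3), half_life = c(2, 3, 4))
  expect_message(compute_csc(profiles, hl), "2 transcript\\(s\\) without")
  hl2 <- hl[1:2, ]
  expect_error(suppressMessages(compute_csc(profiles, hl2)), "at least 3")
  expect_error(compute_csc(profiles, dplyr::mutate(hl, half_life = -1)), "> 0")
})

test_that("transcript scores are frequency-weighted coefficient sums", {
  vals <- stats::setNames(seq(-0.3, 0.3, length.out = 61L), sense_codons())
  csc <- make_csc_table(vals)
  avals <- stats::setNames(seq(-0.2, 0.2, length.out = 20L), amino_acids())
  aasc <- make_aasc_table(avals)

  # degenerate weighting: single-codon-type transcript
  s1 <- transcript_scores(c(one = strrep("GTG", 10L)), csc, aasc)
  expect_equal(s1$avg_csc, unname(vals["GTG"]))
  expect_equal(s1$avg_aasc, unname(avals["V"]))

  # symmetric pair with opposite coefficients averages to zero
  vals2 <- vals; vals2["GTG"] <- 0.2; vals2["AGT"] <- -0.2
  s2 <- transcript_scores(c(two = strrep("GTGAGT", 5L)), make_csc_table(vals2),
                          aasc)
  expect_equal(s2$avg_csc, 0)

  # dot-product oracle on random transcripts
  seqs <- random_cds(10L, len_nt = 150L, seed = 43L)
  sc <- transcript_scores(seqs, csc, aasc)
  prof <- codon_frequencies(seqs)
  for (id in names(seqs)) {
    f <- prof[prof$transcript_id == id, ]
    expect_equal(sc$avg_csc[sc$transcript_id == id],
                 sum(f$freq * vals[f$codon]), tolerance = 1e-12)
  }
})

test_that("NA coefficients are excluded with renormalized weights", {
  vals <- stats::setNames(rep(0.2, 61L), sense_codons())
  vals["GTG"] <- NA
  csc <- make_csc_table(vals)
  avals <- stats::setNames(rep(0.1, 20L), amino_acids())
  aasc <- make_aasc_table(avals)
  sc <- transcript_scores(c(x = strrep("GTGAAA", 5L)), csc, aasc)
  # remaining (AAA) weight renormalizes to 1, so the score is its coefficient
  expect_equal(sc$avg_csc, 0.2)
  expect_equal(sc$n_excluded_codons, 1L)
})

test_that("the extreme/moderate partition follows the AASC magnitude and p rules", {
  vals <- stats::setNames(rep(0.01, 20L), amino_acids())
  ps <- stats::setNames(rep(0.5, 20L), amino_acids())
  vals[c("V", "I", "Y")] <- 0.12; vals[c("S", "H", "Q")] <- -0.12
  ps[c("V", "I", "Y", "S", "H", "Q")] <- 1e-40
  # A has the magnitude but fails the p rule
  vals["A"] <- 0.12; ps["A"] <- 1e-10
  part <- amino_acid_effect_partition(make_aasc_table(vals, ps))
  expect_setequal(part$extreme, c("V", "I", "Y", "S", "H", "Q"))
  expect_false("A" %in% part$extreme)
  expect_equal(sum(part$codons$class == "extreme"), 19L)
  expect_equal(sum(part$codons$class == "moderate"), 42L)
})

test_that("exclusive amino acid counting spans its extremes", {
  all_pos <- make_csc_table(stats::setNames(rep(0.1, 61L), sense_codons()))
  expect_equal(count_exclusive_amino_acids(all_pos), 18L)
  # alternate signs within every synonymous family
  alt <- stats::setNames(numeric(61L), sense_codons())
  for (aa in amino_acids()) {
    fam <- sense_codons()[vapply(sense_codons(), function(cc)
      as.character(Biostrings::GENETIC_CODE[cc]) == aa, logical(1L))]
    alt[fam] <- 0.1 * (-1)^(seq_along(fam))
  }
  expect_equal(count_exclusive_amino_acids(make_csc_table(alt)), 0L)
  # NA or zero members disqualify a family
  one_na <- stats::setNames(rep(0.1, 61L), sense_codons())
  one_na["GTT"] <- NA
  expect_equal(count_exclusive_amino_acids(make_csc_table(one_na)), 17L)
})

test_that("permuting half-lives collapses CSCs toward zero", {
  wide <- tidyr::pivot_wider(planted$tx$profiles, id_cols = "transcript_id",
                             names_from = "codon", values_from = "freq")
  fmat <- as.matrix(wide[, sense_codons()])
  h <- planted$hl$half_life[match(wide$transcript_id,
                                  planted$hl$transcript_id)]
  structured <- mean(abs(stats::cor(fmat, h)))
  set.seed(51)
  null_means <- replicate(100L, mean(abs(stats::cor(fmat, sample(h)))))
  expect_true(all(null_means < structured))
})

test_that("planted codon effects are recovered in sign and significance at n = 2000", {
  csc <- planted$csc
  beta <- planted$cfg$beta_codon
  strong <- names(beta)[abs(beta) > 0]
  for (cod in strong) {
    expect_equal(sign(csc$csc[csc$codon == cod]), sign(beta[[cod]]))
    expect_lt(csc$p_value[csc$codon == cod], 1e-3)
  }
})

test_that("frameshifted profiles give different CSCs than frame 0", {
  rc <- stats::cor(planted$csc$csc, planted$csc_f1$csc,
                   method = "spearman", use = "complete.obs")
  expect_lt(rc, 0.5)
})
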