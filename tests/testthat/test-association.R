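test_that("the GC3-optimality Fisher test equals full hypergeometric enumeration", {
  for (seed in c(71L, 72L, 73L, 74L, 75L)) {
    tai <- tai_from_counts(generate_trna_counts(depth = 1e5, seed = seed))
    res <- fisher_gc3_vs_optimality(tai)
    tab <- attr(res, "table")
    expect_equal(sum(tab), 61L)
    expect_equal(res$p_value, fisher_enum_oracle(tab), tolerance = 1e-9)
    # margins are forced by the genetic code and the strict median rule
    expect_equal(unname(rowSums(tab)), c(31L, 30L))
    expect_equal(unname(colSums(tab)), c(30L, 31L))
  }
})

test_that("the reciprocal transform is -1/x, strictly monotone, and guarded", {
  expect_equal(reciprocal_transform(c(2, 24)), c(-0.5, -1 / 24))
  set.seed(76)
  x <- stats::rlnorm(100, 1, 0.8)
  y <- reciprocal_transform(x)
  expect_true(all(y < 0))
  expect_equal(order(x), order(y))
  expect_error(reciprocal_transform(c(1, 0)), "> 0")
  expect_error(reciprocal_transform(c(1, -2)), "> 0")
})

test_that("the half-life model identifies noiseless coefficients exactly", {
  set.seed(77)
  n <- 50L
  scores <- tibble::tibble(
    transcript_id = paste0("t", 1:n),
    avg_csc = stats::rnorm(n, 0, 0.02),
    gc3_frequency = stats::runif(n, 0.3, 0.8)
  )
  y <- -0.29 + 4.3 * scores$avg_csc - 0.02 * scores$gc3_frequency
  hl <- tibble::tibble(transcript_id = scores$transcript_id,
                       half_life = -1 / y)
  fit <- suppressWarnings(fit_halflife_model(scores, hl))
  suppressWarnings({   # perfect fit: summary.lm warns by design
    td <- tidy(fit)
    adj <- glance(fit)$adj_r_squared
  })
  expect_equal(td$estimate, c(-0.29, 4.3, -0.02), tolerance = 1e-9)
  expect_equal(adj, 1, tolerance = 1e-9)
  # rank-deficiency is named, not silent
  expect_error(
    fit_halflife_model(dplyr::mutate(scores, gc3_frequency = 0.5), hl),
    "gc3_frequency")
  expect_error(fit_halflife_model(scores[1:5, ], hl), "at least 10")
})

test_that("OLS machinery equals the normal-equation oracle on a 20-row fixture", {
  set.seed(78)
  n <- 20L
  scores <- tibble::tibble(
    transcript_id = paste0("t", 1:n),
    avg_csc = stats::rnorm(n, 0, 0.02),
    gc3_frequency = stats::runif(n, 0.3, 0.8)
  )
  y <- -0.3 + 4 * scores$avg_csc - 0.05 * scores$gc3_frequency +
    stats::rnorm(n, 0, 0.01)
  hl <- tibble::tibble(transcript_id = scores$transcript_id, half_life = -1 / y)
  fit <- fit_halflife_model(scores, hl)
  X <- cbind(1, scores$avg_csc, scores$gc3_frequency)
  expect_equal(tidy(fit)$estimate, ols_oracle(X, y), tolerance = 1e-9)
})

test_that("a permuted response yields near-zero explanatory power", {
  set.seed(79)
  n <- 100L
  scores <- tibble::tibble(
    transcript_id = paste0("t", 1:n),
    avg_csc = stats::rnorm(n, 0, 0.02),
    gc3_frequency = stats::runif(n, 0.3, 0.8)
  )
  hl <- tibble::tibble(transcript_id = scores$transcript_id,
                       half_life = stats::rlnorm(n, log(4), 0.4))
  res <- replicate(50L, {
    hl_p <- dplyr::mutate(hl, half_life = sample(half_life))
    g <- glance(fit_halflife_model(scores, hl_p))
    c(g$adj_r_squared, g$p_value)
  })
  expect_lt(mean(res[1L, ]), 0.02)          # adjusted R^2 hovers near zero
  expect_lte(mean(res[2L, ] < 0.05), 0.2)   # overall p roughly uniform
})

test_that("the CSC model recovers zero-noise coefficients and subset sizes", {
  tai <- tai_from_counts(generate_trna_counts(depth = 1e6, seed = 80L))
  csc_vals <- stats::setNames(0.14 * tai$tai, tai$codon)
  csc <- make_csc_table(csc_vals)
  set.seed(81)
  free_aa <- tibble::tibble(amino_acid = amino_acids(),
                            concentration = stats::rlnorm(20L, 0, 0.5))
  fit <- suppressWarnings(fit_csc_model(csc, tai, free_aa))
  suppressWarnings(td <- tidy(fit))
  expect_equal(td$estimate[td$term == "tai"], 0.14, tolerance = 1e-9)
  expect_equal(td$estimate[td$term == "concentration"], 0, tolerance = 1e-9)
  expect_equal(suppressWarnings(glance(fit))$n, 57L)  # Cys/Glu codons excluded

  # canonical six-extreme partition gives the 38/19 codon subsets
  avals <- stats::setNames(rep(0.01, 20L), amino_acids())
  ps <- stats::setNames(rep(0.5, 20L), amino_acids())
  avals[c("V", "I", "Y")] <- 0.12; avals[c("S", "H", "Q")] <- -0.12
  ps[c("V", "I", "Y", "S", "H", "Q")] <- 1e-40
  part <- amino_acid_effect_partition(make_aasc_table(avals, ps))
  fit_mod <- suppressWarnings(
    fit_csc_model(csc, tai, free_aa, codon_subset = "moderate",
                  partition = part))
  fit_ext <- suppressWarnings(
    fit_csc_model(csc, tai, free_aa, codon_subset = "extreme",
                  partition = part))
  expect_equal(suppressWarnings(glance(fit_mod))$n, 38L)
  expect_equal(suppressWarnings(glance(fit_ext))$n, 19L)
  expect_error(fit_csc_model(csc, tai, free_aa, codon_subset = "extreme"),
               "partition")
})

test_that("half-life stratification matches the rank-sum oracle and guards degenerate bins", {
  # shifted bins on a 50-row fixture
  set.seed(82)
  hl <- tibble::tibble(transcript_id = paste0("t", 1:50),
                       half_life = stats::rlnorm(50, log(4), 0.3) +
                         rep(c(0, 2, 4, 6, 8), each = 10L))
  cov <- tibble::tibble(transcript_id = hl$transcript_id,
                        value = rep(1:5, each = 10L) + stats::runif(50, -0.2, 0.2))
  st <- stratify_halflives(hl, cov, bins = 5L)
  expect_equal(sum(st$summary$n), 50L)
  groups <- cut(cov$value,
                seq(min(cov$value), max(cov$value), length.out = 6L),
                include.lowest = TRUE)
  expect_equal(st$statistic, kruskal_oracle(hl$half_life, groups),
               tolerance = 1e-9)
  expect_lt(st$p_value, 1e-6)

  # identical distributions in all bins: p is not systematically small
  ps <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    hl0 <- tibble::tibble(transcript_id = paste0("t", 1:100),
                          half_life = stats::rlnorm(100, log(4), 0.3))
    cov0 <- tibble::tibble(transcript_id = hl0$transcript_id,
                           value = stats::runif(100))
    stratify_halflives(hl0, cov0, bins = 4L)$p_value
  }, numeric(1L))
  expect_gt(stats::median(ps), 0.15)

  expect_error(stratify_halflives(hl, dplyr::mutate(cov, value = 1)),
               "constant")
})

test_that("two-group comparisons agree with full-enumeration and detect shifts", {
  same <- compare_groups(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_gt(same$p_value, 0.99)

  # disjoint supports at n = 5 vs 5: exact p from enumerating all 252 splits
  a <- c(1.1, 1.7, 2.3, 2.9, 3.4)
  b <- c(5.2, 6.1, 7.3, 8.9, 9.4)
  res <- compare_groups(a, b)
  expect_equal(res$p_value, wilcox_enum_oracle(a, b), tolerance = 1e-12)
  expect_equal(res$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$median_diff, median(a) - median(b))

  # location-shifted lognormal groups are reliably detected
  set.seed(83)
  g1 <- stats::rlnorm(40, log(3), 0.4)
  g2 <- stats::rlnorm(40, log(6), 0.4)
  expect_lt(compare_groups(g1, g2)$p_value, 1e-4)
  expect_error(compare_groups(numeric(0), g2), "nonempty")
})

test_that("imputing the ceiling half-life appends flagged rows only for new ids", {
  hl <- tibble::tibble(transcript_id = c("a", "b"), half_life = c(2, 3))
  out <- suppressMessages(impute_max_halflife(hl, c("b", "c", "d")))
  expect_equal(nrow(out), 4L)
  expect_equal(out$half_life[out$transcript_id %in% c("c", "d")], c(24, 24))
  expect_false(any(out$imputed[out$transcript_id %in% c("a", "b")]))
})

test_that("planted transcript-level effects flow through to the half-life model", {
  fit <- fit_halflife_model(planted$scores, planted$hl)
  td <- tidy(fit)
  expect_gt(td$estimate[td$term == "avg_csc"], 0)
  expect_lt(td$p_value[td$term == "avg_csc"], 1e-6)
})
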