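#' Fisher's exact test of GC3 content versus codon optimality
#'
#' Builds the 2x2 contingency table of the 61 sense codons classified by
#' third-base identity (GC3 = G or C at the wobble position, AT3 otherwise)
#' and by optimality call, and applies the two-sided exact test.
#'
#' @param tai A `tai_table`.
#' @return A one-row tibble with `odds_ratio`, `p_value` and the four cell
#'   counts (`gc3_optimal`, `gc3_nonoptimal`, `at3_optimal`,
#'   `at3_nonoptimal`); the 2x2 matrix is attached as attribute `table`.
#' @export
fisher_gc3_vs_optimality <- function(tai) {
  stopifnot(inherits(tai, "tai_table"))
  gc3 <- substr(tai$codon, 3L, 3L) %in% c("G", "C")
  tab <- matrix(c(sum(gc3 & tai$optimal), sum(gc3 & !tai$optimal),
                  sum(!gc3 & tai$optimal), sum(!gc3 & !tai$optimal)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("GC3", "AT3"), c("optimal", "non-optimal")))
  ft <- fisher.test(tab, alternative = "two.sided")
  out <- tibble::tibble(
    odds_ratio = unname(ft$estimate),
    p_value = ft$p.value,
    gc3_optimal = tab[1L, 1L], gc3_nonoptimal = tab[1L, 2L],
    at3_optimal = tab[2L, 1L], at3_nonoptimal = tab[2L, 2L]
  )
  attr(out, "table") <- tab
  out
}

#' Reciprocal transformation of half-lives
#'
#' Maps half-lives to -1/x, a strictly increasing transform that pulls in
#' the right tail of skewed half-life distributions so they better suit
#' linear modeling. All outputs are negative.
#'
#' @param halflives Numeric vector of half-lives (> 0), or a tibble with a
#'   `half_life` column.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' reciprocal_transform(c(2, 24))  # -0.5, -1/24
reciprocal_transform <- function(halflives) {
  x <- if (is.data.frame(halflives)) halflives$half_life else halflives
  if (any(!is.finite(x) | x <= 0)) {
    stop("half-lives must be finite and > 0", call. = FALSE)
  }
  -1 / x
}

.check_regressors <- function(df, terms) {
  for (tm in terms) {
    v <- df[[tm]]
    if (anyNA(v)) stop("regressor `", tm, "` contains NA", call. = FALSE)
    if (sd(v) == 0) {
      stop("regressor `", tm, "` is constant (rank-deficient model)",
           call. = FALSE)
    }
  }
  qrk <- qr(cbind(1, as.matrix(df[terms])))$rank
  if (qrk < length(terms) + 1L) {
    stop("regressors are collinear: ", paste(terms, collapse = " + "),
         call. = FALSE)
  }
  invisible(df)
}

.as_stab_fit <- function(fit, n, data_name) {
  structure(list(lm = fit, n = n, data = data_name), class = "stab_fit")
}

#' Model transformed half-lives on transcript composition
#'
#' Ordinary least squares of the reciprocal-transformed half-life on
#' transcript average CSC and GC3 codon frequency:
#' `-1/half_life ~ avg_csc + gc3_frequency`.
#'
#' @param scores Tibble from [transcript_scores()] (needs `transcript_id`,
#'   `avg_csc`, `gc3_frequency`).
#' @param halflives Tibble with `transcript_id`, `half_life` (> 0).
#' @return An object of class `stab_fit`; see [tidy.stab_fit()] and
#'   [glance.stab_fit()].
#' @export
fit_halflife_model <- function(scores, halflives) {
  df <- dplyr::inner_join(
    scores[, c("transcript_id", "avg_csc", "gc3_frequency")],
    halflives[, c("transcript_id", "half_life")],
    by = "transcript_id"
  )
  if (nrow(df) < 10L) {
    stop("need at least 10 transcripts in both inputs (got ", nrow(df), ")",
         call. = FALSE)
  }
  df$neg_recip_half_life <- reciprocal_transform(df$half_life)
  .check_regressors(df, c("avg_csc", "gc3_frequency"))
  fit <- lm(neg_recip_half_life ~ avg_csc + gc3_frequency, data = df)
  .as_stab_fit(fit, nrow(df), "transcript half-life model")
}

#' Model CSC on tRNA availability and free amino acid concentration
#'
#' Codon-level ordinary least squares `csc ~ tai + free_aa`, where each
#' codon carries the free intracellular concentration of the amino acid it
#' encodes. Codons encoding the amino acids in `exclude` (default cysteine
#' and glutamate, whose free concentrations are unmeasurable or extreme
#' outliers in cell lysates) are removed, leaving 57 rows for the full
#' codon set. With `codon_subset` "moderate" or "extreme", the model is
#' restricted using an [amino_acid_effect_partition()] (38 and 19 rows for
#' the canonical six-extreme partition).
#'
#' @param csc A `csc_table`.
#' @param tai A `tai_table`.
#' @param free_aa Tibble with columns `amino_acid` (one-letter code) and
#'   `concentration` (> 0, relative units).
#' @param codon_subset One of "all", "moderate", "extreme".
#' @param partition Result of [amino_acid_effect_partition()]; required
#'   unless `codon_subset = "all"`.
#' @param exclude Amino acids whose codons are dropped (default C and E).
#' @return An object of class `stab_fit`. The modeled rows are attached as
#'   attribute `data`.
#' @export
fit_csc_model <- function(csc, tai, free_aa,
                          codon_subset = c("all", "moderate", "extreme"),
                          partition = NULL, exclude = c("C", "E")) {
  codon_subset <- match.arg(codon_subset)
  stopifnot(inherits(csc, "csc_table"), inherits(tai, "tai_table"))
  stopifnot(all(c("amino_acid", "concentration") %in% names(free_aa)))
  if (any(free_aa$concentration <= 0)) {
    stop("free amino acid concentrations must be > 0", call. = FALSE)
  }
  df <- csc[, c("codon", "amino_acid", "csc")] |>
    dplyr::inner_join(tai[, c("codon", "tai")], by = "codon") |>
    dplyr::left_join(free_aa[, c("amino_acid", "concentration")],
                     by = "amino_acid") |>
    dplyr::filter(!.data$amino_acid %in% exclude)
  if (codon_subset != "all") {
    if (is.null(partition)) {
      stop("`partition` is required for codon_subset = \"", codon_subset, "\"",
           call. = FALSE)
    }
    keep_aa <- if (codon_subset == "extreme") partition$extreme else partition$moderate
    df <- dplyr::filter(df, .data$amino_acid %in% keep_aa)
  }
  df <- df[stats::complete.cases(df[, c("csc", "tai", "concentration")]), ]
  if (nrow(df) < 3L) {
    stop("fewer than 3 codons in the requested subset", call. = FALSE)
  }
  .check_regressors(df, c("tai", "concentration"))
  fit <- lm(csc ~ tai + concentration, data = df)
  out <- .as_stab_fit(fit, nrow(df),
                      paste0("CSC model (", codon_subset, " codons)"))
  attr(out, "data") <- df
  out
}

#' @export
print.stab_fit <- function(x, ...) {
  cat("<stab_fit> ", x$data, ", n = ", x$n, "\n", sep = "")
  print(tidy(x))
  g <- glance(x)
  cat(sprintf("adjusted R-squared = %.4f, overall p = %.4g\n",
              g$adj_r_squared, g$p_value))
  invisible(x)
}

#' Tidy a stability model fit
#'
#' @param x A `stab_fit` object.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `ci_low`, `ci_high`,
#'   `p_value`.
#' @exportS3Method generics::tidy
tidy.stab_fit <- function(x, conf_level = 0.95, ...) {
  sm <- summary(x$lm)$coefficients
  ci <- confint(x$lm, level = conf_level)
  tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    ci_low = unname(ci[, 1L]),
    ci_high = unname(ci[, 2L]),
    p_value = unname(sm[, "Pr(>|t|)"])
  )
}

#' Glance at a stability model fit
#'
#' @param x A `stab_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `adj_r_squared`, `p_value` (overall
#'   F-test), `n`.
#' @exportS3Method generics::glance
glance.stab_fit <- function(x, ...) {
  sm <- summary(x$lm)
  f <- sm$fstatistic
  tibble::tibble(
    adj_r_squared = sm$adj.r.squared,
    p_value = unname(pf(f[1L], f[2L], f[3L], lower.tail = FALSE)),
    n = x$n
  )
}

#' Stratify half-lives by a covariate
#'
#' Bins transcripts by a per-transcript covariate (default: equal-width
#' bins over the observed range) and summarises the half-life distribution
#' per bin, with a Kruskal-Wallis omnibus test across bins.
#'
#' @param halflives Tibble with `transcript_id`, `half_life`.
#' @param covariate Tibble with `transcript_id` and `value` columns, or a
#'   numeric vector aligned with (and matched to) `halflives`.
#' @param bins Number of equal-width bins (ignored when `bin_edges` given).
#' @param bin_edges Optional explicit bin edges (covering the data range).
#' @return A list with `summary` (tibble `bin`, `n`, `median`, `q1`, `q3`),
#'   `statistic`, `df` and `p_value`.
#' @export
stratify_halflives <- function(halflives, covariate, bins = 5L,
                               bin_edges = NULL) {
  if (is.data.frame(covariate)) {
    stopifnot(all(c("transcript_id", "value") %in% names(covariate)))
    df <- dplyr::inner_join(halflives[, c("transcript_id", "half_life")],
                            covariate[, c("transcript_id", "value")],
                            by = "transcript_id")
  } else {
    stopifnot(length(covariate) == nrow(halflives))
    df <- tibble::tibble(half_life = halflives$half_life, value = covariate)
  }
  df <- df[is.finite(df$half_life) & is.finite(df$value), ]
  if (is.null(bin_edges)) {
    rng <- range(df$value)
    if (diff(rng) == 0) stop("covariate is constant; cannot stratify", call. = FALSE)
    bin_edges <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  }
  df$bin <- cut(df$value, breaks = bin_edges, include.lowest = TRUE)
  df <- df[!is.na(df$bin), ]
  df$bin <- droplevels(df$bin)
  if (nlevels(df$bin) < 2L) {
    stop("need at least 2 nonempty bins to stratify", call. = FALSE)
  }
  kw <- kruskal.test(df$half_life, df$bin)
  summary <- df |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data$half_life),
      q1 = quantile(.data$half_life, 0.25, names = FALSE),
      q3 = quantile(.data$half_life, 0.75, names = FALSE),
      .by = "bin"
    ) |>
    dplyr::arrange(.data$bin)
  list(summary = summary,
       statistic = unname(kw$statistic),
       df = unname(kw$parameter),
       p_value = kw$p.value)
}

#' Compare two groups by a rank-sum test
#'
#' Two-sided Wilcoxon rank-sum comparison of two groups of half-lives or
#' scores (exact p for small tie-free samples, normal approximation with
#' mid-ranks otherwise, as implemented by [stats::wilcox.test()]).
#'
#' @param a,b Numeric vectors, or tibbles with a `half_life` column.
#' @return A one-row tibble with `n_a`, `n_b`, `median_a`, `median_b`,
#'   `median_diff`, `statistic`, `p_value`.
#' @export
compare_groups <- function(a, b) {
  if (is.data.frame(a)) a <- a$half_life
  if (is.data.frame(b)) b <- b$half_life
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  tibble::tibble(
    n_a = length(a), n_b = length(b),
    median_a = median(a), median_b = median(b),
    median_diff = median(a) - median(b),
    statistic = unname(wt$statistic),
    p_value = wt$p.value
  )
}

#' Impute a ceiling half-life for highly stable transcripts
#'
#' Transcripts that pass depth filters but cannot be fitted because they
#' barely decay over the chase can be assigned a stated maximum half-life
#' before group comparisons, making the imputation explicit and logged
#' rather than silently dropping the most stable genes.
#'
#' @param halflives Tibble with `transcript_id`, `half_life`.
#' @param ids Transcript ids to add (those already present are left
#'   untouched).
#' @param max_halflife Imputed half-life in hours (default 24).
#' @return The half-life tibble with imputed rows appended and an
#'   `imputed` logical column.
#' @export
impute_max_halflife <- function(halflives, ids, max_halflife = 24) {
  new_ids <- setdiff(ids, halflives$transcript_id)
  message(length(new_ids), " transcript(s) assigned the maximum half-life (",
          max_halflife, " h)")
  dplyr::bind_rows(
    dplyr::mutate(halflives, imputed = FALSE),
    tibble::tibble(transcript_id = new_ids, half_life = max_halflife,
                   imputed = TRUE)
  )
}
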