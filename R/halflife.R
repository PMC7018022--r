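#' Spike-in normalize a decay timecourse
#'
#' Adjusts a transcript-by-timepoint FPKM matrix for the apparent
#' amplification that arises when the labeled RNA pool shrinks over a chase:
#' each timepoint's spike-in factor is the mean of the two spike-in read
#' counts divided by the total read count, each column is divided by its
#' factor relative to the t0 factor, and each transcript row is then scaled
#' to 100 at t0. Transcripts with raw t0 FPKM below `min_t0_fpkm` are
#' flagged `low_t0`; transcripts with t0 = 0 are flagged `unfit` (they
#' cannot be rescaled) rather than aborting the run.
#'
#' @param fpkm Long tibble with columns `transcript_id`, `time` (hours,
#'   including 0) and `fpkm`, or a wide data frame with a `transcript_id`
#'   column and one numeric column per timepoint (names coercible to
#'   hours).
#' @param spikes Tibble with columns `time`, `luc_reads`, `lysa_reads`,
#'   `total_reads` (all positive).
#' @param min_t0_fpkm Raw t0 FPKM threshold below which a transcript is
#'   flagged (default 1).
#' @return A list of class `decay_timecourse` with elements `abundance`
#'   (long tibble `transcript_id`, `time`, `abundance`, t0 = 100),
#'   `spike_factors` (tibble `time`, `factor`, relative to t0),
#'   `transcripts` (tibble `transcript_id`, `t0_fpkm`, `low_t0`, `unfit`)
#'   and `timepoints`.
#' @export
spike_in_normalize <- function(fpkm, spikes, min_t0_fpkm = 1) {
  stopifnot(all(c("time", "luc_reads", "lysa_reads", "total_reads") %in% names(spikes)))
  if (any(spikes$luc_reads <= 0) || any(spikes$lysa_reads <= 0)) {
    stop("spike-in read counts must be positive at every timepoint", call. = FALSE)
  }
  if (any(spikes$total_reads <= 0)) {
    stop("total read counts must be positive at every timepoint", call. = FALSE)
  }
  if (!all(c("transcript_id", "time", "fpkm") %in% names(fpkm))) {
    # wide matrix: transcript_id + one column per timepoint
    stopifnot("transcript_id" %in% names(fpkm))
    fpkm <- tidyr::pivot_longer(fpkm, -"transcript_id",
                                names_to = "time", values_to = "fpkm") |>
      dplyr::mutate(time = as.numeric(.data$time))
  }
  tp <- sort(unique(fpkm$time))
  if (tp[1L] != 0) stop("timepoints must start at 0", call. = FALSE)
  if (!setequal(tp, spikes$time)) {
    stop("spike-in table timepoints do not match the abundance matrix", call. = FALSE)
  }
  if (any(fpkm$fpkm < 0, na.rm = TRUE)) stop("FPKM values must be >= 0", call. = FALSE)

  sf <- spikes |>
    dplyr::mutate(raw_factor = (.data$luc_reads + .data$lysa_reads) / 2 /
                    .data$total_reads)
  f0 <- sf$raw_factor[sf$time == 0]
  sf <- tibble::tibble(time = sf$time, factor = sf$raw_factor / f0)

  norm <- fpkm |>
    dplyr::left_join(sf, by = "time") |>
    dplyr::mutate(value = .data$fpkm / .data$factor)
  t0 <- norm |>
    dplyr::filter(.data$time == 0) |>
    dplyr::select("transcript_id", t0_fpkm = "fpkm")
  transcripts <- t0 |>
    dplyr::mutate(low_t0 = .data$t0_fpkm < min_t0_fpkm,
                  unfit = .data$t0_fpkm == 0)
  abundance <- norm |>
    dplyr::left_join(t0, by = "transcript_id") |>
    dplyr::mutate(abundance = ifelse(.data$t0_fpkm > 0,
                                     100 * .data$value / .data$t0_fpkm,
                                     NA_real_)) |>
    dplyr::select("transcript_id", "time", "abundance") |>
    dplyr::arrange(.data$transcript_id, .data$time)

  structure(list(abundance = abundance,
                 spike_factors = dplyr::arrange(sf, .data$time),
                 transcripts = transcripts,
                 timepoints = tp),
            class = "decay_timecourse")
}

#' @export
print.decay_timecourse <- function(x, ...) {
  cat("<decay_timecourse> ", dplyr::n_distinct(x$abundance$transcript_id),
      " transcripts x ", length(x$timepoints), " timepoints (",
      paste(x$timepoints, collapse = ", "), " h)\n", sep = "")
  invisible(x)
}

# LAD objective for the pinned model y(t) = 100 exp(-(k + dilution) t)
.lad_obj <- function(k, y, t, dilution) {
  sum(abs(y - 100 * exp(-(k + dilution) * t)))
}

#' Fit an exponential decay by least absolute deviations
#'
#' Fits y(t) = A exp(-(k + ln2 / doubling_time) t) to a t0-normalized
#' trajectory by minimizing the sum of absolute residuals over k >= 0 in
#' linear abundance space. The ln2 / doubling_time term corrects for
#' dilution of the labeled pool by cell growth, so k is the clearance rate
#' and the half-life is ln2 / k. By default the amplitude A is estimated
#' alongside k: the t0 point is a measurement like any other, and anchoring
#' the curve to it (A pinned at 100) propagates t0 noise directly into the
#' rate. Set `free_intercept = FALSE` for the pinned variant. The optimizer
#' is deterministic: a coarse grid over k in \[0, 10 ln2\] per hour (200
#' points, log-spaced above the floor) followed by local refinement around
#' the grid minimum (Nelder-Mead on (log A, log k) when A is free).
#'
#' @param abundance Numeric vector of normalized abundances (t0 = 100
#'   scale).
#' @param timepoints Numeric vector of hours, same length, including 0.
#' @param doubling_time Cell doubling time in hours (default 15); `Inf`
#'   disables the dilution correction.
#' @param free_intercept If `TRUE` (default), the amplitude at t0 is
#'   estimated alongside the rate; if `FALSE`, it is pinned at 100.
#' @return A one-row tibble with columns `half_life` (hours; `Inf` at the
#'   k = 0 boundary), `decay_rate` (per hour), `mean_abs_residual` (on the
#'   t0 = 100 scale, all timepoints included), `n_timepoints`, `fit_ok`
#'   and `reason` (`NA` when fit_ok).
#' @export
#' @examples
#' t <- c(0, 0.5, 1, 2, 3, 4, 6, 8, 10, 12)
#' y <- 100 * exp(-(log(2) / 2 + log(2) / 15) * t)
#' fit_decay_lad(y, t)
fit_decay_lad <- function(abundance, timepoints, doubling_time = 15,
                          free_intercept = TRUE) {
  ok <- is.finite(abundance) & is.finite(timepoints)
  y <- abundance[ok]; t <- timepoints[ok]
  unfit <- function(reason) tibble::tibble(
    half_life = NA_real_, decay_rate = NA_real_,
    mean_abs_residual = NA_real_, n_timepoints = length(y),
    fit_ok = FALSE, reason = reason)
  if (length(y) < 4L || !any(t == 0)) return(unfit("fewer_than_4_points"))
  dilution <- if (is.finite(doubling_time)) log(2) / doubling_time else 0

  k_max <- 10 * log(2)
  grid <- c(0, exp(seq(log(1e-4), log(k_max), length.out = 199L)))
  if (free_intercept) {
    obj2 <- function(par) sum(abs(y - exp(par[1L]) * exp(-(exp(par[2L]) + dilution) * t)))
    vals <- vapply(grid[-1L], function(k) obj2(c(log(100), log(k))), numeric(1L))
    k0 <- grid[-1L][which.min(vals)]
    opt <- stats::optim(c(log(100), log(k0)), obj2, method = "Nelder-Mead",
                        control = list(maxit = 2000L, reltol = 1e-12))
    k <- exp(opt$par[2L]); a <- exp(opt$par[1L])
    resid <- abs(y - a * exp(-(k + dilution) * t))
  } else {
    vals <- vapply(grid, .lad_obj, numeric(1L), y = y, t = t, dilution = dilution)
    i <- which.min(vals)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    k <- if (lo < hi) {
      ref <- optimize(.lad_obj, c(lo, hi), y = y, t = t, dilution = dilution,
                      tol = 1e-10)
      if (ref$objective <= vals[i]) ref$minimum else grid[i]
    } else grid[i]
    resid <- abs(y - 100 * exp(-(k + dilution) * t))
  }
  boundary <- k <= 1e-8
  tibble::tibble(
    half_life = if (boundary) Inf else log(2) / k,
    decay_rate = if (boundary) 0 else k,
    mean_abs_residual = mean(resid),
    n_timepoints = length(y),
    fit_ok = !boundary,
    reason = if (boundary) "non_decaying" else NA_character_
  )
}

#' Fit half-lives for every transcript of a timecourse
#'
#' Maps [fit_decay_lad()] over a normalized [spike_in_normalize()]
#' timecourse. Transcripts flagged unfit at normalization (t0 = 0) are
#' passed through with `fit_ok = FALSE`.
#'
#' @param tc A `decay_timecourse`.
#' @inheritParams fit_decay_lad
#' @return A tibble with one row per transcript: `transcript_id`,
#'   `half_life`, `decay_rate`, `mean_abs_residual`, `n_timepoints`,
#'   `fit_ok`, `reason`, `low_t0`.
#' @export
fit_halflives <- function(tc, doubling_time = 15, free_intercept = TRUE) {
  stopifnot(inherits(tc, "decay_timecourse"))
  fits <- tc$abundance |>
    dplyr::summarise(
      fit = list(fit_decay_lad(.data$abundance, .data$time,
                               doubling_time = doubling_time,
                               free_intercept = free_intercept)),
      .by = "transcript_id"
    ) |>
    tidyr::unnest("fit")
  dplyr::left_join(fits,
                   tc$transcripts[, c("transcript_id", "low_t0", "unfit")],
                   by = "transcript_id") |>
    dplyr::mutate(
      fit_ok = .data$fit_ok & !.data$unfit,
      reason = dplyr::case_when(.data$unfit ~ "t0_zero", .default = .data$reason)
    ) |>
    dplyr::select(-"unfit")
}

#' Filter half-life estimates
#'
#' Retains estimates with half-life at most `max_halflife` hours and mean
#' absolute residual at most `max_mean_abs_residual` (on the t0 = 100
#' scale). Failed fits are always rejected. The rejection report counts
#' every reason independently, so an estimate failing two rules appears in
#' both counts.
#'
#' @param estimates Tibble from [fit_halflives()] (or a row-bound set of
#'   [fit_decay_lad()] results with a `transcript_id` column).
#' @param max_halflife Maximum retained half-life in hours (default 18).
#' @param max_mean_abs_residual Maximum retained mean absolute residual
#'   (default 20).
#' @return A list with elements `passed` (tibble subset), `rejected`
#'   (tibble with a `reject_reasons` column) and `report` (tibble
#'   `reason`, `n`).
#' @export
filter_estimates <- function(estimates, max_halflife = 18,
                             max_mean_abs_residual = 20) {
  bad_fit <- !estimates$fit_ok
  bad_hl <- !bad_fit & estimates$half_life > max_halflife
  bad_res <- !bad_fit & estimates$mean_abs_residual > max_mean_abs_residual
  keep <- !(bad_fit | bad_hl | bad_res)
  reasons <- purrr::pmap_chr(list(bad_fit, bad_hl, bad_res, estimates$reason),
    function(f, h, r, why) {
      out <- c(if (f) paste0("fit_failed:", why),
               if (h) "half_life_gt_max",
               if (r) "residual_gt_max")
      paste(out, collapse = ";")
    })
  report <- tibble::tibble(
    reason = c("fit_failed", "half_life_gt_max", "residual_gt_max"),
    n = c(sum(bad_fit), sum(bad_hl), sum(bad_res))
  )
  list(
    passed = estimates[keep, , drop = FALSE],
    rejected = dplyr::mutate(estimates[!keep, , drop = FALSE],
                             reject_reasons = reasons[!keep]),
    report = report
  )
}
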