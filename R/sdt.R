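# Signal-detection analysis: hit / false-alarm counts, boundary-rate
# correction, d-prime, per-speaker percent correct, and the soft-ceiling
# chi-square diagnostic. In recognition, a hit is an "old" response to a
# previously heard voice and a false alarm an "old" response to a new
# voice; in discrimination, "different" plays the signal role.

#' Assemble signal-detection counts
#'
#' @param hits,false_alarms Integer counts.
#' @param n_signal,n_noise Trial totals (>= 1).
#' @return A list of class `sdt_counts`.
#' @export
sdt_counts <- function(hits, false_alarms, n_signal, n_noise) {
  stopifnot(n_signal >= 1, n_noise >= 1,
            hits >= 0, hits <= n_signal,
            false_alarms >= 0, false_alarms <= n_noise)
  structure(list(hits = hits, false_alarms = false_alarms,
                 n_signal = n_signal, n_noise = n_noise),
            class = "sdt_counts")
}

#' Correct boundary hit / false-alarm rates
#'
#' The default `halfN` rule replaces a rate of 0 by `1/(2N)` and a rate
#' of 1 by `1 - 1/(2N)`, leaving interior rates untouched (idempotent).
#' The `loglinear` rule recomputes every rate as `(count + 0.5)/(N + 1)`
#' regardless of boundaries.
#'
#' @param counts An `sdt_counts` object.
#' @param method `"halfN"` (default) or `"loglinear"`.
#' @return A list with `hit_rate`, `fa_rate` (both in the open unit
#'   interval) and `correction_applied`.
#' @export
corrected_rates <- function(counts, method = c("halfN", "loglinear")) {
  method <- match.arg(method)
  stopifnot(inherits(counts, "sdt_counts"))
  if (method == "halfN") {
    fix <- function(k, n) {
      if (k == 0) 1 / (2 * n) else if (k == n) 1 - 1 / (2 * n) else k / n
    }
    hr <- fix(counts$hits, counts$n_signal)
    fr <- fix(counts$false_alarms, counts$n_noise)
    applied <- counts$hits %in% c(0, counts$n_signal) ||
      counts$false_alarms %in% c(0, counts$n_noise)
  } else {
    hr <- (counts$hits + 0.5) / (counts$n_signal + 1)
    fr <- (counts$false_alarms + 0.5) / (counts$n_noise + 1)
    applied <- TRUE
  }
  list(hit_rate = hr, fa_rate = fr, correction_applied = applied)
}

#' Sensitivity d-prime from corrected rates
#'
#' `d' = Z(hit rate) - Z(false alarm rate)` with `Z` the standard
#' normal quantile. Swapping the rates negates the result.
#'
#' @param hit_rate,fa_rate Rates in the open interval (0, 1).
#' @return The d-prime value.
#' @export
dprime <- function(hit_rate, fa_rate) {
  if (any(c(hit_rate, fa_rate) <= 0) || any(c(hit_rate, fa_rate) >= 1))
    abort("rates must lie strictly inside (0, 1); apply corrected_rates() first")
  stats::qnorm(hit_rate) - stats::qnorm(fa_rate)
}

#' d-prime straight from counts
#'
#' Convenience composition of [corrected_rates()] and [dprime()].
#'
#' @inheritParams corrected_rates
#' @return A list: `hit_rate`, `fa_rate`, `dprime`, `correction_applied`.
#' @export
dprime_from_counts <- function(counts, method = c("halfN", "loglinear")) {
  r <- corrected_rates(counts, method)
  r$dprime <- dprime(r$hit_rate, r$fa_rate)
  r
}

#' Two-cell chi-square goodness of fit
#'
#' Pearson statistic over the two cells (at-or-above threshold, below
#' threshold): `(o - e)^2 / e + ((n - o) - (n - e))^2 / (n - e)`, with
#' the p-value from the chi-square distribution on 1 df.
#'
#' @param observed Observed count in the focal cell.
#' @param expected Expected count, strictly between 0 and `n`.
#' @param n Total count.
#' @return A list with `chi2`, `df` (= 1) and `p`.
#' @export
chi_square_gof <- function(observed, expected, n) {
  if (expected <= 0 || expected >= n)
    abort("expected count must lie strictly between 0 and n")
  chi2 <- (observed - expected)^2 / expected +
    ((n - observed) - (n - expected))^2 / (n - expected)
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Soft-ceiling diagnostic on a d-prime distribution
#'
#' Sets a soft ceiling threshold at the empirical `percentile`-th
#' percentile (linear-interpolation convention, `type = 7`), counts the
#' participants at or above it, and compares the count with its
#' expectation via a two-cell chi-square test. Under the default
#' `normal_tail` mode the expected count is `n * P(X >= threshold)` for
#' `X ~ Normal(sample mean, sample SD)`; `fixed_fraction` uses
#' `(1 - percentile/100) * n`.
#'
#' @param dprimes Numeric vector of per-participant d-prime values
#'   (length >= 10).
#' @param percentile Threshold percentile (default 90).
#' @param expected_mode `"normal_tail"` (default) or `"fixed_fraction"`.
#' @return A list with `threshold`, `observed`, `expected`, `chi2`,
#'   `p`, `n`, and `quantile_type` (metadata: the convention used).
#' @export
ceiling_analysis <- function(dprimes, percentile = 90,
                             expected_mode = c("normal_tail",
                                               "fixed_fraction")) {
  expected_mode <- match.arg(expected_mode)
  n <- length(dprimes)
  if (n < 10) abort("ceiling analysis needs at least 10 observations")
  threshold <- unname(stats::quantile(dprimes, percentile / 100, type = 7))
  observed <- sum(dprimes >= threshold)
  if (expected_mode == "normal_tail") {
    s <- stats::sd(dprimes)
    if (s == 0) abort("zero standard deviation; normal_tail mode undefined")
    expected <- n * stats::pnorm(threshold, mean(dprimes), s,
                                 lower.tail = FALSE)
  } else {
    expected <- (1 - percentile / 100) * n
  }
  gof <- chi_square_gof(observed, expected, n)
  list(threshold = threshold, observed = observed, expected = expected,
       chi2 = gof$chi2, p = gof$p, n = n, quantile_type = 7L,
       expected_mode = expected_mode)
}

# --- response-log scoring ---------------------------------------------

# signal definition per trial type: "old" for recognition trials,
# "different" for discrimination trials
signal_label <- function(trial_type) {
  ifelse(trial_type == "recognition", "old", "different")
}

#' Score recognition performance per participant and phase
#'
#' Aggregates a trial-level response log into per-participant,
#' per-phase hit / false-alarm counts and corrected d-prime.
#'
#' @param log A response log (see [simulate_experiment()]); only rows
#'   with `trial_type == "recognition"` are used.
#' @param method Correction method, see [corrected_rates()].
#' @return A data frame with one row per participant x phase:
#'   `participant_id`, `version`, `order`, `phase_index`, `task`,
#'   counts, corrected rates, `dprime`, `correction_applied`.
#' @export
score_recognition <- function(log, method = c("halfN", "loglinear")) {
  method <- match.arg(method)
  score_log(log[log$trial_type == "recognition", , drop = FALSE], method)
}

#' Score discrimination performance per participant and phase
#'
#' As [score_recognition()] but over same-different discrimination
#' trials, with "different" as the signal response.
#'
#' @inheritParams score_recognition
#' @export
score_discrimination <- function(log, method = c("halfN", "loglinear")) {
  method <- match.arg(method)
  score_log(log[log$trial_type == "discrimination", , drop = FALSE], method)
}

score_log <- function(log, method) {
  if (nrow(log) == 0)
    abort("no trials to score")
  key <- interaction(log$participant_id, log$phase_index, drop = TRUE)
  out <- lapply(split(log, key), function(d) {
    sig <- signal_label(d$trial_type[1])
    is_sig <- d$truth == sig
    counts <- sdt_counts(hits = sum(is_sig & d$response == sig),
                         false_alarms = sum(!is_sig & d$response == sig),
                         n_signal = sum(is_sig), n_noise = sum(!is_sig))
    r <- dprime_from_counts(counts, method)
    data.frame(participant_id = d$participant_id[1],
               version = d$version[1], order = d$order[1],
               phase_index = d$phase_index[1], task = d$task[1],
               n_signal = counts$n_signal, n_noise = counts$n_noise,
               hits = counts$hits, false_alarms = counts$false_alarms,
               hit_rate = r$hit_rate, fa_rate = r$fa_rate,
               dprime = r$dprime, correction_applied = r$correction_applied,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$participant_id, out$phase_index), ]
}

#' Per-speaker percent correct
#'
#' Percent correct old/new judgements per tested voice identity, pooled
#' over participants and reported per condition (experiment version).
#'
#' @param log A response log; only recognition trials are used.
#' @return A data frame: `version`, `speaker_id`, `n_trials`,
#'   `n_correct`, `pc` (percent, 0-100). Speakers absent from the log
#'   are simply not listed.
#' @export
percent_correct_by_speaker <- function(log) {
  rec <- log[log$trial_type == "recognition", , drop = FALSE]
  if (nrow(rec) == 0) abort("no recognition trials in log")
  key <- interaction(rec$version, rec$speaker_id, drop = TRUE)
  out <- lapply(split(rec, key), function(d) {
    data.frame(version = d$version[1], speaker_id = d$speaker_id[1],
               n_trials = nrow(d), n_correct = sum(d$response == d$truth),
               pc = 100 * mean(d$response == d$truth),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$version, out$speaker_id), ]
}
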