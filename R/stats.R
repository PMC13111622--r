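# Group-level inference: Welch t-tests with Bonferroni adjustment,
# Shapiro-Wilk-gated Spearman correlations, the additive / interaction
# linear mixed-effects models of recognition sensitivity, and a
# simulate -> analyse -> fit parameter-recovery harness.

#' Welch's unequal-variances t-test
#'
#' @param x,y Numeric samples (each n >= 2).
#' @return A list with `t`, `df` (Welch-Satterthwaite) and `p`
#'   (two-sided, unadjusted; apply [bonferroni()] over the declared
#'   family).
#' @export
compare_groups <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = length(x) + length(y) - 2,
                                        p = 1))
    abort("both samples have zero variance; Welch statistic undefined")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Bonferroni adjustment over a declared family
#'
#' @param p P-value(s).
#' @param m Family size (declared, never inferred).
#' @return `min(1, p * m)`, vectorised.
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, p * m)
}

#' Spearman rank correlation with a normality gate
#'
#' Computes Spearman's rho (rank-based, tie-aware) together with
#' Shapiro-Wilk normality tests of both inputs, reported alongside so
#' the non-parametric choice is auditable.
#'
#' @param x,y Paired numeric samples (n >= 4).
#' @return A list: `rho`, `p`, `shapiro_p_x`, `shapiro_p_y`,
#'   `normality_ok` (both Shapiro p-values > .05).
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    abort("constant input; correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  sw_x <- stats::shapiro.test(x)$p.value
  sw_y <- stats::shapiro.test(y)$p.value
  list(rho = unname(ct$estimate), p = ct$p.value,
       shapiro_p_x = sw_x, shapiro_p_y = sw_y,
       normality_ok = sw_x > 0.05 && sw_y > 0.05)
}

#' Prepare recognition scores for mixed-model fitting
#'
#' Recodes a [score_recognition()] table into factors with explicit
#' reference levels, chosen so every reported coefficient is a named,
#' unambiguous contrast: `awareness` (reference `explicit`; the
#' `implicit` coefficient is the implicit-minus-explicit advantage),
#' `load` (reference `challenging`; the `simple` coefficient is the
#' simple-minus-challenging advantage) and `phase` (reference
#' `phase2`; the `phase1` coefficient is phase-1-minus-phase-2).
#'
#' @param scores Output of [score_recognition()].
#' @return A data frame with `dprime`, `awareness`, `load`, `phase`,
#'   `participant`.
#' @export
prepare_model_data <- function(scores) {
  data.frame(
    dprime = scores$dprime,
    awareness = factor(scores$task, levels = c("explicit", "implicit")),
    load = factor(scores$version, levels = c("challenging", "simple")),
    phase = factor(paste0("phase", scores$phase_index),
                   levels = c("phase2", "phase1")),
    participant = factor(scores$participant_id))
}

#' Fit the recognition mixed-effects model
#'
#' Fits `dprime ~ awareness + load + phase + (1 | participant)` (or the
#' full three-way interaction model when `interactions = TRUE`) by
#' maximum likelihood, with Satterthwaite degrees of freedom and
#' p-values via \pkg{lmerTest}. Confidence intervals are
#' `estimate +/- t(df, .975) * SE`, consistent with the reported df.
#' Factor coding (see [prepare_model_data()]) makes every coefficient's
#' direction explicit in its term name.
#'
#' @param data Output of [prepare_model_data()], or any data frame with
#'   columns `dprime`, `awareness`, `load`, `phase`, `participant`.
#' @param interactions Fit the full factorial model (default `FALSE`,
#'   the additive model).
#' @return A list of class `lmm_fit`: `terms` (data frame: `term`,
#'   `estimate`, `se`, `df`, `t`, `p`, `ci_lo`, `ci_hi`), `varcorr`
#'   (participant-intercept SD and residual SD), `singular`,
#'   `p_method`, and the fitted `model`.
#' @export
fit_lmm <- function(data, interactions = FALSE) {
  stopifnot(all(c("dprime", "awareness", "load", "phase", "participant")
                %in% colnames(data)))
  form <- if (interactions)
    dprime ~ awareness * load * phase + (1 | participant)
  else
    dprime ~ awareness + load + phase + (1 | participant)
  fit <- lmerTest::lmer(form, data = data, REML = FALSE)
  singular <- lme4::isSingular(fit)
  if (singular)
    warning("singular fit: participant intercept variance estimated at the boundary")
  cf <- stats::coef(summary(fit)) # Satterthwaite df from lmerTest
  terms <- data.frame(
    term = rownames(cf),
    estimate = cf[, "Estimate"], se = cf[, "Std. Error"],
    df = cf[, "df"], t = cf[, "t value"], p = cf[, "Pr(>|t|)"],
    stringsAsFactors = FALSE)
  q <- stats::qt(0.975, terms$df)
  terms$ci_lo <- terms$estimate - q * terms$se
  terms$ci_hi <- terms$estimate + q * terms$se
  rownames(terms) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(terms = terms,
                 varcorr = data.frame(component = vc$grp,
                                      sd = vc$sdcor),
                 singular = singular, p_method = "satterthwaite",
                 model = fit),
            class = "lmm_fit")
}

#' @method print lmm_fit
#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model (ML), p-values:", x$p_method,
      if (x$singular) "[singular fit]" else "", "\n")
  print(x$terms, digits = 3)
  cat("Variance components (SD):\n")
  print(x$varcorr, digits = 3)
  invisible(x)
}

# implied additive coefficients of a generative configuration:
# awareness = participant-weighted mean of per-version implicit-explicit
# contrasts; load = mean(simple cells) - mean(challenging cells);
# phase1 = order effect
implied_effects <- function(config) {
  mu <- config$recognition_means
  n <- config$n_participants
  aw <- (n[["simple"]] * (mu[["simple.implicit"]] - mu[["simple.explicit"]]) +
           n[["challenging"]] * (mu[["challenging.implicit"]] -
                                   mu[["challenging.explicit"]])) /
    (n[["simple"]] + n[["challenging"]])
  ld <- mean(c(mu[["simple.implicit"]], mu[["simple.explicit"]])) -
    mean(c(mu[["challenging.implicit"]], mu[["challenging.explicit"]]))
  c(awarenessimplicit = unname(aw), loadsimple = unname(ld),
    phasephase1 = config$order_effect)
}

#' Parameter-recovery harness
#'
#' Runs the full simulate -> score -> fit loop across seeds and
#' summarises, per fixed-effect term, the mean and empirical SD of the
#' estimates and the coverage of the 95% confidence intervals against
#' the generative truth implied by the configuration.
#'
#' @param config A `generative_config`.
#' @param n_seeds Number of simulation replicates.
#' @param base_seed Master seed; replicate seeds are derived from it.
#' @param plans Optional prebuilt `study_plans` reused across
#'   replicates (built once from `base_seed` when `NULL`).
#' @param method d-prime correction method.
#' @return A list of class `recovery_summary`: `per_seed` (term
#'   estimates and CIs per replicate; failed fits are counted in
#'   `n_failed`, not fatal), `summary` (per term: `truth`,
#'   `mean_estimate`, `bias`, `sd_estimate`, `ci_coverage`), and
#'   `n_failed`.
#' @export
recovery_harness <- function(config = generative_config(), n_seeds = 20L,
                             base_seed = 1L, plans = NULL,
                             method = "halfN") {
  if (is.null(plans)) plans <- build_study_plans(derive_seed(base_seed, 0L))
  truth <- implied_effects(config)
  per_seed <- list()
  n_failed <- 0L
  for (s in seq_len(n_seeds)) {
    seed_s <- derive_seed(base_seed, s)
    res <- tryCatch({
      sim <- simulate_study(config, seed = seed_s, plans = plans)
      scores <- score_recognition(sim$log, method = method)
      fit <- suppressMessages(suppressWarnings(fit_lmm(prepare_model_data(scores))))
      cbind(seed = seed_s, rep = s, fit$terms)
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else
      per_seed[[length(per_seed) + 1L]] <- res
  }
  per_seed <- do.call(rbind, per_seed)
  terms <- setdiff(unique(per_seed$term), "(Intercept)")
  summary <- do.call(rbind, lapply(terms, function(tm) {
    d <- per_seed[per_seed$term == tm, ]
    tr <- if (tm %in% names(truth)) truth[[tm]] else NA_real_
    data.frame(term = tm, truth = tr,
               mean_estimate = mean(d$estimate),
               bias = mean(d$estimate) - tr,
               sd_estimate = stats::sd(d$estimate),
               ci_coverage = if (is.na(tr)) NA_real_ else
                 mean(d$ci_lo <= tr & tr <= d$ci_hi),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_seed = per_seed, summary = summary,
                 n_failed = n_failed, truth = truth),
            class = "recovery_summary")
}

#' @method print recovery_summary
#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d replicate(s), %d failed\n",
              length(unique(x$per_seed$rep)), x$n_failed))
  print(x$summary, digits = 3)
  invisible(x)
}
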