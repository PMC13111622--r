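# Synthetic data generation.
#
# Two generators live here: (1) synthetic speaker features (unit-sphere
# embedding centroids with within-speaker jitter and gender-specific
# mean F0) feeding the stimulus-selection module, and (2) an
# equal-variance signal-detection simulator producing trial-level
# binary responses for a whole experiment plan, with participant-level
# heterogeneity and per-condition sensitivity. The generative model is
# the exact inverse of the d-prime estimator: on signal trials the
# probability of a signal response is Phi(d/2 - c), on noise trials
# Phi(-d/2 - c).

#' Generative configuration for behavioural simulation
#'
#' Default cell parameters are the study's descriptive statistics:
#' recognition d-prime means (SDs) of 0.472 (0.653) simple-explicit,
#' 0.592 (0.679) simple-implicit, 0.056 (0.379) challenging-explicit
#' and 0.341 (0.408) challenging-implicit, and discrimination means
#' (SDs) of 1.96 (0.41) simple and 2.02 (0.45) challenging, with 81
#' simple and 51 challenging participants.
#'
#' @param recognition_means,recognition_sds Named numeric vectors over
#'   cells `simple.explicit`, `simple.implicit`, `challenging.explicit`,
#'   `challenging.implicit`.
#' @param discrimination_means,discrimination_sds Named numeric vectors
#'   over `simple`, `challenging`.
#' @param criterion Response criterion c (default 0, unbiased).
#' @param order_effect Additive shift of latent d-prime in phase 1
#'   (default 0).
#' @param participant_share Share in `[0, 1]` of each cell's variance
#'   carried by a participant-level deviate shared across that
#'   participant's cells (cross-cell correlation). Default 0: the
#'   latent d-prime is drawn independently per (task, phase) cell, all
#'   of it participant-level; the true split between stable individual
#'   ability and cell-specific variation is not identified by the
#'   descriptive statistics, so it is exposed as a parameter.
#' @param truncate_recognition Truncate latent recognition d-prime at 0
#'   (default `FALSE`; negative individual sensitivities do occur).
#' @param n_participants Named integer vector `c(simple=, challenging=)`.
#' @return A list of class `generative_config`.
#' @export
generative_config <- function(
    recognition_means = c(simple.explicit = 0.472, simple.implicit = 0.592,
                          challenging.explicit = 0.056,
                          challenging.implicit = 0.341),
    recognition_sds = c(simple.explicit = 0.653, simple.implicit = 0.679,
                        challenging.explicit = 0.379,
                        challenging.implicit = 0.408),
    discrimination_means = c(simple = 1.96, challenging = 2.02),
    discrimination_sds = c(simple = 0.41, challenging = 0.45),
    criterion = 0, order_effect = 0, participant_share = 0,
    truncate_recognition = FALSE,
    n_participants = c(simple = 81L, challenging = 51L)) {
  stopifnot(all(recognition_sds >= 0), all(discrimination_sds >= 0),
            participant_share >= 0, participant_share <= 1)
  structure(list(recognition_means = recognition_means,
                 recognition_sds = recognition_sds,
                 discrimination_means = discrimination_means,
                 discrimination_sds = discrimination_sds,
                 criterion = criterion, order_effect = order_effect,
                 participant_share = participant_share,
                 truncate_recognition = truncate_recognition,
                 n_participants = n_participants),
            class = "generative_config")
}

#' Read / write a generative configuration as YAML
#' @param path YAML file path.
#' @return For `read_generative_config`, a `generative_config`.
#' @export
read_generative_config <- function(path) {
  if (!file.exists(path)) abort("input file not found: %s", path)
  y <- yaml::read_yaml(path)
  do.call(generative_config, lapply(y, function(v)
    if (is.list(v)) unlist(v) else v))
}

#' @rdname read_generative_config
#' @param config A `generative_config`.
#' @export
write_generative_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(v)
    if (!is.null(names(v))) as.list(v) else v), path)
  invisible(path)
}

#' Generate synthetic speaker features
#'
#' Each speaker gets a unit-norm embedding centroid drawn uniformly on
#' the sphere; recordings are the centroid plus isotropic Gaussian
#' jitter, renormalised. Mean F0 is drawn from a gender-specific
#' Gaussian (defaults 120 +/- 20 Hz male, 210 +/- 25 Hz female).
#'
#' @param n_per_gender Speakers per gender (>= 2).
#' @param dim Embedding dimension (>= 2, default 16).
#' @param n_recordings Recordings per speaker (default 3).
#' @param within_speaker_spread SD of the pre-normalisation jitter
#'   (default 0.15; 0 makes all of a speaker's recordings identical).
#' @param f0_params List with `male = c(mean, sd)` and `female =
#'   c(mean, sd)` in Hz.
#' @param seed Integer seed.
#' @return A `speaker_features` data frame.
#' @export
gen_speakers <- function(n_per_gender, dim = 16L, n_recordings = 3L,
                         within_speaker_spread = 0.15,
                         f0_params = list(male = c(120, 20),
                                          female = c(210, 25)),
                         seed = 1L) {
  if (n_per_gender < 2) abort("need at least 2 speakers per gender")
  if (dim < 2) abort("embedding dimension must be >= 2")
  if (within_speaker_spread < 0) abort("within_speaker_spread must be >= 0")
  with_seed(seed, {
    rows <- list()
    for (g in c("male", "female")) {
      fp <- f0_params[[g]]
      for (s in seq_len(n_per_gender)) {
        sp <- sprintf("%s%02d", substr(g, 1, 1), s)
        centroid <- stats::rnorm(dim)
        centroid <- centroid / sqrt(sum(centroid^2))
        f0 <- max(50, stats::rnorm(1, fp[1], fp[2]))
        emb <- t(vapply(seq_len(n_recordings), function(r) {
          v <- centroid + stats::rnorm(dim, 0, within_speaker_spread)
          v / sqrt(sum(v^2))
        }, numeric(dim)))
        rows[[length(rows) + 1L]] <- list(
          speaker_id = rep(sp, n_recordings), gender = rep(g, n_recordings),
          mean_f0_hz = rep(f0, n_recordings),
          recording_id = sprintf("%s_r%02d", sp, seq_len(n_recordings)),
          emb = emb)
      }
    }
  })
  speaker_features(
    speaker_id = unlist(lapply(rows, `[[`, "speaker_id")),
    gender = unlist(lapply(rows, `[[`, "gender")),
    mean_f0_hz = unlist(lapply(rows, `[[`, "mean_f0_hz")),
    recording_id = unlist(lapply(rows, `[[`, "recording_id")),
    embeddings = do.call(rbind, lapply(rows, `[[`, "emb")))
}

#' Response probabilities of the equal-variance SDT observer
#'
#' @param d_eff Latent sensitivity.
#' @param criterion Criterion c.
#' @param is_signal Logical (vector): signal trial?
#' @return Probability of a signal response ("old" / "different").
#' @export
sdt_response_prob <- function(d_eff, criterion = 0, is_signal) {
  stats::pnorm(ifelse(is_signal, d_eff / 2, -d_eff / 2) - criterion)
}

#' Simulate one or more SDT trials
#'
#' @param truth Character vector with signal semantics: `"signal"` (or
#'   `"old"` / `"different"`) versus noise (`"noise"`, `"new"`,
#'   `"same"`).
#' @param d_eff Latent sensitivity (finite).
#' @param criterion Criterion c.
#' @return Logical vector: signal response emitted? Consumes the
#'   caller's RNG stream.
#' @export
simulate_trial <- function(truth, d_eff, criterion = 0) {
  stopifnot(all(is.finite(d_eff)))
  is_signal <- truth %in% c("signal", "old", "different")
  p <- sdt_response_prob(d_eff, criterion, is_signal)
  stats::runif(length(p)) < p
}

# latent d-prime per participant x cell; shared participant deviate z_p
# carries `participant_share` of each cell's variance
latent_dprime <- function(mu, sigma, z_p, z_cell, share) {
  mu + sigma * (sqrt(share) * z_p + sqrt(1 - share) * z_cell)
}

#' Simulate a full response log for an experiment plan
#'
#' Every participant receives a latent sensitivity per condition cell
#' (recognition after implicit / explicit exposure, plus the version's
#' discrimination sensitivity), drawn from the configured Gaussian cell
#' with a participant-level random effect, and then answers every
#' scheduled discrimination and recognition trial through the
#' equal-variance SDT observer. Memorization exposure is passive
#' (no responses) and contributes no rows.
#'
#' @param plan An `experiment_plan`.
#' @param config A `generative_config`.
#' @param participant_ids Character vector of participants to run
#'   through this plan.
#' @param seed Integer seed (per-participant streams are derived).
#' @return A response-log data frame, one row per answered trial:
#'   `participant_id`, `version`, `order`, `phase_index`, `task`,
#'   `trial_type`, `trial_index`, `speaker_id`, `speaker_b`,
#'   `snippet_id`, `snippet_b`, `truth`, `response`.
#' @export
simulate_experiment <- function(plan, config, participant_ids, seed = 1L) {
  stopifnot(inherits(plan, "experiment_plan"),
            inherits(config, "generative_config"))
  version <- plan$version
  rec_mu <- config$recognition_means
  rec_sd <- config$recognition_sds
  for (task in c("implicit", "explicit")) {
    if (is.na(rec_mu[paste(version, task, sep = ".")]))
      abort("missing recognition cell parameters for %s.%s", version, task)
  }
  logs <- list()
  for (pi in seq_along(participant_ids)) {
    pid <- participant_ids[pi]
    with_seed(derive_seed(seed, pi), {
      z_p <- stats::rnorm(1)
      for (ph in seq_along(plan$phases)) {
        phase <- plan$phases[[ph]]
        shift <- if (ph == 1) config$order_effect else 0
        # exposure trials (discrimination only; memorization is passive)
        if (phase$task == "implicit") {
          d_disc <- latent_dprime(config$discrimination_means[[version]],
                                  config$discrimination_sds[[version]],
                                  z_p, stats::rnorm(1),
                                  config$participant_share) + shift
          tr <- phase$exposure
          resp <- simulate_trial(tr$truth, d_disc, config$criterion)
          logs[[length(logs) + 1L]] <- data.frame(
            participant_id = pid, version = version, order = plan$order,
            phase_index = ph, task = phase$task,
            trial_type = "discrimination", trial_index = tr$trial,
            speaker_id = tr$speaker_a, speaker_b = tr$speaker_b,
            snippet_id = tr$snippet_a, snippet_b = tr$snippet_b,
            truth = tr$truth,
            response = ifelse(resp, "different", "same"),
            stringsAsFactors = FALSE)
        }
        # recognition trials
        cell <- paste(version, phase$task, sep = ".")
        d_rec <- latent_dprime(rec_mu[[cell]], rec_sd[[cell]],
                               z_p, stats::rnorm(1),
                               config$participant_share) + shift
        if (config$truncate_recognition) d_rec <- max(0, d_rec)
        tr <- phase$recognition
        resp <- simulate_trial(tr$truth, d_rec, config$criterion)
        logs[[length(logs) + 1L]] <- data.frame(
          participant_id = pid, version = version, order = plan$order,
          phase_index = ph, task = phase$task,
          trial_type = "recognition", trial_index = tr$trial,
          speaker_id = tr$speaker, speaker_b = NA_character_,
          snippet_id = tr$snippet, snippet_b = NA_character_,
          truth = tr$truth,
          response = ifelse(resp, "old", "new"),
          stringsAsFactors = FALSE)
      }
    })
  }
  out <- do.call(rbind, logs)
  rownames(out) <- NULL
  out
}

#' Build the default study plans (both versions, both orders)
#'
#' Generates synthetic speakers, runs the similarity-controlled
#' selection, and builds the four counterbalanced plans of the
#' two-version study.
#'
#' @param seed Integer seed.
#' @param n_per_gender Named vector of speakers per gender for each
#'   version; defaults provide enough disjoint pairs (simple: 8 pairs,
#'   challenging: 20 pairs).
#' @return A nested list `plans[[version]][[order]]` plus the
#'   assignments and feature tables, class `study_plans`.
#' @export
build_study_plans <- function(seed = 1L,
                              n_per_gender = c(simple = 10L,
                                               challenging = 22L)) {
  out <- list(plans = list(), assignments = list(), features = list())
  for (version in c("simple", "challenging")) {
    feats <- gen_speakers(n_per_gender[[version]],
                          seed = derive_seed(seed, match(version, c(
                            "simple", "challenging"))))
    pt <- fuse_distance(build_pair_table(feats))
    assignment <- select_pairs(pt, n_pairs_per_task = version_load(version),
                               seed = derive_seed(seed, 100L))
    out$features[[version]] <- feats
    out$assignments[[version]] <- assignment
    out$plans[[version]] <- list(
      IE = build_plan(assignment, version, "IE",
                      seed = derive_seed(seed, 200L)),
      EI = build_plan(assignment, version, "EI",
                      seed = derive_seed(seed, 300L)))
  }
  structure(out, class = "study_plans")
}

#' Simulate the complete two-version study
#'
#' Allocates participants to the two task orders by alternating index
#' (counterbalancing), simulates every participant through their plan,
#' and returns the pooled response log.
#'
#' @param config A `generative_config`.
#' @param seed Integer seed.
#' @param plans Optional `study_plans` (rebuilt from `seed` when
#'   `NULL`); passing prebuilt plans keeps the stimulus side fixed
#'   while varying behaviour across seeds.
#' @return A list: `log` (pooled response log), `plans`, `config`.
#' @export
simulate_study <- function(config = generative_config(), seed = 1L,
                           plans = NULL) {
  if (is.null(plans)) plans <- build_study_plans(seed)
  logs <- list()
  for (version in c("simple", "challenging")) {
    n <- config$n_participants[[version]]
    ids <- sprintf("%s%03d", toupper(substr(version, 1, 1)), seq_len(n))
    ord <- rep(c("IE", "EI"), length.out = n)
    for (o in c("IE", "EI")) {
      sel <- ids[ord == o]
      if (length(sel) == 0) next
      logs[[length(logs) + 1L]] <- simulate_experiment(
        plans$plans[[version]][[o]], config, sel,
        seed = derive_seed(seed, 400L + match(version, c("simple",
                                                         "challenging")) * 10L +
                             match(o, c("IE", "EI"))))
    }
  }
  list(log = do.call(rbind, logs), plans = plans, config = config)
}

#' Write / read a response log as CSV
#' @param log A response-log data frame.
#' @param path CSV path.
#' @export
write_response_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_response_log
#' @export
read_response_log <- function(path) {
  if (!file.exists(path)) abort("input file not found: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
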