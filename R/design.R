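# Counterbalanced two-phase experiment plans.
#
# Each participant group runs two exposure phases (implicit voice
# discrimination and explicit voice memorization, order counterbalanced)
# each followed by an old-new voice recognition test on that phase's
# learned voices plus their similarity-matched impostors. Two versions
# exist: simple (4 voices per task) and challenging (10 voices per
# task). Every sentence snippet is used at most once across a whole
# plan; the snippet pool object enforces this.

#' Create a snippet pool
#'
#' One entry per speaker holding that speaker's unused sentence snippet
#' ids. Draws remove snippets, so threading one pool through all
#' schedule builders guarantees that no snippet is reused anywhere in a
#' plan.
#'
#' @param speaker_ids Character vector of speakers.
#' @param n_sentences Sentences available per speaker (default 256).
#' @return A list of class `snippet_pool`.
#' @export
make_snippet_pool <- function(speaker_ids, n_sentences = 256L) {
  pool <- lapply(speaker_ids, function(sp)
    sprintf("%s_s%03d", sp, seq_len(n_sentences)))
  names(pool) <- speaker_ids
  structure(pool, class = "snippet_pool")
}

# draw k snippets for one speaker; relies on the caller's RNG state
draw_snippets <- function(pool, speaker, k) {
  avail <- pool[[speaker]]
  if (is.null(avail))
    abort("speaker '%s' is not in the snippet pool", speaker)
  if (length(avail) < k)
    abort("snippet pool exhausted for speaker '%s': %d requested, %d left",
          speaker, k, length(avail))
  take <- sample(avail, k)
  pool[[speaker]] <- setdiff(avail, take)
  list(ids = take, pool = pool)
}

#' Build a same-different voice discrimination schedule
#'
#' Each voice appears in `same_per_voice` same-speaker trials (two
#' distinct snippets per trial) and makes `diff_per_voice` appearances
#' in different-speaker trials (one snippet per appearance), for a
#' per-voice total of `2 * same_per_voice + diff_per_voice` distinct
#' snippets (defaults: 12 snippets, 8 trial appearances). Different
#' trials pair voices within the exposure set, balanced by construction;
#' trial order is shuffled under the seed.
#'
#' @param voices Character vector of exposure voices (>= 2 when
#'   different trials are requested).
#' @param pool A `snippet_pool` covering `voices`.
#' @param same_per_voice Same-speaker trials per voice (default 4).
#' @param diff_per_voice Different-trial appearances per voice
#'   (default 4).
#' @param seed Integer seed.
#' @param isi_s Inter-stimulus interval in seconds (metadata only).
#' @return A list with `trials` (data frame: `trial`, `speaker_a`,
#'   `snippet_a`, `speaker_b`, `snippet_b`, `truth`) and the updated
#'   `pool`.
#' @export
build_discrimination <- function(voices, pool, same_per_voice = 4L,
                                 diff_per_voice = 4L, seed = 1L,
                                 isi_s = 1) {
  n <- length(voices)
  if (diff_per_voice > 0 && n < 2)
    abort("different-speaker trials need >= 2 voices")
  if ((n * diff_per_voice) %% 2L != 0L)
    abort("odd total of different-trial appearances (%d x %d); cannot pair",
          n, diff_per_voice)
  with_seed(seed, {
    rows <- list()
    # same-speaker trials
    for (v in voices) {
      for (t in seq_len(same_per_voice)) {
        d <- draw_snippets(pool, v, 2L); pool <- d$pool
        rows[[length(rows) + 1L]] <- data.frame(
          speaker_a = v, snippet_a = d$ids[1],
          speaker_b = v, snippet_b = d$ids[2],
          truth = "same", stringsAsFactors = FALSE)
      }
    }
    # different-speaker trials: shuffle appearance slots, repair any
    # adjacent self-pairings by swapping with a compatible slot
    if (diff_per_voice > 0) {
      slots <- sample(rep(voices, diff_per_voice))
      m <- length(slots) / 2L
      partner <- function(i) ifelse(i %% 2L == 1L, i + 1L, i - 1L)
      for (j in seq_len(m)) {
        a <- 2L * j - 1L
        if (slots[a] != slots[a + 1L]) next
        # swap the second slot with one whose pair stays valid after the swap
        cand <- setdiff(seq_along(slots), c(a, a + 1L))
        cand <- cand[slots[cand] != slots[a] &
                     slots[partner(cand)] != slots[a + 1L]]
        if (length(cand) == 0)
          abort("cannot construct non-self different-trial pairing")
        s <- cand[1]
        tmp <- slots[a + 1L]; slots[a + 1L] <- slots[s]; slots[s] <- tmp
      }
      for (j in seq_len(m)) {
        va <- slots[2L * j - 1L]; vb <- slots[2L * j]
        da <- draw_snippets(pool, va, 1L); pool <- da$pool
        db <- draw_snippets(pool, vb, 1L); pool <- db$pool
        rows[[length(rows) + 1L]] <- data.frame(
          speaker_a = va, snippet_a = da$ids,
          speaker_b = vb, snippet_b = db$ids,
          truth = "different", stringsAsFactors = FALSE)
      }
    }
    trials <- do.call(rbind, rows)
    trials <- trials[sample(nrow(trials)), ]
    trials <- cbind(trial = seq_len(nrow(trials)), trials)
    rownames(trials) <- NULL
  })
  attr(trials, "isi_s") <- isi_s
  list(trials = trials, pool = pool)
}

#' Build an explicit voice memorization schedule
#'
#' One block per voice (block order shuffled under the seed) presenting
#' `snippets_per_voice` distinct snippets of 1.2 s with 0.5-s pauses; a
#' 3-s fixation interval separates consecutive voices. Total per-voice
#' exposure matches the discrimination task's 12 snippets.
#'
#' @param voices Character vector of voices.
#' @param pool A `snippet_pool`.
#' @param snippets_per_voice Snippets per voice (default 12).
#' @param seed Integer seed.
#' @return A list with `presentations` (data frame: `block`, `speaker`,
#'   `position`, `snippet`, `fixation_before_s`) and the updated `pool`.
#' @export
build_memorization <- function(voices, pool, snippets_per_voice = 12L,
                               seed = 1L) {
  stopifnot(length(voices) >= 1)
  with_seed(seed, {
    block_order <- sample(voices)
    rows <- list()
    for (b in seq_along(block_order)) {
      v <- block_order[b]
      d <- draw_snippets(pool, v, snippets_per_voice); pool <- d$pool
      rows[[length(rows) + 1L]] <- data.frame(
        block = b, speaker = v, position = seq_len(snippets_per_voice),
        snippet = d$ids,
        fixation_before_s = ifelse(b > 1 & seq_len(snippets_per_voice) == 1,
                                   3, 0),
        stringsAsFactors = FALSE)
    }
  })
  presentations <- do.call(rbind, rows)
  rownames(presentations) <- NULL
  attr(presentations, "pause_s") <- 0.5
  list(presentations = presentations, pool = pool)
}

#' Build an old-new voice recognition schedule
#'
#' Tests every identity (learned voices plus impostors) in
#' `trials_per_identity` trials; snippets are drawn from the shared
#' pool, so they are automatically disjoint from the snippets used
#' during exposure. Trial order is shuffled under the seed.
#'
#' @param learned Character vector of learned ("old") voices.
#' @param impostors Character vector of impostor ("new") voices,
#'   disjoint from `learned`.
#' @param pool A `snippet_pool`.
#' @param trials_per_identity Trials per identity (default 3).
#' @param seed Integer seed.
#' @return A list with `trials` (data frame: `trial`, `speaker`,
#'   `snippet`, `truth` in `{old, new}`) and the updated `pool`.
#' @export
build_recognition <- function(learned, impostors, pool,
                              trials_per_identity = 3L, seed = 1L) {
  if (length(intersect(learned, impostors)) > 0)
    abort("learned and impostor sets must be disjoint")
  ids <- c(learned, impostors)
  if (length(ids) == 0) {
    trials <- data.frame(trial = integer(0), speaker = character(0),
                         snippet = character(0), truth = character(0),
                         stringsAsFactors = FALSE)
    return(list(trials = trials, pool = pool))
  }
  with_seed(seed, {
    rows <- list()
    for (v in ids) {
      d <- draw_snippets(pool, v, trials_per_identity); pool <- d$pool
      rows[[length(rows) + 1L]] <- data.frame(
        speaker = v, snippet = d$ids,
        truth = if (v %in% learned) "old" else "new",
        stringsAsFactors = FALSE)
    }
    trials <- do.call(rbind, rows)
    trials <- trials[sample(nrow(trials)), ]
    trials <- cbind(trial = seq_len(nrow(trials)), trials)
    rownames(trials) <- NULL
  })
  list(trials = trials, pool = pool)
}

#' Voices per task for an experiment version
#' @param version `"simple"` (4) or `"challenging"` (10).
#' @return Integer voice load.
#' @export
version_load <- function(version = c("simple", "challenging")) {
  c(simple = 4L, challenging = 10L)[[match.arg(version)]]
}

#' Build a full counterbalanced experiment plan
#'
#' Assembles the two-phase plan for one participant group: the
#' requested task order (`"IE"` = implicit exposure first, `"EI"` =
#' explicit first), each exposure followed by an old-new recognition
#' test over that phase's learned voices and their impostors. Voice
#' sets of the two phases are disjoint by construction (they come from
#' different assignment rows); one snippet pool is threaded through all
#' four schedules so no snippet is reused anywhere in the plan.
#'
#' @param assignment A `condition_assignment` from [select_pairs()]
#'   providing at least `version_load(version)` pairs per task.
#' @param version `"simple"` or `"challenging"`.
#' @param order `"IE"` or `"EI"`.
#' @param seed Integer seed; schedule-level seeds are derived from it.
#' @param n_sentences Sentence pool size per speaker (default 256).
#' @return A list of class `experiment_plan`: `version`, `order`,
#'   `seed`, `n_per_task`, and `phases`, a list of two entries each
#'   holding `task`, `exposure` (trials or presentations) and
#'   `recognition`.
#' @export
build_plan <- function(assignment, version = c("simple", "challenging"),
                       order = c("IE", "EI"), seed = 1L,
                       n_sentences = 256L) {
  version <- match.arg(version)
  order <- match.arg(order)
  n_req <- version_load(version)
  tasks_in_order <- if (order == "IE") c("implicit", "explicit")
                    else c("explicit", "implicit")
  pairs <- list()
  for (task in c("implicit", "explicit")) {
    rows <- assignment[assignment$task == task, ]
    if (nrow(rows) < n_req)
      abort("version '%s' needs %d %s pairs but the assignment provides %d",
            version, n_req, task, nrow(rows))
    pairs[[task]] <- rows[seq_len(n_req), ]
  }
  speakers <- unlist(lapply(pairs, function(p) c(p$learned_id, p$impostor_id)))
  if (anyDuplicated(speakers))
    abort("assignment reuses a speaker across pairs")
  pool <- make_snippet_pool(speakers, n_sentences)
  phases <- list()
  for (ph in 1:2) {
    task <- tasks_in_order[ph]
    p <- pairs[[task]]
    if (task == "implicit") {
      ex <- build_discrimination(p$learned_id, pool,
                                 seed = derive_seed(seed, 10L * ph + 1L))
      exposure <- ex$trials
    } else {
      ex <- build_memorization(p$learned_id, pool,
                               seed = derive_seed(seed, 10L * ph + 1L))
      exposure <- ex$presentations
    }
    pool <- ex$pool
    rec <- build_recognition(p$learned_id, p$impostor_id, pool,
                             seed = derive_seed(seed, 10L * ph + 2L))
    pool <- rec$pool
    phases[[ph]] <- list(task = task, exposure = exposure,
                         recognition = rec$trials)
  }
  structure(list(version = version, order = order, seed = seed,
                 n_per_task = n_req, phases = phases),
            class = "experiment_plan")
}

#' Collect every snippet id used in a plan
#' @param plan An `experiment_plan`.
#' @return Character vector of snippet ids (with repeats, if any).
#' @export
plan_snippets <- function(plan) {
  out <- character(0)
  for (ph in plan$phases) {
    ex <- ph$exposure
    if ("snippet_a" %in% colnames(ex)) {
      out <- c(out, ex$snippet_a, ex$snippet_b)
    } else {
      out <- c(out, ex$snippet)
    }
    out <- c(out, ph$recognition$snippet)
  }
  out
}

#' Serialize an experiment plan
#'
#' Writes the plan as JSON and, optionally, its trial lists as flat CSV
#' files (`<stem>_phase<k>_exposure.csv`, `<stem>_phase<k>_recognition.csv`).
#'
#' @param plan An `experiment_plan`.
#' @param json_path Output JSON path (or `NULL`).
#' @param csv_stem Path stem for CSV trial lists (or `NULL`).
#' @return Invisibly, the written paths.
#' @export
write_plan <- function(plan, json_path = NULL, csv_stem = NULL) {
  paths <- character(0)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(version = plan$version, order = plan$order, seed = plan$seed,
           n_per_task = plan$n_per_task,
           phases = lapply(plan$phases, function(ph)
             list(task = ph$task, exposure = ph$exposure,
                  recognition = ph$recognition))),
      json_path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
    paths <- c(paths, json_path)
  }
  if (!is.null(csv_stem)) {
    for (k in seq_along(plan$phases)) {
      pe <- sprintf("%s_phase%d_exposure.csv", csv_stem, k)
      pr <- sprintf("%s_phase%d_recognition.csv", csv_stem, k)
      utils::write.csv(plan$phases[[k]]$exposure, pe, row.names = FALSE)
      utils::write.csv(plan$phases[[k]]$recognition, pr, row.names = FALSE)
      paths <- c(paths, pe, pr)
    }
  }
  invisible(paths)
}
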