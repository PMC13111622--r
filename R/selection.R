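# Similarity-controlled stimulus selection.
#
# The method consolidates recording-level embedding cosine similarities
# into per-speaker-pair averages, augments them with absolute mean-F0
# differences (delta F0), fuses both feature families into a Euclidean
# distance per same-gender speaker pair, ranks pairs by ascending
# distance (rank 1 = most similar), and greedily extracts disjoint pairs
# from the top of the ranked list, assigning them alternately to the
# implicit (discrimination) and explicit (memorization) tasks. Within a
# pair one voice becomes the to-be-learned ("old") voice and the other
# its impostor ("new" voice, test phase only).

cosine_matrix <- function(emb) {
  nrm <- sqrt(rowSums(emb^2))
  if (any(nrm == 0)) abort("zero-length embedding vector encountered")
  tcrossprod(emb / nrm)
}

check_selection_input <- function(features) {
  validate_speaker_features(features)
  spk <- speaker_summary(features)
  for (g in unique(spk$gender)) {
    if (sum(spk$gender == g) < 2)
      abort("gender '%s' has fewer than 2 speakers; no within-gender pairs", g)
  }
  invisible(spk)
}

pair_key <- function(i, k) {
  paste(pmin(i, k), pmax(i, k), sep = "|")
}

#' Consolidate recording-level cosine similarities per speaker pair
#'
#' Computes, for every unordered same-gender speaker pair, the mean
#' cosine similarity over all cross-speaker recording pairs (one
#' recording from each speaker). Cross-gender pairs are not formed.
#'
#' @param features A `speaker_features` data frame.
#' @return A pair table: `data.frame` with columns `speaker_i`,
#'   `speaker_k` (lexicographically ordered within pair), `gender`,
#'   `avg_cosine`.
#' @export
consolidate_similarity <- function(features) {
  spk <- check_selection_input(features)
  ecols <- embedding_cols(features)
  out <- list()
  for (g in unique(spk$gender)) {
    ids <- sort(spk$speaker_id[spk$gender == g])
    sub <- features[features$speaker_id %in% ids, ]
    sim <- cosine_matrix(as.matrix(sub[, ecols]))
    who <- sub$speaker_id
    for (a in seq_along(ids)) {
      for (b in seq_along(ids)) {
        if (b <= a) next
        block <- sim[who == ids[a], who == ids[b], drop = FALSE]
        out[[length(out) + 1L]] <- data.frame(
          speaker_i = ids[a], speaker_k = ids[b], gender = g,
          avg_cosine = mean(block), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Absolute mean-F0 differences per same-gender speaker pair
#'
#' @param features A `speaker_features` data frame.
#' @return A `data.frame` with columns `speaker_i`, `speaker_k`,
#'   `gender`, `delta_f0` (Hz, >= 0).
#' @export
delta_f0_table <- function(features) {
  spk <- check_selection_input(features)
  out <- list()
  for (g in unique(spk$gender)) {
    ids <- sort(spk$speaker_id[spk$gender == g])
    f0 <- spk$mean_f0_hz[match(ids, spk$speaker_id)]
    cmb <- utils::combn(seq_along(ids), 2)
    out[[length(out) + 1L]] <- data.frame(
      speaker_i = ids[cmb[1, ]], speaker_k = ids[cmb[2, ]], gender = g,
      delta_f0 = abs(f0[cmb[1, ]] - f0[cmb[2, ]]), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Build the full pair table (similarity + delta F0)
#'
#' Convenience wrapper joining [consolidate_similarity()] and
#' [delta_f0_table()].
#'
#' @inheritParams consolidate_similarity
#' @return A pair table with `avg_cosine` and `delta_f0` columns.
#' @export
build_pair_table <- function(features) {
  a <- consolidate_similarity(features)
  b <- delta_f0_table(features)
  merge(a, b, by = c("speaker_i", "speaker_k", "gender"), sort = TRUE)
}

# reconstruct a symmetric speaker x speaker matrix (diag NA) from pair rows
pair_matrix <- function(pairs, ids, value_col) {
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  for (r in seq_len(nrow(pairs))) {
    m[pairs$speaker_i[r], pairs$speaker_k[r]] <- pairs[[value_col]][r]
    m[pairs$speaker_k[r], pairs$speaker_i[r]] <- pairs[[value_col]][r]
  }
  m
}

# z-score the off-diagonal entries of each column; zero-variance columns
# are neutralised (set to 0) so they contribute nothing to distances
zscore_columns <- function(m) {
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    ok <- !is.na(v)
    s <- stats::sd(v[ok])
    if (!is.finite(s) || s == 0) {
      m[ok, j] <- 0
    } else {
      m[ok, j] <- (v[ok] - mean(v[ok])) / s
    }
  }
  m
}

#' Fuse similarity and delta F0 into ranked Euclidean distances
#'
#' In the default `row_vector` mode each speaker is represented by a
#' feature row holding its consolidated cosine similarity and its delta
#' F0 to every other same-gender speaker (delta-F0 columns appended to
#' the similarity columns, all features weighted equally), and the
#' distance of a pair \{i,k\} is the Euclidean distance between the two
#' rows. By default the columns referring to i and k themselves are
#' dropped before the norm (`drop_self = TRUE`) so a pair's distance
#' reflects how similarly the two speakers relate to the *rest* of the
#' set, not how similar they are to each other. The alternative
#' `pair_2d` mode scores each pair directly by the Euclidean norm of its
#' 2-vector of dissimilarity offsets `(1 - avg_cosine, delta_f0)`.
#'
#' Ranks are assigned within gender, ascending by distance (rank 1 =
#' most similar); ties are broken by lexicographic speaker-id order.
#'
#' @param pair_table Output of [build_pair_table()].
#' @param mode `"row_vector"` (default) or `"pair_2d"`.
#' @param scaling `"none"` (default; raw equal weighting) or `"zscore"`
#'   (columns standardised first; zero-variance columns contribute 0).
#' @param drop_self In `row_vector` mode, drop the columns referring to
#'   the pair's own members before computing the distance.
#' @return The pair table with `distance` and `rank` columns added.
#' @export
fuse_distance <- function(pair_table,
                          mode = c("row_vector", "pair_2d"),
                          scaling = c("none", "zscore"),
                          drop_self = TRUE) {
  mode <- match.arg(mode)
  scaling <- match.arg(scaling)
  stopifnot(all(c("avg_cosine", "delta_f0") %in% colnames(pair_table)))
  pair_table$distance <- NA_real_
  for (g in unique(pair_table$gender)) {
    rows <- which(pair_table$gender == g)
    pg <- pair_table[rows, ]
    ids <- sort(unique(c(pg$speaker_i, pg$speaker_k)))
    if (mode == "row_vector") {
      if (length(ids) < 3)
        abort("row_vector mode needs >= 3 speakers in gender '%s' (rows are empty after self-column removal)", g)
      cosm <- pair_matrix(pg, ids, "avg_cosine")
      df0m <- pair_matrix(pg, ids, "delta_f0")
      if (!drop_self) { # self-columns retained: self-similarity 1, self-dF0 0
        diag(cosm) <- 1
        diag(df0m) <- 0
      }
      if (scaling == "zscore") {
        cosm <- zscore_columns(cosm)
        df0m <- zscore_columns(df0m)
      }
      d <- numeric(nrow(pg))
      for (r in seq_len(nrow(pg))) {
        i <- pg$speaker_i[r]; k <- pg$speaker_k[r]
        keep <- if (drop_self) setdiff(ids, c(i, k)) else setdiff(ids, c())
        dcos <- cosm[i, keep] - cosm[k, keep]
        ddf0 <- df0m[i, keep] - df0m[k, keep]
        dcos[is.na(dcos)] <- 0 # diagonal cells when drop_self = FALSE
        ddf0[is.na(ddf0)] <- 0
        d[r] <- sqrt(sum(dcos^2) + sum(ddf0^2))
      }
    } else {
      x <- cbind(1 - pg$avg_cosine, pg$delta_f0)
      if (scaling == "zscore") {
        for (j in 1:2) {
          s <- stats::sd(x[, j])
          x[, j] <- if (!is.finite(s) || s == 0) 0 else
            (x[, j] - mean(x[, j])) / s
        }
      }
      d <- sqrt(rowSums(x^2))
    }
    pair_table$distance[rows] <- d
  }
  # within-gender ranks, ascending distance, lexicographic tie-break
  pair_table$rank <- NA_integer_
  for (g in unique(pair_table$gender)) {
    rows <- which(pair_table$gender == g)
    ord <- order(pair_table$distance[rows],
                 pair_table$speaker_i[rows], pair_table$speaker_k[rows])
    pair_table$rank[rows][ord] <- seq_along(rows)
  }
  pair_table
}

#' Select disjoint speaker pairs and assign tasks and roles
#'
#' Scans the ranked pair list from the top (most similar first),
#' accepting a pair only if neither speaker has been used, until
#' `2 * n_pairs_per_task` pairs are accepted. Accepted pairs are
#' assigned alternately to the implicit and explicit task; within each
#' pair the learned (to-be-learned, "old") versus impostor ("new")
#' role is drawn at random under the seed. One learning sentence and one
#' distinct test sentence are drawn per pair, with no sentence id reused
#' anywhere in the assignment.
#'
#' @param pair_table Output of [fuse_distance()] (needs `distance`).
#' @param n_pairs_per_task Number of pairs for each of the two tasks.
#' @param seed Integer seed for role draws and sentence selection.
#' @param n_sentences Size of the sentence pool per speaker (default 256).
#' @return A `data.frame` (class `condition_assignment`) with one row
#'   per selected pair: `selection_order`, `learned_id`, `impostor_id`,
#'   `gender`, `task`, `distance`, `learn_sentence_id`,
#'   `test_sentence_id`.
#' @export
select_pairs <- function(pair_table, n_pairs_per_task, seed = 1L,
                         n_sentences = 256L) {
  stopifnot("distance" %in% colnames(pair_table),
            n_pairs_per_task >= 0)
  n_needed <- 2L * as.integer(n_pairs_per_task)
  empty <- data.frame(selection_order = integer(0),
                      learned_id = character(0), impostor_id = character(0),
                      gender = character(0), task = character(0),
                      distance = numeric(0),
                      learn_sentence_id = integer(0),
                      test_sentence_id = integer(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("condition_assignment", "data.frame")
  if (n_needed == 0L) return(empty)
  if (2L * n_needed > n_sentences)
    abort("sentence pool of %d cannot supply %d unique sentences",
          n_sentences, 2L * n_needed)
  ord <- order(pair_table$distance, pair_table$speaker_i, pair_table$speaker_k)
  ranked <- pair_table[ord, ]
  used <- character(0)
  sel <- integer(0)
  for (r in seq_len(nrow(ranked))) {
    if (length(sel) == n_needed) break
    i <- ranked$speaker_i[r]; k <- ranked$speaker_k[r]
    if (i %in% used || k %in% used) next
    sel <- c(sel, r)
    used <- c(used, i, k)
  }
  if (length(sel) < n_needed)
    abort("insufficient disjoint pairs: needed %d but only %d achievable",
          n_needed, length(sel))
  chosen <- ranked[sel, ]
  with_seed(seed, {
    learned_first <- stats::runif(n_needed) < 0.5
    sentences <- sample.int(n_sentences, 2L * n_needed)
  })
  out <- data.frame(
    selection_order = seq_len(n_needed),
    learned_id = ifelse(learned_first, chosen$speaker_i, chosen$speaker_k),
    impostor_id = ifelse(learned_first, chosen$speaker_k, chosen$speaker_i),
    gender = chosen$gender,
    task = rep(c("implicit", "explicit"), length.out = n_needed),
    distance = chosen$distance,
    learn_sentence_id = sentences[seq_len(n_needed)],
    test_sentence_id = sentences[n_needed + seq_len(n_needed)],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("condition_assignment", "data.frame")
  out
}

#' Write a condition assignment to CSV and JSON
#'
#' @param assignment A `condition_assignment`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, the written paths.
#' @export
write_assignment <- function(assignment, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(assignment, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(as.data.frame(assignment), json_path,
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, json = json_path))
}
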