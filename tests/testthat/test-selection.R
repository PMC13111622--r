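test_that("consolidated cosine similarity matches hand-computed values", {
  # identical embeddings
  f <- make_features(list(
    a = list(gender = "female", f0 = 200, emb = matrix(c(1, 2), 1)),
    b = list(gender = "female", f0 = 210, emb = matrix(c(1, 2), 1))))
  expect_equal(consolidate_similarity(f)$avg_cosine, 1.0)
  # orthogonal
  f <- make_features(list(
    a = list(gender = "female", f0 = 200, emb = matrix(c(1, 0), 1)),
    b = list(gender = "female", f0 = 210, emb = matrix(c(0, 1), 1))))
  expect_equal(consolidate_similarity(f)$avg_cosine, 0.0)
  # multi-recording average: cos((1,0),(1,1)/sqrt2) = cos((0,1),.) = 0.7071
  f <- make_features(list(
    a = list(gender = "female", f0 = 200,
             emb = rbind(c(1, 0), c(0, 1))),
    b = list(gender = "female", f0 = 210,
             emb = matrix(c(1, 1) / sqrt(2), 1))))
  expect_equal(consolidate_similarity(f)$avg_cosine, sqrt(0.5),
               tolerance = 1e-10)
})

test_that("consolidation forms only same-gender pairs and flags bad input", {
  f <- make_features(list(
    a = list(gender = "female", f0 = 200, emb = matrix(c(1, 0), 1)),
    b = list(gender = "female", f0 = 210, emb = matrix(c(0, 1), 1)),
    c = list(gender = "male", f0 = 120, emb = matrix(c(1, 1), 1)),
    d = list(gender = "male", f0 = 110, emb = matrix(c(1, 2), 1))))
  pt <- consolidate_similarity(f)
  expect_equal(nrow(pt), 2) # one female pair, one male pair, no cross
  expect_setequal(pt$gender, c("female", "male"))

  lone <- make_features(list(
    a = list(gender = "female", f0 = 200, emb = matrix(c(1, 0), 1)),
    b = list(gender = "female", f0 = 210, emb = matrix(c(0, 1), 1)),
    c = list(gender = "male", f0 = 120, emb = matrix(c(1, 1), 1))))
  expect_error(consolidate_similarity(lone), "male")

  bad <- make_features(list(
    a = list(gender = "female", f0 = 200, emb = matrix(c(1, 0), 1)),
    b = list(gender = "female", f0 = 210, emb = matrix(c(0, 1), 1))))
  bad$e1[1] <- NA
  expect_error(consolidate_similarity(bad), "numeric and complete")
})

test_that("delta F0 enumerates within-gender absolute differences", {
  f <- make_features(list(
    a = list(gender = "female", f0 = 100, emb = matrix(c(1, 0), 1)),
    b = list(gender = "female", f0 = 110, emb = matrix(c(0, 1), 1)),
    c = list(gender = "female", f0 = 125, emb = matrix(c(1, 1), 1))))
  d <- delta_f0_table(f)
  expect_setequal(d$delta_f0, c(10, 25, 15))
  expect_error(
    speaker_features("a", "female", -5, "r1", matrix(c(1, 0), 1)),
    "non-positive or missing mean F0.*a")
})

test_that("fused distances match the brute-force oracle on small instances", {
  for (trial_seed in 1:8) {
    set.seed(trial_seed)
    n <- sample(3:6, 1)
    f <- random_features(n)
    pt <- fuse_distance(build_pair_table(f))
    ids <- sort(unique(f$speaker_id))
    # oracle matrices from independent double loops
    cosm <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    df0m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    spk <- unique(f[, c("speaker_id", "mean_f0_hz")])
    for (i in ids) for (k in ids) {
      if (i == k) next
      ei <- as.matrix(f[f$speaker_id == i, grep("^e", names(f))])
      ek <- as.matrix(f[f$speaker_id == k, grep("^e", names(f))])
      cosm[i, k] <- oracle_avg_cosine(ei, ek)
      df0m[i, k] <- abs(spk$mean_f0_hz[spk$speaker_id == i] -
                          spk$mean_f0_hz[spk$speaker_id == k])
    }
    for (r in seq_len(nrow(pt))) {
      expect_equal(pt$avg_cosine[r],
                   cosm[pt$speaker_i[r], pt$speaker_k[r]],
                   tolerance = 1e-10)
      expect_equal(pt$distance[r],
                   oracle_row_distance(ids, cosm, df0m,
                                       pt$speaker_i[r], pt$speaker_k[r]),
                   tolerance = 1e-10)
    }
    # ranks are a permutation of 1..n_pairs
    expect_setequal(pt$rank, seq_len(nrow(pt)))
  }
})

test_that("identical features give zero distances and lexicographic ranks", {
  f <- make_features(list(
    a = list(gender = "female", f0 = 200, emb = matrix(c(1, 0, 0), 1)),
    b = list(gender = "female", f0 = 200, emb = matrix(c(1, 0, 0), 1)),
    c = list(gender = "female", f0 = 200, emb = matrix(c(1, 0, 0), 1))))
  pt <- fuse_distance(build_pair_table(f))
  expect_true(all(pt$distance == 0))
  ord <- order(pt$rank)
  expect_equal(paste(pt$speaker_i, pt$speaker_k)[ord],
               c("a b", "a c", "b c"))
})

test_that("z-scored fusion neutralises zero-variance columns", {
  # equal F0 everywhere: all delta-F0 columns are constant zero
  f <- make_features(list(
    a = list(gender = "female", f0 = 200, emb = matrix(c(1, 0, 0), 1)),
    b = list(gender = "female", f0 = 200, emb = matrix(c(0, 1, 0), 1)),
    c = list(gender = "female", f0 = 200, emb = matrix(c(0, 0, 1), 1))))
  raw <- fuse_distance(build_pair_table(f), scaling = "none")
  z <- fuse_distance(build_pair_table(f), scaling = "zscore")
  expect_true(all(is.finite(z$distance)))
  # with one remaining column per family after self-drop, the z-scored
  # cosine column is centred; distances must not be NA or inflated by
  # the constant delta-F0 family
  expect_true(all(z$distance >= 0))
  expect_error(fuse_distance(build_pair_table(f)[1, ], mode = "row_vector"),
               ">= 3 speakers")
})

test_that("pair selection is greedy, disjoint, alternating and seeded", {
  # six speakers with engineered distances: rank order ab, ac, bc, cd,
  # de, ef ... greedy must take ab, then skip ac and bc, then take cd
  mk_pt <- function() {
    pairs <- t(combn(letters[1:6], 2))
    pt <- data.frame(speaker_i = pairs[, 1], speaker_k = pairs[, 2],
                     gender = "female", avg_cosine = 0, delta_f0 = 0,
                     stringsAsFactors = FALSE)
    pt$distance <- 10
    pt$distance[pt$speaker_i == "a" & pt$speaker_k == "b"] <- 1
    pt$distance[pt$speaker_i == "a" & pt$speaker_k == "c"] <- 2
    pt$distance[pt$speaker_i == "b" & pt$speaker_k == "c"] <- 3
    pt$distance[pt$speaker_i == "c" & pt$speaker_k == "d"] <- 4
    pt$distance[pt$speaker_i == "e" & pt$speaker_k == "f"] <- 5
    pt
  }
  sel <- select_pairs(mk_pt(), n_pairs_per_task = 1, seed = 7)
  expect_equal(sort(c(sel$learned_id[1], sel$impostor_id[1])), c("a", "b"))
  expect_equal(sort(c(sel$learned_id[2], sel$impostor_id[2])), c("c", "d"))
  expect_equal(sel$task, c("implicit", "explicit"))

  sel3 <- select_pairs(mk_pt(), n_pairs_per_task = 1, seed = 7)
  expect_identical(sel, sel3) # bit-for-bit reproducible

  # every speaker at most once; sentences globally unique
  all_sp <- c(sel$learned_id, sel$impostor_id)
  expect_equal(anyDuplicated(all_sp), 0L)
  expect_equal(anyDuplicated(c(sel$learn_sentence_id,
                               sel$test_sentence_id)), 0L)

  expect_equal(nrow(select_pairs(mk_pt(), 0)), 0)
  expect_error(select_pairs(mk_pt(), 2), "needed 4 but only 3 achievable")
})

test_that("task counts stay balanced for larger selections", {
  set.seed(42)
  f <- random_features(10)
  pt <- fuse_distance(build_pair_table(f))
  sel <- select_pairs(pt, n_pairs_per_task = 2, seed = 3)
  expect_equal(sum(sel$task == "implicit"), 2)
  expect_equal(sum(sel$task == "explicit"), 2)
  expect_equal(anyDuplicated(c(sel$learned_id, sel$impostor_id)), 0L)
})
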