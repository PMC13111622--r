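voices10 <- sprintf("v%02d", 1:10)
voices4 <- sprintf("v%02d", 1:4)

test_that("challenging discrimination yields 60 trials with the stated per-voice structure", {
  pool <- make_snippet_pool(voices10)
  d <- build_discrimination(voices10, pool, seed = 5)
  tr <- d$trials
  expect_equal(nrow(tr), 60)
  expect_equal(sum(tr$truth == "same"), 40)
  expect_equal(sum(tr$truth == "different"), 20)
  for (v in voices10) {
    appearances <- sum(tr$speaker_a == v | tr$speaker_b == v)
    expect_equal(appearances, 8) # heard 8 times during exposure
    snips <- c(tr$snippet_a[tr$speaker_a == v], tr$snippet_b[tr$speaker_b == v])
    expect_length(unique(snips), 12) # 12 distinct snippets per voice
  }
  expect_equal(anyDuplicated(c(tr$snippet_a, tr$snippet_b)), 0L)
  # different trials never pair a voice with itself
  expect_true(all(tr$speaker_a[tr$truth == "different"] !=
                    tr$speaker_b[tr$truth == "different"]))
  expect_true(all(tr$speaker_a[tr$truth == "same"] ==
                    tr$speaker_b[tr$truth == "same"]))
})

test_that("tiny discrimination instances and error paths behave", {
  pool <- make_snippet_pool(c("a", "b"), n_sentences = 6)
  d <- build_discrimination(c("a", "b"), pool, same_per_voice = 1,
                            diff_per_voice = 1, seed = 2)
  expect_equal(nrow(d$trials), 3) # 2 same + 1 different
  expect_equal(sum(d$trials$truth == "different"), 1)

  expect_error(
    build_discrimination(c("a", "b", "c"), make_snippet_pool(c("a", "b", "c")),
                         diff_per_voice = 1),
    "odd")
  expect_error(
    build_discrimination(c("a", "b"), make_snippet_pool(c("a", "b"),
                                                        n_sentences = 3),
                         seed = 1),
    "exhausted")
})

test_that("memorization presents 12 snippets per voice in seeded blocks", {
  pool <- make_snippet_pool(voices4)
  m <- build_memorization(voices4, pool, seed = 9)
  expect_equal(nrow(m$presentations), 48) # 4 x 12
  expect_equal(as.integer(table(m$presentations$speaker)), rep(12L, 4))
  # one block per voice, 3-s fixation before every block but the first
  expect_equal(sum(m$presentations$fixation_before_s == 3), 3)

  single <- build_memorization("a", make_snippet_pool("a"), seed = 1)
  expect_equal(nrow(single$presentations), 12)
  expect_equal(sum(single$presentations$fixation_before_s), 0)

  m2 <- build_memorization(voices4, pool, seed = 9)
  expect_identical(m$presentations, m2$presentations)
})

test_that("recognition tests every identity three times with fresh snippets", {
  pool <- make_snippet_pool(c(voices4, sprintf("i%02d", 1:4)))
  r <- build_recognition(voices4, sprintf("i%02d", 1:4), pool, seed = 3)
  expect_equal(nrow(r$trials), 24) # (4 + 4) x 3
  expect_equal(as.integer(table(r$trials$truth)), c(12L, 12L))

  pool10 <- make_snippet_pool(c(voices10, sprintf("i%02d", 1:10)))
  r10 <- build_recognition(voices10, sprintf("i%02d", 1:10), pool10, seed = 3)
  expect_equal(nrow(r10$trials), 60)

  empty <- build_recognition(character(0), character(0), pool, seed = 1)
  expect_equal(nrow(empty$trials), 0)
  expect_error(build_recognition(c("a", "b"), c("b"),
                                 make_snippet_pool(c("a", "b"))), "disjoint")
})

make_assignment <- function(n_per_task) {
  n <- 2 * n_per_task
  data.frame(
    selection_order = seq_len(2 * n_per_task * 1L),
    learned_id = sprintf("L%02d", seq_len(n)),
    impostor_id = sprintf("N%02d", seq_len(n)),
    gender = "female",
    task = rep(c("implicit", "explicit"), length.out = n),
    distance = seq_len(n) / 10,
    learn_sentence_id = seq_len(n),
    test_sentence_id = n + seq_len(n),
    stringsAsFactors = FALSE)
}

test_that("plans are counterbalanced with disjoint phases and no snippet reuse", {
  asg <- make_assignment(10)
  ie <- build_plan(asg, "challenging", "IE", seed = 4)
  ei <- build_plan(asg, "challenging", "EI", seed = 4)

  expect_equal(ie$phases[[1]]$task, "implicit")
  expect_true("truth" %in% colnames(ie$phases[[1]]$exposure)) # discrimination
  expect_equal(ie$phases[[2]]$task, "explicit")
  expect_true("block" %in% colnames(ie$phases[[2]]$exposure)) # memorization
  expect_equal(ei$phases[[1]]$task, "explicit")

  # per-phase recognition covers learned + impostors three times each
  expect_equal(nrow(ie$phases[[1]]$recognition), 60)
  expect_equal(nrow(ie$phases[[2]]$recognition), 60)

  # voice sets per task identical across orders, phases swapped
  voices_of <- function(plan, ph) sort(unique(plan$phases[[ph]]$recognition$speaker))
  expect_equal(voices_of(ie, 1), voices_of(ei, 2))
  expect_equal(voices_of(ie, 2), voices_of(ei, 1))
  # disjoint voice sets across phases
  expect_length(intersect(voices_of(ie, 1), voices_of(ie, 2)), 0)

  # conservation: every snippet id used at most once across the plan
  expect_equal(anyDuplicated(plan_snippets(ie)), 0L)

  # determinism under the seed
  ie2 <- build_plan(asg, "challenging", "IE", seed = 4)
  expect_identical(ie, ie2)

  # simple version counts
  sp <- build_plan(make_assignment(4), "simple", "IE", seed = 4)
  expect_equal(nrow(sp$phases[[1]]$recognition), 24)
  expect_equal(nrow(sp$phases[[1]]$exposure), 24) # 16 same + 8 different

  expect_error(build_plan(make_assignment(4), "challenging", "IE"),
               "needs 10")
})

test_that("exposure presentation counts match across implicit and explicit tasks", {
  plan <- build_plan(make_assignment(4), "simple", "IE", seed = 8)
  disc <- plan$phases[[1]]$exposure
  memo <- plan$phases[[2]]$exposure
  disc_snips_per_voice <- sapply(unique(c(disc$speaker_a)), function(v)
    length(unique(c(disc$snippet_a[disc$speaker_a == v],
                    disc$snippet_b[disc$speaker_b == v]))))
  expect_true(all(disc_snips_per_voice == 12))
  expect_true(all(table(memo$speaker) == 12))
})
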