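# Independent brute-force oracles and tiny fixture builders, kept free
# of any package internals so they can disagree with the implementation.

# average cosine similarity between two speakers by explicit double loop
oracle_avg_cosine <- function(emb_a, emb_b) {
  tot <- 0
  for (i in seq_len(nrow(emb_a))) {
    for (j in seq_len(nrow(emb_b))) {
      u <- emb_a[i, ]; v <- emb_b[j, ]
      tot <- tot + sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
    }
  }
  tot / (nrow(emb_a) * nrow(emb_b))
}

# row-vector fused distance for pair {i,k} over explicit feature vectors:
# cosine and delta-F0 entries to every other speaker, self-columns dropped
oracle_row_distance <- function(ids, cosm, df0m, i, k) {
  others <- setdiff(ids, c(i, k))
  vi <- c(cosm[i, others], df0m[i, others])
  vk <- c(cosm[k, others], df0m[k, others])
  sqrt(sum((vi - vk)^2))
}

# build a feature table from a named list: speaker -> list(gender, f0,
# embeddings matrix)
make_features <- function(defs) {
  ids <- names(defs)
  speaker_features(
    speaker_id = unlist(mapply(function(id, s) rep(id, nrow(s$emb)),
                               ids, defs, SIMPLIFY = FALSE)),
    gender = unlist(mapply(function(id, s) rep(s$gender, nrow(s$emb)),
                           ids, defs, SIMPLIFY = FALSE)),
    mean_f0_hz = unlist(mapply(function(id, s) rep(s$f0, nrow(s$emb)),
                               ids, defs, SIMPLIFY = FALSE)),
    recording_id = unlist(mapply(function(id, s)
      paste0(id, "_r", seq_len(nrow(s$emb))), ids, defs, SIMPLIFY = FALSE)),
    embeddings = do.call(rbind, lapply(defs, `[[`, "emb")))
}

# random small instance for property tests
random_features <- function(n_speakers, max_recordings = 3, dim = 4,
                            gender = "female") {
  defs <- list()
  for (s in seq_len(n_speakers)) {
    nr <- sample(max_recordings, 1)
    defs[[sprintf("spk%02d", s)]] <- list(
      gender = gender, f0 = runif(1, 150, 260),
      emb = matrix(rnorm(nr * dim), nr, dim))
  }
  make_features(defs)
}
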