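#!/usr/bin/env Rscript
# Step 1 -- similarity-controlled stimulus selection.
#
# Generates synthetic speaker features (unit-sphere embeddings per
# recording, gender-specific mean F0), consolidates recording-level
# cosine similarities per speaker pair, fuses them with delta F0 into
# ranked Euclidean distances, and greedily extracts disjoint pairs,
# alternating implicit / explicit task assignment. One speaker set per
# experiment version (simple: 4 pairs per task, challenging: 10).

library(voicelearn)

seed <- 20260926L
out_dir <- "results/selection"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

for (version in c("simple", "challenging")) {
  n_gen <- c(simple = 10L, challenging = 22L)[[version]]
  feats <- gen_speakers(n_gen, seed = derive_seed(seed, match(version,
    c("simple", "challenging"))))
  pt <- fuse_distance(build_pair_table(feats))
  asg <- select_pairs(pt, n_pairs_per_task = version_load(version),
                      seed = derive_seed(seed, 100L))
  write_speaker_features(feats,
    file.path(out_dir, sprintf("speakers_%s.csv", version)))
  utils::write.csv(pt, file.path(out_dir, sprintf("pairs_%s.csv", version)),
                   row.names = FALSE)
  write_assignment(asg,
    csv_path = file.path(out_dir, sprintf("assignment_%s.csv", version)),
    json_path = file.path(out_dir, sprintf("assignment_%s.json", version)))
  cat(sprintf(
    "%s version: %d speakers, %d within-gender pairs, %d pairs selected (distance %.3f-%.3f)\n",
    version, length(unique(feats$speaker_id)), nrow(pt), nrow(asg),
    min(asg$distance), max(asg$distance)))
}
cat(sprintf("written under %s\n", out_dir))
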