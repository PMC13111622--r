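#!/usr/bin/env Rscript
# Step 4 -- signal-detection analysis of the simulated cohort.
#
# Per-participant corrected d' for the discrimination (learning) and
# recognition (test) phases, condition descriptives, the soft-ceiling
# chi-square diagnostic, the learning-vs-test Spearman correlation
# (with Shapiro-Wilk gate), per-speaker percent correct, and the
# learned-vs-impostor recognizability comparison (Welch t per pair,
# Bonferroni over the declared family of pairs).

library(voicelearn)

out_dir <- "results/analysis"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
log <- read_response_log("results/study/response_log.csv")

disc <- score_discrimination(log)
rec <- score_recognition(log)
utils::write.csv(disc, file.path(out_dir, "discrimination_scores.csv"),
                 row.names = FALSE)
utils::write.csv(rec, file.path(out_dir, "recognition_scores.csv"),
                 row.names = FALSE)

cat("== Learning phase (discrimination) ==\n")
for (v in c("challenging", "simple")) {
  d <- disc$dprime[disc$version == v]
  cat(sprintf("%s (n=%d, trials=%d): mean d' %.2f (SD %.2f, median %.2f)\n",
              v, length(d), disc$n_signal[disc$version == v][1] +
                disc$n_noise[disc$version == v][1],
              mean(d), sd(d), median(d)))
  ca <- ceiling_analysis(d)
  cat(sprintf("  soft ceiling at d'=%.2f: %d of %d at/above vs %.2f expected, chi2(1)=%.2f, p=%.3f\n",
              ca$threshold, ca$observed, ca$n, ca$expected, ca$chi2, ca$p))
}

cat("\n== Test phase (recognition) descriptives ==\n")
desc <- do.call(rbind, lapply(split(rec, paste(rec$version, rec$task)),
  function(d) data.frame(version = d$version[1], task = d$task[1],
                         n = nrow(d), mean = mean(d$dprime),
                         median = median(d$dprime), sd = sd(d$dprime))))
desc <- desc[order(desc$version, desc$task), ]
print(desc, digits = 3, row.names = FALSE)
utils::write.csv(desc, file.path(out_dir, "recognition_descriptives.csv"),
                 row.names = FALSE)

cat("\n== Learning vs test correlation (implicit phases) ==\n")
for (v in c("simple", "challenging")) {
  dd <- disc[disc$version == v, c("participant_id", "dprime")]
  rr <- rec[rec$version == v & rec$task == "implicit",
            c("participant_id", "dprime")]
  m <- merge(dd, rr, by = "participant_id", suffixes = c("_disc", "_rec"))
  ct <- correlate(m$dprime_disc, m$dprime_rec)
  cat(sprintf("%s: rho = %.3f, p = %.3f (Shapiro p: %.3f / %.3f)\n",
              v, ct$rho, ct$p, ct$shapiro_p_x, ct$shapiro_p_y))
}

cat("\n== Per-speaker percent correct ==\n")
pc <- percent_correct_by_speaker(log)
utils::write.csv(pc, file.path(out_dir, "pc_by_speaker.csv"),
                 row.names = FALSE)
cat(sprintf("%d tested identities; PC range %.1f-%.1f%%\n",
            nrow(pc), min(pc$pc), max(pc$pc)))

cat("\n== Learned vs impostor recognizability (Welch t per pair, Bonferroni) ==\n")
for (v in c("simple", "challenging")) {
  asg <- utils::read.csv(sprintf("results/selection/assignment_%s.csv", v),
                         stringsAsFactors = FALSE)
  asg <- asg[seq_len(2 * version_load(v)), ]
  rows <- log[log$trial_type == "recognition" & log$version == v, ]
  correct_by_part <- function(sp) {
    d <- rows[rows$speaker_id == sp, ]
    tapply(d$response == d$truth, d$participant_id, mean)
  }
  res <- data.frame()
  for (i in seq_len(nrow(asg))) {
    cmp <- compare_groups(correct_by_part(asg$learned_id[i]),
                          correct_by_part(asg$impostor_id[i]))
    res <- rbind(res, data.frame(
      learned = asg$learned_id[i], impostor = asg$impostor_id[i],
      t = cmp$t, df = cmp$df, p_adj = bonferroni(cmp$p, nrow(asg))))
  }
  utils::write.csv(res, file.path(out_dir,
    sprintf("learned_vs_impostor_%s.csv", v)), row.names = FALSE)
  cat(sprintf("%s: %d of %d pairs significant after Bonferroni (alpha .05)\n",
              v, sum(res$p_adj < 0.05), nrow(res)))
}
cat(sprintf("\nwritten under %s\n", out_dir))
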