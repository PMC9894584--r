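#!/usr/bin/env Rscript
# Hippocampal pathway: localizer decoding accuracy (leave-one-out), the
# successor/predecessor classifier-evidence contrast on partial trials, and
# the time-resolved evidence difference with HRF time-to-peak estimation.
# Uses a 20-subject cohort under forward-skew isolation conditions: no
# symmetric localizer coactivation (which cancels the skew at the decoder)
# and a large hippocampal ROI, so the anticipatory component dominates the
# random pattern-geometry overlaps.

suppressPackageStartupMessages(library(srmap))
dir.create("results", showWarnings = FALSE)

n <- 20
truth <- ground_truth(hippocampus_tuning = list(type = "none",
                                                intercept = NULL,
                                                slope = NULL),
                      hippocampus_voxels = 512)
cohort <- make_cohort(n_subjects = n, truth = truth, seed = 20260401)
acc <- numeric(n); succ <- numeric(n); pred <- numeric(n)
tc <- NULL
for (i in seq_len(n)) {
  sim <- realize_subject(cohort, i)
  loc <- realize_localizer(cohort, i)
  blocks <- loc$schedule$blocks[!loc$schedule$blocks$rest, ]
  ts_loc <- preprocess(loc$hippocampus)
  samples <- extract_trial_samples(ts_loc, blocks$onset_s,
                                   rep(1L, nrow(blocks)), blocks$location,
                                   window = c(3, 13.5))
  acc[i] <- loo_cross_validate(samples)
  dec <- analyze_subject_decoding(sim, loc, time_resolved = TRUE)
  succ[i] <- dec$contrast$successor
  pred[i] <- dec$contrast$predecessor
  tc <- if (is.null(tc)) dec$timecourse$diff_evidence
        else tc + dec$timecourse$diff_evidence
}
tc <- tc / n
offsets <- seq(0, 13.5, by = 1.5)

t_acc <- one_sample_t(acc, 1 / 8)
cat(sprintf("Localizer decoding accuracy: %.1f%% +/- %.1f%% (mean +/- sd); vs chance 12.5%%: t(%d) = %.2f, p = %.2g\n",
            100 * mean(acc), 100 * sd(acc), t_acc$df, t_acc$statistic,
            t_acc$p))
t_sp <- paired_t(succ, pred)
cat(sprintf("Evidence contrast: successor %.4f vs predecessor %.4f; paired t(%d) = %.2f, p = %.2g\n",
            mean(succ), mean(pred), t_sp$df, t_sp$statistic, t_sp$p))

peak <- fit_hrf_peak(tc, offsets)
if (peak$no_transient) {
  cat("Time-resolved difference course shows no positive transient.\n")
} else {
  cat(sprintf("Time-resolved successor-minus-predecessor evidence peaks at %.1f s post onset.\n",
              peak$time_to_peak))
}

write.table(data.frame(subject = seq_len(n), loo_accuracy = acc,
                       successor = succ, predecessor = pred),
            "results/hippocampus_decoding.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(offset_s = offsets, diff_evidence = tc),
            "results/evidence_timecourse.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Wrote results/hippocampus_decoding.tsv and results/evidence_timecourse.tsv\n")
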