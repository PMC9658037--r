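#!/usr/bin/env Rscript
# Stage 5 — checks against the published reference tables.
#
# The published yam trial's raw data are not available, but two pieces of
# its arithmetic are reproducible from the printed tables alone:
#  (a) row-wise squared sums of the printed loadings must reproduce the
#      printed communalities and their 77%/23% average;
#  (b) the sign-sense goal classifier applied to the printed per-trait
#      gains must reproduce the printed goal flags (15 desired, 3
#      undesired) and the printed desired-gain totals.

library(faiselect)

ref_l <- reference_loadings()
L <- as.matrix(ref_l[, c("F1", "F2", "F3", "F4", "F5")])
rownames(L) <- ref_l$trait
cm <- communalities(L)
cat(sprintf("stem_number communality: computed %.4f, printed %.2f\n",
            cm$communality[ref_l$trait == "stem_number"], 0.92))
cat(sprintf("tuber_yield communality: computed %.4f, printed %.2f\n",
            cm$communality[ref_l$trait == "tuber_yield"], 0.78))
cat(sprintf("mean communality: computed %.1f%%, printed 77%%\n",
            100 * mean(ref_l$communality)))

ref_g <- reference_gains()
goal <- classify_goal(ref_g$gain_percent, ref_g$sense)
stopifnot(identical(goal, ref_g$goal))
tot <- gain_totals(data.frame(sense = ref_g$sense, goal = goal,
                              gain_percent = ref_g$gain_percent))
cat(sprintf("goal flags reproduced: %d desired / %d undesired\n",
            sum(goal == 100), sum(goal == 0)))
cat(sprintf("total (increase): computed %+.2f, printed +148.91\n",
            tot$total_increase))
cat(sprintf("total (decrease): computed %+.2f, printed -29.26\n",
            tot$total_decrease))

write.csv(data.frame(check = c("communality_stem_number",
                               "communality_tuber_yield",
                               "mean_communality_pct",
                               "total_increase", "total_decrease",
                               "n_desired", "n_undesired"),
                     computed = c(
                       cm$communality[ref_l$trait == "stem_number"],
                       cm$communality[ref_l$trait == "tuber_yield"],
                       100 * mean(ref_l$communality),
                       tot$total_increase, tot$total_decrease,
                       sum(goal == 100), sum(goal == 0)),
                     printed = c(0.92, 0.78, 77, 148.91, -29.26, 15, 3)),
          "results/reference_checks.csv", row.names = FALSE, quote = FALSE)
cat("Wrote reference_checks.csv\n")
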