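#!/usr/bin/env Rscript
# Stage 4 — predicted selection gains.
#
# Computes per-trait gains SG% = (Xs - Xo) * h2 / Xo * 100 from the
# selected set on the BLUP genotypic-value scale, classifies each gain
# against its desired sense (goal 100/0), attributes traits to factors
# by maximum absolute rotated loading, and totals desired gains by sense.

library(faiselect)

traits <- read_trait_specs("results/trait_specs.csv")
bv <- as.matrix(read.csv("results/genotypic_values.csv", row.names = 1))
rank_tab <- read.csv("results/ranking.csv")
selected <- rank_tab$genotype[rank_tab$selected]
diag <- jsonlite::read_json("results/fit_diagnostics.json",
                            simplifyVector = TRUE)
h2 <- vapply(diag, function(x) x$h2, numeric(1))
load_tab <- read.csv("results/loadings.csv")
L <- as.matrix(load_tab[, grep("^F", names(load_tab))])
rownames(L) <- load_tab$trait

gt <- gains_table(bv, selected, h2, traits, loadings = L)

out <- rbind(gt$rows[, c("factor", "trait", "sense", "goal",
                         "gain_percent")],
             data.frame(factor = "", trait = "Total (Increase)",
                        sense = "", goal = NA,
                        gain_percent = gt$total_increase),
             data.frame(factor = "", trait = "Total (Decrease)",
                        sense = "", goal = NA,
                        gain_percent = gt$total_decrease))
write.csv(out, "results/gains.csv", row.names = FALSE, quote = FALSE)

cat(sprintf("%d of %d traits show desired gains (goal = 100)\n",
            sum(gt$rows$goal == 100), nrow(gt$rows)))
cat(sprintf("Total gain, traits desired increased: %+.2f%%\n",
            gt$total_increase))
cat(sprintf("Total gain, traits desired decreased: %+.2f%%\n",
            gt$total_decrease))
cat("Wrote gains.csv\n")
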