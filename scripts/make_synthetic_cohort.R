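#!/usr/bin/env Rscript
## Regenerates the synthetic cohort shipped under inst/extdata/: a
## COMBO-scale stand-in (62 taxa x 98 samples) for demonstrating and
## smoke-testing the full workflow.  Entirely synthetic: a random binary
## tree, DTM counts, and a BMI-like response driven by four two-leaf
## log-contrasts.  Run from the repository root.

library(mbtree)

seed <- 20260920L
n_taxa <- 62L
n_samples <- 98L

tree <- random_tree(n_taxa, seed = seed)
set.seed(seed + 1L)
depths <- pmax(rnbinom(n_samples, size = 5, mu = 10000), 500L)
data <- sample_dtm(tree, list(alpha = 1), depths, seed = seed + 2L)
comp <- attr(data, "true_compositions")

effects <- c(T1 = 1.5, T2 = -1.5, T10 = 1.0, T11 = -1.0,
             T20 = 0.8, T21 = -0.8, T30 = 0.6, T31 = -0.6)
bmi <- 25 + sample_response(comp, effects, noise_sd = 2,
                            model = "log-contrast", seed = seed + 3L)

md <- data.frame(sample = rownames(data$counts),
                 bmi = round(bmi, 2))
counts_df <- data.frame(sample = rownames(data$counts), data$counts,
                        check.names = FALSE)

write.table(counts_df, "inst/extdata/synthetic_combo_counts.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(md, "inst/extdata/synthetic_combo_metadata.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
ape::write.tree(tree, "inst/extdata/synthetic_combo_tree.nwk")
cat("wrote synthetic cohort fixtures\n")
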