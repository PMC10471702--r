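#!/usr/bin/env Rscript
# Stage 3 — cross model validation, true and permuted.
#
# Runs the 20-iteration, 8-fold-outer / 7-fold-inner CMV twice on the
# standardized joined matrix: PLS-DA on the line labels and PLS on the IMF
# phenotype, each with embedded variable selection (VIP >= 0.8 and 95%
# jackknife CI excluding 0), plus one permuted-label run per mode as the
# chance reference. Writes the selection tallies, the pooled
# misclassification tables, the per-model Q2 values, and a stage summary.

suppressPackageStartupMessages(library(metabodiverge))

seed <- if (length(a <- commandArgs(TRUE))) as.integer(a[1]) else 1L

tr <- read.csv("results/transformed.csv", check.names = FALSE)
X <- as.matrix(tr[, -1]); rownames(X) <- tr$sample_id
meta <- read.csv("results/panel/panel_metadata.csv")
meta <- meta[match(rownames(X), meta$sample_id), ]

cc_da <- cmv_config(seed = derive_seed(seed, 4L))
da <- run_cmv(X, meta$line, "discriminant", cc_da)
print(da)

cc_pls <- cmv_config(seed = derive_seed(seed, 5L))
pls <- run_cmv(X, meta$imf, "regression", cc_pls, strata = meta$line)
print(pls)

perm_da <- permutation_cmv(X, meta$line, "discriminant",
                           cmv_config(seed = derive_seed(seed, 6L)))[[1]]
perm_pls <- permutation_cmv(X, meta$imf, "regression",
                            cmv_config(seed = derive_seed(seed, 7L)))[[1]]

tab_true <- misclassification_table(da)
tab_perm <- misclassification_table(perm_da)
message("pooled misclassification, true labels (rows sum to 100):")
print(round(tab_true, 1))
message("pooled misclassification, permuted labels:")
print(round(tab_perm, 1))
message(sprintf("mean test Q2: true %.2f, permuted %.2f; %d of %d PLS models excluded (Q2 < %.1f)",
                mean(pls$q2_distribution), mean(perm_pls$q2_distribution),
                length(pls$excluded_models), pls$n_models,
                cc_pls$q2_exclusion))

write.csv(
  data.frame(metabolite_id = names(da$tally),
             tally_da = as.integer(da$tally),
             tally_pls = as.integer(pls$tally[names(da$tally)])),
  "results/tally.csv", row.names = FALSE
)
write.csv(
  data.frame(model = seq_along(pls$q2_distribution),
             q2_true = pls$q2_distribution,
             q2_permuted = perm_pls$q2_distribution),
  "results/q2_distribution.csv", row.names = FALSE
)
jsonlite::write_json(
  list(n_models = da$n_models,
       consensus_threshold = cc_da$selection_frequency * da$n_models,
       misclassification_true = tab_true,
       misclassification_permuted = tab_perm,
       average_misclassification_true = da$average_misclassification,
       average_misclassification_permuted = perm_da$average_misclassification,
       mean_q2_true = mean(pls$q2_distribution),
       mean_q2_permuted = mean(perm_pls$q2_distribution),
       n_q2_excluded = length(pls$excluded_models)),
  "results/cmv_summary.json", auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
)
message("wrote results/{tally,q2_distribution}.csv and results/cmv_summary.json")
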