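#!/usr/bin/env Rscript

# Step 2: pair automated with retrospectively calculated eGFR and measure
# agreement. The MDRD equation is applied to each patient's currently stored
# demographics and creatinine; both values are stored at tenth precision and
# the conservative whole-number screen flags discordant pairs. Emits the
# pair table, Bland-Altman summary and point cloud, the CKD stage agreement
# matrix, and Cohen's kappa under results/.

suppressPackageStartupMessages(library(egfrdrift))

cohort <- read_cohort("results/cohort/cohort.csv")
excl <- apply_exclusions(cohort)
pairs <- build_pairs(excl$retained)

n <- nrow(pairs)
n_disc <- sum(!pairs$concordant_value)
cat(sprintf("%d pairs; %d (%.2f%%) discordant in value, %d (%.2f%%) in CKD stage\n",
            n, n_disc, 100 * n_disc / n,
            sum(!pairs$concordant_stage), 100 * mean(!pairs$concordant_stage)))

ba <- bland_altman(pairs)
cat(sprintf("Bland-Altman: mean difference %.2f, limits of agreement %.2f to %.2f\n",
            ba$mean_difference, ba$loa_lower, ba$loa_upper))

agree <- stage_agreement(pairs)
kap <- cohen_kappa(agree$matrix)
cat(sprintf("stage agreement %.2f%%; kappa %.2f (%.2f-%.2f)\n",
            agree$percent_agreement, kap$estimate_x100,
            kap$ci_lower_x100, kap$ci_upper_x100))

dir.create("results", showWarnings = FALSE)
write.csv(pairs, "results/pairs.csv", row.names = FALSE)
write.csv(ba$points, "results/bland_altman_points.csv", row.names = FALSE)
write.csv(as.data.frame.matrix(agree$matrix), "results/stage_matrix.csv")
jsonlite::write_json(
  list(n = n, n_discordant_value = n_disc,
       percent_discordant = 100 * n_disc / n,
       bland_altman = ba[c("mean_difference", "sd_difference",
                           "loa_lower", "loa_upper")],
       percent_agreement = agree$percent_agreement,
       kappa = kap[c("estimate_x100", "ci_lower_x100", "ci_upper_x100")]),
  "results/concordance.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote results/pairs.csv, bland_altman_points.csv, stage_matrix.csv, concordance.json\n")
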