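#!/usr/bin/env Rscript
# Lasso biomarker signature of genetic ITH: binary SSM features over the
# candidate panel, tenfold cross-validated fit with entry order, and
# cross-cohort transfer to an independently simulated cohort. Writes
# results/model.json and results/signature_evaluation.tsv.

suppressPackageStartupMessages(library(tumorith))
seed <- as.integer(Sys.getenv("COHORT_SEED", "11"))

mutations <- read_mutations("results/cohort/mutations.tsv", format = "tsv")
panel <- read_gene_panel("results/cohort/panel.txt")
ith <- read_tsv_canonical("results/ith.tsv")

X <- encode_ssm_features(mutations, panel, samples = ith$sample_id)
model <- suppressMessages(fit_lasso_signature(X, ith$shannon, seed = seed))
write_signature_model(model, "results/model.json")
print(model)

train_ev <- evaluate_predictions(ith$shannon, predict_ith(model, X))

# independent cohort from the same planted design, different seed
b2 <- simulate_cohort(cohort_design(n_samples = 100L, seed = seed + 1000L))
ith2 <- suppressWarnings(recover_genetic_ith(b2$mutations, b2$meta,
                                             b2$segments))
X2 <- encode_ssm_features(b2$mutations, panel, samples = ith2$sample_id)
transfer_ev <- transfer_evaluation(model, X2, ith2$shannon)

ev <- rbind(cbind(cohort = "training", train_ev),
            cbind(cohort = "transfer", transfer_ev))
write_tsv_canonical(ev, "results/signature_evaluation.tsv")
message(sprintf("training r = %.3f (R2 = %.3f); transfer r = %.3f",
                train_ev$pearson_r, train_ev$r2, transfer_ev$pearson_r))
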