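#!/usr/bin/env Rscript
# Cohort-level statistics: logistic model of metastatic potential, planted
# cytoband amplification enrichment (relapse vs non-relapse), Spearman
# correlation matrix of the ITH measures and burdens, and the pro/anti
# metastatic cell-ratio stratification. Writes results/glm.tsv,
# results/band_enrichment.tsv, results/correlations.tsv.

suppressPackageStartupMessages(library(tumorith))

segments <- read_segments("results/cohort/segments.tsv", coords = "zero_based")
meta <- read_sample_meta("results/cohort/meta.tsv")
cellfr <- read_cell_fractions("results/cohort/cell_fractions.tsv")
bands <- read_cytobands("results/cohort/cytobands.tsv")
ith <- read_tsv_canonical("results/ith.tsv")
micro <- read_tsv_canonical("results/microenv_ith.tsv")

meta <- meta[match(ith$sample_id, meta$sample_id), ]
micro_all <- micro[micro$index_kind == "microenv_all", ]
covs <- data.frame(
  genetic_ith = ith$shannon,
  microenv_ith = micro_all$shannon[match(ith$sample_id,
                                         micro_all$sample_id)],
  ssm_burden = ith$clonal_ssm + ith$subclonal_ssm,
  cnv_burden = ith$clonal_cnv + ith$subclonal_cnv)

glm_res <- metastasis_glm(covs, meta$relapse)
write_tsv_canonical(as.data.frame(glm_res), "results/glm.tsv")
message("metastatic-potential GLM (log-odds per SD):")
print(as.data.frame(glm_res))

groups <- setNames(ifelse(meta$relapse == 1, "relapse", "no_relapse"),
                   meta$sample_id)
freqs <- cnv_band_frequencies(segments, bands, groups)
enr <- band_enrichment(freqs, "relapse", "no_relapse")
enr <- enr[order(enr$p_uncorrected), ]
write_tsv_canonical(enr, "results/band_enrichment.tsv")
message("top enriched band: ", enr$band_id[1], " (", enr$event[1],
        "), -log10 p = ", round(enr$neg_log10_p[1], 2))

cm <- correlation_matrix(covs)
write_tsv_canonical(data.frame(measure = rownames(cm$rho), cm$rho,
                               check.names = FALSE),
                    "results/correlations.tsv")

pr <- prognostic_ratio(cellfr[ith$sample_id, ])
tab <- table(pr$group, meta$relapse)
message("pro/anti-metastatic cell-ratio groups vs relapse:")
print(tab)
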