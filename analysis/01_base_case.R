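#!/usr/bin/env Rscript
# Base-case analysis of the whole trial population: derive the per-cycle
# transition matrices from the published survival medians, run both arms
# through the half-cycle-corrected cohort model over 5 years, and compare
# discounted costs, QALYs, ICER and NMB.

suppressPackageStartupMessages(library(mbcmarkov))
outdir <- "results/base_case"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

sc <- load_config(system.file("extdata", "whole_group.yaml",
                              package = "mbcmarkov"))

# published-precision transition tables (3 decimals; comparator truncated)
export_matrix_csv(build_matrix(sc$strategies$nc$clinical, "paper_3dp"),
                  file.path(outdir, "transitions_nc_3dp.csv"))
export_matrix_csv(build_matrix(sc$strategies$lc$clinical, "paper_3dp",
                               three_dp = "truncate"),
                  file.path(outdir, "transitions_lc_3dp.csv"))
# full-precision matrices actually used by the cohort engine
for (id in names(sc$strategies))
  export_matrix_csv(build_matrix(sc$strategies[[id]]$clinical),
                    file.path(outdir, sprintf("transitions_%s.csv", id)))
export_parameter_csv(sc, file.path(outdir, "parameters.csv"))

res <- compare_strategies(sc)
print(res)
files <- export_traces_csv(res, outdir)
export_ce_json(res, file.path(outdir, "ce_result.json"))
writeLines(ce_markdown(res), file.path(outdir, "ce_result.md"))
write_manifest(outdir, sc,
               files = c("transitions_nc_3dp.csv", "transitions_lc_3dp.csv",
                         "transitions_nc.csv", "transitions_lc.csv",
                         "parameters.csv", files, "ce_result.json",
                         "ce_result.md"))

cat("\nFindings: the intervention arm gains",
    sprintf("%.3f QALYs", res$increments["delta_qaly"]),
    "over the comparator at an incremental cost of",
    sprintf("$%.2f", res$increments["delta_cost"]),
    sprintf("(ICER %.2f USD/QALY, decision: %s).\n",
            res$icer$icer, res$decision))
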