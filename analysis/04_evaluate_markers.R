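#!/usr/bin/env Rscript

# Stage 4 — per-marker diagnostic scores: sensitivity (fraction of tumor
# samples crossing the tier cut in the published direction), specificity
# (leave-one-out reconstruction over the individual normal libraries) and
# the summary AUC = (Sp + Sn)/2 with its strict > 0.7 "valuable" rule.
# Contradictory published markers are scored in both directions.

library(mirmark)

outdir <- "results/analysis"
indir <- file.path(outdir, "inputs")

catalogue <- load_marker_catalogue(file.path(indir, "catalogue.tsv"))
deep <- read.delim(file.path(indir, "counts_deep.tsv"), check.names = FALSE)
m <- as.matrix(deep[, -1]); rownames(m) <- deep$mirna
ct <- normalize_counts(pool_count_columns(m, sprintf("N%d", 1:6)))
pr <- per_sample_ratios(ct, sprintf("T%d", 1:9), "normal_pool")

# per-normal RPM for the specificity reconstruction (members, not the pool)
normals <- normalize_counts(m[, sprintf("N%d", 1:6)])$rpm

ev <- do.call(rbind, lapply(c("SOFT", "MEDIUM", "STRICT"), function(t)
  evaluate_markers(catalogue, pr, t, normal_abundances = normals)))
write.table(ev, file.path(outdir, "evaluations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

for (t in c("SOFT", "MEDIUM", "STRICT")) {
  sel <- ev$tier == t & !is.na(ev$sn) & ev$sn > 0.7
  cat(sprintf("%-6s tier: %2d marker-directions with Sn > 0.7; %2d valuable (AUC > 0.7)\n",
              t, sum(sel),
              sum(ev$tier == t & !is.na(ev$valuable) & ev$valuable)))
}
cat(sprintf("markers assessed: %d/%d\n",
            sum(ev$assessed[ev$tier == "SOFT" & !duplicated(ev$mirna_id)]),
            nrow(catalogue)))
cat("evaluations written to", file.path(outdir, "evaluations.tsv"), "\n")
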