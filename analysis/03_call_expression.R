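#!/usr/bin/env Rscript

# Stage 3 — the three platform-specific differential-expression callers:
#  * DS: per-tumor-sample ratios against the pooled normal, classified by
#    fold-change voting at the soft (2, 0.5), medium (3, 1/3) and strict
#    (4, 0.25) tiers — run on both the read-derived count table (stage 2)
#    and the deeper count-level simulation (stage 1);
#  * SSH: >= 10 normalised reads across the subtracted pair and a 1.5-fold
#    difference;
#  * MA: Welch test on log2 signals at p < 0.01 plus a 1.5-fold change.

library(mirmark)

outdir <- "results/analysis"
indir <- file.path(outdir, "inputs")
tiers <- c("SOFT", "MEDIUM", "STRICT")
tumor_ids <- sprintf("T%d", 1:9)

# DS from the deep count-level table (the study-design scale)
deep <- read.delim(file.path(indir, "counts_deep.tsv"), check.names = FALSE)
m <- as.matrix(deep[, -1]); rownames(m) <- deep$mirna
ct_deep <- normalize_counts(pool_count_columns(m, sprintf("N%d", 1:6)))
pr_deep <- per_sample_ratios(ct_deep, tumor_ids, "normal_pool")
ds_deep <- do.call(rbind, lapply(tiers, function(t)
  vote_classify(pr_deep, t)))
write.table(ds_deep, file.path(outdir, "calls_ds_deep.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# DS from the read-derived quantification (full raw-read path)
ct_reads <- read_count_table(outdir)
pr_reads <- per_sample_ratios(ct_reads, tumor_ids, "normal_pool")
ds_reads <- vote_classify(pr_reads, "SOFT")
write.table(ds_reads, file.path(outdir, "calls_ds_reads.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

ssh_pairs <- read.delim(file.path(indir, "ssh_pairs.tsv"))
ssh <- ssh_differential(ssh_pairs, min_total = 10, min_fold = 1.5)
write.table(ssh, file.path(outdir, "calls_ssh.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

arr <- read.delim(file.path(indir, "array_signals.tsv"), check.names = FALSE)
sig <- as.matrix(arr[, -1]); rownames(sig) <- arr$mirna
ma <- ma_differential(sig, sprintf("T%d", 1:8), sprintf("N%d", 1:4),
                      p_threshold = 0.01, min_fold = 1.5)
write.table(ma$calls, file.path(outdir, "calls_ma.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

for (t in tiers) {
  tal <- direction_tally(ds_deep$status[ds_deep$tier == t])
  cat(sprintf("DS %-6s tier: %2d up / %2d down / %d mixed / %d neutral\n",
              t, tal["n_up"], tal["n_down"], tal["n_mixed"], tal["n_neutral"]))
}
cat(sprintf("SSH: %d/%d assessable, %s\n", sum(ssh$assessed), nrow(ssh),
            paste(names(table(ssh$status[ssh$assessed])),
                  table(ssh$status[ssh$assessed]), collapse = " ")))
cat(sprintf("MA: %d differential of %d probes\n",
            sum(ma$calls$status != "NEUTRAL"), nrow(ma$calls)))
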