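#!/usr/bin/env Rscript

# Stage 1 — build every synthetic input the study design needs, with known
# ground truth: a 100-miRNA marker panel (20 truly up 4-fold, 20 truly down
# 4-fold, 60 neutral), raw small-RNA read libraries for 9 tumors and 6
# normals (rendered with 3' adapters and 0.5% per-base error), microarray
# signals (8 tumor / 4 normal), SSH subtracted-library read pairs, and a
# marker catalogue whose published directions follow the simulated truth.

library(mirmark)

seed <- 1
outdir <- "results/analysis"
dir.create(file.path(outdir, "inputs", "reads"), recursive = TRUE,
           showWarnings = FALSE)

truth <- generate_truth(n_mirna = 100, frac_up = 0.2, frac_down = 0.2,
                        fold_up = 4, fold_down = 0.25, seed = seed)
write.table(truth, file.path(outdir, "inputs", "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

catalogue <- truth_to_catalogue(truth, seed = seed + 1)
save_marker_catalogue(catalogue, file.path(outdir, "inputs", "catalogue.tsv"))

# read-level libraries at desk scale (2e4 mapped reads per library)
counts <- simulate_count_libraries(truth, n_tumor = 9, n_normal = 6,
                                   depth = 2e4, dispersion = 0.05,
                                   seed = seed + 2)
reference <- generate_reference(rownames(counts), seed = seed + 3)
write_reference_fasta(reference,
                      file.path(outdir, "inputs", "reference.fa"))
adapter <- "TCGTATGCCGTCTTCTGCTTG"
libs <- render_reads(counts, reference, adapter, error_rate = 0.005,
                     seed = seed + 4)
for (lib in libs)
  write_library_fastq(lib, file.path(outdir, "inputs", "reads",
                                     paste0(lib$sample_id, ".fastq")))

# count-level libraries at the full study design scale (1e5 mapped reads)
deep <- simulate_count_libraries(truth, n_tumor = 9, n_normal = 6,
                                 depth = 1e5, dispersion = 0.05,
                                 seed = seed + 5)
write.table(data.frame(mirna = rownames(deep), deep, check.names = FALSE),
            file.path(outdir, "inputs", "counts_deep.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

signals <- simulate_array_signals(truth, n_tumor = 8, n_normal = 4,
                                  log_sd = 0.5, seed = seed + 6)
write.table(data.frame(mirna = rownames(signals), signals,
                       check.names = FALSE),
            file.path(outdir, "inputs", "array_signals.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

ssh <- simulate_ssh_pairs(truth, depth = 1e4, capture_bias = 0.4,
                          seed = seed + 7)
write.table(ssh, file.path(outdir, "inputs", "ssh_pairs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("panel: %d miRNAs (%d up, %d down, %d neutral)\n",
            nrow(truth), sum(truth$true_status == "UP"),
            sum(truth$true_status == "DOWN"),
            sum(truth$true_status == "NEUTRAL")))
cat(sprintf("read libraries: %d (%s reads total)\n", length(libs),
            format(sum(vapply(libs, function(l) length(l$reads), numeric(1))),
                   big.mark = ",")))
cat(sprintf("SSH pairs captured: %d/%d\n", sum(ssh$captured), nrow(ssh)))
cat("inputs written under", file.path(outdir, "inputs"), "\n")
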