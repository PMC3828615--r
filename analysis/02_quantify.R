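#!/usr/bin/env Rscript

# Stage 2 — quantify the raw read libraries: trim the 3' adapter, drop
# reads shorter than 16 nt, collapse to unique sequences, map to the mature
# miRNA reference allowing up to 2 mismatches (ties split fractionally),
# pool the six normal libraries into the common denominator library, and
# normalise every sample to reads per million mapped.

library(mirmark)

outdir <- "results/analysis"
indir <- file.path(outdir, "inputs")
adapter <- "TCGTATGCCGTCTTCTGCTTG"

reference <- read_reference(file.path(indir, "reference.fa"))
fq <- list.files(file.path(indir, "reads"), full.names = TRUE)
ids <- sub("\\.fastq$", "", basename(fq))
libs <- Map(function(f, id)
  read_library(f, sample_id = id,
               condition = if (grepl("^T", id)) "TUMOR" else "NORMAL"),
  fq, ids)

pool <- pool_libraries(libs[grepl("^N", ids)])
counts <- quantify_libraries(c(libs[grepl("^T", ids)], list(pool)),
                             reference, adapter = adapter,
                             min_len = 16, max_mismatch = 2)
write_count_table(counts, outdir)
write.table(counts$stats, file.path(outdir, "quantify_stats.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

st <- counts$stats
cat(sprintf("quantified %d samples; mapped fraction %.1f-%.1f%% (median %.1f%%)\n",
            nrow(st), 100 * min(st$n_mapped / st$n_kept),
            100 * max(st$n_mapped / st$n_kept),
            100 * median(st$n_mapped / st$n_kept)))
cat(sprintf("every RPM column closes to 1e6 (max abs error %.2g)\n",
            max(abs(colSums(counts$rpm) - 1e6))))
cat("count tables written under", outdir, "\n")
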