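#' Read a small-RNA library from FASTA or FASTQ
#'
#' Sequences are returned as plain upper-case character strings; FASTQ
#' qualities are ignored (the pipeline trims by adapter sequence, not
#' quality).
#'
#' @param path FASTA or FASTQ file (format inferred from the extension, or
#'   forced via `format`).
#' @param sample_id Library label; defaults to the file name without
#'   extension.
#' @param condition One of `"TUMOR"`, `"NORMAL"`, `"POOLED_NORMAL"`.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return A `read_library`: list with `sample_id`, `condition` and `reads`
#'   (character vector; may be empty).
#' @export
read_library <- function(path, sample_id = NULL,
                         condition = c("TUMOR", "NORMAL", "POOLED_NORMAL"),
                         format = c("auto", "fasta", "fastq")) {
  condition <- match.arg(condition)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  seqs <- Biostrings::readDNAStringSet(path, format = format)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  new_read_library(sample_id, condition, toupper(as.character(seqs)))
}

new_read_library <- function(sample_id, condition, reads) {
  if (!nzchar(sample_id)) stop("sample_id must be non-empty", call. = FALSE)
  structure(list(sample_id = sample_id, condition = condition,
                 reads = unname(reads)),
            class = "read_library")
}

#' @export
print.read_library <- function(x, ...) {
  cat(sprintf("<read_library> %s (%s): %d reads\n",
              x$sample_id, x$condition, length(x$reads)))
  invisible(x)
}

#' Write a library to FASTQ
#'
#' Constant placeholder qualities are emitted; downstream steps never read
#' them.
#'
#' @param library A `read_library`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_library_fastq <- function(library, path) {
  n <- length(library$reads)
  seqs <- Biostrings::DNAStringSet(library$reads)
  names(seqs) <- sprintf("%s_read%d", library$sample_id, seq_len(max(n, 0)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq")
  invisible(path)
}

#' Read a mature-miRNA reference FASTA
#'
#' Headers are canonicalised with [normalize_mirna_name()]; the first
#' whitespace-separated token of each header is taken as the name (miRBase
#' style).
#'
#' @param path FASTA file of mature miRNA sequences.
#' @return Named character vector of upper-case sequences, names canonical.
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("reference FASTA is empty: ", path, call. = FALSE)
  ids <- normalize_mirna_name(sub("\\s.*$", "", names(seqs)))
  if (anyDuplicated(ids))
    stop("duplicate reference ids after canonicalisation", call. = FALSE)
  setNames(toupper(as.character(seqs)), ids)
}

#' Trim a 3' sequencing adapter
#'
#' Each read is cut at the leftmost exact occurrence of an adapter prefix of
#' length at least `min_overlap`, including prefixes running off the read's
#' 3' end; reads without such an occurrence are returned unchanged. Matching
#' is exact (no mismatches) — the deterministic behaviour the synthetic read
#' generator relies on.
#'
#' @param reads Character vector of reads.
#' @param adapter Adapter sequence (5' end ligated to the read's 3' end).
#' @param min_overlap Minimum matched adapter-prefix length (default 6).
#' @return Character vector of trimmed reads, same length/order.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 6L) {
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 1L || min_overlap > nchar(adapter))
    stop("min_overlap must be between 1 and the adapter length", call. = FALSE)
  if (length(reads) == 0L) return(character(0))
  trim_adapter_cpp(reads, adapter, min_overlap)
}

#' Discard short sequences
#'
#' @param x Character vector of reads, or a `collapsed_reads` object.
#' @param min_len Minimum surviving length in nucleotides (default 16, the
#'   shortest credible mature miRNA fragment).
#' @return Same shape as the input with entries shorter than `min_len`
#'   removed; relative order preserved.
#' @export
filter_short <- function(x, min_len = 16L) {
  if (min_len < 1L) stop("min_len must be >= 1", call. = FALSE)
  if (inherits(x, "collapsed_reads")) {
    keep <- nchar(names(x$entries)) >= min_len
    return(new_collapsed_reads(x$entries[keep]))
  }
  x[nchar(x) >= min_len]
}

new_collapsed_reads <- function(entries) {
  structure(list(entries = entries), class = "collapsed_reads")
}

#' Collapse reads to a non-redundant list
#'
#' @param reads Character vector of (trimmed, filtered) reads.
#' @return A `collapsed_reads` object: `entries` is a named integer vector,
#'   unique sequence -> multiplicity; multiplicities sum to `length(reads)`.
#' @export
collapse_reads <- function(reads) {
  if (length(reads) == 0L)
    return(new_collapsed_reads(setNames(integer(0), character(0))))
  tab <- table(reads)
  new_collapsed_reads(setNames(as.integer(tab), names(tab)))
}

#' @export
print.collapsed_reads <- function(x, ...) {
  cat(sprintf("<collapsed_reads> %d unique sequences, %d reads\n",
              length(x$entries), sum(x$entries)))
  invisible(x)
}

#' Map collapsed reads to a mature-miRNA reference
#'
#' Each unique sequence is assigned to the reference entries at minimal
#' Hamming distance among alignments against every same-length window of
#' each reference sequence (a read longer than a reference never hits it).
#' Hits farther than `max_mismatch` are unmapped; `N` bases never match.
#' When k references tie at the minimal distance the sequence's multiplicity
#' is split equally (1/k each), so read mass is conserved and the result
#' does not depend on reference order.
#'
#' @param collapsed A `collapsed_reads` object.
#' @param reference Named character vector from [read_reference()] (or a
#'   path to a FASTA file).
#' @param max_mismatch Maximum Hamming distance for a hit (default 2).
#' @return List with `counts` (named numeric, per reference id; fractional
#'   for split multi-hits), `unmapped` (named integer vector of unmapped
#'   unique sequences with multiplicities) and `assignments` (data.frame
#'   `sequence`, `mirna_id`, `distance`, `weight` for mapped sequences).
#' @export
map_to_reference <- function(collapsed, reference, max_mismatch = 2L) {
  if (is.character(reference) && length(reference) == 1L && is.null(names(reference)))
    reference <- read_reference(reference)
  if (length(reference) == 0L) stop("reference is empty", call. = FALSE)
  seqs <- names(collapsed$entries)
  counts <- setNames(numeric(length(reference)), names(reference))
  if (length(seqs) == 0L) {
    return(list(counts = counts,
                unmapped = setNames(integer(0), character(0)),
                assignments = data.frame(sequence = character(0),
                                         mirna_id = character(0),
                                         distance = integer(0),
                                         weight = numeric(0))))
  }
  res <- hamming_map_cpp(seqs, unname(reference), as.integer(max_mismatch))
  nhit <- lengths(res$hits)
  mapped <- nhit > 0L
  if (any(mapped)) {
    idx <- unlist(res$hits[mapped], use.names = FALSE)
    w <- rep(collapsed$entries[mapped] / nhit[mapped], nhit[mapped])
    add <- tapply(w, idx, sum)
    counts[as.integer(names(add))] <- counts[as.integer(names(add))] + add
    assignments <- data.frame(
      sequence = rep(seqs[mapped], nhit[mapped]),
      mirna_id = names(reference)[idx],
      distance = rep(res$distance[mapped], nhit[mapped]),
      weight = rep(1 / nhit[mapped], nhit[mapped]),
      stringsAsFactors = FALSE)
  } else {
    assignments <- data.frame(sequence = character(0), mirna_id = character(0),
                              distance = integer(0), weight = numeric(0))
  }
  list(counts = counts,
       unmapped = collapsed$entries[!mapped],
       assignments = assignments)
}

#' Normalise raw counts to reads per million mapped (RPM)
#'
#' @param raw Numeric matrix, miRNA x sample, of raw (possibly fractional)
#'   mapped counts.
#' @param scale Normalisation constant (default `1e6`, i.e. RPM).
#' @return A `count_table`: list with `raw`, `rpm` (both miRNA x sample
#'   matrices), `total_mapped` (named vector) and `degenerate` (logical per
#'   sample, `TRUE` where nothing mapped; such samples are all-zero in
#'   `rpm`). For every non-degenerate sample the RPM column sums to `scale`.
#' @export
normalize_counts <- function(raw, scale = 1e6) {
  raw <- as.matrix(raw)
  if (any(raw < 0)) stop("raw counts must be non-negative", call. = FALSE)
  total <- colSums(raw)
  rpm <- raw
  pos <- total > 0
  rpm[, pos] <- sweep(raw[, pos, drop = FALSE], 2, total[pos], "/") * scale
  rpm[, !pos] <- 0
  structure(list(raw = raw, rpm = rpm, total_mapped = total,
                 degenerate = total == 0),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d miRNAs x %d samples; total mapped: %s\n",
              nrow(x$raw), ncol(x$raw),
              paste(format(x$total_mapped, digits = 4), collapse = ", ")))
  invisible(x)
}

#' Pool normal libraries into one in-silico mixture
#'
#' Mirrors the physical pooling of normal-tissue RNA before sequencing:
#' reads are concatenated, so quantifying the pool equals summing the
#' members' raw counts and then normalising.
#'
#' @param libraries List of `read_library` objects, all condition `NORMAL`.
#' @param sample_id Label for the pool (default `"normal_pool"`).
#' @return A `read_library` with condition `POOLED_NORMAL`.
#' @export
pool_libraries <- function(libraries, sample_id = "normal_pool") {
  if (length(libraries) < 1L) stop("need at least one library", call. = FALSE)
  cond <- vapply(libraries, function(l) l$condition, character(1))
  if (any(cond != "NORMAL"))
    stop("all pooled libraries must have condition NORMAL", call. = FALSE)
  new_read_library(sample_id, "POOLED_NORMAL",
                   unlist(lapply(libraries, `[[`, "reads"), use.names = FALSE))
}

#' Quantify a set of libraries against a miRNA reference
#'
#' Runs the full per-library path — adapter trimming, length filtering,
#' collapsing, mismatch-tolerant mapping, RPM normalisation — and assembles
#' one count table over all samples. Reads hitting the optional spike-in
#' reference are counted separately and excluded from the mapped total used
#' for normalisation.
#'
#' @param libraries List of `read_library` objects.
#' @param reference Named character vector (see [read_reference()]).
#' @param adapter 3' adapter sequence, or `NULL` to skip trimming.
#' @param min_len Minimum read length after trimming (default 16).
#' @param max_mismatch Maximum Hamming distance for a mapping hit (default 2).
#' @param min_overlap Minimum adapter-prefix overlap for trimming (default 6).
#' @param spike_reference Optional named character vector of artificially
#'   introduced (spike-in) sequences used as a fallback sink.
#' @param scale RPM scale (default `1e6`).
#' @return A `count_table` (see [normalize_counts()]) with an extra
#'   `stats` data.frame: per sample, `n_input`, `n_short`, `n_kept`,
#'   `n_mapped`, `n_spike`, `n_unmapped` (read-mass accounting:
#'   `n_short + n_kept = n_input` and `n_mapped + n_spike + n_unmapped =
#'   n_kept`).
#' @export
quantify_libraries <- function(libraries, reference, adapter = NULL,
                               min_len = 16L, max_mismatch = 2L,
                               min_overlap = 6L, spike_reference = NULL,
                               scale = 1e6) {
  ids <- vapply(libraries, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids", call. = FALSE)
  raw <- matrix(0, nrow = length(reference), ncol = length(libraries),
                dimnames = list(names(reference), ids))
  stats <- data.frame(sample_id = ids, n_input = 0L, n_short = 0L,
                      n_kept = 0L, n_mapped = 0, n_spike = 0, n_unmapped = 0)
  for (i in seq_along(libraries)) {
    reads <- libraries[[i]]$reads
    stats$n_input[i] <- length(reads)
    if (!is.null(adapter)) reads <- trim_adapter(reads, adapter, min_overlap)
    kept <- filter_short(reads, min_len)
    stats$n_short[i] <- length(reads) - length(kept)
    stats$n_kept[i] <- length(kept)
    collapsed <- collapse_reads(kept)
    hit <- map_to_reference(collapsed, reference, max_mismatch)
    raw[, i] <- hit$counts
    stats$n_mapped[i] <- sum(hit$counts)
    n_spike <- 0
    if (!is.null(spike_reference) && length(hit$unmapped)) {
      spike <- map_to_reference(new_collapsed_reads(hit$unmapped),
                                spike_reference, max_mismatch)
      n_spike <- sum(spike$counts)
      stats$n_unmapped[i] <- sum(spike$unmapped)
    } else {
      stats$n_unmapped[i] <- sum(hit$unmapped)
    }
    stats$n_spike[i] <- n_spike
  }
  out <- normalize_counts(raw, scale)
  out$stats <- stats
  out
}

#' Write a count table to TSV
#'
#' Two matrices are written side by side in long-friendly wide format: one
#' file for raw counts and one for RPM, rows = miRNA, columns = samples.
#'
#' @param counts A `count_table`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix (default `"counts"`).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_count_table <- function(counts, dir, prefix = "counts") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_raw.tsv", "_rpm.tsv")))
  for (p in seq_along(paths)) {
    m <- if (p == 1) counts$raw else counts$rpm
    df <- data.frame(mirna = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, paths[p], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Read a count table written by [write_count_table()]
#'
#' @param dir Directory containing the files.
#' @param prefix File-name prefix used at write time.
#' @return A `count_table` (degenerate flags recomputed from totals).
#' @export
read_count_table <- function(dir, prefix = "counts") {
  rawdf <- read.delim(file.path(dir, paste0(prefix, "_raw.tsv")),
                      check.names = FALSE, stringsAsFactors = FALSE)
  raw <- as.matrix(rawdf[, -1, drop = FALSE])
  rownames(raw) <- rawdf$mirna
  normalize_counts(raw)
}
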