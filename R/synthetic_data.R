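#' Draw a ground-truth table of miRNA expression states
#'
#' Fixes, per synthetic miRNA, its true differential status in tumor vs
#' normal tissue, the true fold change and the expected baseline abundance
#' (RPM in normal tissue, log-uniform over `abundance_range`). The
#' fractions are converted to exact counts (`round(n * frac)`), so the
#' composition of the truth table is deterministic given the arguments.
#'
#' @param n_mirna Number of miRNAs.
#' @param frac_up,frac_down Fractions of truly up-/down-regulated miRNAs
#'   (their sum must not exceed 1).
#' @param fold_up True tumor/normal fold for UP miRNAs (> 1).
#' @param fold_down True fold for DOWN miRNAs (< 1).
#' @param seed Integer seed; same seed, same table.
#' @param abundance_range Baseline RPM range (default `c(10, 3162)`,
#'   log-uniform: spans low- to high-abundance miRNAs).
#' @param in_catalogue Logical (recycled): whether each miRNA is carried in
#'   the marker catalogue.
#' @return Data.frame: `mirna_id` (`mirsim001`, ...), `true_status`
#'   (`UP`/`DOWN`/`NEUTRAL`), `true_fold` (1 for NEUTRAL),
#'   `base_abundance`, `in_catalogue`.
#' @export
generate_truth <- function(n_mirna, frac_up = 0.2, frac_down = 0.2,
                           fold_up = 4, fold_down = 0.25, seed = 1,
                           abundance_range = c(10, 10^3.5),
                           in_catalogue = TRUE) {
  if (frac_up + frac_down > 1)
    stop("frac_up + frac_down must not exceed 1", call. = FALSE)
  if (fold_up <= 1) stop("fold_up must exceed 1", call. = FALSE)
  if (fold_down >= 1) stop("fold_down must be below 1", call. = FALSE)
  n_up <- round(n_mirna * frac_up)
  n_down <- round(n_mirna * frac_down)
  set.seed(seed)
  status <- sample(rep(c("UP", "DOWN", "NEUTRAL"),
                       c(n_up, n_down, n_mirna - n_up - n_down)))
  fold <- c(UP = fold_up, DOWN = fold_down, NEUTRAL = 1)[status]
  base <- exp(runif(n_mirna, log(abundance_range[1]), log(abundance_range[2])))
  data.frame(mirna_id = sprintf("mirsim%03d", seq_len(n_mirna)),
             true_status = status,
             true_fold = unname(fold),
             base_abundance = base,
             in_catalogue = rep_len(in_catalogue, n_mirna),
             stringsAsFactors = FALSE)
}

#' Simulate raw miRNA count libraries
#'
#' Draws per-sample raw counts from a negative-binomial model: the expected
#' count of miRNA *i* in a library whose panel depth is *d* is
#' `d * a_i / sum(a)` in normal tissue and additionally multiplied by the
#' true fold in tumors; `dispersion` is the NB dispersion (variance
#' `mu + dispersion * mu^2`), with 0 degenerating to Poisson. Normal member
#' libraries are drawn individually so they can be pooled downstream the
#' way physical normal pools are.
#'
#' Real libraries are normalised to the *total* mapped reads, a denominator
#' dominated by the bulk of the small-RNA transcriptome, not by the marker
#' panel under study. The simulator therefore adds one aggregate
#' `background` row carrying the remaining read mass,
#' `depth * (1e6 - sum(base_abundance)) / 1e6`, with no tumor/normal fold.
#' Being the sum of a great many independent features, its biological
#' variation averages out, so it is drawn Poisson. Without this row a
#' panel-only library total would absorb the panel's own fold changes and
#' shift every neutral marker's RPM ratio away from 1 — a compositional
#' artifact the real denominator does not have at marker scale. Set
#' `background = FALSE` for a panel-only matrix.
#'
#' @param truth Truth table from [generate_truth()]; `base_abundance` is
#'   read as RPM of total mapped reads, so the panel must sum to less than
#'   `1e6`.
#' @param n_tumor Number of tumor libraries (default 9).
#' @param n_normal Number of normal member libraries (default 6).
#' @param depth Expected total mapped reads per library (default `1e5`).
#' @param dispersion NB dispersion (default 0.05).
#' @param seed Integer seed.
#' @param background Draw the aggregate non-panel row (default `TRUE`).
#' @return Numeric matrix, miRNA x sample, columns `T1..Tn` then `N1..Nm`;
#'   one extra `background` row when `background = TRUE`.
#' @export
simulate_count_libraries <- function(truth, n_tumor = 9, n_normal = 6,
                                     depth = 1e5, dispersion = 0.05,
                                     seed = 1, background = TRUE) {
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  rel <- truth$base_abundance / 1e6
  if (background && sum(rel) >= 1)
    stop("panel abundances exceed the library: sum(base_abundance) must be < 1e6 RPM",
         call. = FALSE)
  mu_normal <- depth * rel
  mu_tumor <- mu_normal * truth$true_fold
  bg_mu <- depth * max(0, 1 - sum(rel))
  set.seed(seed)
  draw <- function(mu) {
    panel <- if (dispersion == 0) rpois(length(mu), mu)
             else rnbinom(length(mu), size = 1 / dispersion, mu = mu)
    if (background) c(panel, rpois(1, bg_mu)) else panel
  }
  ids <- if (background) c(truth$mirna_id, "background") else truth$mirna_id
  cols <- c(sprintf("T%d", seq_len(n_tumor)), sprintf("N%d", seq_len(n_normal)))
  m <- matrix(0, nrow = length(ids), ncol = length(cols),
              dimnames = list(ids, cols))
  for (j in seq_len(n_tumor)) m[, j] <- draw(mu_tumor)
  for (j in seq_len(n_normal)) m[, n_tumor + j] <- draw(mu_normal)
  m
}

#' Pool normal count columns into one pseudo-library
#'
#' In-silico analogue of pooling normal RNA before sequencing: member
#' counts are summed into a single `normal_pool` column placed after the
#' retained columns.
#'
#' @param counts Raw count matrix from [simulate_count_libraries()].
#' @param normal_ids Column names to pool.
#' @param pool_id Name of the pooled column (default `"normal_pool"`).
#' @return Count matrix with the member columns replaced by the pool.
#' @export
pool_count_columns <- function(counts, normal_ids, pool_id = "normal_pool") {
  missing <- setdiff(normal_ids, colnames(counts))
  if (length(missing))
    stop("unknown normal column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  keep <- counts[, setdiff(colnames(counts), normal_ids), drop = FALSE]
  pool <- rowSums(counts[, normal_ids, drop = FALSE])
  out <- cbind(keep, pool)
  colnames(out)[ncol(out)] <- pool_id
  out
}

#' Generate a synthetic mature-miRNA reference
#'
#' Random 20–23-nt sequences, one per feature; used as both the mapping
#' reference and the template for [render_reads()].
#'
#' @param x Truth table from [generate_truth()], or a character vector of
#'   feature ids (e.g. the row names of a simulated count matrix, so the
#'   aggregate `background` feature gets a sequence too).
#' @param seed Integer seed.
#' @param len_range Mature-sequence length range (default `c(20, 23)`).
#' @return Named character vector of sequences (names = feature ids).
#' @export
generate_reference <- function(x, seed = 1, len_range = c(20, 23)) {
  ids <- if (is.data.frame(x)) x$mirna_id else x
  set.seed(seed)
  lens <- sample(len_range[1]:len_range[2], length(ids), replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  # regenerate any accidental duplicates so ids map one-to-one
  while (anyDuplicated(seqs)) {
    i <- which(duplicated(seqs))
    seqs[i] <- vapply(lens[i], function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
  }
  setNames(seqs, ids)
}

#' Write a reference to FASTA
#'
#' @param reference Named character vector of sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  seqs <- Biostrings::DNAStringSet(reference)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Render count libraries into raw reads
#'
#' Materialises each sample's counts as sequencing reads: for every counted
#' miRNA, `count` copies of its mature sequence with independent per-base
#' substitution errors at `error_rate`, 3'-suffixed with the adapter. With
#' `error_rate = 0`, quantifying the output reproduces the input counts
#' exactly; at small rates the binomial error tail keeps almost every read
#' within the 2-mismatch mapping tolerance.
#'
#' @param counts Integer matrix, miRNA x sample (raw counts).
#' @param reference Named character vector covering every counted miRNA.
#' @param adapter 3' adapter sequence appended to every read.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param seed Integer seed.
#' @param conditions Named character vector mapping sample -> condition;
#'   defaults to `TUMOR` for columns starting with `"T"`, else `NORMAL`.
#' @return Named list of `read_library` objects, one per column.
#' @export
render_reads <- function(counts, reference, adapter, error_rate = 0.01,
                         seed = 1, conditions = NULL) {
  if (error_rate < 0 || error_rate >= 1)
    stop("error_rate must be in [0, 1)", call. = FALSE)
  missing <- setdiff(rownames(counts)[rowSums(counts) > 0], names(reference))
  if (length(missing))
    stop("no reference sequence for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.null(conditions))
    conditions <- setNames(ifelse(grepl("^T", colnames(counts)),
                                  "TUMOR", "NORMAL"), colnames(counts))
  bases <- c("A", "C", "G", "T")
  set.seed(seed)
  out <- list()
  for (s in colnames(counts)) {
    cnt <- counts[, s]
    cnt <- cnt[cnt > 0]
    reads <- rep(unname(reference[names(cnt)]), cnt)
    if (error_rate > 0 && length(reads)) {
      # per-read error count is Binomial(len, rate); only touch reads that
      # drew at least one substitution (equivalent to independent per-base
      # errors, since a base is substituted at most once)
      n_err <- stats::rbinom(length(reads), nchar(reads), error_rate)
      for (i in which(n_err > 0)) {
        b <- strsplit(reads[i], "", fixed = TRUE)[[1]]
        pos <- sample(length(b), n_err[i])
        b[pos] <- vapply(b[pos], function(orig)
          sample(setdiff(bases, orig), 1L), character(1))
        reads[i] <- paste(b, collapse = "")
      }
    }
    if (length(reads)) reads <- paste0(reads, adapter)
    out[[s]] <- new_read_library(s, unname(conditions[s]), reads)
  }
  out
}

#' Simulate microarray signal tables
#'
#' Log-normal intensities: each probe gets a baseline log2 level drawn
#' uniformly over `log2_baseline`, tumors are shifted by `log2(true_fold)`,
#' and every observation carries Gaussian noise with standard deviation
#' `log_sd` on the log2 scale.
#'
#' @param truth Truth table from [generate_truth()].
#' @param n_tumor,n_normal Group sizes (>= 2 each).
#' @param log_sd Noise SD on the log2 scale (default 0.5).
#' @param seed Integer seed.
#' @param log2_baseline Baseline log2-intensity range (default `c(6, 12)`).
#' @return Numeric matrix, probe x sample, columns `T1..` then `N1..`.
#' @export
simulate_array_signals <- function(truth, n_tumor = 8, n_normal = 4,
                                   log_sd = 0.5, seed = 1,
                                   log2_baseline = c(6, 12)) {
  if (log_sd < 0) stop("log_sd must be >= 0", call. = FALSE)
  if (n_tumor < 2 || n_normal < 2)
    stop("need >= 2 samples per group", call. = FALSE)
  set.seed(seed)
  n <- nrow(truth)
  base <- runif(n, log2_baseline[1], log2_baseline[2])
  cols <- c(sprintf("T%d", seq_len(n_tumor)), sprintf("N%d", seq_len(n_normal)))
  m <- matrix(0, nrow = n, ncol = length(cols),
              dimnames = list(truth$mirna_id, cols))
  for (j in seq_len(n_tumor))
    m[, j] <- 2^(base + log2(truth$true_fold) + rnorm(n, 0, log_sd))
  for (j in seq_len(n_normal))
    m[, n_tumor + j] <- 2^(base + rnorm(n, 0, log_sd))
  m
}

#' Simulate subtracted-library (SSH) read pairs
#'
#' Models the poly(A)-dependent capture step that makes SSH miss most
#' mature miRNAs: each miRNA is captured with probability `capture_bias`;
#' captured miRNAs receive Poisson counts proportional to abundance (times
#' the true fold in the tumor-enriched library), uncaptured ones get 0/0
#' and are never assessable.
#'
#' @param truth Truth table from [generate_truth()].
#' @param depth Expected reads per subtracted library (default `1e4`).
#' @param capture_bias Capture probability in `[0, 1]` (default 0.4).
#' @param seed Integer seed.
#' @return Data.frame: `mirna_id`, `sr_bc`, `sr_n`, `captured`.
#' @export
simulate_ssh_pairs <- function(truth, depth = 1e4, capture_bias = 0.4,
                               seed = 1) {
  if (capture_bias < 0 || capture_bias > 1)
    stop("capture_bias must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  n <- nrow(truth)
  captured <- runif(n) < capture_bias
  rel <- truth$base_abundance / sum(truth$base_abundance)
  sr_n <- ifelse(captured, rpois(n, depth * rel), 0)
  sr_bc <- ifelse(captured, rpois(n, depth * rel * truth$true_fold), 0)
  data.frame(mirna_id = truth$mirna_id, sr_bc = sr_bc, sr_n = sr_n,
             captured = captured, stringsAsFactors = FALSE)
}

#' Build a marker catalogue from a truth table
#'
#' Converts the `in_catalogue` miRNAs of a truth table into catalogue rows
#' whose published status equals the true status' direction (NEUTRAL
#' markers are published with a random direction — emulating literature
#' claims the data do not support).
#'
#' @param truth Truth table from [generate_truth()].
#' @param seed Integer seed (for the spurious directions).
#' @return Catalogue data.frame in [load_marker_catalogue()] layout.
#' @export
truth_to_catalogue <- function(truth, seed = 1) {
  set.seed(seed)
  rows <- truth[truth$in_catalogue, , drop = FALSE]
  status <- ifelse(rows$true_status == "NEUTRAL",
                   sample(c("UP", "DOWN"), nrow(rows), replace = TRUE),
                   rows$true_status)
  out <- data.frame(mirna_id = rows$mirna_id,
                    published_status = status,
                    marker_type = "EXPRESSION",
                    pathway_note = "",
                    stringsAsFactors = FALSE)
  out$references <- rep(list("synthetic truth"), nrow(out))
  out[, c("mirna_id", "published_status", "marker_type", "references",
          "pathway_note")]
}
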