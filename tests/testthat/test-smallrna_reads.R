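adapter <- "TCGTATGCCG"

test_that("adapter trimming cuts at the leftmost sufficient prefix match", {
  expect_equal(trim_adapter(paste0("ACGTACGT", "TCGTAT"), adapter, 6),
               "ACGTACGT")                       # prefix runs off the 3' end
  expect_equal(trim_adapter("AAAACCCCGGGG", adapter, 6), "AAAACCCCGGGG")
  expect_equal(trim_adapter(adapter, adapter, 6), "")
  # leftmost occurrence wins
  expect_equal(trim_adapter(paste0("AA", adapter, "CC", adapter), adapter, 6),
               "AA")
  # overlap below min_overlap is ignored
  expect_equal(trim_adapter("AAAATCGTA", adapter, 6), "AAAATCGTA")
  expect_error(trim_adapter("ACGT", adapter, nchar(adapter) + 1),
               "min_overlap")
})

test_that("length filtering keeps >= min_len and preserves order", {
  reads <- c(strrep("A", 15), strrep("C", 16), strrep("G", 22))
  expect_equal(nchar(filter_short(reads)), c(16, 22))
  expect_equal(filter_short(character(0)), character(0))
  expect_equal(filter_short(reads, 10), reads)  # identity when all pass
})

test_that("read collapsing conserves multiplicity", {
  cr <- collapse_reads(c("AAAC", "AAAC", "GGGT"))
  expect_equal(cr$entries[["AAAC"]], 2L)
  expect_equal(cr$entries[["GGGT"]], 1L)
  expect_equal(length(collapse_reads(character(0))$entries), 0L)
  cr2 <- collapse_reads(rep("ACGTACGTACGTACGT", 100))
  expect_equal(unname(cr2$entries), 100L)
  expect_equal(length(cr2$entries), 1L)
})

test_that("mapping assigns minimal-distance hits and splits ties", {
  set.seed(42)
  refs <- vapply(rep(22, 10), random_seq, character(1))
  names(refs) <- sprintf("mir%02d", 1:10)
  # exact read -> full multiplicity at distance 0
  m <- map_to_reference(collapse_reads(rep(refs[[3]], 5)), refs)
  expect_equal(unname(m$counts["mir03"]), 5)
  expect_equal(sum(m$counts), 5)
  # distance-1 tie between two references, multiplicity 4 -> 2 each
  base <- random_seq(22)
  r1 <- base; substr(r1, 5, 5) <- setdiff(c("A","C","G","T"),
                                          substr(base, 5, 5))[1]
  r2 <- base; substr(r2, 9, 9) <- setdiff(c("A","C","G","T"),
                                          substr(base, 9, 9))[1]
  refs2 <- c(refA = r1, refB = r2, refs[1:8])
  cr <- collapse_reads(rep(base, 4))
  ora <- oracle_map_one(base, unname(refs2))
  expect_equal(ora$hits, 1:2)          # oracle confirms the two-way tie
  expect_equal(ora$distance, 1L)
  m2 <- map_to_reference(cr, refs2)
  expect_equal(unname(m2$counts[c("refA", "refB")]), c(2, 2))
  # distance > max_mismatch everywhere -> unmapped
  far <- strrep("AGTC", 6)
  stopifnot(is.na(oracle_map_one(far, unname(refs))$distance))
  m3 <- map_to_reference(collapse_reads(rep(far, 3)), refs)
  expect_equal(sum(m3$counts), 0)
  expect_equal(unname(m3$unmapped), 3L)
  expect_error(map_to_reference(cr, character(0)), "empty")
})

test_that("mapping agrees with the exhaustive Hamming oracle on random instances", {
  set.seed(7)
  refs <- vapply(sample(20:24, 50, replace = TRUE), random_seq, character(1))
  names(refs) <- sprintf("m%02d", 1:50)
  reads <- character(200)
  for (i in 1:200) {
    if (i %% 2 == 0) {           # reads derived from a reference, mutated
      ref <- sample(refs, 1)
      len <- sample(16:min(25, nchar(ref)), 1)
      start <- sample(seq_len(nchar(ref) - len + 1), 1)
      rd <- substr(ref, start, start + len - 1)
      nmut <- sample(0:3, 1)
      for (k in seq_len(nmut)) {
        pos <- sample(len, 1)
        substr(rd, pos, pos) <- sample(c("A", "C", "G", "T", "N"), 1)
      }
      reads[i] <- rd
    } else {
      reads[i] <- random_seq(sample(16:25, 1))
    }
  }
  cr <- collapse_reads(reads)
  m <- map_to_reference(cr, refs, max_mismatch = 2)
  asg <- split(m$assignments, m$assignments$sequence)
  for (s in names(cr$entries)) {
    ora <- oracle_map_one(s, unname(refs), 2)
    if (length(ora$hits) == 0) {
      expect_true(s %in% names(m$unmapped))
    } else {
      a <- asg[[s]]
      expect_equal(sort(match(a$mirna_id, names(refs))), ora$hits)
      expect_equal(unique(a$distance), ora$distance)
    }
  }
  # read mass conserved between counts and unmapped
  expect_equal(sum(m$counts) + sum(m$unmapped), length(reads))
})

test_that("N bases never match, even against N", {
  refs <- c(ra = "ACGTACGTACGTACGTACGT")
  rdN <- "ACGTACGTACGTACGTACGN"
  m <- map_to_reference(collapse_reads(rdN), refs, max_mismatch = 2)
  expect_equal(m$assignments$distance, 1L)
  expect_equal(oracle_map_one(rdN, unname(refs))$distance, 1L)
})

test_that("RPM normalisation sums to scale and flags degenerate samples", {
  raw <- cbind(s1 = c(a = 5, b = 15), s2 = c(a = 0, b = 0))
  ct <- normalize_counts(raw)
  expect_equal(unname(ct$rpm[, "s1"]), c(250000, 750000))
  expect_true(ct$degenerate[["s2"]])
  expect_equal(unname(ct$rpm[, "s2"]), c(0, 0))
  raw2 <- matrix(c(7, 0), dimnames = list(c("a", "b"), "s"))
  expect_equal(normalize_counts(raw2)$rpm[1, 1], 1e6)  # single miRNA takes all
  expect_error(normalize_counts(cbind(s = c(-1, 2))), "non-negative")
})

test_that("trim -> filter -> collapse conserves read mass", {
  set.seed(11)
  mature <- vapply(sample(18:23, 30, replace = TRUE), random_seq, character(1))
  reads <- paste0(sample(mature, 500, replace = TRUE), adapter)
  # truncate a third of the reads to below 16 nt after trimming
  short <- sample(500, 150)
  reads[short] <- paste0(substr(reads[short], 1, 10), adapter)
  trimmed <- trim_adapter(reads, adapter, 6)
  kept <- filter_short(trimmed, 16)
  cr <- collapse_reads(kept)
  discarded <- length(trimmed) - length(kept)
  expect_equal(sum(cr$entries) + discarded, length(reads))
  expect_true(all(nchar(names(cr$entries)) >= 16))
})

test_that("pooling then mapping equals mapping then summing raw counts", {
  set.seed(5)
  refs <- vapply(rep(22, 10), random_seq, character(1))
  names(refs) <- sprintf("p%02d", 1:10)
  lib <- function(id, n) {
    reads <- paste0(sample(refs, n, replace = TRUE), adapter)
    mirmark:::new_read_library(id, "NORMAL", reads)
  }
  libs <- list(lib("n1", 25), lib("n2", 25))
  pool <- pool_libraries(libs)
  expect_equal(length(pool$reads), 50)
  expect_equal(pool$condition, "POOLED_NORMAL")
  ct_pool <- quantify_libraries(list(pool), refs, adapter = adapter)
  ct_members <- quantify_libraries(libs, refs, adapter = adapter)
  expect_equal(unname(ct_pool$raw[, 1]), unname(rowSums(ct_members$raw)))
  expect_error(pool_libraries(list(mirmark:::new_read_library("t", "TUMOR", "ACGT"))),
               "NORMAL")
  one <- pool_libraries(libs[1])
  expect_equal(one$reads, libs[[1]]$reads)
})

test_that("FASTQ/FASTA round-trips preserve reads, and quantification accounts for every read", {
  set.seed(3)
  refs <- setNames(vapply(rep(21, 5), random_seq, character(1)),
                   sprintf("q%d", 1:5))
  reads <- paste0(sample(refs, 40, replace = TRUE), adapter)
  lib <- mirmark:::new_read_library("s1", "TUMOR", reads)
  fq <- tempfile(fileext = ".fastq")
  write_library_fastq(lib, fq)
  back <- read_library(fq, condition = "TUMOR")
  expect_equal(back$reads, lib$reads)
  fa <- tempfile(fileext = ".fa")
  write_reference_fasta(refs, fa)
  expect_equal(read_reference(fa), refs)
  ct <- quantify_libraries(list(back), refs, adapter = adapter)
  st <- ct$stats
  expect_equal(st$n_short + st$n_kept, st$n_input)
  expect_equal(st$n_mapped + st$n_spike + st$n_unmapped, st$n_kept)
  expect_equal(sum(ct$rpm[, 1]), 1e6, tolerance = 1e-9)
})

test_that("count tables survive a TSV round-trip", {
  raw <- matrix(c(5, 15, 2.5, 0, 3, 7), nrow = 3,
                dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  ct <- normalize_counts(raw)
  d <- tempfile()
  write_count_table(ct, d)
  ct2 <- read_count_table(d)
  expect_equal(ct2$raw, ct$raw)
  expect_equal(ct2$rpm, ct$rpm)
})
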