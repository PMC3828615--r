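# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Hamming distance between two equal-length strings; N never matches.
oracle_hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  sum(av != bv | av == "N" | bv == "N")
}

# Exhaustive scan of every same-length window of every reference.
# Returns list(hits = sorted integer indices at the minimal distance
# (<= max_mismatch), distance = that distance or NA).
oracle_map_one <- function(read, refs, max_mismatch = 2) {
  best <- Inf
  hits <- integer(0)
  for (j in seq_along(refs)) {
    rl <- nchar(read); fl <- nchar(refs[j])
    if (rl > fl) next
    dj <- Inf
    for (off in 0:(fl - rl))
      dj <- min(dj, oracle_hamming(read, substr(refs[j], off + 1, off + rl)))
    if (dj < best) { best <- dj; hits <- j }
    else if (dj == best && is.finite(dj)) hits <- c(hits, j)
  }
  if (best > max_mismatch) list(hits = integer(0), distance = NA_integer_)
  else list(hits = sort(hits), distance = as.integer(best))
}

# Direct vote enumeration for one ratio vector at explicit cuts.
oracle_votes <- function(ratios, up_cut, down_cut) {
  r <- ratios[!is.na(ratios)]
  up <- sum(r > up_cut)
  down <- sum(r < down_cut)
  status <- if (up > down) "UP" else if (down > up) "DOWN"
    else if (up > 0) "MIXED" else "NEUTRAL"
  list(up = up, down = down, neutral = length(r) - up - down, status = status)
}

random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")

# Tiny catalogue TSV on disk for marker_db tests.
write_catalogue_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("name\tstatus\ttype\treferences\tnote", rows), path)
  path
}
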