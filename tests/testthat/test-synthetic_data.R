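test_that("truth tables have exact composition and are seed-deterministic", {
  tr <- generate_truth(100, 0.2, 0.2, 4, 0.25, seed = 1)
  expect_equal(as.vector(table(tr$true_status)[c("UP", "DOWN", "NEUTRAL")]),
               c(20L, 20L, 60L))
  expect_true(all(tr$true_fold[tr$true_status == "UP"] > 1))
  expect_true(all(tr$true_fold[tr$true_status == "DOWN"] < 1))
  expect_true(all(tr$true_fold[tr$true_status == "NEUTRAL"] == 1))
  expect_identical(tr, generate_truth(100, 0.2, 0.2, 4, 0.25, seed = 1))
  expect_false(identical(tr, generate_truth(100, 0.2, 0.2, 4, 0.25, seed = 2)))
  expect_error(generate_truth(10, 0.6, 0.6), "exceed 1")
  expect_error(generate_truth(10, fold_up = 0.5), "fold_up")
  expect_error(generate_truth(10, fold_down = 2), "fold_down")
})

test_that("count simulation hits its negative-binomial means", {
  # one miRNA at relative abundance 1e-3 (1000 RPM), Poisson regime
  tr <- generate_truth(2, 0, 0, seed = 3)
  tr$base_abundance <- c(1000, 99000)
  reps <- vapply(1:200, function(s)
    simulate_count_libraries(tr, n_tumor = 0, n_normal = 1, depth = 1e6,
                             dispersion = 0, seed = 100 + s)["mirsim001", 1],
    numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - 1000), 3 * se + 1e-9)
  # expected tumor/normal ratio equals the true fold
  tr2 <- data.frame(mirna_id = c("u", "n"), true_status = c("UP", "NEUTRAL"),
                    true_fold = c(4, 1), base_abundance = c(20000, 20000),
                    in_catalogue = TRUE)
  m <- simulate_count_libraries(tr2, n_tumor = 200, n_normal = 200,
                                depth = 1e4, dispersion = 0, seed = 9)
  tum <- rowMeans(m[, grepl("^T", colnames(m))])
  nor <- rowMeans(m[, grepl("^N", colnames(m))])
  expect_equal(unname(tum["u"] / nor["u"]), 4, tolerance = 0.05)
  expect_equal(unname(tum["n"] / nor["n"]), 1, tolerance = 0.05)
  # the aggregate background row completes the library to its mapped total
  expect_true("background" %in% rownames(m))
  expect_equal(mean(colSums(m)), 1e4, tolerance = 0.05)
  m2 <- simulate_count_libraries(tr2, 2, 2, 1e4, 0, seed = 9,
                                 background = FALSE)
  expect_false("background" %in% rownames(m2))
})

test_that("pooling count columns sums members into one denominator library", {
  tr <- generate_truth(20, seed = 4)
  m <- simulate_count_libraries(tr, n_tumor = 2, n_normal = 3, depth = 1e4,
                                seed = 4)
  pooled <- pool_count_columns(m, c("N1", "N2", "N3"))
  expect_equal(colnames(pooled), c("T1", "T2", "normal_pool"))
  expect_equal(unname(pooled[, "normal_pool"]),
               unname(rowSums(m[, c("N1", "N2", "N3")])))
  expect_error(pool_count_columns(m, "N9"), "unknown normal")
})

test_that("error-free rendered reads quantify back to the input counts exactly", {
  tr <- generate_truth(20, seed = 5)
  counts <- simulate_count_libraries(tr, n_tumor = 2, n_normal = 1,
                                     depth = 4000, seed = 5)
  ref <- generate_reference(rownames(counts), seed = 5)
  adapter <- "TCGTATGCCGTCTTCTGCTTG"
  libs <- render_reads(counts, ref, adapter, error_rate = 0, seed = 5)
  expect_gte(sum(counts), 1e4 - 2000)   # a ~10^4-read round-trip fixture
  ct <- quantify_libraries(libs, ref, adapter = adapter)
  expect_equal(ct$raw[rownames(counts), colnames(counts)],
               counts + 0.0)
  # adapter present on every read: mean trimmed length = mature length
  lens <- nchar(trim_adapter(libs$T1$reads, adapter, 6))
  tab <- counts[, "T1"]
  expect_equal(mean(lens),
               sum(nchar(ref[names(tab)]) * tab) / sum(tab))
})

test_that("low error rates keep almost every read mappable within 2 mismatches", {
  tr <- generate_truth(20, seed = 6, abundance_range = c(100, 100))
  ref <- generate_reference(tr, seed = 6)
  counts <- matrix(100L, nrow = 20, ncol = 1,
                   dimnames = list(tr$mirna_id, "T1"))
  libs <- render_reads(counts, ref, adapter = "TCGTATGCCG",
                       error_rate = 0.01, seed = 6)
  ct <- quantify_libraries(libs, ref, adapter = "TCGTATGCCG")
  mapped_fraction <- ct$stats$n_mapped / ct$stats$n_kept
  # binomial tail: P(> 2 errors in ~22 nt at 1%) ~ 1.3e-3
  expect_gt(mapped_fraction, 0.99)
})

test_that("array signal simulation is log-normal around the designed folds", {
  tr <- generate_truth(10, 0.5, 0, fold_up = 2, seed = 7)
  noiseless <- simulate_array_signals(tr, n_tumor = 2, n_normal = 2,
                                      log_sd = 0, seed = 7)
  ratio <- rowMeans(noiseless[, 1:2]) / rowMeans(noiseless[, 3:4])
  expect_equal(unname(ratio), tr$true_fold, tolerance = 1e-12)
  expect_identical(noiseless,
                   simulate_array_signals(tr, n_tumor = 2, n_normal = 2,
                                          log_sd = 0, seed = 7))
  expect_error(simulate_array_signals(tr, n_tumor = 1, n_normal = 4),
               ">= 2")
})

test_that("SSH capture bias controls the assessable fraction", {
  tr <- generate_truth(100, seed = 8, abundance_range = c(1000, 1000))
  all_in <- simulate_ssh_pairs(tr, depth = 1e5, capture_bias = 1, seed = 8)
  calls <- ssh_differential(all_in)
  # noise-free-ish regime: every captured & assessable marker recovers truth
  joined <- merge(calls, tr, by = "mirna_id")
  ok <- joined$assessed
  expect_true(all(joined$status[ok] == joined$true_status[ok] |
                    joined$true_status[ok] == "NEUTRAL"))
  none <- simulate_ssh_pairs(tr, depth = 1e5, capture_bias = 0, seed = 8)
  expect_true(all(none$sr_bc == 0 & none$sr_n == 0))
  expect_equal(sum(ssh_differential(none)$assessed), 0L)
  # capture_bias 0.4 on 100 markers: seed-fixed realised count near 40
  some <- simulate_ssh_pairs(tr, depth = 1e5, capture_bias = 0.4, seed = 8)
  expect_equal(sum(some$captured), 43L)  # exact Binomial(100, 0.4) draw under this seed
  expect_lt(abs(sum(some$captured) - 40), 3 * sqrt(100 * 0.4 * 0.6))
  expect_identical(some,
                   simulate_ssh_pairs(tr, depth = 1e5, capture_bias = 0.4,
                                      seed = 8))
})

ds_truth_run <- function(depth, dispersion, seed) {
  tr <- generate_truth(100, 0.2, 0.2, fold_up = 4, fold_down = 0.25,
                       seed = seed)
  raw <- simulate_count_libraries(tr, n_tumor = 9, n_normal = 6,
                                  depth = depth, dispersion = dispersion,
                                  seed = seed)
  ct <- normalize_counts(pool_count_columns(raw, sprintf("N%d", 1:6)))
  pr <- per_sample_ratios(ct, sprintf("T%d", 1:9), "normal_pool")
  joined <- merge(vote_classify(pr, "SOFT"), tr, by = "mirna_id")
  directional <- joined$true_status != "NEUTRAL"
  list(recovery = mean(!is.na(joined$status[directional]) &
                         joined$status[directional] ==
                           joined$true_status[directional]),
       false_dir = mean(!is.na(joined$status[!directional]) &
                          joined$status[!directional] %in% c("UP", "DOWN")))
}

test_that("the DS pipeline recovers true directions at the soft tier", {
  res <- ds_truth_run(depth = 1e5, dispersion = 0.05, seed = 11)
  expect_gte(res$recovery, 0.9)
})

test_that("neutral false-directional calls vanish as counting noise does", {
  # the zero-margin voting rule false-calls neutral markers whenever one
  # sample crosses a cut; that rate is driven by counting + biological
  # noise, so it must shrink with depth and vanish without dispersion
  shallow <- ds_truth_run(depth = 1e5, dispersion = 0.05, seed = 11)
  deep <- ds_truth_run(depth = 5e6, dispersion = 0.05, seed = 11)
  expect_lt(deep$false_dir, shallow$false_dir)
  clean <- ds_truth_run(depth = 5e6, dispersion = 0, seed = 11)
  expect_lte(clean$false_dir, 0.05)
  expect_gte(clean$recovery, 0.99)
})
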