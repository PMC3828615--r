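#' Default run configuration
#'
#' Assembles the configuration for [run_pipeline()]. Calling thresholds
#' default to the study's stated values: 16-nt minimum read length, up to 2
#' mapping mismatches, voting tiers (2, 0.5) / (3, 1/3) / (4, 0.25),
#' microarray p < 0.01 with a 1.5-fold change, and an SSH evidence floor of
#' 10 reads. The `"study"` preset emulates the study design — 9 tumor
#' libraries of expected depth 1e5 against a pool of 6 normals, NB
#' dispersion 0.05, true folds 4 and 0.25, 8 vs 4 array samples — at the
#' count level; the `"smoke"` preset is a small everything-from-raw-reads
#' run (30 miRNAs, depth 5000) that exercises trimming, mapping and
#' quantification too.
#'
#' @param preset `"study"` or `"smoke"`.
#' @param seed Integer seed for all stochastic steps.
#' @param outdir Output directory.
#' @param ... Named overrides for any top-level config entry.
#' @return Nested list: `simulate`, `params`, `seed`, `outdir`, `use_reads`.
#' @export
run_config <- function(preset = c("study", "smoke"), seed = 1,
                       outdir = tempfile("mirmark_run"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    preset = preset,
    seed = as.integer(seed),
    outdir = outdir,
    use_reads = preset == "smoke",
    simulate = list(
      n_mirna = if (preset == "smoke") 30 else 100,
      frac_up = 0.2, frac_down = 0.2, fold_up = 4, fold_down = 0.25,
      n_tumor = 9, n_normal = 6,
      depth = if (preset == "smoke") 5000 else 1e5,
      dispersion = 0.05,
      adapter = "TCGTATGCCGTCTTCTGCTTG",
      error_rate = 0.005,
      array_n_tumor = 8, array_n_normal = 4, array_log_sd = 0.5,
      ssh_depth = 1e4, ssh_capture_bias = 0.4),
    params = list(
      min_len = 16L, max_mismatch = 2L, min_overlap = 6L,
      tiers = c("SOFT", "MEDIUM", "STRICT"),
      p_threshold = 0.01, min_fold = 1.5, min_total = 10,
      ssh_total_mode = "sum"))
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm %in% c("simulate", "params")) cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  cfg
}

#' Run the full marker-validation pipeline on synthetic inputs
#'
#' Simulates every platform's input with known truth (per the config),
#' quantifies, calls differential expression with all three procedures,
#' scores the markers and assembles the concordance report. All outputs are
#' plain TSV/JSON under `config$outdir`; a `manifest.json` echoing the full
#' configuration makes the run exactly reproducible.
#'
#' @param config Configuration list from [run_config()].
#' @return Invisibly, a list with the in-memory results: `truth`,
#'   `catalogue`, `counts`, `profiles`, `calls` (per method/tier),
#'   `evaluations`, `report`, `outdir`.
#' @export
run_pipeline <- function(config = run_config()) {
  sim <- config$simulate
  prm <- config$params
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  truth <- generate_truth(sim$n_mirna, sim$frac_up, sim$frac_down,
                          sim$fold_up, sim$fold_down, seed = config$seed)
  catalogue <- truth_to_catalogue(truth, seed = config$seed + 1L)

  raw <- simulate_count_libraries(truth, sim$n_tumor, sim$n_normal,
                                  sim$depth, sim$dispersion,
                                  seed = config$seed + 2L)
  tumor_ids <- sprintf("T%d", seq_len(sim$n_tumor))
  normal_ids <- sprintf("N%d", seq_len(sim$n_normal))

  if (isTRUE(config$use_reads)) {
    reference <- generate_reference(rownames(raw), seed = config$seed + 3L)
    libs <- render_reads(raw, reference, sim$adapter, sim$error_rate,
                         seed = config$seed + 4L)
    normals <- lapply(libs[normal_ids], function(l)
      new_read_library(l$sample_id, "NORMAL", l$reads))
    pool <- pool_libraries(normals)
    counts <- quantify_libraries(c(libs[tumor_ids], list(pool)), reference,
                                 adapter = sim$adapter,
                                 min_len = prm$min_len,
                                 max_mismatch = prm$max_mismatch,
                                 min_overlap = prm$min_overlap)
  } else {
    pooled <- pool_count_columns(raw, normal_ids)
    counts <- normalize_counts(pooled)
  }

  profiles <- per_sample_ratios(counts, tumor_ids, "normal_pool")
  ds_calls <- lapply(prm$tiers, function(tier) vote_classify(profiles, tier))
  names(ds_calls) <- prm$tiers

  ssh_pairs <- simulate_ssh_pairs(truth, sim$ssh_depth, sim$ssh_capture_bias,
                                  seed = config$seed + 5L)
  ssh_calls <- ssh_differential(ssh_pairs, prm$min_total, prm$min_fold,
                                prm$ssh_total_mode)

  signals <- simulate_array_signals(truth, sim$array_n_tumor,
                                    sim$array_n_normal, sim$array_log_sd,
                                    seed = config$seed + 6L)
  ma <- ma_differential(signals,
                        sprintf("T%d", seq_len(sim$array_n_tumor)),
                        sprintf("N%d", seq_len(sim$array_n_normal)),
                        prm$p_threshold, prm$min_fold)

  evaluations <- do.call(rbind, lapply(prm$tiers, function(tier)
    evaluate_markers(catalogue, profiles, tier)))

  report <- concordance_summary(
    list(DS = ds_calls[[1]], SSH = ssh_calls, MA = ma$calls), catalogue)

  # ---- persist everything as TSV/JSON ----
  out <- config$outdir
  wt <- function(df, name) write.table(df, file.path(out, name), sep = "\t",
                                       quote = FALSE, row.names = FALSE)
  wt(truth, "truth.tsv")
  save_marker_catalogue(catalogue, file.path(out, "catalogue.tsv"))
  write_count_table(counts, out)
  wt(do.call(rbind, ds_calls), "calls_ds.tsv")
  wt(ssh_calls, "calls_ssh.tsv")
  wt(ma$calls, "calls_ma.tsv")
  wt(evaluations, "evaluations.tsv")
  write_concordance_report(report, out)
  manifest <- list(package = "mirmark",
                   version = as.character(utils::packageVersion("mirmark")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   config = config[setdiff(names(config), "outdir")])
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(truth = truth, catalogue = catalogue, counts = counts,
                 profiles = profiles,
                 calls = c(list(DS = ds_calls), list(SSH = ssh_calls),
                           list(MA = ma$calls)),
                 evaluations = evaluations, report = report,
                 signals = signals, ssh_pairs = ssh_pairs, outdir = out))
}
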