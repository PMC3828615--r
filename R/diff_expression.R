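#' Fold-change voting tiers
#'
#' The three cut-off tiers used by the deep-sequencing voting rule: a tumor
#' sample votes "up" when its tumor/normal ratio exceeds `up_cut` and "down"
#' when it falls below `down_cut = 1/up_cut`.
#'
#' @format Named list; each element is `c(up = up_cut, down = down_cut)` for
#'   tiers `SOFT` (2, 0.5), `MEDIUM` (3, 1/3) and `STRICT` (4, 0.25).
#' @export
VOTE_TIERS <- list(SOFT = c(up = 2, down = 0.5),
                   MEDIUM = c(up = 3, down = 1 / 3),
                   STRICT = c(up = 4, down = 0.25))

.tier_cuts <- function(tier) {
  tier <- toupper(tier)
  if (!tier %in% names(VOTE_TIERS))
    stop("unknown tier '", tier, "' (use SOFT, MEDIUM or STRICT)",
         call. = FALSE)
  VOTE_TIERS[[tier]]
}

#' Per-tumor-sample expression ratios against the pooled normal
#'
#' For each miRNA and tumor sample computes `r = R_BC / R_N`, the ratio of
#' the sample's normalised abundance to the pooled-normal abundance. A
#' tumor-positive / normal-zero pair yields `Inf` (direction preserved for
#' markers completely suppressed in normal tissue); a sample where both
#' terms are zero carries no evidence and is excluded (`NA`).
#'
#' @param counts A `count_table` from [quantify_libraries()] or
#'   [normalize_counts()].
#' @param tumor_ids Column names of the tumor samples.
#' @param pooled_normal_id Column name of the pooled-normal sample.
#' @param min_evidence Minimum number of non-excluded tumor samples for a
#'   miRNA to count as assessed (default 1, the weakest defensible rule; a
#'   stricter floor suppresses calls driven by single noisy samples).
#' @return A `ratio_profiles` object: list with `ratios` (miRNA x tumor
#'   matrix; `NA` = excluded, `Inf` = zero denominator with positive
#'   numerator) and `assessed` (logical per miRNA: at least `min_evidence`
#'   non-excluded samples).
#' @export
per_sample_ratios <- function(counts, tumor_ids, pooled_normal_id,
                              min_evidence = 1L) {
  rpm <- counts$rpm
  missing <- setdiff(c(tumor_ids, pooled_normal_id), colnames(rpm))
  if (length(missing))
    stop("unknown sample id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (min_evidence < 1L) stop("min_evidence must be >= 1", call. = FALSE)
  num <- rpm[, tumor_ids, drop = FALSE]
  den <- rpm[, pooled_normal_id]
  ratios <- num / den                      # x/0 -> Inf, 0/0 -> NaN
  ratios[num == 0 & den == 0] <- NA_real_
  structure(list(ratios = ratios,
                 assessed = rowSums(!is.na(ratios)) >= min_evidence),
            class = "ratio_profiles")
}

#' @export
print.ratio_profiles <- function(x, ...) {
  cat(sprintf("<ratio_profiles> %d miRNAs x %d tumor samples (%d assessed)\n",
              nrow(x$ratios), ncol(x$ratios), sum(x$assessed)))
  invisible(x)
}

.vote_status <- function(up, down) {
  if (up > down) "UP"
  else if (down > up) "DOWN"
  else if (up > 0) "MIXED"
  else "NEUTRAL"
}

#' Classify miRNAs by per-sample fold-change votes (deep sequencing)
#'
#' The deep-sequencing calling rule: a miRNA is up-regulated when more tumor
#' samples show a tumor/normal ratio above the tier's upper cut than show a
#' ratio below the lower cut, down-regulated in the mirror case, `MIXED`
#' when the two vote counts tie at a positive value and `NEUTRAL` when
#' nobody votes. `Inf` ratios count as up-votes at every tier; excluded
#' (`NA`) samples do not vote.
#'
#' @param profiles A `ratio_profiles` object, or a numeric vector of ratios
#'   for a single miRNA.
#' @param tier `"SOFT"`, `"MEDIUM"` or `"STRICT"`.
#' @return Data.frame of status calls: `mirna_id`, `method` (`"DS"`),
#'   `tier`, `status` (`UP`/`DOWN`/`MIXED`/`NEUTRAL`, `NA` for miRNAs with
#'   no voting sample), `up_votes`, `down_votes`, `neutral_votes`,
#'   `assessed`.
#' @export
vote_classify <- function(profiles, tier = "SOFT") {
  cuts <- .tier_cuts(tier)
  if (is.numeric(profiles))
    profiles <- structure(list(ratios = matrix(profiles, nrow = 1,
                                               dimnames = list("mirna", NULL)),
                               assessed = any(!is.na(profiles))),
                          class = "ratio_profiles")
  r <- profiles$ratios
  up <- rowSums(r > cuts[["up"]], na.rm = TRUE)
  down <- rowSums(r < cuts[["down"]], na.rm = TRUE)
  voting <- rowSums(!is.na(r))
  assessed <- voting > 0
  if (!is.null(profiles$assessed)) assessed <- assessed & profiles$assessed
  status <- mapply(.vote_status, up, down)
  status[!assessed] <- NA_character_
  data.frame(mirna_id = rownames(r),
             method = "DS",
             tier = toupper(tier),
             status = status,
             up_votes = as.integer(up),
             down_votes = as.integer(down),
             neutral_votes = as.integer(voting - up - down),
             assessed = unname(assessed),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential-expression call from a subtracted-library read pair (SSH)
#'
#' A miRNA observed in the tumor-enriched (BC+) and normal-enriched (BC-)
#' subtracted libraries is assessable when the two normalised read counts
#' together reach `min_total`; it is then called `UP` when the BC/normal
#' ratio is at least `min_fold`, `DOWN` when at most `1/min_fold`, and
#' `NEUTRAL` otherwise. `total_mode = "each"` is the stricter reading that
#' demands `min_total` reads in each library separately.
#'
#' @param pairs Data.frame with columns `mirna_id`, `sr_bc`, `sr_n`
#'   (normalised read counts, non-negative).
#' @param min_total Minimum evidence (default 10).
#' @param min_fold Minimum fold difference (default 1.5).
#' @param total_mode `"sum"` (default) or `"each"`.
#' @return Data.frame of status calls (method `"SSH"`), with `ratio` and
#'   `assessed` columns; unassessed miRNAs have `status = NA`.
#' @export
ssh_differential <- function(pairs, min_total = 10, min_fold = 1.5,
                             total_mode = c("sum", "each")) {
  total_mode <- match.arg(total_mode)
  if (any(pairs$sr_bc < 0) || any(pairs$sr_n < 0))
    stop("SSH read counts must be non-negative", call. = FALSE)
  assessed <- if (total_mode == "sum") (pairs$sr_bc + pairs$sr_n) >= min_total
              else pairs$sr_bc >= min_total & pairs$sr_n >= min_total
  ratio <- pairs$sr_bc / pairs$sr_n      # x/0 -> Inf, 0/0 -> NaN
  ratio[pairs$sr_bc == 0 & pairs$sr_n == 0] <- NA_real_
  status <- ifelse(ratio >= min_fold, "UP",
                   ifelse(ratio <= 1 / min_fold, "DOWN", "NEUTRAL"))
  status[!assessed] <- NA_character_
  data.frame(mirna_id = pairs$mirna_id,
             method = "SSH",
             status = status,
             ratio = ratio,
             assessed = assessed,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-sample location test on log2 intensities
#'
#' The statistical test behind the microarray p-value criterion: a
#' two-sided Welch (unequal-variance) t-test on log2-transformed signals.
#' Two identical constant groups return p = 1 by convention; two different
#' constant groups return p = 0.
#'
#' @param group_a,group_b Numeric vectors of positive intensities, each of
#'   length >= 2.
#' @return Two-sided p-value in `[0, 1]`; symmetric in the group order.
#' @export
location_test <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  if (any(c(group_a, group_b) <= 0))
    stop("intensities must be positive (log scale)", call. = FALSE)
  a <- log2(group_a); b <- log2(group_b)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(if (mean(a) == mean(b)) 1 else 0)
  t.test(a, b, var.equal = FALSE)$p.value
}

#' Differential-expression calls from microarray signals
#'
#' A probe is differential when (1) the location test on its log2 signals
#' gives p below `p_threshold` and (2) the mean tumor and mean normal
#' signals differ at least `min_fold`-fold; the direction comes from the
#' mean ratio. Per-tumor-sample ratios against the average normal signal
#' (`S_BC / SaN`) are reported for every probe regardless of the call.
#'
#' @param signals Numeric matrix, probe x sample, of positive intensities
#'   with canonical miRNA row names.
#' @param tumor_ids,normal_ids Column names of the two groups (>= 2 each).
#' @param p_threshold P-value criterion (default 0.01).
#' @param min_fold Fold-change criterion (default 1.5).
#' @return List with `calls` (data.frame: `mirna_id`, `method = "MA"`,
#'   `status` `UP`/`DOWN`/`NEUTRAL`, `p_value`, `mean_ratio`, `assessed =
#'   TRUE`) and `sample_ratios` (probe x tumor matrix of `S_BC / SaN`).
#' @export
ma_differential <- function(signals, tumor_ids, normal_ids,
                            p_threshold = 0.01, min_fold = 1.5) {
  signals <- as.matrix(signals)
  missing <- setdiff(c(tumor_ids, normal_ids), colnames(signals))
  if (length(missing))
    stop("unknown sample id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(tumor_ids) < 2L || length(normal_ids) < 2L)
    stop("need at least 2 samples per group", call. = FALSE)
  tum <- signals[, tumor_ids, drop = FALSE]
  nor <- signals[, normal_ids, drop = FALSE]
  p <- vapply(seq_len(nrow(signals)),
              function(i) location_test(tum[i, ], nor[i, ]), numeric(1))
  ratio <- rowMeans(tum) / rowMeans(nor)
  status <- rep("NEUTRAL", nrow(signals))
  status[p < p_threshold & ratio >= min_fold] <- "UP"
  status[p < p_threshold & ratio <= 1 / min_fold] <- "DOWN"
  calls <- data.frame(mirna_id = rownames(signals),
                      method = "MA",
                      status = status,
                      p_value = p,
                      mean_ratio = ratio,
                      assessed = TRUE,
                      stringsAsFactors = FALSE, row.names = NULL)
  list(calls = calls, sample_ratios = tum / rowMeans(nor))
}
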