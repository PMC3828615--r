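#' Sensitivity of a marker at a fold-change tier
#'
#' The fraction of non-excluded tumor samples whose tumor/normal ratio lies
#' in the marker's published direction at the tier's cut: above `up_cut`
#' for an `UP` marker, below `down_cut` for a `DOWN` marker.
#'
#' @param direction `"UP"` or `"DOWN"` (the direction being tested).
#' @param ratios Numeric vector of per-tumor-sample ratios (`NA` =
#'   excluded, `Inf` allowed).
#' @param tier `"SOFT"`, `"MEDIUM"` or `"STRICT"`.
#' @return Sensitivity in `[0, 1]`, or `NA` when no sample is assessable.
#' @export
sensitivity_score <- function(direction, ratios, tier = "SOFT") {
  direction <- match.arg(direction, c("UP", "DOWN"))
  cuts <- .tier_cuts(tier)
  ok <- !is.na(ratios)
  if (!any(ok)) return(NA_real_)
  hit <- if (direction == "UP") ratios[ok] > cuts[["up"]]
         else ratios[ok] < cuts[["down"]]
  sum(hit) / sum(ok)
}

#' Specificity of a marker from leave-one-out normal ratios
#'
#' With tumors compared against a normal pool there is no per-normal "truth"
#' axis, so specificity is reconstructed by treating each normal sample as a
#' pseudo-case: its abundance is divided by the mean abundance of the
#' remaining normals, and specificity is the fraction of normal samples NOT
#' called in the marker's direction at the tier's cut.
#'
#' @param direction `"UP"` or `"DOWN"`.
#' @param normal_abundances Numeric vector (length >= 2) of the marker's
#'   normalised abundance in each individual normal sample.
#' @param tier `"SOFT"`, `"MEDIUM"` or `"STRICT"`.
#' @return Specificity in `[0, 1]`, or `NA` with fewer than 2 normals or
#'   when no leave-one-out ratio is defined.
#' @export
specificity_score <- function(direction, normal_abundances, tier = "SOFT") {
  direction <- match.arg(direction, c("UP", "DOWN"))
  cuts <- .tier_cuts(tier)
  n <- length(normal_abundances)
  if (n < 2L) return(NA_real_)
  loo_mean <- (sum(normal_abundances) - normal_abundances) / (n - 1)
  r <- normal_abundances / loo_mean
  r[normal_abundances == 0 & loo_mean == 0] <- NA_real_
  ok <- !is.na(r)
  if (!any(ok)) return(NA_real_)
  called <- if (direction == "UP") r[ok] > cuts[["up"]] else r[ok] < cuts[["down"]]
  sum(!called) / sum(ok)
}

#' Summary AUC from specificity and sensitivity
#'
#' The marker-quality summary `AUC = (Sp + Sn) / 2`; a marker is deemed
#' valuable when its AUC strictly exceeds 0.7. This is an arithmetic-mean
#' summary of the two rates at one operating point, not a ROC-curve
#' integral.
#'
#' @param sp,sn Specificity and sensitivity, both in `[0, 1]` (`NA`
#'   propagates).
#' @return Numeric vector of AUC values.
#' @export
auc_score <- function(sp, sn) {
  bad <- !is.na(sp) & (sp < 0 | sp > 1) | !is.na(sn) & (sn < 0 | sn > 1)
  if (any(bad)) stop("Sp and Sn must lie in [0, 1]", call. = FALSE)
  (sp + sn) / 2
}

#' Is a marker's AUC valuable?
#'
#' @param auc AUC values from [auc_score()].
#' @return Logical: `TRUE` where AUC strictly exceeds 0.7.
#' @export
auc_valuable <- function(auc) !is.na(auc) & auc > 0.7

#' Evaluate every catalogue marker at a tier
#'
#' Joins the catalogue to the observed ratio profiles and scores each
#' assessed marker's sensitivity (and, when per-normal abundances are
#' supplied, specificity and AUC). Markers with contradictory published
#' directions are tested both ways and reported as two rows; markers absent
#' from the profiles come back as not-assessed rows with `NA` scores.
#'
#' @param catalogue Data.frame from [load_marker_catalogue()].
#' @param profiles A `ratio_profiles` object from [per_sample_ratios()].
#' @param tier `"SOFT"`, `"MEDIUM"` or `"STRICT"`.
#' @param normal_abundances Optional numeric matrix, miRNA x normal sample,
#'   of per-normal normalised abundances for the specificity
#'   reconstruction; `NULL` (the default, matching a single-pooled-normal
#'   design) leaves Sp and AUC undefined.
#' @return Data.frame: `mirna_id`, `published_status`, `direction_tested`,
#'   `tier`, `assessed`, `sn`, `sp`, `auc`, `valuable`.
#' @export
evaluate_markers <- function(catalogue, profiles, tier = "SOFT",
                             normal_abundances = NULL) {
  rows <- list()
  for (i in seq_len(nrow(catalogue))) {
    id <- catalogue$mirna_id[i]
    pub <- catalogue$published_status[i]
    dirs <- if (pub == "CONTRADICTORY") c("UP", "DOWN") else pub
    assessed <- id %in% rownames(profiles$ratios) &&
      isTRUE(profiles$assessed[[id]])
    for (d in dirs) {
      sn <- sp <- NA_real_
      if (assessed) {
        sn <- sensitivity_score(d, profiles$ratios[id, ], tier)
        if (!is.null(normal_abundances) && id %in% rownames(normal_abundances))
          sp <- specificity_score(d, normal_abundances[id, ], tier)
      }
      auc <- ifelse(is.na(sp) | is.na(sn), NA_real_, auc_score(sp, sn))
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = id, published_status = pub, direction_tested = d,
        tier = toupper(tier), assessed = assessed,
        sn = sn, sp = sp, auc = auc,
        valuable = auc_valuable(auc),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
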