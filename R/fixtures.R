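#' Paths to the packaged worked-example fixtures
#'
#' The package ships three small synthetic fixtures (all hand-constructed,
#' none derived from patient data):
#'
#' * `"catalogue"` — `marker_catalogue_synthetic.tsv`, a 102-marker
#'   catalogue emulating the published bladder-cancer miRNA marker
#'   database: 95 expression + 7 methylation markers, carrying the marker
#'   names discussed in the bladder-cancer literature plus clearly-labelled
#'   synthetic fillers (`mirsynNN`).
#' * `"ds_abundance"` — `ds_worked_abundance_synthetic.tsv`, a raw count
#'   table (38 catalogue miRNAs + one absorbing `miscpool` row x 9 tumor
#'   samples + 1 pooled normal) constructed so the deep-sequencing voting
#'   pipeline reproduces the study's headline arithmetic: 33/38 markers
#'   concordant at the soft tier (86.8%, printed as 87%), a
#'   20 up / 15 down / 3 mixed tally, four markers with Sn > 0.7 at the
#'   medium tier and two more at the soft tier only. Every column sums to
#'   the same total, so RPM normalisation preserves the designed ratios
#'   exactly.
#' * `"congruence_calls"` — `congruence_calls_synthetic.tsv`, SSH and MA
#'   status calls over the same markers, constructed so exactly one marker
#'   (mir205) is called UP by all three platforms.
#'
#' @param which One of `"catalogue"`, `"ds_abundance"`,
#'   `"congruence_calls"`.
#' @return Absolute path to the fixture file.
#' @export
mirmark_extdata <- function(which = c("catalogue", "ds_abundance",
                                      "congruence_calls")) {
  which <- match.arg(which)
  file <- switch(which,
                 catalogue = "marker_catalogue_synthetic.tsv",
                 ds_abundance = "ds_worked_abundance_synthetic.tsv",
                 congruence_calls = "congruence_calls_synthetic.tsv")
  path <- system.file("extdata", file, package = "mirmark")
  if (!nzchar(path)) stop("fixture not found: ", file, call. = FALSE)
  path
}

#' Load the worked deep-sequencing fixture as ratio profiles
#'
#' Reads the packaged abundance fixture, normalises it to RPM and computes
#' the per-tumor-sample ratio profiles against the pooled normal — the
#' exact path real count data would take.
#'
#' @return List with `counts` (a `count_table`) and `profiles` (a
#'   `ratio_profiles` over tumor samples `T1..T9`).
#' @export
load_worked_ds_fixture <- function() {
  tab <- read.delim(mirmark_extdata("ds_abundance"), check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$mirna
  counts <- normalize_counts(m)
  profiles <- per_sample_ratios(counts, sprintf("T%d", 1:9), "normal_pool")
  list(counts = counts, profiles = profiles)
}
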