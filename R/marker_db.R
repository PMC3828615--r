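#' Canonicalise a miRNA name
#'
#' Collapses the citation-style variants of a mature miRNA name ("hsa-miR-205",
#' "miR205", "Let-7c") onto one lower-case token so that catalogue entries,
#' reference FASTA headers and result tables can be joined. The species prefix
#' ("hsa-") and internal hyphens/spaces are removed; mature-arm suffixes
#' ("-5p"/"-3p") are kept, as "mir125b-5p" and "mir125b-3p" are distinct
#' mature molecules.
#'
#' @param raw Character vector of free-text miRNA names.
#' @return Character vector of canonical ids (e.g. `"mir205"`, `"let7c"`,
#'   `"mir125b-5p"`). The transform is idempotent.
#' @examples
#' normalize_mirna_name(c("hsa-miR-205", "miR141", "Let-7c", "hsa-miR-125b-5p"))
#' @export
normalize_mirna_name <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  if (!is.character(raw) || anyNA(raw) || any(!nzchar(trimws(raw))))
    stop("miRNA names must be non-empty strings", call. = FALSE)
  x <- tolower(trimws(raw))
  # preserve the arm suffix across hyphen stripping
  arm <- rep("", length(x))
  has_arm <- grepl("-(5p|3p)$", x)
  arm[has_arm] <- sub("^.*-(5p|3p)$", "-\\1", x[has_arm])
  x[has_arm] <- sub("-(5p|3p)$", "", x[has_arm])
  x <- sub("^hsa[-_ ]?", "", x)
  x <- gsub("[-_ ]", "", x)
  paste0(x, arm)
}

.status_levels <- c("UP", "DOWN", "CONTRADICTORY")
.type_levels <- c("EXPRESSION", "METHYLATION_HYPO", "METHYLATION_HYPER")

#' Resolve a published direction from per-study reports
#'
#' A marker reported up-regulated by every study is `UP`, down-regulated by
#' every study `DOWN`; markers with opposing reports (the miR141/miR205
#' situation in the bladder-cancer literature) are `CONTRADICTORY`.
#'
#' @param directions Character vector of per-study directions, `"UP"` or
#'   `"DOWN"`; order does not matter.
#' @return One of `"UP"`, `"DOWN"`, `"CONTRADICTORY"`.
#' @export
resolve_published_status <- function(directions) {
  if (length(directions) == 0L)
    stop("at least one reported direction is required", call. = FALSE)
  if (!all(directions %in% c("UP", "DOWN")))
    stop("directions must be 'UP' or 'DOWN'", call. = FALSE)
  u <- unique(directions)
  if (length(u) > 1L) "CONTRADICTORY" else u
}

#' Load a published-marker catalogue
#'
#' Reads a tab-separated catalogue of published miRNA markers. The file needs
#' a header row with columns `name`, `status`, `type`, `references` and
#' `note`; `references` holds pipe-separated citation strings. Names are
#' canonicalised with [normalize_mirna_name()]; a file whose rows collide
#' after canonicalisation is rejected.
#'
#' @param path Path to a UTF-8 TSV file.
#' @return A data.frame with one row per marker: `mirna_id`,
#'   `published_status` (`UP`/`DOWN`/`CONTRADICTORY`), `marker_type`
#'   (`EXPRESSION`/`METHYLATION_HYPO`/`METHYLATION_HYPER`), `references`
#'   (list column of citation strings) and `pathway_note`.
#' @seealso [save_marker_catalogue()]
#' @export
load_marker_catalogue <- function(path) {
  if (!file.exists(path)) stop("catalogue file not found: ", path, call. = FALSE)
  raw <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = NULL, quote = "", fileEncoding = "UTF-8")
  need <- c("name", "status", "type", "references", "note")
  if (!all(need %in% names(raw)))
    stop("catalogue must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- which(!raw$status %in% .status_levels)
  if (length(bad))
    stop("unknown status '", raw$status[bad[1]], "' in catalogue row ",
         bad[1], call. = FALSE)
  bad <- which(!raw$type %in% .type_levels)
  if (length(bad))
    stop("unknown marker type '", raw$type[bad[1]], "' in catalogue row ",
         bad[1], call. = FALSE)
  id <- normalize_mirna_name(raw$name)
  if (anyDuplicated(id)) {
    dup <- id[duplicated(id)][1]
    stop("duplicate marker id after canonicalisation: '", dup, "'",
         call. = FALSE)
  }
  refs <- strsplit(raw$references, "|", fixed = TRUE)
  refs <- lapply(refs, function(r) r[nzchar(r)])
  n_contra <- raw$status == "CONTRADICTORY" & lengths(refs) < 2L
  if (any(n_contra))
    stop("CONTRADICTORY marker '", id[which(n_contra)[1]],
         "' must carry at least two references", call. = FALSE)
  out <- data.frame(mirna_id = id,
                    published_status = raw$status,
                    marker_type = raw$type,
                    pathway_note = raw$note,
                    stringsAsFactors = FALSE)
  out$references <- refs
  out[, c("mirna_id", "published_status", "marker_type", "references",
          "pathway_note")]
}

#' Write a marker catalogue back to TSV
#'
#' Inverse of [load_marker_catalogue()]; loading a canonical file, saving it
#' and loading again round-trips exactly.
#'
#' @param catalogue Data.frame as returned by [load_marker_catalogue()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_marker_catalogue <- function(catalogue, path) {
  out <- data.frame(name = catalogue$mirna_id,
                    status = catalogue$published_status,
                    type = catalogue$marker_type,
                    references = vapply(catalogue$references, paste,
                                        character(1), collapse = "|"),
                    note = catalogue$pathway_note,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
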