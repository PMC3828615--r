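#' Directional agreement between an observed call and the published status
#'
#' A directional observed call (`UP` or `DOWN`) agrees with a matching
#' published direction; a `CONTRADICTORY` published status (opposing
#' literature reports) is matched by either direction. `MIXED` and
#' `NEUTRAL` observed calls carry no direction and are `NOT_DIRECTIONAL`
#' (they count against the concordance percentage but are not
#' disagreements).
#'
#' @param observed Character vector of observed statuses
#'   (`UP`/`DOWN`/`MIXED`/`NEUTRAL`).
#' @param published Character vector (recycled) of published statuses
#'   (`UP`/`DOWN`/`CONTRADICTORY`).
#' @return Character vector: `"AGREE"`, `"DISAGREE"` or
#'   `"NOT_DIRECTIONAL"`.
#' @export
marker_agreement <- function(observed, published) {
  n <- max(length(observed), length(published))
  observed <- rep_len(observed, n)
  published <- rep_len(published, n)
  out <- rep("DISAGREE", n)
  out[observed %in% c("NEUTRAL", "MIXED")] <- "NOT_DIRECTIONAL"
  out[observed %in% c("UP", "DOWN") &
        (observed == published | published == "CONTRADICTORY")] <- "AGREE"
  out
}

#' Fraction of catalogue markers assessed by a platform
#'
#' @param catalogue Marker catalogue data.frame.
#' @param assessed_ids Canonical ids the platform could assess.
#' @return List with `count` and `percent` (of the catalogue size).
#' @export
assessed_fraction <- function(catalogue, assessed_ids) {
  count <- sum(catalogue$mirna_id %in% assessed_ids)
  list(count = count,
       percent = if (nrow(catalogue) > 0) 100 * count / nrow(catalogue) else 0)
}

#' Tally directional calls for one platform
#'
#' @param status Character vector of assessed calls
#'   (`UP`/`DOWN`/`MIXED`/`NEUTRAL`; `NA` ignored).
#' @return Named integer vector `c(n_up, n_down, n_mixed, n_neutral)`; the
#'   four counts partition the assessed set.
#' @export
direction_tally <- function(status) {
  status <- status[!is.na(status)]
  c(n_up = sum(status == "UP"), n_down = sum(status == "DOWN"),
    n_mixed = sum(status == "MIXED"), n_neutral = sum(status == "NEUTRAL"))
}

.dir_of <- function(status) ifelse(status %in% c("UP", "DOWN"), status, NA)

# Congruence cell for one marker: the largest set of methods (including the
# PUBLISHED pseudo-method) sharing one direction. CONTRADICTORY published
# joins whichever observed group is larger. Ties between an UP and a DOWN
# group go to the group containing PUBLISHED, then to UP. Markers assessed
# by >= 2 methods where no two methods share a direction fall in the
# reserved "(discordant)" cell.
.congruence_cell <- function(dirs) {
  methods <- names(dirs)
  pub <- dirs[["PUBLISHED"]]
  obs <- dirs[setdiff(methods, "PUBLISHED")]
  grp <- list(UP = names(obs)[!is.na(obs) & obs == "UP"],
              DOWN = names(obs)[!is.na(obs) & obs == "DOWN"])
  if (!is.na(pub)) {
    if (pub == "CONTRADICTORY") {
      side <- if (length(grp$DOWN) > length(grp$UP)) "DOWN" else "UP"
      grp[[side]] <- c(grp[[side]], "PUBLISHED")
    } else {
      grp[[pub]] <- c(grp[[pub]], "PUBLISHED")
    }
  }
  sizes <- lengths(grp)
  if (max(sizes) < 2L) return("(discordant)")
  side <- if (sizes["UP"] > sizes["DOWN"]) "UP"
          else if (sizes["DOWN"] > sizes["UP"]) "DOWN"
          else if ("PUBLISHED" %in% grp$UP) "UP"
          else if ("PUBLISHED" %in% grp$DOWN) "DOWN"
          else "UP"
  paste(sort(grp[[side]]), collapse = "+")
}

#' Concordance of observed calls with the published catalogue
#'
#' Combines per-method status calls into one report: a per-marker matrix of
#' observed statuses and agreement flags, per-method concordance
#' percentages (share of assessed markers whose directional call matches
#' the published status), and the congruence partition — for each marker
#' assessed by at least two methods (the published direction acting as a
#' pseudo-method `PUBLISHED`), the largest set of methods agreeing on one
#' direction. The congruence cells are disjoint and cover every
#' multi-method marker, so Venn-style panel counts can be read off
#' directly.
#'
#' @param calls Named list of status-call data.frames (columns `mirna_id`,
#'   `status`, `assessed`), one per method, e.g.
#'   `list(DS = ..., SSH = ..., MA = ...)`.
#' @param catalogue Marker catalogue data.frame.
#' @return A `concordance_report`: list with `per_marker` (data.frame:
#'   published status, one observed-status and one agreement column per
#'   method, `congruence_cell`), `summary` (data.frame per method:
#'   `n_assessed`, `n_agree`, `percent_agree`) and `congruence` (named
#'   list: cell label -> character vector of marker ids).
#' @export
concordance_summary <- function(calls, catalogue) {
  if (length(calls) < 1L) stop("need calls from at least one method",
                               call. = FALSE)
  if (is.null(names(calls)) || any(!nzchar(names(calls))))
    stop("'calls' must be a named list (one element per method)",
         call. = FALSE)
  ids <- catalogue$mirna_id
  per <- data.frame(mirna_id = ids, published = catalogue$published_status,
                    stringsAsFactors = FALSE)
  for (m in names(calls)) {
    tab <- calls[[m]]
    st <- tab$status[match(ids, tab$mirna_id)]
    st[!ids %in% tab$mirna_id[tab$assessed]] <- NA
    per[[paste0("status_", m)]] <- st
    agr <- rep(NA_character_, length(ids))
    has <- !is.na(st)
    agr[has] <- marker_agreement(st[has], per$published[has])
    per[[paste0("agree_", m)]] <- agr
  }
  summary <- do.call(rbind, lapply(names(calls), function(m) {
    agr <- per[[paste0("agree_", m)]]
    n_assessed <- sum(!is.na(agr))
    n_agree <- sum(agr == "AGREE", na.rm = TRUE)
    data.frame(method = m, n_assessed = n_assessed, n_agree = n_agree,
               percent_agree = if (n_assessed > 0) 100 * n_agree / n_assessed
                               else NA_real_,
               stringsAsFactors = FALSE)
  }))
  # congruence over methods + PUBLISHED
  cells <- rep(NA_character_, length(ids))
  for (i in seq_along(ids)) {
    obs <- vapply(names(calls), function(m) {
      s <- per[[paste0("status_", m)]][i]
      if (is.na(s)) NA_character_ else s
    }, character(1))
    dirs <- c(.dir_of(obs), PUBLISHED = per$published[i])
    names(dirs)[seq_along(calls)] <- names(calls)
    if (sum(!is.na(obs)) >= 2L) cells[i] <- .congruence_cell(dirs)
  }
  per$congruence_cell <- cells
  congruence <- split(ids[!is.na(cells)], cells[!is.na(cells)])
  structure(list(per_marker = per, summary = summary,
                 congruence = congruence),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report>\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-6s %2d/%2d agree (%.1f%%)\n", x$summary$method[i],
                x$summary$n_agree[i], x$summary$n_assessed[i],
                x$summary$percent_agree[i]))
  cat("  congruence cells:",
      paste(sprintf("%s[%d]", names(x$congruence), lengths(x$congruence)),
            collapse = " "), "\n")
  invisible(x)
}

#' Write a concordance report to disk
#'
#' The per-marker matrix goes to TSV, the per-method summary and congruence
#' cells to JSON.
#'
#' @param report A `concordance_report`.
#' @param dir Output directory (created if missing).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_concordance_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "concordance_per_marker.tsv")
  json <- file.path(dir, "concordance_summary.json")
  write.table(report$per_marker, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(summary = report$summary,
                            congruence = report$congruence),
                       json, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(tsv, json))
}
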