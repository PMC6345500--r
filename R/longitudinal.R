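# Serial-study comparison and white-matter spread-route proposals.

#' Compare two serial infiltration reports
#'
#' Set differences of the infiltrated cells of two studies of the same
#' patient: `gained` (in later only), `lost` (in earlier only), `stable`
#' (both), plus volume change and per-cell volume changes for stable cells.
#'
#' @param earlier,later `infiltration_report`s in the same space; when both
#'   carry dates, `earlier` must not postdate `later`.
#' @return An object of class `progression_delta` with elements `gained`,
#'   `lost`, `stable` (character vectors of labels), `volume_change_cm3`,
#'   `cell_volume_changes` (data frame for stable cells) and `interval`.
#' @examples
#' r1 <- infiltration_report("A2C2S1", study_id = "2002")
#' r2 <- infiltration_report(c("A2C2S1", "A3C2S1"), study_id = "2010")
#' compare_reports(r1, r2)
#' @export
compare_reports <- function(earlier, later) {
  stopifnot(inherits(earlier, "infiltration_report"),
            inherits(later, "infiltration_report"))
  if (!identical(earlier$space_tag, later$space_tag))
    stop("reports are in different spaces ('", earlier$space_tag, "' vs '",
         later$space_tag, "')", call. = FALSE)
  if (!is.na(earlier$date) && !is.na(later$date) &&
      as.Date(earlier$date) > as.Date(later$date))
    stop("'earlier' report is dated after 'later'", call. = FALSE)
  e <- earlier$cells$label
  l <- later$cells$label
  stable <- intersect(e, l)
  gained <- setdiff(l, e)
  lost <- setdiff(e, l)
  cvc <- data.frame(label = stable,
                    volume_mm3_earlier =
                      earlier$cells$volume_mm3[match(stable, e)],
                    volume_mm3_later =
                      later$cells$volume_mm3[match(stable, l)],
                    stringsAsFactors = FALSE)
  cvc$change_mm3 <- cvc$volume_mm3_later - cvc$volume_mm3_earlier
  structure(list(gained = gained[order(cell_id(gained))],
                 lost = lost[order(cell_id(lost))],
                 stable = stable[order(cell_id(stable))],
                 volume_change_cm3 =
                   later$total_volume_cm3 - earlier$total_volume_cm3,
                 cell_volume_changes = cvc,
                 interval = c(earlier = .study_tag(earlier),
                              later = .study_tag(later))),
            class = "progression_delta")
}

.study_tag <- function(report) {
  if (!is.na(report$study_id)) return(report$study_id)
  if (!is.na(report$date)) return(report$date)
  NA_character_
}

#' @export
print.progression_delta <- function(x, ...) {
  iv <- x$interval
  if (!all(is.na(iv)))
    cat("Progression ", iv["earlier"], " -> ", iv["later"], "\n", sep = "")
  else cat("Progression delta\n")
  cat("  gained: ", if (length(x$gained)) paste(x$gained, collapse = ", ")
                    else "(none)", "\n",
      "  lost:   ", if (length(x$lost)) paste(x$lost, collapse = ", ")
                    else "(none)", "\n",
      "  stable: ", length(x$stable), " cells\n",
      "  volume change: ", sprintf("%+.2f", x$volume_change_cm3),
      " cm^3\n", sep = "")
  invisible(x)
}

#' Propose white-matter spread routes for newly infiltrated cells
#'
#' For each gained cell, every face-adjacent baseline cell (midline A2-A3
#' adjacency included) is paired with the white-matter structures whose cell
#' sets contain both, proposing the pathway along which the cell was
#' reached. Gained cells with no infiltrated neighbor are flagged as
#' non-contiguous appearances.
#'
#' @param delta A [compare_reports()] result (or a character vector of
#'   gained cell labels).
#' @param baseline_cells Cells infiltrated at the earlier study.
#' @param table A `tract_table`.
#' @return A list of class `spread_routes`: `routes` (data frame `from_cell`,
#'   `to_cell`, `shared_structures` semicolon-joined) and `non_contiguous`
#'   (labels of gained cells with no adjacent baseline cell).
#' @examples
#' r1 <- infiltration_report("A2C2S1")
#' r2 <- infiltration_report(c("A2C2S1", "A3C2S1"))
#' progression_routes(compare_reports(r1, r2), r1$cells$label)
#' @export
progression_routes <- function(delta, baseline_cells,
                               table = load_tract_table()) {
  gained <- if (inherits(delta, "progression_delta")) delta$gained
            else canonical_label(delta)
  baseline_cells <- if (length(baseline_cells) > 0L)
    canonical_label(baseline_cells) else character(0)
  rows <- list()
  orphan <- character(0)
  for (g in gained) {
    nb <- intersect(adjacent_cells(g), baseline_cells)
    if (length(nb) == 0L) {
      orphan <- c(orphan, g)
      next
    }
    for (b in nb) {
      hit <- vapply(table$cells, function(cs) all(c(g, b) %in% cs),
                    logical(1))
      structs <- paste0(table$name[hit],
                        ifelse(table$hemisphere[hit] == "midline", "",
                               paste0("-", table$hemisphere[hit])))
      rows[[length(rows) + 1L]] <-
        data.frame(from_cell = b, to_cell = g,
                   shared_structures = paste(sort(structs), collapse = ";"),
                   stringsAsFactors = FALSE)
    }
  }
  routes <- if (length(rows) > 0L) do.call(rbind, rows)
    else data.frame(from_cell = character(0), to_cell = character(0),
                    shared_structures = character(0),
                    stringsAsFactors = FALSE)
  structure(list(routes = routes, non_contiguous = orphan),
            class = "spread_routes")
}

#' @export
print.spread_routes <- function(x, ...) {
  if (nrow(x$routes) == 0L) {
    cat("No contiguous spread routes.\n")
  } else {
    cat("Proposed spread routes:\n")
    for (i in seq_len(nrow(x$routes))) {
      s <- x$routes$shared_structures[i]
      cat("  ", x$routes$from_cell[i], " -> ", x$routes$to_cell[i], "  [",
          if (nzchar(s)) s else "no shared structure in table", "]\n",
          sep = "")
    }
  }
  if (length(x$non_contiguous) > 0L)
    cat("Non-contiguous appearances:",
        paste(x$non_contiguous, collapse = ", "), "\n")
  invisible(x)
}

#' Write a progression delta (and optional routes) to JSON
#'
#' @param delta A `progression_delta`.
#' @param path Output path.
#' @param routes Optional [progression_routes()] result to embed.
#' @return `path`, invisibly.
#' @export
write_delta <- function(delta, path, routes = NULL) {
  stopifnot(inherits(delta, "progression_delta"))
  doc <- list(interval = as.list(delta$interval),
              gained = delta$gained, lost = delta$lost,
              stable = delta$stable,
              volume_change_cm3 = delta$volume_change_cm3)
  if (!is.null(routes)) {
    doc$routes <- lapply(seq_len(nrow(routes$routes)), function(i)
      as.list(routes$routes[i, ]))
    doc$non_contiguous <- routes$non_contiguous
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
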