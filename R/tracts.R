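# White-matter structure <-> grid-cell association table and queries.

.TRACT_CATEGORIES <- c("commissural", "projection", "associative")
.TRACT_HEMIS <- c("L", "R", "midline")

#' Load a tract-to-cell association table
#'
#' Reads a tab-separated table with columns `name`, `hemisphere`
#' (`L`/`R`/`midline`), `category` (`commissural`/`projection`/
#' `associative`) and `cells` (semicolon-separated grid-cell labels). An
#' optional `provenance` column records where each entry's cell set comes
#' from. The default is the shipped table of 34 major white-matter
#' bundles/structures mapped to the grid on a population-average diffusion
#' template.
#'
#' @param path Path to a TSV file; the default loads the shipped table.
#' @return An object of class `tract_table`: a data frame with the columns
#'   above, `cells` being a list column of canonical labels, plus a
#'   `provenance` attribute.
#' @examples
#' tt <- load_tract_table()
#' nrow(tt)  # 34
#' @export
load_tract_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tract_atlas.tsv", package = "braingrid",
                        mustWork = TRUE)
    prov <- "shipped"
  } else prov <- path
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("name", "hemisphere", "category", "cells")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("tract table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"provenance" %in% names(df)) df$provenance <- ""
  key <- paste(df$name, df$hemisphere)
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop("duplicate tract entry '", df$name[i], "' (", df$hemisphere[i],
         ") at line ", i + 1L, call. = FALSE)
  }
  bad_h <- !df$hemisphere %in% .TRACT_HEMIS
  if (any(bad_h))
    stop("unknown hemisphere '", df$hemisphere[bad_h][1L], "' at line ",
         which(bad_h)[1L] + 1L, call. = FALSE)
  bad_c <- !df$category %in% .TRACT_CATEGORIES
  if (any(bad_c))
    stop("unknown category '", df$category[bad_c][1L], "' at line ",
         which(bad_c)[1L] + 1L, call. = FALSE)
  cells <- strsplit(df$cells, ";", fixed = TRUE)
  for (i in seq_along(cells)) {
    if (length(cells[[i]]) == 0L || all(!nzchar(cells[[i]])))
      stop("empty cell set for '", df$name[i], "' at line ", i + 1L,
           call. = FALSE)
    cells[[i]] <- tryCatch(canonical_label(trimws(cells[[i]])),
                           error = function(e)
                             stop("invalid cell label for '", df$name[i],
                                  "' at line ", i + 1L, ": ",
                                  conditionMessage(e), call. = FALSE))
    cells[[i]] <- cells[[i]][order(cell_id(cells[[i]]))]
  }
  df$cells <- cells
  attr(df, "provenance") <- prov
  class(df) <- c("tract_table", "data.frame")
  df
}

#' Save a tract table to TSV
#'
#' @param table A `tract_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_tract_table <- function(table, path) {
  stopifnot(inherits(table, "tract_table"))
  out <- data.frame(name = table$name, hemisphere = table$hemisphere,
                    category = table$category,
                    cells = vapply(table$cells, paste, "", collapse = ";"),
                    provenance = table$provenance,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.tract_table <- function(x, ...) {
  cat("tract_table: ", nrow(x), " white-matter structures (",
      sum(x$hemisphere == "midline"), " midline, ",
      sum(x$hemisphere != "midline"), " lateralized)\n", sep = "")
  cat("  categories:", paste(sprintf("%s=%d", names(table(x$category)),
                                     table(x$category)), collapse = ", "),
      "\n")
  invisible(x)
}

#' White-matter structures traversing a set of grid cells
#'
#' Answers "which structures are at risk" for a set of infiltrated cells:
#' every table entry whose cell set intersects the query, ranked by the
#' number of shared cells (ties broken by name, then hemisphere).
#'
#' @param cells Character vector of grid-cell labels.
#' @param table A `tract_table` (default: the shipped atlas).
#' @return Data frame with columns `name`, `hemisphere`, `category`,
#'   `n_shared_cells` and `shared_cells` (semicolon-joined), most-involved
#'   structures first.
#' @examples
#' tracts_in_cells("A3C2S2")
#' @export
tracts_in_cells <- function(cells, table = load_tract_table()) {
  stopifnot(inherits(table, "tract_table"))
  cells <- canonical_label(cells)
  shared <- lapply(table$cells, intersect, x = cells)
  n <- vapply(shared, length, 1L)
  keep <- n > 0L
  out <- data.frame(name = table$name[keep],
                    hemisphere = table$hemisphere[keep],
                    category = table$category[keep],
                    n_shared_cells = n[keep],
                    shared_cells = vapply(shared[keep], paste, "",
                                          collapse = ";"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_shared_cells, out$name, out$hemisphere), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Grid cells traversed by a named structure
#'
#' @param name Structure code, e.g. `"IFOF"`, `"CC-genu"`.
#' @param hemisphere `"L"`, `"R"` or `"midline"`.
#' @param table A `tract_table`.
#' @return Character vector of canonical cell labels.
#' @examples
#' cells_of_tract("CC-genu", "midline")
#' @export
cells_of_tract <- function(name, hemisphere = c("L", "R", "midline"),
                           table = load_tract_table()) {
  stopifnot(inherits(table, "tract_table"))
  hemisphere <- match.arg(hemisphere)
  i <- which(table$name == name & table$hemisphere == hemisphere)
  if (length(i) == 0L) {
    near <- unique(table$name[agrepl(name, table$name, ignore.case = TRUE,
                                     max.distance = 0.3)])
    hint <- if (length(near) > 0L)
      paste0("; did you mean: ", paste(near, collapse = ", "), "?") else ""
    stop("unknown structure '", name, "' (", hemisphere, ")", hint,
         call. = FALSE)
  }
  table$cells[[i]]
}

#' Build a tract table from per-structure masks
#'
#' Reproduces the atlas-to-grid analysis for any set of tract masks: for
#' each named mask the associated cells are those whose overlap volume
#' (voxel-center membership) exceeds `min_overlap_mm3`.
#'
#' @param tract_masks Named list of [volume_mask()] objects. Names may be
#'   `"NAME"` (midline) or `"NAME.L"` / `"NAME.R"` to set the hemisphere.
#' @param grid A [brain_grid()].
#' @param min_overlap_mm3 Minimum overlap volume per cell (mm^3).
#' @param category Category assigned to every entry, or a named character
#'   vector keyed like `tract_masks`.
#' @return A `tract_table`; empty masks are dropped with a warning.
#' @export
build_table_from_masks <- function(tract_masks, grid, min_overlap_mm3 = 0,
                                   category = "associative") {
  stopifnot(inherits(grid, "brain_grid"))
  if (is.null(names(tract_masks)) || any(!nzchar(names(tract_masks))))
    stop("'tract_masks' must be a named list", call. = FALSE)
  cats <- if (length(category) == 1L)
    stats::setNames(rep(category, length(tract_masks)), names(tract_masks))
  else category
  rows <- list()
  for (nm in names(tract_masks)) {
    rep <- classify_mask(tract_masks[[nm]], grid,
                         min_overlap_mm3 = min_overlap_mm3)
    if (rep$n_cells == 0L) {
      warning("tract mask '", nm, "' has no cells above threshold; dropped",
              call. = FALSE)
      next
    }
    hemi <- "midline"
    name <- nm
    if (grepl("\\.(L|R)$", nm)) {
      hemi <- sub("^.*\\.", "", nm)
      name <- sub("\\.(L|R)$", "", nm)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(name = name, hemisphere = hemi,
                 category = unname(cats[nm]),
                 cells = I(list(rep$cells$label)),
                 provenance = sprintf("mask-derived (min overlap %g mm^3)",
                                      min_overlap_mm3),
                 stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    stop("no non-empty tract masks supplied", call. = FALSE)
  df <- do.call(rbind, rows)
  class(df$cells) <- NULL
  attr(df, "provenance") <- "mask-derived"
  class(df) <- c("tract_table", "data.frame")
  df
}
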