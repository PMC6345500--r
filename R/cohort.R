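# Cohort tables, summaries, and per-cell infiltration frequency maps.

.COHORT_COLUMNS <- c("patient_id", "gender", "age", "histology", "who_grade",
                     "side", "local_anatomy", "margins", "volume_cm3",
                     "bg_voxels", "onset", "procedure", "n_mri")

.cohort_codes <- list(gender = c("M", "F"), histology = c("A", "O"),
                      who_grade = c("2", "3"), side = c("R", "L", "B"),
                      margins = c("B", "D"), procedure = c("R", "B"))

#' Load a cohort table
#'
#' Reads a CSV with one row per patient and the columns `patient_id`,
#' `gender` (M/F), `age` (years), `histology` (A astrocytoma / O
#' oligodendroglioma), `who_grade` (2/3), `side` (R/L/B), `local_anatomy`
#' (lobar annotation, free text), `margins` (B bulky / D diffuse),
#' `volume_cm3`, `bg_voxels` (number of infiltrated grid cells, 1-48),
#' `onset`, `procedure` (R resection / B biopsy), `n_mri`, and optionally
#' `cells` (semicolon-separated grid-cell labels, whose count must equal
#' `bg_voxels`). The default loads the shipped transcription of the
#' 39-patient WHO grade II-III glioma cohort.
#'
#' @param path Path to a CSV file; `NULL` loads the shipped cohort.
#' @return A data frame of class `cohort_table` (row numbers preserved for
#'   error reporting; `cells`, when present, is a list column).
#' @examples
#' nrow(load_cohort_table())  # 39
#' @export
load_cohort_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cohort_table1.csv",
                        package = "braingrid", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  miss <- setdiff(.COHORT_COLUMNS, names(df))
  if (length(miss) > 0L)
    stop("cohort table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  .bad <- function(col, ok) {
    i <- which(!df[[col]] %in% ok)
    if (length(i) > 0L)
      stop("invalid ", col, " '", df[[col]][i[1L]], "' in row ", i[1L],
           " (expected ", paste(ok, collapse = "/"), ")", call. = FALSE)
  }
  for (col in names(.cohort_codes)) .bad(col, .cohort_codes[[col]])
  .num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    i <- which(is.na(v))
    if (length(i) > 0L)
      stop("non-numeric ", col, " '", df[[col]][i[1L]], "' in row ", i[1L],
           call. = FALSE)
    v
  }
  df$age <- .num("age")
  df$volume_cm3 <- .num("volume_cm3")
  df$bg_voxels <- as.integer(.num("bg_voxels"))
  df$n_mri <- as.integer(.num("n_mri"))
  df$who_grade <- as.integer(df$who_grade)
  if (any(df$volume_cm3 <= 0))
    stop("volume_cm3 must be positive (row ",
         which(df$volume_cm3 <= 0)[1L], ")", call. = FALSE)
  bad_bg <- which(df$bg_voxels < 1L | df$bg_voxels > 48L)
  if (length(bad_bg) > 0L)
    stop("bg_voxels must be in 1-48 (row ", bad_bg[1L], " has ",
         df$bg_voxels[bad_bg[1L]], ")", call. = FALSE)
  if ("cells" %in% names(df)) {
    cl <- strsplit(df$cells, ";", fixed = TRUE)
    cl <- lapply(cl, function(x) x[nzchar(x)])
    for (i in seq_along(cl)) {
      if (length(cl[[i]]) == 0L) next
      cl[[i]] <- tryCatch(canonical_label(trimws(cl[[i]])),
                          error = function(e)
                            stop("invalid cell label in row ", i, ": ",
                                 conditionMessage(e), call. = FALSE))
      if (length(unique(cl[[i]])) != df$bg_voxels[i])
        stop("row ", i, ": cells column lists ",
             length(unique(cl[[i]])), " cells but bg_voxels is ",
             df$bg_voxels[i], call. = FALSE)
    }
    df$cells <- cl
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Summarize a glioma cohort
#'
#' Counts by histology, grade, margins, side and procedure, means and ranges
#' of age, tumor volume and infiltrated grid-cell count, and subgroup means
#' (bulky/diffuse, grade II/III). Raw unrounded values are retained; the
#' print method rounds to one decimal for display.
#'
#' @param records A `cohort_table`.
#' @return A list of class `cohort_summary`.
#' @examples
#' cohort_summary(load_cohort_table())
#' @export
cohort_summary <- function(records) {
  stopifnot(inherits(records, "cohort_table"))
  if (nrow(records) == 0L)
    stop("empty cohort", call. = FALSE)
  cnt <- function(col) {
    t <- table(factor(records[[col]], levels = .cohort_codes[[col]]))
    stats::setNames(as.integer(t), names(t))
  }
  grade_split <- table(factor(records$histology, levels = c("A", "O")),
                       factor(records$who_grade, levels = c(2L, 3L)))
  rng <- function(v) c(mean = mean(v), min = min(v), max = max(v))
  sub_mean <- function(sel) if (any(sel)) mean(records$bg_voxels[sel]) else NA_real_
  structure(list(
    n = nrow(records),
    histology = cnt("histology"),
    histology_by_grade = grade_split,
    margins = cnt("margins"),
    side = cnt("side"),
    procedure = cnt("procedure"),
    age = rng(records$age),
    volume_cm3 = rng(records$volume_cm3),
    bg_voxels = rng(records$bg_voxels),
    bg_voxels_bulky = sub_mean(records$margins == "B"),
    bg_voxels_diffuse = sub_mean(records$margins == "D"),
    bg_voxels_grade2 = sub_mean(records$who_grade == 2L),
    bg_voxels_grade3 = sub_mean(records$who_grade == 3L)),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  f1 <- function(v) format(round(v, 1), nsmall = 1)
  cat("Cohort of ", x$n, " patients\n", sep = "")
  cat("  histology: A=", x$histology["A"], " (grade II ",
      x$histology_by_grade["A", "2"], ", III ",
      x$histology_by_grade["A", "3"], "), O=", x$histology["O"],
      " (grade II ", x$histology_by_grade["O", "2"], ", III ",
      x$histology_by_grade["O", "3"], ")\n", sep = "")
  cat("  margins: bulky=", x$margins["B"], ", diffuse=", x$margins["D"],
      "\n", sep = "")
  cat("  side: L=", x$side["L"], ", R=", x$side["R"], ", bilateral=",
      x$side["B"], "\n", sep = "")
  cat("  procedure: resection=", x$procedure["R"], ", biopsy=",
      x$procedure["B"], "\n", sep = "")
  cat("  age: mean ", f1(x$age["mean"]), " (", x$age["min"], "-",
      x$age["max"], ")\n", sep = "")
  cat("  volume: mean ", f1(x$volume_cm3["mean"]), " cm^3 (",
      x$volume_cm3["min"], "-", x$volume_cm3["max"], ")\n", sep = "")
  cat("  grid cells: mean ", f1(x$bg_voxels["mean"]), " (",
      x$bg_voxels["min"], "-", x$bg_voxels["max"], "); bulky ",
      f1(x$bg_voxels_bulky), ", diffuse ", f1(x$bg_voxels_diffuse),
      "; grade II ", f1(x$bg_voxels_grade2), ", III ",
      f1(x$bg_voxels_grade3), "\n", sep = "")
  invisible(x)
}

# Frequency bin edges in percent: [0,5], (5,25], (25,50), [50,80], (80,100].
.freq_bin <- function(pct) {
  ifelse(pct <= 5, "0-5%",
         ifelse(pct <= 25, "5-25%",
                ifelse(pct < 50, "25-50%",
                       ifelse(pct <= 80, "50-80%", ">80%"))))
}

#' Per-cell infiltration frequency map
#'
#' For a stratum of the cohort (e.g. left-sided patients), the fraction of
#' records whose cell set contains each of the 48 grid cells, with the
#' display binning used for frequency maps (white 0-5% up to dark red >80%)
#' and a high-frequency flag at >= 50% of the lesions.
#'
#' @param records A `cohort_table` whose rows carry a `cells` column.
#' @param side Optional side code(s) (`"L"`, `"R"`, `"B"`) restricting the
#'   stratum; `NULL` uses all records.
#' @param which Optional logical or integer index selecting the stratum
#'   directly (applied after `side`).
#' @return A data frame of class `frequency_map` with one row per cell:
#'   `label`, `id`, `count`, `frequency` (0-1), `bin`, `high`; the stratum
#'   size is in attribute `n_records`.
#' @export
frequency_map <- function(records, side = NULL, which = NULL) {
  stopifnot(inherits(records, "cohort_table"))
  if (!"cells" %in% names(records))
    stop("frequency_map needs per-record cell sets ('cells' column)",
         call. = FALSE)
  sel <- rep(TRUE, nrow(records))
  if (!is.null(side)) sel <- sel & records$side %in% side
  df <- records[sel, , drop = FALSE]
  if (!is.null(which)) df <- df[which, , drop = FALSE]
  if (nrow(df) == 0L)
    stop("empty stratum", call. = FALSE)
  empty <- vapply(df$cells, length, 1L) == 0L
  if (any(empty))
    stop("record(s) in stratum lack cell sets: ",
         paste(df$patient_id[empty], collapse = ", "), call. = FALSE)
  counts <- integer(48L)
  for (cl in df$cells) {
    ids <- unique(cell_id(cl))
    counts[ids] <- counts[ids] + 1L
  }
  freq <- counts / nrow(df)
  out <- data.frame(label = cell_label(1:48), id = 1:48, count = counts,
                    frequency = freq, bin = .freq_bin(100 * freq),
                    high = 100 * freq >= 50, stringsAsFactors = FALSE)
  attr(out, "n_records") <- nrow(df)
  attr(out, "side") <- if (is.null(side)) "all" else paste(side, collapse = "+")
  class(out) <- c("frequency_map", "data.frame")
  out
}

#' @export
print.frequency_map <- function(x, ...) {
  cat("frequency_map over ", attr(x, "n_records"), " records (side: ",
      attr(x, "side"), ")\n", sep = "")
  top <- x[order(-x$frequency), , drop = FALSE]
  top <- top[top$count > 0L, , drop = FALSE]
  n <- min(nrow(top), 8L)
  if (n == 0L) {
    cat("  no infiltrated cells\n")
  } else {
    cat("  most frequent cells:\n")
    for (i in seq_len(n))
      cat(sprintf("    %s  %5.1f%%  [%s]%s\n", top$label[i],
                  100 * top$frequency[i], top$bin[i],
                  if (top$high[i]) " high" else ""))
  }
  invisible(x)
}
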