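# Tumor mask -> infiltration report: cells, volumes, plane distances,
# laterality.

plane_vector <- function(planes) {
  c(x_right = unname(planes$x_planes[1L]),
    x_midline = unname(planes$x_planes[2L]),
    x_left = unname(planes$x_planes[3L]),
    y_anterior_insular = unname(planes$y_planes[1L]),
    y_posterior_insular = unname(planes$y_planes[2L]),
    y_parieto_occipital = unname(planes$y_planes[3L]),
    z_callosal_cingulate = unname(planes$z_planes[1L]),
    z_inferior_insular = unname(planes$z_planes[2L]))
}

new_infiltration_report <- function(cells, total_volume_mm3, plane_distances,
                                    space_tag, study_id = NA_character_,
                                    date = NA_character_) {
  lat <- .laterality_from_cells(cells$label)
  structure(list(study_id = study_id, date = date, space_tag = space_tag,
                 cells = cells, n_cells = nrow(cells),
                 total_volume_cm3 = total_volume_mm3 / 1000,
                 plane_distances = plane_distances, laterality = lat),
            class = "infiltration_report")
}

#' Assemble an infiltration report from cell labels
#'
#' Builds an [classify_mask()]-style report directly from labels (and
#' optional per-cell volumes), e.g. when transcribing a visually read study
#' or exchanging reports between tools.
#'
#' @param labels Character vector of infiltrated cell labels.
#' @param volumes_mm3 Optional per-cell overlap volumes (mm^3), recycled.
#' @param space_tag Coordinate space of the study.
#' @param study_id,date Optional study identifier and ISO date.
#' @param plane_distances Optional named numeric of the eight plane distances.
#' @return An `infiltration_report`.
#' @examples
#' infiltration_report(c("A2C2S1"), study_id = "case1-2002")
#' @export
infiltration_report <- function(labels, volumes_mm3 = 0, space_tag = "MNI",
                                study_id = NA_character_,
                                date = NA_character_,
                                plane_distances = NULL) {
  labels <- canonical_label(labels)
  if (anyDuplicated(labels))
    stop("duplicated cell label: ", labels[duplicated(labels)][1L],
         call. = FALSE)
  volumes_mm3 <- rep_len(as.numeric(volumes_mm3), length(labels))
  cells <- data.frame(label = labels, id = cell_id(labels),
                      volume_mm3 = volumes_mm3, stringsAsFactors = FALSE)
  cells <- cells[order(cells$id), , drop = FALSE]
  rownames(cells) <- NULL
  if (is.null(plane_distances))
    plane_distances <- stats::setNames(rep(NA_real_, 8L),
                                       names(plane_vector(default_planes("MNI"))))
  new_infiltration_report(cells, sum(volumes_mm3), plane_distances,
                          space_tag, study_id, date)
}

.laterality_from_cells <- function(labels) {
  if (length(labels) == 0L) return("indeterminate")
  a <- parse_label(labels)[, "a"]
  right <- any(a <= 2L)
  left <- any(a >= 3L)
  if (right && left) "bilateral" else if (left) "left" else "right"
}

#' Classify a tumor mask against the Brain-Grid
#'
#' Computes per-cell overlap volumes by voxel-center membership: each
#' foreground voxel is assigned to the cell containing its center, and a
#' cell counts as infiltrated when its overlap volume exceeds
#' `min_overlap_mm3` (default 0, i.e. any non-zero overlap counts). The
#' per-cell volumes of infiltrated cells at threshold 0 sum exactly to the
#' total foreground volume.
#'
#' @param mask A [volume_mask()].
#' @param grid A [brain_grid()]; its space tag should match the mask's.
#' @param min_overlap_mm3 Minimum overlap volume (mm^3) for a cell to count
#'   as infiltrated.
#' @param study_id,date Optional study identifier and ISO date carried into
#'   the report.
#' @return An object of class `infiltration_report`: `cells` (data frame
#'   `label`, `id`, `volume_mm3`), `n_cells`, `total_volume_cm3`,
#'   `plane_distances` (eight named minimum unsigned distances, mm; `NA`
#'   for an empty mask) and `laterality` (`"left"`, `"right"`,
#'   `"bilateral"` or `"indeterminate"`).
#' @examples
#' geo <- make_reference_geometry(c(41, 41, 41), 2)
#' g <- brain_grid("MNI")
#' les <- make_ellipsoid_lesion(lesion_spec(c(-10, 0, 0), 5), geo)
#' classify_mask(les, g)
#' @export
classify_mask <- function(mask, grid, min_overlap_mm3 = 0,
                          study_id = NA_character_, date = NA_character_) {
  stopifnot(inherits(mask, "volume_mask"), inherits(grid, "brain_grid"))
  if (min_overlap_mm3 < 0)
    stop("'min_overlap_mm3' must be >= 0", call. = FALSE)
  coords <- mask_foreground_coords(mask)
  pv <- plane_vector(grid$planes)
  if (nrow(coords) == 0L) {
    cells <- data.frame(label = character(0), id = integer(0),
                        volume_mm3 = numeric(0), stringsAsFactors = FALSE)
    return(new_infiltration_report(cells, 0,
                                   stats::setNames(rep(NA_real_, 8L),
                                                   names(pv)),
                                   grid$planes$space_tag, study_id, date))
  }
  ids <- label_point_id(coords, grid)
  counts <- tabulate(ids, nbins = 48L)
  vols <- counts * mask$voxel_volume
  keep <- which(vols > min_overlap_mm3)
  cells <- data.frame(label = cell_label(keep), id = keep,
                      volume_mm3 = vols[keep], stringsAsFactors = FALSE)
  rownames(cells) <- NULL
  dists <- .plane_distances_from_coords(coords, pv)
  new_infiltration_report(cells, sum(vols), dists, grid$planes$space_tag,
                          study_id, date)
}

.plane_distances_from_coords <- function(coords, pv) {
  axis <- c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L)
  d <- vapply(seq_along(pv), function(i) {
    v <- coords[, axis[i]]
    if (min(v) <= pv[i] && max(v) >= pv[i]) return(0)
    min(abs(v - pv[i]))
  }, numeric(1))
  stats::setNames(d, names(pv))
}

#' Minimum distances from a tumor border to each grid plane
#'
#' For each of the eight landmark planes, the minimum over foreground voxel
#' centers of the unsigned distance (mm) to the plane; 0 when the foreground
#' spans the plane. Distances are compared across serial studies to track
#' approach toward a grid line.
#'
#' @param mask A non-empty [volume_mask()].
#' @param grid A [brain_grid()].
#' @return Named numeric vector of length 8.
#' @export
plane_distances <- function(mask, grid) {
  stopifnot(inherits(mask, "volume_mask"), inherits(grid, "brain_grid"))
  coords <- mask_foreground_coords(mask)
  if (nrow(coords) == 0L)
    stop("plane distances are undefined for an empty mask", call. = FALSE)
  .plane_distances_from_coords(coords, plane_vector(grid$planes))
}

#' Laterality of an infiltration report
#'
#' A1/A2 cells lie in the right hemisphere, A3/A4 in the left (radiological
#' convention: A1 is the patient's right). A study is bilateral when both
#' sides carry infiltrated cells.
#'
#' @param report An `infiltration_report`.
#' @return List with `laterality` and per-side infiltrated-cell counts
#'   `n_right`, `n_left`.
#' @examples
#' laterality_summary(infiltration_report(c("A2C2S1", "A3C2S1")))
#' @export
laterality_summary <- function(report) {
  stopifnot(inherits(report, "infiltration_report"))
  labels <- report$cells$label
  if (length(labels) == 0L)
    return(list(laterality = "indeterminate", n_right = 0L, n_left = 0L))
  a <- parse_label(labels)[, "a"]
  list(laterality = .laterality_from_cells(labels),
       n_right = sum(a <= 2L), n_left = sum(a >= 3L))
}

#' @export
print.infiltration_report <- function(x, ...) {
  id <- if (is.na(x$study_id)) "" else paste0(" [", x$study_id, "]")
  cat("Brain-Grid infiltration report", id, " (", x$space_tag, " space)\n",
      sep = "")
  cat("  infiltrated cells: ", x$n_cells, " / 48", sep = "")
  if (x$n_cells > 0L)
    cat(" (", paste(x$cells$label, collapse = ", "), ")", sep = "")
  cat("\n  total volume: ", signif(x$total_volume_cm3, 4), " cm^3\n",
      "  laterality: ", x$laterality, "\n", sep = "")
  invisible(x)
}

#' @export
summary.infiltration_report <- function(object, ...) {
  print(object)
  if (object$n_cells > 0L) {
    cat("  per-cell volumes (mm^3):\n")
    df <- object$cells
    df$volume_mm3 <- signif(df$volume_mm3, 5)
    print(df, row.names = FALSE)
  }
  if (!all(is.na(object$plane_distances))) {
    cat("  plane distances (mm):\n")
    print(round(object$plane_distances, 2))
  }
  invisible(object)
}

#' Write an infiltration report to JSON
#'
#' @param report An `infiltration_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "infiltration_report"))
  cells <- lapply(seq_len(nrow(report$cells)), function(i)
    list(label = report$cells$label[i], id = report$cells$id[i],
         volume_mm3 = report$cells$volume_mm3[i]))
  doc <- list(study_id = report$study_id, date = report$date,
              space = report$space_tag, n_cells = report$n_cells,
              cells = cells, total_volume_cm3 = report$total_volume_cm3,
              plane_distances = as.list(report$plane_distances),
              laterality = report$laterality)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read an infiltration report from JSON
#'
#' @param path Path to a JSON report written by [write_report()].
#' @return An `infiltration_report`.
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  labels <- vapply(doc$cells, function(c) c$label, "")
  vols <- vapply(doc$cells, function(c) as.numeric(c$volume_mm3), 0)
  pd <- vapply(doc$plane_distances,
               function(v) if (is.null(v)) NA_real_ else as.numeric(v),
               numeric(1))
  if (length(pd) == 0L) pd <- NULL
  infiltration_report(labels, vols, space_tag = doc$space,
                      study_id = if (is.null(doc$study_id)) NA_character_
                                 else doc$study_id,
                      date = if (is.null(doc$date)) NA_character_
                             else doc$date,
                      plane_distances = pd)
}
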