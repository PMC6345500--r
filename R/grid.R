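# Brain-Grid geometry: landmark planes, the 48-cell partition, labeling.

# Printed landmark-plane constants for the two standard spaces (world mm).
.BG_DEFAULT_PLANES <- list(
  MNI = list(
    x_planes = c(right = 33, midline = 0, left = -33),
    y_planes = c(anterior_insular = 28, posterior_insular = -23,
                 parieto_occipital = -68),
    z_planes = c(callosal_cingulate = 33, inferior_insular = -13)
  ),
  Talairach = list(
    x_planes = c(right = 32, midline = 0, left = -32),
    y_planes = c(anterior_insular = 25, posterior_insular = -24,
                 parieto_occipital = -66),
    z_planes = c(callosal_cingulate = 31, inferior_insular = -7)
  )
)

#' Landmark planes of the Brain-Grid
#'
#' Eight world-mm plane coordinates that partition the brain: three lateral
#' (x) planes at the right and left middle frontal sulcus and the midline,
#' three sagittal-axis (y) planes at the anterior insular point, posterior
#' insular point and parieto-occipital sulcus, and two axial-axis (z) planes
#' at the callosal-cingulate space and the inferior insular point. World
#' coordinates follow the RAS+ convention (right = +x, anterior = +y,
#' superior = +z), so each vector must be strictly decreasing.
#'
#' @param x_planes Numeric length 3: right, midline, left lateral planes (mm).
#' @param y_planes Numeric length 3: anterior-insular, posterior-insular,
#'   parieto-occipital planes (mm).
#' @param z_planes Numeric length 2: callosal-cingulate, inferior-insular
#'   planes (mm).
#' @param space_tag `"MNI"`, `"Talairach"` or `"subject"` (patient-specific
#'   landmark placement).
#' @return An object of class `grid_planes`.
#' @examples
#' grid_planes(c(33, 0, -33), c(28, -23, -68), c(33, -13), "MNI")
#' @seealso [brain_grid()], [read_planes_json()]
#' @export
grid_planes <- function(x_planes, y_planes, z_planes,
                        space_tag = c("subject", "MNI", "Talairach")) {
  space_tag <- match.arg(space_tag)
  x_planes <- as.numeric(x_planes)
  y_planes <- as.numeric(y_planes)
  z_planes <- as.numeric(z_planes)
  if (length(x_planes) != 3L || length(y_planes) != 3L || length(z_planes) != 2L)
    stop("need 3 x-planes, 3 y-planes and 2 z-planes", call. = FALSE)
  if (anyNA(c(x_planes, y_planes, z_planes)) ||
      any(!is.finite(c(x_planes, y_planes, z_planes))))
    stop("plane coordinates must be finite", call. = FALSE)
  if (any(diff(x_planes) >= 0))
    stop("x_planes must be strictly decreasing (right, midline, left)",
         call. = FALSE)
  if (any(diff(y_planes) >= 0))
    stop("y_planes must be strictly decreasing (anterior to posterior)",
         call. = FALSE)
  if (any(diff(z_planes) >= 0))
    stop("z_planes must be strictly decreasing (superior to inferior)",
         call. = FALSE)
  names(x_planes) <- names(.BG_DEFAULT_PLANES$MNI$x_planes)
  names(y_planes) <- names(.BG_DEFAULT_PLANES$MNI$y_planes)
  names(z_planes) <- names(.BG_DEFAULT_PLANES$MNI$z_planes)
  structure(list(x_planes = x_planes, y_planes = y_planes,
                 z_planes = z_planes, space_tag = space_tag),
            class = "grid_planes")
}

#' Default landmark planes for a standard space
#'
#' @param space_tag `"MNI"` or `"Talairach"`.
#' @return A [grid_planes()] object with the published constants.
#' @examples
#' default_planes("MNI")$y_planes
#' @export
default_planes <- function(space_tag = c("MNI", "Talairach")) {
  if (length(space_tag) == 1L && !space_tag %in% c("MNI", "Talairach"))
    stop("unknown space_tag '", space_tag,
         "'; valid tags are 'MNI' and 'Talairach'", call. = FALSE)
  space_tag <- match.arg(space_tag)
  p <- .BG_DEFAULT_PLANES[[space_tag]]
  grid_planes(p$x_planes, p$y_planes, p$z_planes, space_tag)
}

#' Construct a Brain-Grid
#'
#' Builds the 48-cell grid either from the published landmark constants of a
#' standard space or from subject-specific landmark planes (the grid lines
#' are drawn on each patient's own landmarks; the published constants
#' describe the average brain).
#'
#' @param space_tag `"MNI"` (default) or `"Talairach"`; ignored when `planes`
#'   is supplied.
#' @param planes Optional [grid_planes()] object overriding the defaults.
#' @return An object of class `brain_grid` with elements `planes` and
#'   `cells` (a 48-row data frame with columns `id`, `a`, `c`, `s`, `label`).
#' @examples
#' g <- brain_grid("MNI")
#' nrow(g$cells)           # 48
#' label_point(c(-10, 0, 0), g)
#' @export
brain_grid <- function(space_tag = c("MNI", "Talairach"), planes = NULL) {
  if (is.null(planes)) {
    planes <- default_planes(space_tag)
  } else if (!inherits(planes, "grid_planes")) {
    stop("'planes' must be a grid_planes object", call. = FALSE)
  }
  ids <- 1:48
  acs <- cell_label_parts(ids)
  cells <- data.frame(id = ids, a = acs[, "a"], c = acs[, "c"], s = acs[, "s"],
                      label = make_label(acs[, "a"], acs[, "c"], acs[, "s"]),
                      stringsAsFactors = FALSE)
  structure(list(planes = planes, cells = cells), class = "brain_grid")
}

#' @export
print.brain_grid <- function(x, ...) {
  p <- x$planes
  cat("Brain-Grid (", p$space_tag, " space): ", nrow(x$cells),
      " cells A(1-4) x C(1-3) x S(1-4)\n", sep = "")
  cat("  x planes (lateral):  ", paste(p$x_planes, collapse = ", "), " mm\n",
      sep = "")
  cat("  y planes (sagittal): ", paste(p$y_planes, collapse = ", "), " mm\n",
      sep = "")
  cat("  z planes (axial):    ", paste(p$z_planes, collapse = ", "), " mm\n",
      sep = "")
  invisible(x)
}

#' @export
print.grid_planes <- function(x, ...) {
  cat("Brain-Grid landmark planes (", x$space_tag, " space)\n", sep = "")
  cat("  x:", paste(sprintf("%s=%g", names(x$x_planes), x$x_planes),
                    collapse = ", "), "\n")
  cat("  y:", paste(sprintf("%s=%g", names(x$y_planes), x$y_planes),
                    collapse = ", "), "\n")
  cat("  z:", paste(sprintf("%s=%g", names(x$z_planes), x$z_planes),
                    collapse = ", "), "\n")
  invisible(x)
}

#' Build a canonical cell label string
#'
#' @param a,c,s Integer axial (1-4), coronal (1-3) and sagittal (1-4) indices;
#'   recycled to a common length.
#' @return Character vector of canonical labels, e.g. `"A3C2S2"`.
#' @examples
#' make_label(3, 2, 2)
#' @export
make_label <- function(a, c, s) {
  n <- max(length(a), length(c), length(s))
  a <- rep_len(as.integer(a), n)
  c <- rep_len(as.integer(c), n)
  s <- rep_len(as.integer(s), n)
  .check_acs(a, c, s)
  sprintf("A%dC%dS%d", a, c, s)
}

.check_acs <- function(a, c, s) {
  if (anyNA(a) || anyNA(c) || anyNA(s))
    stop("cell indices must not be NA", call. = FALSE)
  if (any(a < 1L | a > 4L))
    stop("axial index a out of range 1-4: ",
         paste(unique(a[a < 1L | a > 4L]), collapse = ", "), call. = FALSE)
  if (any(c < 1L | c > 3L))
    stop("coronal index c out of range 1-3: ",
         paste(unique(c[c < 1L | c > 3L]), collapse = ", "), call. = FALSE)
  if (any(s < 1L | s > 4L))
    stop("sagittal index s out of range 1-4: ",
         paste(unique(s[s < 1L | s > 4L]), collapse = ", "), call. = FALSE)
  invisible(NULL)
}

#' Parse Brain-Grid cell labels
#'
#' Accepts the compact (`"A3C2S2"`) and dashed (`"A3-C2-S2"`) nomenclature,
#' case-insensitively.
#'
#' @param x Character vector of labels.
#' @return Integer matrix with one row per label and columns `a`, `c`, `s`.
#' @examples
#' parse_label("A3-C2-S2")
#' parse_label(c("a3c2s1", "A1C1S1"))
#' @export
parse_label <- function(x) {
  x <- as.character(x)
  m <- regmatches(x, regexec("^[Aa]([0-9]+)-?[Cc]([0-9]+)-?[Ss]([0-9]+)$",
                             trimws(x)))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("malformed grid label: '", x[bad][1L], "'", call. = FALSE)
  a <- as.integer(vapply(m, `[`, "", 2L))
  c <- as.integer(vapply(m, `[`, "", 3L))
  s <- as.integer(vapply(m, `[`, "", 4L))
  out_a <- a < 1L | a > 4L
  out_c <- c < 1L | c > 3L
  out_s <- s < 1L | s > 4L
  if (any(out_a | out_c | out_s))
    stop("grid label index out of range in '", x[out_a | out_c | out_s][1L],
         "' (a in 1-4, c in 1-3, s in 1-4)", call. = FALSE)
  cbind(a = a, c = c, s = s)
}

#' Canonicalize cell labels
#'
#' @param x Character vector of labels in any accepted form.
#' @return Labels in canonical `"A{a}C{c}S{s}"` form.
#' @examples
#' canonical_label("a3-c2-s2")
#' @export
canonical_label <- function(x) {
  p <- parse_label(x)
  make_label(p[, "a"], p[, "c"], p[, "s"])
}

#' Integer cell IDs and their inverse
#'
#' The fixed bijection between the 48 labels and IDs 1-48 used in exported
#' labelmaps: `id = (a - 1) * 12 + (c - 1) * 4 + s`. The formula is part of
#' the file format, so labelmaps are bit-stable across versions.
#'
#' @param label Character vector of cell labels.
#' @return `cell_id()`: integer vector of IDs in 1-48.
#' @examples
#' cell_id("A3C2S2")   # 30
#' cell_label(25)      # "A3C1S1"
#' @export
cell_id <- function(label) {
  p <- parse_label(label)
  as.integer((p[, "a"] - 1L) * 12L + (p[, "c"] - 1L) * 4L + p[, "s"])
}

# id -> (a, c, s) matrix
cell_label_parts <- function(id) {
  id <- as.integer(id)
  if (anyNA(id) || any(id < 1L | id > 48L))
    stop("cell id out of range 1-48: ",
         paste(unique(id[is.na(id) | id < 1L | id > 48L]), collapse = ", "),
         call. = FALSE)
  z <- id - 1L
  cbind(a = z %/% 12L + 1L, c = (z %% 12L) %/% 4L + 1L, s = z %% 4L + 1L)
}

#' @rdname cell_id
#' @param id Integer vector of cell IDs in 1-48.
#' @return `cell_label()`: character vector of canonical labels.
#' @export
cell_label <- function(id) {
  p <- cell_label_parts(id)
  make_label(p[, "a"], p[, "c"], p[, "s"])
}

#' Label world-space points with Brain-Grid cells
#'
#' Assigns each point the unique cell whose half-open slab intervals contain
#' it. The axial index A increases as x decreases (A1 is the patient's right,
#' largest x), C increases as z decreases (cranio-caudal) and S increases as
#' y decreases (anterior-posterior). A point lying exactly on a plane belongs
#' to the lower-index (right/cranial/anterior) slab, so the partition is
#' exhaustive and non-overlapping.
#'
#' @param points Numeric length-3 vector or n x 3 matrix of world-mm
#'   coordinates (RAS+).
#' @param grid A [brain_grid()].
#' @return Character vector of canonical cell labels, one per point.
#' @examples
#' g <- brain_grid("MNI")
#' label_point(c(-10, 0, 0), g)          # "A3C2S2"
#' label_point(rbind(c(50, 40, 50), c(0, 28, 33)), g)
#' @export
label_point <- function(points, grid) {
  stopifnot(inherits(grid, "brain_grid"))
  if (is.null(dim(points))) {
    if (length(points) != 3L)
      stop("'points' must be a length-3 vector or an n x 3 matrix",
           call. = FALSE)
    points <- matrix(points, ncol = 3L)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop("'points' must have 3 columns (x, y, z)", call. = FALSE)
  if (anyNA(points) || any(!is.finite(points)))
    stop("point coordinates must be finite", call. = FALSE)
  p <- grid$planes
  a <- 1L + (points[, 1L] < p$x_planes[1L]) + (points[, 1L] < p$x_planes[2L]) +
    (points[, 1L] < p$x_planes[3L])
  c <- 1L + (points[, 3L] < p$z_planes[1L]) + (points[, 3L] < p$z_planes[2L])
  s <- 1L + (points[, 2L] < p$y_planes[1L]) + (points[, 2L] < p$y_planes[2L]) +
    (points[, 2L] < p$y_planes[3L])
  make_label(a, c, s)
}

# Vectorized point -> cell id (internal fast path used by classification).
label_point_id <- function(points, grid) {
  p <- grid$planes
  a <- 1L + (points[, 1L] < p$x_planes[1L]) + (points[, 1L] < p$x_planes[2L]) +
    (points[, 1L] < p$x_planes[3L])
  c <- 1L + (points[, 3L] < p$z_planes[1L]) + (points[, 3L] < p$z_planes[2L])
  s <- 1L + (points[, 2L] < p$y_planes[1L]) + (points[, 2L] < p$y_planes[2L]) +
    (points[, 2L] < p$y_planes[3L])
  as.integer((a - 1L) * 12L + (c - 1L) * 4L + s)
}

#' Mirror a cell across the midline
#'
#' Maps A1 to A4, A2 to A3 (and vice versa), keeping C and S: the
#' contralateral-landmark fallback used when a tumor infiltrates or
#' dislocates a landmark. The operation is an involution.
#'
#' @param label Character vector of cell labels.
#' @return Mirrored canonical labels.
#' @examples
#' mirror_label("A1C2S2")  # "A4C2S2"
#' @export
mirror_label <- function(label) {
  p <- parse_label(label)
  make_label(5L - p[, "a"], p[, "c"], p[, "s"])
}

#' Face-adjacent cells in the grid lattice
#'
#' Neighbors differing by one step on exactly one axis of the 4 x 3 x 4
#' lattice; midline adjacency A2-A3 is included. Used to propose contiguous
#' white-matter spread routes.
#'
#' @param label A single cell label.
#' @return Character vector of neighboring canonical labels, in cell-ID order.
#' @examples
#' adjacent_cells("A1C1S1")
#' @export
adjacent_cells <- function(label) {
  p <- parse_label(label)
  if (nrow(p) != 1L)
    stop("'label' must be a single cell label", call. = FALSE)
  steps <- rbind(c(-1L, 0L, 0L), c(1L, 0L, 0L),
                 c(0L, -1L, 0L), c(0L, 1L, 0L),
                 c(0L, 0L, -1L), c(0L, 0L, 1L))
  cand <- sweep(steps, 2L, as.integer(p), "+")
  keep <- cand[, 1L] >= 1L & cand[, 1L] <= 4L &
    cand[, 2L] >= 1L & cand[, 2L] <= 3L &
    cand[, 3L] >= 1L & cand[, 3L] <= 4L
  cand <- cand[keep, , drop = FALSE]
  lab <- make_label(cand[, 1L], cand[, 2L], cand[, 3L])
  lab[order(cell_id(lab))]
}

#' Read a landmark-plane override from JSON
#'
#' The document has the form
#' `{"space_tag": "subject", "x_planes": [..], "y_planes": [..], "z_planes": [..]}`.
#'
#' @param path Path to a JSON file.
#' @return A [grid_planes()] object.
#' @export
read_planes_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("x_planes", "y_planes", "z_planes")
  miss <- setdiff(need, names(doc))
  if (length(miss) > 0L)
    stop("planes JSON is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tag <- if (is.null(doc$space_tag)) "subject" else as.character(doc$space_tag)
  grid_planes(doc$x_planes, doc$y_planes, doc$z_planes, tag)
}

#' Write landmark planes to JSON
#'
#' @param planes A [grid_planes()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_planes_json <- function(planes, path) {
  stopifnot(inherits(planes, "grid_planes"))
  jsonlite::write_json(
    list(space_tag = planes$space_tag,
         x_planes = unname(planes$x_planes),
         y_planes = unname(planes$y_planes),
         z_planes = unname(planes$z_planes)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
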