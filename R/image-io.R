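# NIfTI volume I/O, affine handling, canonical orientation, labelmap export.

#' In-memory binary volume with an affine
#'
#' The unit of tumor/tract input: a 3-D logical array plus the 4 x 4 affine
#' mapping 1-based voxel indices (minus one, i.e. NIfTI 0-based indices) to
#' world millimetres. The voxel volume is the absolute determinant of the
#' affine's 3 x 3 linear part.
#'
#' @param data 3-D array; non-logical input is thresholded at > 0.5.
#' @param affine 4 x 4 numeric voxel-to-world matrix (must be invertible).
#' @param space_tag Coordinate space of the world coordinates.
#' @return An object of class `volume_mask` with elements `data`, `affine`,
#'   `voxel_volume` (mm^3) and `space_tag`.
#' @examples
#' m <- volume_mask(array(c(rep(FALSE, 13), TRUE, rep(FALSE, 13)),
#'                        dim = c(3, 3, 3)), diag(4))
#' mask_volume(m)  # 1 mm^3
#' @export
volume_mask <- function(data, affine, space_tag = "MNI") {
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3-D array (got ", length(dim(data)),
         " dimensions)", call. = FALSE)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || anyNA(affine) ||
      any(!is.finite(affine)))
    stop("'affine' must be a finite 4 x 4 matrix", call. = FALSE)
  lin <- affine[1:3, 1:3]
  dt <- det(lin)
  if (!is.finite(dt) || abs(dt) < .Machine$double.eps * 100)
    stop("affine is singular (determinant ", signif(dt, 3), ")",
         call. = FALSE)
  if (!is.logical(data))
    data <- array(as.numeric(data) > 0.5, dim = dim(data))
  data[is.na(data)] <- FALSE
  structure(list(data = data, affine = unname(affine),
                 voxel_volume = abs(dt), space_tag = space_tag),
            class = "volume_mask")
}

#' @export
print.volume_mask <- function(x, ...) {
  n <- sum(x$data)
  cat("volume_mask: ", paste(dim(x$data), collapse = " x "),
      " voxels (", x$space_tag, " space), voxel volume ",
      signif(x$voxel_volume, 4), " mm^3\n", sep = "")
  cat("  foreground: ", n, " voxels = ", signif(n * x$voxel_volume / 1000, 4),
      " cm^3\n", sep = "")
  invisible(x)
}

#' Total foreground volume of a mask
#'
#' @param mask A [volume_mask()].
#' @param units `"mm3"` or `"cm3"`.
#' @return Foreground volume in the requested units.
#' @export
mask_volume <- function(mask, units = c("mm3", "cm3")) {
  stopifnot(inherits(mask, "volume_mask"))
  units <- match.arg(units)
  v <- sum(mask$data) * mask$voxel_volume
  if (units == "cm3") v / 1000 else v
}

# World coordinates of voxel centers for 1-based index matrix (n x 3).
voxel_centers <- function(index, affine) {
  index <- as.matrix(index)
  h <- cbind(index - 1, 1)
  out <- h %*% t(affine)
  out[, 1:3, drop = FALSE]
}

# World coordinates of the foreground voxel centers of a mask.
mask_foreground_coords <- function(mask) {
  idx <- which(mask$data, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(matrix(numeric(0), ncol = 3L))
  voxel_centers(idx, mask$affine)
}

#' Read a binary mask from a NIfTI file
#'
#' Loads a 3-D NIfTI volume, reorients the array to canonical RAS+ axis
#' order (world coordinates of voxel centers are unchanged by the
#' reorientation) and thresholds it to a binary foreground.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param foreground_threshold Values strictly greater than this are
#'   foreground (default 0.5, sensible for both binary and probabilistic
#'   segmentations).
#' @param space_tag Coordinate space the file's world coordinates live in.
#' @return A [volume_mask()].
#' @export
read_mask <- function(path, foreground_threshold = 0.5, space_tag = "MNI") {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  d <- dim(img)
  if (length(d) == 4L && d[4L] == 1L) {
    img <- RNifti::asNifti(array(img[, , , 1L], dim = d[1:3]),
                           reference = img)
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop("'", path, "' is not a 3-D volume (", length(d), " dimensions)",
         call. = FALSE)
  hdr <- RNifti::niftiHeader(img)
  if (hdr$sform_code > 0L || hdr$qform_code > 0L)
    RNifti::orientation(img) <- "RAS"   # untagged files are taken as RAS
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  arr <- array(as.numeric(img), dim = dim(img))
  volume_mask(arr > foreground_threshold, aff, space_tag = space_tag)
}

# Shared NIfTI writer: sets pixdim before the xforms so spacing survives the
# round trip, and stamps both sform and qform with the same matrix.
write_nifti_volume <- function(arr, affine, path, datatype = "auto") {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a mask to a NIfTI file
#'
#' @param mask A [volume_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "volume_mask"))
  arr <- array(as.integer(mask$data), dim = dim(mask$data))
  write_nifti_volume(arr, mask$affine, path, datatype = "uint8")
}

#' Reference voxel geometry centered on the world origin
#'
#' Builds an RAS+ axis-aligned geometry whose world origin (0, 0, 0) lies at
#' the volume center; with odd dimensions the central voxel maps exactly to
#' the origin. Used to rasterize grids and synthetic lesions.
#'
#' @param shape Integer length 3: array dimensions.
#' @param voxel_size_mm Positive voxel edge length(s), scalar or length 3.
#' @param space_tag Coordinate space tag (default `"MNI"`).
#' @return An object of class `reference_geometry` with elements `shape`,
#'   `affine` and `space_tag`.
#' @examples
#' make_reference_geometry(c(91, 109, 91), 2)
#' @export
make_reference_geometry <- function(shape, voxel_size_mm = 1,
                                    space_tag = "MNI") {
  shape <- as.integer(shape)
  if (length(shape) != 3L || anyNA(shape) || any(shape < 1L))
    stop("'shape' must be 3 positive integers", call. = FALSE)
  vs <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (anyNA(vs) || any(vs <= 0))
    stop("'voxel_size_mm' must be positive", call. = FALSE)
  affine <- diag(c(vs, 1))
  affine[1:3, 4L] <- -vs * (shape - 1L) / 2
  structure(list(shape = shape, affine = affine, space_tag = space_tag),
            class = "reference_geometry")
}

#' @export
print.reference_geometry <- function(x, ...) {
  vs <- sqrt(colSums(x$affine[1:3, 1:3]^2))
  cat("reference_geometry: ", paste(x$shape, collapse = " x "), " voxels, ",
      paste(signif(vs, 4), collapse = " x "), " mm (", x$space_tag,
      " space)\n", sep = "")
  invisible(x)
}

# Geometry (shape + affine) of an existing NIfTI file, reoriented to RAS.
#' Reference geometry of an existing NIfTI file
#'
#' @param path Path to a NIfTI file whose grid should be reused.
#' @param space_tag Coordinate space tag.
#' @return A `reference_geometry`.
#' @export
reference_geometry_from_file <- function(path, space_tag = "MNI") {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("'", path, "' is not a 3-D volume", call. = FALSE)
  hdr <- RNifti::niftiHeader(img)
  if (hdr$sform_code > 0L || hdr$qform_code > 0L)
    RNifti::orientation(img) <- "RAS"
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  structure(list(shape = dim(img), affine = aff, space_tag = space_tag),
            class = "reference_geometry")
}

# All voxel-center world coordinates of a geometry, as an n x 3 matrix in
# array (column-major) order.
geometry_coords <- function(geometry) {
  s <- geometry$shape
  idx <- cbind(rep.int(seq_len(s[1L]), s[2L] * s[3L]),
               rep.int(rep(seq_len(s[2L]), each = s[1L]), s[3L]),
               rep(seq_len(s[3L]), each = s[1L] * s[2L]))
  voxel_centers(idx, geometry$affine)
}

#' Export the Brain-Grid as an integer labelmap
#'
#' Rasterizes the grid onto a reference geometry: every voxel holds the cell
#' ID (1-48, see [cell_id()]) of its center's world coordinate. The result
#' can be overlaid on any image sharing that geometry.
#'
#' @param geometry A [make_reference_geometry()] or
#'   [reference_geometry_from_file()] result.
#' @param grid A [brain_grid()].
#' @param path Optional output NIfTI path; when given the labelmap is
#'   written with an integer datatype.
#' @return A list of class `grid_labelmap` with elements `data` (integer 3-D
#'   array of cell IDs), `affine` and `space_tag`, invisibly when `path` is
#'   given.
#' @export
export_grid_labelmap <- function(geometry, grid, path = NULL) {
  stopifnot(inherits(geometry, "reference_geometry"),
            inherits(grid, "brain_grid"))
  ids <- label_point_id(geometry_coords(geometry), grid)
  arr <- array(as.integer(ids), dim = geometry$shape)
  out <- structure(list(data = arr, affine = geometry$affine,
                        space_tag = geometry$space_tag),
                   class = "grid_labelmap")
  if (!is.null(path)) {
    write_nifti_volume(arr, geometry$affine, path, datatype = "int16")
    return(invisible(out))
  }
  out
}

#' @export
print.grid_labelmap <- function(x, ...) {
  cat("grid_labelmap: ", paste(dim(x$data), collapse = " x "),
      " voxels, cell IDs ", min(x$data), "-", max(x$data), " (",
      x$space_tag, " space)\n", sep = "")
  invisible(x)
}
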