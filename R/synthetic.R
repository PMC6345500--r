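# Synthetic lesion phantoms: bulky ellipsoids, diffuse digitated lesions,
# nested longitudinal growth series, and synthetic cohorts.

#' Specify a synthetic lesion
#'
#' Parameterizes a phantom emulating the two radiological phenotypes of
#' low-grade glioma: a bulky lesion is a plain ellipsoid with well-defined
#' margins; a diffuse lesion adds finger-like digitations (capsules) along
#' given directions, emulating infiltration along deep white-matter fibers.
#'
#' @param center World-mm center of the core ellipsoid.
#' @param radii Semi-axes in mm (scalar for a sphere, or length 3).
#' @param digitations List of [digitation()] specs (empty for bulky).
#' @param noise_fraction Fraction of surface voxels toggled off as boundary
#'   jitter, in `[0, 1]`.
#' @param seed Integer seed controlling the jitter; the same spec always
#'   rasterizes to the same mask.
#' @return An object of class `lesion_spec`.
#' @examples
#' lesion_spec(c(-10, 0, 0), 5)
#' @export
lesion_spec <- function(center, radii, digitations = list(),
                        noise_fraction = 0, seed = 1L) {
  center <- as.numeric(center)
  if (length(center) != 3L || anyNA(center) || any(!is.finite(center)))
    stop("'center' must be a finite length-3 point", call. = FALSE)
  radii <- rep_len(as.numeric(radii), 3L)
  if (anyNA(radii) || any(radii <= 0))
    stop("'radii' must be positive", call. = FALSE)
  if (noise_fraction < 0 || noise_fraction > 1)
    stop("'noise_fraction' must be in [0, 1]", call. = FALSE)
  for (d in digitations)
    if (!inherits(d, "digitation"))
      stop("'digitations' must be a list of digitation() specs",
           call. = FALSE)
  structure(list(center = center, radii = radii, digitations = digitations,
                 noise_fraction = noise_fraction, seed = as.integer(seed)),
            class = "lesion_spec")
}

#' Specify one finger-like digitation
#'
#' A capsule (cylinder with hemispherical caps) extending from the lesion
#' center along a direction.
#'
#' @param direction Length-3 direction (normalized internally).
#' @param length Extent along the direction, mm (>= 0).
#' @param radius Capsule radius, mm (> 0).
#' @return An object of class `digitation`.
#' @export
digitation <- function(direction, length, radius) {
  direction <- as.numeric(direction)
  if (base::length(direction) != 3L || sum(direction^2) == 0)
    stop("'direction' must be a non-zero length-3 vector", call. = FALSE)
  if (length < 0) stop("'length' must be >= 0", call. = FALSE)
  if (radius <= 0) stop("'radius' must be > 0", call. = FALSE)
  structure(list(direction = direction / sqrt(sum(direction^2)),
                 length = as.numeric(length), radius = as.numeric(radius)),
            class = "digitation")
}

# World-mm bounding box of a lesion spec (core + digitations).
.lesion_bbox <- function(spec) {
  lo <- spec$center - spec$radii
  hi <- spec$center + spec$radii
  for (d in spec$digitations) {
    tip <- spec$center + d$direction * d$length
    lo <- pmin(lo, tip - d$radius)
    hi <- pmax(hi, tip + d$radius)
  }
  rbind(lo = lo, hi = hi)
}

.check_fov <- function(spec, geometry, step = NULL) {
  bb <- .lesion_bbox(spec)
  corners <- rbind(c(1, 1, 1), geometry$shape)
  world <- voxel_centers(corners, geometry$affine)
  lo <- pmin(world[1L, ], world[2L, ])
  hi <- pmax(world[1L, ], world[2L, ])
  if (any(bb["lo", ] < lo) || any(bb["hi", ] > hi))
    stop("lesion", if (!is.null(step)) paste0(" at step ", step),
         " exceeds the field of view (lesion extent [",
         paste(signif(bb["lo", ], 3), collapse = ", "), "] to [",
         paste(signif(bb["hi", ], 3), collapse = ", "),
         "] mm vs FOV centers [", paste(signif(lo, 3), collapse = ", "),
         "] to [", paste(signif(hi, 3), collapse = ", "), "] mm)",
         call. = FALSE)
  invisible(NULL)
}

# Rasterize core + digitations on the geometry's voxel centers.
.rasterize_lesion <- function(spec, geometry) {
  xyz <- geometry_coords(geometry)
  u <- sweep(xyz, 2L, spec$center)
  inside <- (u[, 1L] / spec$radii[1L])^2 + (u[, 2L] / spec$radii[2L])^2 +
    (u[, 3L] / spec$radii[3L])^2 <= 1
  for (d in spec$digitations) {
    t <- u %*% d$direction
    tc <- pmin(pmax(t, 0), d$length)
    dx <- u[, 1L] - tc * d$direction[1L]
    dy <- u[, 2L] - tc * d$direction[2L]
    dz <- u[, 3L] - tc * d$direction[3L]
    inside <- inside | (dx^2 + dy^2 + dz^2 <= d$radius^2)
  }
  array(inside, dim = geometry$shape)
}

# Toggle a seeded random fraction of surface voxels (6-connectivity) off.
.apply_boundary_jitter <- function(arr, noise_fraction, seed) {
  if (noise_fraction <= 0 || !any(arr)) return(arr)
  s <- dim(arr)
  nb_bg <- array(FALSE, dim = s)
  shift <- function(a, ax, by) {
    out <- array(FALSE, dim = dim(a))
    idx_src <- idx_dst <- lapply(dim(a), seq_len)
    n <- dim(a)[ax]
    if (by > 0) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    else { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  bg <- !arr
  for (ax in 1:3) for (by in c(-1L, 1L))
    nb_bg <- nb_bg | shift(bg, ax, by)
  # voxels on the FOV boundary count as surface too
  edge <- array(FALSE, dim = s)
  edge[c(1L, s[1L]), , ] <- TRUE
  edge[, c(1L, s[2L]), ] <- TRUE
  edge[, , c(1L, s[3L])] <- TRUE
  surface <- which(arr & (nb_bg | edge))
  n_jitter <- floor(noise_fraction * length(surface))
  if (n_jitter == 0L) return(arr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  arr[sample(surface, n_jitter)] <- FALSE
  arr
}

#' Rasterize a bulky (ellipsoidal) lesion
#'
#' Voxels whose centers satisfy the ellipsoid inequality become foreground;
#' when `noise_fraction > 0`, that fraction of surface voxels is toggled off
#' under the lesion spec's seed, so identical specs give identical masks and
#' different seeds differ only in boundary voxels.
#'
#' @param spec A [lesion_spec()] (digitations, if any, are ignored here).
#' @param geometry A [make_reference_geometry()].
#' @return A [volume_mask()].
#' @examples
#' geo <- make_reference_geometry(c(31, 31, 31), 1)
#' m <- make_ellipsoid_lesion(lesion_spec(c(0, 0, 0), 10), geo)
#' mask_volume(m, "cm3")  # close to 4/3 * pi * 1^3 = 4.19
#' @export
make_ellipsoid_lesion <- function(spec, geometry) {
  stopifnot(inherits(spec, "lesion_spec"),
            inherits(geometry, "reference_geometry"))
  core <- lesion_spec(spec$center, spec$radii, list(),
                      spec$noise_fraction, spec$seed)
  .check_fov(core, geometry)
  arr <- .rasterize_lesion(core, geometry)
  arr <- .apply_boundary_jitter(arr, spec$noise_fraction, spec$seed)
  volume_mask(arr, geometry$affine, space_tag = geometry$space_tag)
}

#' Rasterize a diffuse (digitated) lesion
#'
#' Union of the core ellipsoid and capsule-shaped digitations along the
#' spec's directions; with zero digitations this equals
#' [make_ellipsoid_lesion()].
#'
#' @inheritParams make_ellipsoid_lesion
#' @return A [volume_mask()].
#' @examples
#' geo <- make_reference_geometry(c(45, 55, 45), 2)
#' sp <- lesion_spec(c(-10, 0, 0), 8,
#'                   digitations = list(digitation(c(0, 1, 0), 30, 4)))
#' make_diffuse_lesion(sp, geo)
#' @export
make_diffuse_lesion <- function(spec, geometry) {
  stopifnot(inherits(spec, "lesion_spec"),
            inherits(geometry, "reference_geometry"))
  .check_fov(spec, geometry)
  arr <- .rasterize_lesion(spec, geometry)
  arr <- .apply_boundary_jitter(arr, spec$noise_fraction, spec$seed)
  volume_mask(arr, geometry$affine, space_tag = geometry$space_tag)
}

#' Generate a nested longitudinal growth series
#'
#' Emulates serial MRI of a growing lesion: at each step the lesion is
#' dilated (`dilation_mm` added to every semi-axis) and translated by
#' `growth_vector`, and the rasterized masks are accumulated by union so the
#' series is nested (each mask a subset of the next), as expected of
#' untreated growth.
#'
#' @param spec Initial [lesion_spec()].
#' @param growth_vector Length-3 translation per step, mm.
#' @param n_steps Number of masks to generate (>= 1).
#' @param geometry A [make_reference_geometry()].
#' @param dilation_mm Semi-axis increment per step, mm (default 1).
#' @return List of [volume_mask()]s, one per step, strictly nested.
#' @examples
#' geo <- make_reference_geometry(c(45, 55, 45), 2)
#' series <- make_growth_series(lesion_spec(c(-12, 20, 10), 5),
#'                              c(6, 0, 0), 3, geo)
#' @export
make_growth_series <- function(spec, growth_vector, n_steps, geometry,
                               dilation_mm = 1) {
  stopifnot(inherits(spec, "lesion_spec"),
            inherits(geometry, "reference_geometry"))
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("'n_steps' must be >= 1", call. = FALSE)
  growth_vector <- rep_len(as.numeric(growth_vector), 3L)
  if (dilation_mm < 0) stop("'dilation_mm' must be >= 0", call. = FALSE)
  masks <- vector("list", n_steps)
  acc <- NULL
  for (i in seq_len(n_steps)) {
    sp <- lesion_spec(spec$center + (i - 1L) * growth_vector,
                      spec$radii + (i - 1L) * dilation_mm,
                      spec$digitations, spec$noise_fraction,
                      spec$seed + i - 1L)
    .check_fov(sp, geometry, step = i)
    arr <- .rasterize_lesion(sp, geometry)
    arr <- .apply_boundary_jitter(arr, sp$noise_fraction, sp$seed)
    acc <- if (is.null(acc)) arr else acc | arr
    masks[[i]] <- volume_mask(acc, geometry$affine,
                              space_tag = geometry$space_tag)
  }
  masks
}

#' Simulate a cohort with known per-cell infiltration probabilities
#'
#' Draws each record's infiltrated-cell set by independent per-cell
#' Bernoulli trials with the given probabilities (records drawn empty are
#' redrawn, matching the cohort invariant of at least one infiltrated
#' cell), then fills the remaining columns with plausible values. Used to
#' check that empirical frequency maps recover the generative
#' probabilities.
#'
#' @param n Number of records.
#' @param cell_probs Named numeric vector: per-cell infiltration
#'   probability, names being cell labels; cells absent default to 0.
#' @param seed Integer seed.
#' @return A `cohort_table` with a `cells` list column.
#' @examples
#' co <- simulate_cohort(20, c(A3C2S2 = 0.8, A3C2S1 = 0.5), seed = 7)
#' frequency_map(co)
#' @export
simulate_cohort <- function(n, cell_probs, seed = 1L) {
  if (is.null(names(cell_probs)) || any(!nzchar(names(cell_probs))))
    stop("'cell_probs' must be named by cell label", call. = FALSE)
  if (any(cell_probs < 0 | cell_probs > 1))
    stop("'cell_probs' must be probabilities", call. = FALSE)
  p <- numeric(48L)
  p[cell_id(names(cell_probs))] <- cell_probs
  if (all(p == 0))
    stop("at least one cell probability must be positive", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  labels <- cell_label(1:48)
  a_idx <- parse_label(labels)[, "a"]
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      hit <- stats::runif(48L) < p
      if (any(hit)) break
    }
    cells[[i]] <- labels[hit]
  }
  nv <- vapply(cells, length, 1L)
  side <- vapply(cells, function(cl) {
    a <- a_idx[match(cl, labels)]
    if (any(a <= 2L) && any(a >= 3L)) "B" else if (any(a >= 3L)) "L" else "R"
  }, "")
  df <- data.frame(
    patient_id = sprintf("sim%03d", seq_len(n)),
    gender = sample(c("M", "F"), n, replace = TRUE),
    age = round(stats::runif(n, 20, 75)),
    histology = sample(c("A", "O"), n, replace = TRUE),
    who_grade = sample(2:3, n, replace = TRUE),
    side = side,
    local_anatomy = "F",
    margins = ifelse(nv >= 7L, "D", "B"),
    volume_cm3 = round(stats::rlnorm(n, log(35), 0.6), 1),
    bg_voxels = nv,
    onset = "SEIZURE GEN",
    procedure = sample(c("R", "B"), n, replace = TRUE, prob = c(0.8, 0.2)),
    n_mri = 2L,
    stringsAsFactors = FALSE)
  df$cells <- cells
  class(df) <- c("cohort_table", "data.frame")
  df
}
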