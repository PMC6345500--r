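# Independent brute-force labeler: tests every cell's interval membership
# instead of counting plane crossings, so it shares no code path with
# label_point().

slab_member <- function(v, bounds, k) {
  m <- length(bounds) + 1L
  if (k == 1L) v >= bounds[1L]
  else if (k == m) v < bounds[m - 1L]
  else v >= bounds[k] && v < bounds[k - 1L]
}

# Returns ALL matching labels (the partition property demands exactly one).
oracle_labels <- function(pt, planes) {
  hits <- character(0)
  for (a in 1:4) for (cc in 1:3) for (s in 1:4) {
    if (slab_member(pt[1L], unname(planes$x_planes), a) &&
        slab_member(pt[3L], unname(planes$z_planes), cc) &&
        slab_member(pt[2L], unname(planes$y_planes), s))
      hits <- c(hits, sprintf("A%dC%dS%d", a, cc, s))
  }
  hits
}

random_points <- function(n, seed, lim = 120) {
  set.seed(seed)
  pts <- matrix(stats::runif(3 * n, -lim, lim), ncol = 3L)
  # sprinkle in exact plane hits to exercise the tie rule
  planes <- braingrid::default_planes("MNI")
  k <- min(n, 50L)
  pts[seq_len(k), 1L] <- sample(c(planes$x_planes, pts[seq_len(k), 1L]),
                                k, replace = TRUE)
  pts[seq_len(k), 2L] <- sample(c(planes$y_planes, pts[seq_len(k), 2L]),
                                k, replace = TRUE)
  pts
}

# Small whole-head field of view covering all 48 cells at 3 mm.
whole_head_geometry <- function(voxel = 3) {
  braingrid::make_reference_geometry(c(61, 73, 61), voxel)
}

# Representative interior world point of each cell (well away from planes).
cell_rep_point <- function(label) {
  p <- braingrid::parse_label(label)
  xr <- c(40, 15, -15, -40)
  zr <- c(40, 10, -30)
  yr <- c(35, 0, -45, -80)
  cbind(xr[p[, "a"]], yr[p[, "s"]], zr[p[, "c"]])
}
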