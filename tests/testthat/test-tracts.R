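# Tract <-> cell association table.

test_that("the shipped atlas has 34 structures and valid cell sets", {
  tt <- load_tract_table()
  expect_equal(nrow(tt), 34L)
  expect_equal(anyDuplicated(paste(tt$name, tt$hemisphere)), 0L)
  expect_true(all(tt$category %in% c("commissural", "projection",
                                     "associative")))
  expect_true(all(vapply(tt$cells, length, 1L) > 0L))
  # every stored label is one of the 48 canonical labels
  expect_true(all(unlist(tt$cells) %in% cell_label(1:48)))
})

test_that("the published cell-structure associations are encoded", {
  tt <- load_tract_table()
  has <- function(cell, name, hemi) {
    hit <- tracts_in_cells(cell, tt)
    any(hit$name == name & hit$hemisphere == hemi)
  }
  # sub-insular / basal-ganglia cells, both hemispheres
  for (nm in c("IFOF", "UF", "ExC", "ATR")) {
    expect_true(has("A3C2S2", nm, "L"))
    expect_true(has("A2C2S2", nm, "R"))
  }
  # fronto-medial cells
  for (cell in c("A2C2S1", "A3C2S1")) {
    hemi <- if (cell == "A2C2S1") "R" else "L"
    expect_true(has(cell, "ATR", hemi))
    expect_true(has(cell, "CC-genu", "midline"))
    expect_true(has(cell, "Ci", hemi))
    expect_true(has(cell, "IFOF", hemi))
  }
  # right insular-cortical / fronto-opercular cell
  for (nm in c("AF", "SLF-h", "FAT"))
    expect_true(has("A1C2S2", nm, "R"))
  # callosal genu spans the midline pair; left uncinate reaches the
  # sub-insular cell
  expect_true(all(c("A2C2S1", "A3C2S1") %in%
                    cells_of_tract("CC-genu", "midline", tt)))
  expect_true("A3C2S2" %in% cells_of_tract("UF", "L", tt))
})

test_that("tracts_in_cells ranks by shared-cell count with name tie-break", {
  tt <- load_tract_table()
  res <- tracts_in_cells(c("A3C2S1", "A3C2S2", "A3C2S3"), tt)
  expect_true(all(diff(res$n_shared_cells) <= 0))
  top <- res[res$n_shared_cells == max(res$n_shared_cells), ]
  expect_true(!is.unsorted(top$name))
  # Ci-L and IFOF-L each share 3 cells; the name tie-break puts Ci first
  expect_equal(top$name[1:2], c("Ci", "IFOF"))
  expect_equal(nrow(tracts_in_cells(character(0), tt)), 0L)
})

test_that("cells_of_tract rejects unknown structures with near misses", {
  tt <- load_tract_table()
  expect_error(cells_of_tract("XYZ", "L", tt), "unknown structure")
  expect_error(cells_of_tract("IFO", "L", tt), "did you mean.*IFOF")
})

test_that("table loading validates labels, duplicates and categories", {
  write_tsv <- function(lines) {
    path <- withr::local_tempfile(fileext = ".tsv",
                                  .local_envir = parent.frame())
    writeLines(c("name\themisphere\tcategory\tcells", lines), path)
    path
  }
  expect_error(load_tract_table(write_tsv("UF\tL\tassociative\tA9C1S1")),
               "invalid cell label")
  expect_error(load_tract_table(write_tsv(c(
    "UF\tL\tassociative\tA3C2S2", "UF\tL\tassociative\tA3C2S1"))),
    "duplicate tract entry 'UF'")
  expect_error(load_tract_table(write_tsv("UF\tL\tmagic\tA3C2S2")),
               "unknown category")
  expect_error(load_tract_table(write_tsv("UF\tX\tassociative\tA3C2S2")),
               "unknown hemisphere")
  expect_error(load_tract_table(write_tsv("UF\tL\tassociative\t")),
               "empty cell set")
})

test_that("tables round-trip through TSV", {
  tt <- load_tract_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  save_tract_table(tt, path)
  tt2 <- load_tract_table(path)
  expect_equal(tt2$name, tt$name)
  expect_equal(tt2$hemisphere, tt$hemisphere)
  expect_equal(tt2$category, tt$category)
  expect_equal(tt2$cells, tt$cells)
})

test_that("build_table_from_masks recovers constructed geometry", {
  g <- brain_grid("MNI")
  geo <- whole_head_geometry(3)
  # bar along x through y = 40, z = 10: spans exactly A2C2S1 and A3C2S1
  xyz <- braingrid:::geometry_coords(geo)
  bar <- abs(xyz[, 2] - 40) <= 2 & abs(xyz[, 3] - 10) <= 2 &
    abs(xyz[, 1]) <= 20
  bar_mask <- volume_mask(array(bar, dim = geo$shape), geo$affine)
  tab <- build_table_from_masks(list(bar = bar_mask), g,
                                category = "commissural")
  expect_setequal(tab$cells[[1]], c("A2C2S1", "A3C2S1"))
  expect_equal(tab$hemisphere[1], "midline")
  # one-voxel mask at (-10, 0, 0) -> the label_point cell
  one <- array(FALSE, dim = geo$shape)
  idx <- round(solve(geo$affine) %*% c(-10, 0, 0, 1))[1:3] + 1
  one[idx[1], idx[2], idx[3]] <- TRUE
  tab1 <- build_table_from_masks(list(dot.L = volume_mask(one, geo$affine)),
                                 g)
  expect_equal(tab1$cells[[1]], "A3C2S2")
  expect_equal(tab1$hemisphere[1], "L")
  expect_equal(tab1$name[1], "dot")
  # overlap below threshold excludes the cell: 3 voxels in A2C2S1 but only
  # 1 in A3C2S1, thresholded between the two
  vox <- bar_mask$voxel_volume
  lop <- array(FALSE, dim = geo$shape)
  for (pt in list(c(10, 40, 10), c(16, 40, 10), c(22, 40, 10),
                  c(-10, 40, 10)))
    lop[t(round(solve(geo$affine) %*% c(pt, 1))[1:3] + 1)] <- TRUE
  tab_thr <- build_table_from_masks(list(lop = volume_mask(lop, geo$affine)),
                                    g, min_overlap_mm3 = 2 * vox)
  expect_equal(tab_thr$cells[[1]], "A2C2S1")
  expect_warning(
    build_table_from_masks(list(e = volume_mask(array(FALSE, geo$shape),
                                                geo$affine),
                                dot = volume_mask(one, geo$affine)), g),
    "no cells above threshold")
})

test_that("masks synthesized from a table's own cells recover it exactly", {
  g <- brain_grid("MNI")
  geo <- whole_head_geometry(3)
  tt <- load_tract_table()
  pick <- tt[tt$name %in% c("CC-genu", "IFOF", "AF"), ]
  masks <- list()
  for (i in seq_len(nrow(pick))) {
    arr <- array(FALSE, dim = geo$shape)
    pts <- cell_rep_point(pick$cells[[i]])
    idx <- round(solve(geo$affine) %*% t(cbind(pts, 1)))[1:3, , drop = FALSE]
    for (j in seq_len(ncol(idx)))
      arr[idx[1, j] + 1, idx[2, j] + 1, idx[3, j] + 1] <- TRUE
    nm <- if (pick$hemisphere[i] == "midline") pick$name[i]
          else paste(pick$name[i], pick$hemisphere[i], sep = ".")
    masks[[nm]] <- volume_mask(arr, geo$affine)
  }
  rebuilt <- build_table_from_masks(masks, g, min_overlap_mm3 = 0)
  for (i in seq_len(nrow(pick))) {
    j <- which(rebuilt$name == pick$name[i] &
                 rebuilt$hemisphere == pick$hemisphere[i])
    expect_setequal(rebuilt$cells[[j]], pick$cells[[i]])
  }
})
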