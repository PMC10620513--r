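make_map <- function(m, section = 1L, ap = NA_real_) {
  attr(m, "section_index") <- as.integer(section)
  attr(m, "ap_mm") <- ap
  m
}

cell_row <- function(x, y, section = 1L, ap = NA_real_) {
  tibble::tibble(section_index = as.integer(section), ap_mm = ap,
                 x_px = x, y_px = y, size_px = 4L, region_id = 0L)
}

test_that("region assignment reads the label under the centroid", {
  uni <- make_map(matrix(42L, 20, 20))
  out <- assign_regions(cell_row(11, 11), list(uni))
  expect_equal(out$region_id, 42L)

  # boundary at x = 10.5 resolves to the lower column (10)
  split <- matrix(1L, 20, 20)
  split[, 12:20] <- 2L          # 0-based columns 11+ are label 2
  out <- assign_regions(cell_row(10.5, 5), list(make_map(split)))
  expect_equal(out$region_id, 1L)
  out <- assign_regions(cell_row(10.51, 5), list(make_map(split)))
  expect_equal(out$region_id, 2L)

  # label 0 under the centroid: retained but unassigned
  zero <- make_map(matrix(0L, 20, 20))
  out <- assign_regions(cell_row(3, 3), list(zero))
  expect_equal(nrow(out), 1)
  expect_equal(out$region_id, 0L)
})

test_that("assignment rejects missing maps and out-of-bounds centroids", {
  uni <- make_map(matrix(1L, 20, 20), section = 2L)
  expect_error(assign_regions(cell_row(1, 1, section = 1L), list(uni)),
               "no label map")
  small <- make_map(matrix(1L, 5, 5))
  expect_error(assign_regions(cell_row(10, 10), list(small)), "shape")
})

test_that("assignment agrees with ground truth on a rendered scene", {
  s <- make_test_scene(rate = 2, noise_sd = 0, seed = 53)
  det <- detect_cells_stack(s$scene$images) |>
    assign_regions(s$scene$labels)
  truth <- s$scene$truth$cells
  joined <- dplyr::inner_join(
    det, truth, by = c("section_index", "x_px", "y_px"),
    suffix = c("", "_t"))
  expect_equal(nrow(joined), nrow(truth))
  expect_equal(joined$region_id, joined$region_id_t)
})

test_that("AP exclusion removes only listed parents inside the window", {
  ont <- build_toy_ontology(14, 2)
  lut <- parent_lookup(ont)
  leaves <- ontology_leaves(ont)
  leaf_of <- function(acr) {
    pid <- ont$region_id[ont$acronym == acr]
    intersect(lut$region_id[lut$parent_region_id == pid], leaves)[1]
  }
  cells <- dplyr::bind_rows(
    cell_row(1, 1, 1L, -4.0),  # isocortex inside window -> removed
    cell_row(2, 2, 2L, -2.0),  # isocortex outside window -> kept
    cell_row(3, 3, 3L, -4.0),  # thalamus inside window -> kept
    cell_row(4, 4, 4L, -4.7),  # closed endpoint -> removed
    cell_row(5, 5, 5L, -3.2)   # closed endpoint -> removed
  )
  cells$region_id <- c(leaf_of("Isocortex"), leaf_of("Isocortex"),
                       leaf_of("TH"), leaf_of("OLF"), leaf_of("HPF"))
  kept <- apply_ap_exclusion(cells, ont, exclusion_spec())
  expect_equal(kept$section_index, c(2L, 3L))
  # idempotent
  expect_identical(apply_ap_exclusion(kept, ont, exclusion_spec()), kept)
  # empty input passes through
  expect_equal(nrow(apply_ap_exclusion(cells[0, ], ont)), 0)
  # unknown parent acronym rejected
  expect_error(
    apply_ap_exclusion(cells, ont,
                       exclusion_spec(parent_acronyms = "NOPE")),
    "not in ontology")
  expect_error(exclusion_spec(ap_min_mm = -3, ap_max_mm = -4), "<")
})

test_that("counting covers all leaves and drops unassigned cells", {
  ont <- build_toy_ontology(2, 2)
  leaves <- ontology_leaves(ont)
  cells <- dplyr::bind_rows(
    cell_row(1, 1), cell_row(2, 2), cell_row(3, 3), cell_row(4, 4))
  cells$region_id <- c(leaves[1], leaves[1], leaves[3], 0L)
  counts <- count_cells(cells, ont)
  expect_equal(nrow(counts), length(leaves))
  expect_equal(counts$count[counts$region_id == leaves[1]], 2L)
  expect_equal(sum(counts$count), 3L)  # the label-0 cell is excluded
  bad <- cells; bad$region_id[1] <- 999L
  expect_error(count_cells(bad, ont), "unknown")
})
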