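#' Assign detected cells to atlas regions
#'
#' Looks up each cell's region in the registered label map of its section:
#' the label at the nearest integer pixel to the centroid, with half-pixel
#' ties broken toward the lower index (round-half-down per axis, so
#' x = 10.5 falls in column 10). Cells landing on label 0 (outside the
#' registered brain) are retained with `region_id = 0`, i.e. flagged
#' unassigned; they are excluded from all downstream denominators.
#'
#' @param cells Cell tibble from [detect_cells()] / [detect_cells_stack()].
#' @param maps List of integer label matrices, each with a `section_index`
#'   attribute (as produced by [render_scene()]).
#' @return The cell tibble with `region_id` filled in.
#' @export
assign_regions <- function(cells, maps) {
  if (nrow(cells) == 0L) return(cells)
  sec_of <- vapply(maps, function(m) attr(m, "section_index") %||% NA_integer_,
                   integer(1))
  if (anyNA(sec_of)) abort("every label map needs a `section_index` attribute.")
  missing_sec <- setdiff(unique(cells$section_index), sec_of)
  if (length(missing_sec) > 0)
    abort(paste0("no label map for section(s): ",
                 paste(missing_sec, collapse = ", ")))
  rid <- integer(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    m <- maps[[match(cells$section_index[i], sec_of)]]
    # round-half-down: ceiling(v - 0.5); 0-based -> 1-based indexing
    col <- ceiling(cells$x_px[i] - 0.5) + 1L
    row <- ceiling(cells$y_px[i] - 0.5) + 1L
    if (row < 1L || row > nrow(m) || col < 1L || col > ncol(m))
      abort("cell centroid outside the label map: shape mismatch?")
    rid[i] <- m[row, col]
  }
  mutate(cells, region_id = as.integer(rid))
}

#' Anterior-posterior exclusion specification
#'
#' Section series often lose dorsal cortical tissue in a posterior AP range
#' during preparation; such (parent region, AP window) combinations are
#' excluded from analysis. The default excludes the isocortex, olfactory
#' areas, hippocampal formation and cortical subplate between AP -4.7 and
#' -3.2 mm.
#'
#' @param parent_acronyms Character vector of depth-2 parent acronyms.
#' @param ap_min_mm,ap_max_mm Closed AP interval in mm (`ap_min < ap_max`).
#' @return A tibble with one row per excluded parent.
#' @export
exclusion_spec <- function(parent_acronyms = c("Isocortex", "OLF", "HPF",
                                               "CTXsp"),
                           ap_min_mm = -4.7, ap_max_mm = -3.2) {
  if (!(ap_min_mm < ap_max_mm)) abort("`ap_min_mm` must be < `ap_max_mm`.")
  tibble(parent_acronym = parent_acronyms,
         ap_min_mm = ap_min_mm, ap_max_mm = ap_max_mm)
}

#' Apply the AP exclusion window
#'
#' Removes cells whose leaf region descends from a listed parent region and
#' whose section AP coordinate lies inside the closed interval
#' `[ap_min_mm, ap_max_mm]`. All other cells — including unassigned ones —
#' pass through untouched. Applying the same spec twice is a no-op.
#'
#' @param cells Assigned cell tibble (with `ap_mm` and `region_id`).
#' @param ontology The region ontology.
#' @param spec An [exclusion_spec()] tibble.
#' @return The filtered cell tibble.
#' @export
apply_ap_exclusion <- function(cells, ontology, spec = exclusion_spec()) {
  if (nrow(cells) == 0L) return(cells)
  bad <- setdiff(spec$parent_acronym,
                 ontology$acronym[ontology$depth == 2L])
  if (length(bad) > 0)
    abort(paste0("exclusion parents not in ontology: ",
                 paste(bad, collapse = ", ")))
  lut <- parent_lookup(ontology)
  joined <- cells %>%
    left_join(lut, by = "region_id") %>%
    left_join(spec, by = "parent_acronym")
  drop <- !is.na(joined$ap_min_mm) &
    !is.na(joined$ap_mm) &
    joined$ap_mm >= joined$ap_min_mm &
    joined$ap_mm <= joined$ap_max_mm
  cells[!drop, , drop = FALSE]
}

#' Count assigned cells per leaf region
#'
#' Tallies assigned cells (region_id > 0) over all leaf regions of the
#' ontology, reporting explicit zeros for leaves with no cells.
#'
#' @param cells Assigned cell tibble.
#' @param ontology The region ontology.
#' @return A tibble `region_id`, `count` covering every leaf.
#' @export
count_cells <- function(cells, ontology) {
  leaves <- ontology_leaves(ontology)
  assigned <- filter(cells, .data$region_id > 0L)
  unknown <- setdiff(unique(assigned$region_id), leaves)
  if (length(unknown) > 0)
    abort(paste0("cells assigned to non-leaf or unknown regions: ",
                 paste(head(unknown, 5), collapse = ", ")))
  tibble(region_id = as.integer(leaves)) %>%
    left_join(dplyr::count(assigned, .data$region_id, name = "count"),
              by = "region_id") %>%
    mutate(count = tidyr::replace_na(.data$count, 0L))
}
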