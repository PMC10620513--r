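#' Region ontologies
#'
#' A region ontology is a rooted tree of brain regions held as a tibble with
#' one row per region: `region_id` (positive integer; 0 is reserved for
#' "outside brain / unassigned" and never appears as a node), `acronym`,
#' `name`, `parent_id` (`NA` for the root) and `depth` (root = 1). The
#' depth-2 nodes are the "parent regions" (the broad regional classification,
#' e.g. isocortex, thalamus, medulla); the leaves are the subdivided regions
#' in which cells are counted.
#'
#' @name ontology
NULL

# canonical acronyms for the 14-parent broad classification of the mouse brain
.parent14_acronyms <- c(
  "Isocortex", "OLF", "HPF", "CTXsp", "STR", "PAL", "TH", "HY",
  "MB", "P", "MY", "CB", "fiber_tracts", "VS"
)

.parent14_names <- c(
  "Isocortex", "Olfactory areas", "Hippocampal formation",
  "Cortical subplate", "Striatum", "Pallidum", "Thalamus", "Hypothalamus",
  "Midbrain", "Pons", "Medulla", "Cerebellum", "Fiber tracts",
  "Ventricular systems"
)

#' Build a toy region ontology
#'
#' Constructs a small rooted region tree for simulation and testing: one root,
#' `n_parents` depth-2 parent regions, and a configurable number of leaf
#' regions under each parent. When `n_parents == 14` the parents carry the
#' standard acronyms of the broad mouse-brain classification (Isocortex, OLF,
#' HPF, CTXsp, STR, PAL, TH, HY, MB, P, MY, CB, fiber tracts, ventricular
#' systems). With `hypothalamus_extra_depth = TRUE` the hypothalamus parent
#' (or the first parent if no `HY` exists) gets an intermediate node so its
#' leaves sit one level deeper than everyone else's, mirroring atlases whose
#' hypothalamic subdivisions live one ontology level below the rest.
#'
#' @param n_parents Number of depth-2 parent regions (default 14).
#' @param leaves_per_parent Integer scalar or length-`n_parents` vector giving
#'   the number of leaf regions under each parent (default 25).
#' @param hypothalamus_extra_depth If `TRUE`, insert an intermediate node
#'   under the hypothalamus so its leaves are one level deeper.
#' @param seed Unused entropy slot kept for interface symmetry with the other
#'   generators; the construction is deterministic.
#' @return A `trap_ontology` tibble with columns `region_id`, `acronym`,
#'   `name`, `parent_id`, `depth`.
#' @examples
#' ont <- build_toy_ontology(n_parents = 14, leaves_per_parent = 2)
#' nrow(ont) # 1 root + 14 parents + 28 leaves
#' @export
build_toy_ontology <- function(n_parents = 14, leaves_per_parent = 25,
                               hypothalamus_extra_depth = FALSE, seed = 1L) {
  if (length(n_parents) != 1L || !is.finite(n_parents) || n_parents < 1)
    abort("`n_parents` must be a single positive integer.")
  n_parents <- as.integer(n_parents)
  if (length(leaves_per_parent) == 1L)
    leaves_per_parent <- rep(leaves_per_parent, n_parents)
  if (length(leaves_per_parent) != n_parents)
    abort("`leaves_per_parent` must have length 1 or `n_parents`.")
  if (any(!is.finite(leaves_per_parent)) || any(leaves_per_parent < 1))
    abort("`leaves_per_parent` entries must be positive integers.")
  leaves_per_parent <- as.integer(leaves_per_parent)

  if (n_parents == 14L) {
    par_acr <- .parent14_acronyms
    par_name <- .parent14_names
  } else {
    par_acr <- sprintf("P%02d", seq_len(n_parents))
    par_name <- sprintf("Parent region %d", seq_len(n_parents))
  }

  rows <- list(tibble(
    region_id = 1L, acronym = "root", name = "whole brain",
    parent_id = NA_integer_, depth = 1L
  ))
  next_id <- 2L
  deep_parent <- if (hypothalamus_extra_depth) {
    hy <- match("HY", par_acr)
    if (is.na(hy)) 1L else hy
  } else 0L

  for (p in seq_len(n_parents)) {
    pid <- next_id
    next_id <- next_id + 1L
    rows[[length(rows) + 1L]] <- tibble(
      region_id = pid, acronym = par_acr[p], name = par_name[p],
      parent_id = 1L, depth = 2L
    )
    leaf_parent <- pid
    leaf_depth <- 3L
    if (p == deep_parent) {
      # intermediate node so this parent's leaves sit one level deeper
      mid <- next_id
      next_id <- next_id + 1L
      rows[[length(rows) + 1L]] <- tibble(
        region_id = mid, acronym = paste0(par_acr[p], "-mid"),
        name = paste(par_name[p], "intermediate division"),
        parent_id = pid, depth = 3L
      )
      leaf_parent <- mid
      leaf_depth <- 4L
    }
    k <- leaves_per_parent[p]
    ids <- next_id + seq_len(k) - 1L
    next_id <- next_id + k
    rows[[length(rows) + 1L]] <- tibble(
      region_id = ids,
      acronym = sprintf("%s.%02d", par_acr[p], seq_len(k)),
      name = sprintf("%s subdivision %d", par_name[p], seq_len(k)),
      parent_id = leaf_parent, depth = leaf_depth
    )
  }
  ont <- bind_rows(rows)
  class(ont) <- c("trap_ontology", class(ont))
  validate_ontology(ont)
  ont
}

#' Validate a region ontology
#'
#' Checks the structural invariants: unique positive region ids (0 reserved
#' for unassigned), exactly one root, every node reachable from the root, no
#' cycles, and parent pointers that exist.
#'
#' @param ontology An ontology tibble.
#' @return The ontology, invisibly; errors when an invariant fails.
#' @export
validate_ontology <- function(ontology) {
  req <- c("region_id", "acronym", "name", "parent_id", "depth")
  if (!all(req %in% names(ontology)))
    abort(paste("ontology must have columns:", paste(req, collapse = ", ")))
  ids <- ontology$region_id
  if (anyDuplicated(ids)) abort("region_ids must be unique.")
  if (any(ids <= 0)) abort("region_ids must be positive (0 is reserved).")
  root <- ontology$region_id[is.na(ontology$parent_id)]
  if (length(root) != 1L) abort("ontology must have exactly one root.")
  if (!all(ontology$parent_id[!is.na(ontology$parent_id)] %in% ids))
    abort("every parent_id must refer to an existing region.")
  # reachability / acyclicity via parent-pointer walk with depth bound
  parent_of <- setNames(ontology$parent_id, as.character(ids))
  for (id in ids) {
    seen <- 0L
    cur <- id
    while (!is.na(parent_of[[as.character(cur)]])) {
      cur <- parent_of[[as.character(cur)]]
      seen <- seen + 1L
      if (seen > nrow(ontology)) abort("ontology contains a cycle.")
    }
    if (cur != root) abort("every node must be reachable from the root.")
  }
  invisible(ontology)
}

#' Map every region to its depth-2 ancestor
#'
#' @param ontology An ontology tibble.
#' @return A tibble with `region_id`, `parent_region_id`, `parent_acronym`;
#'   one row per non-root region. Depth-2 regions map to themselves.
#' @export
parent_lookup <- function(ontology) {
  parent_of <- setNames(ontology$parent_id, as.character(ontology$region_id))
  depth_of <- setNames(ontology$depth, as.character(ontology$region_id))
  acr_of <- setNames(ontology$acronym, as.character(ontology$region_id))
  anc <- function(id) {
    cur <- id
    while (!is.na(cur) && depth_of[[as.character(cur)]] > 2L)
      cur <- parent_of[[as.character(cur)]]
    if (is.na(cur) || depth_of[[as.character(cur)]] != 2L) NA_integer_
    else as.integer(cur)
  }
  ids <- ontology$region_id[ontology$depth >= 2L]
  pid <- vapply(ids, anc, integer(1))
  tibble(
    region_id = as.integer(ids),
    parent_region_id = pid,
    parent_acronym = unname(acr_of[as.character(pid)])
  )
}

#' Leaf regions of an ontology
#'
#' @param ontology An ontology tibble.
#' @return Integer vector of region ids that have no children.
#' @export
ontology_leaves <- function(ontology) {
  setdiff(ontology$region_id, ontology$parent_id[!is.na(ontology$parent_id)])
}

#' Aggregate a count table through the ontology
#'
#' Sums leaf-level counts into their depth-2 parent regions. Counts are long
#' tibbles with one row per animal and region (`animal_id`, `condition`,
#' `method`, `region_id`, `count`); aggregation conserves each animal's total.
#'
#' @param counts A long count tibble.
#' @param ontology The ontology the `region_id`s belong to.
#' @param level `"parent14"` to aggregate to depth-2 parents, `"leaf"` to
#'   return the table unchanged (after validating its regions).
#' @return A long count tibble at the requested level.
#' @export
aggregate_to_parents <- function(counts, ontology,
                                 level = c("parent14", "leaf")) {
  level <- match.arg(level)
  if (nrow(counts) == 0L) return(counts)
  lut <- parent_lookup(ontology)
  unknown <- setdiff(unique(counts$region_id), lut$region_id)
  if (length(unknown) > 0)
    abort(paste0(
      "count table columns with no depth-2 ancestor in the ontology: ",
      paste(head(unknown, 5), collapse = ", ")
    ))
  if (level == "leaf") return(counts)
  meta <- intersect(c("animal_id", "condition", "method"), names(counts))
  counts %>%
    left_join(lut, by = "region_id") %>%
    group_by(across(all_of(c(meta, "parent_region_id")))) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    rename(region_id = "parent_region_id")
}

#' Read / write an ontology as CSV
#'
#' Plain CSV with columns `region_id,acronym,name,parent_id,depth`; the root
#' has an empty `parent_id`.
#'
#' @param ontology An ontology tibble.
#' @param path File path.
#' @return `write_ontology_csv` returns `path` invisibly;
#'   `read_ontology_csv` returns a validated `trap_ontology` tibble.
#' @export
write_ontology_csv <- function(ontology, path) {
  readr::write_csv(as_tibble(ontology), path, na = "")
  invisible(path)
}

#' @rdname write_ontology_csv
#' @export
read_ontology_csv <- function(path) {
  ont <- readr::read_csv(
    path,
    col_types = readr::cols(
      region_id = readr::col_integer(),
      acronym = readr::col_character(),
      name = readr::col_character(),
      parent_id = readr::col_integer(),
      depth = readr::col_integer()
    )
  )
  class(ont) <- c("trap_ontology", class(ont))
  validate_ontology(ont)
  ont
}
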