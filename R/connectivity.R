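#' Drop regions with no expression anywhere
#'
#' Connectivity is estimated only over regions with at least one cFos-TRAPed
#' cell in at least one animal of the full dataset; regions whose count is
#' zero in every animal are removed before correlation.
#'
#' @param counts Long count tibble (`animal_id`, ..., `region_id`, `count`).
#' @return The table restricted to expressed regions, with a message
#'   reporting how many regions were retained; a warning and an empty table
#'   when nothing is expressed.
#' @export
filter_expressed <- function(counts) {
  if (nrow(counts) == 0L) abort("`counts` is empty.")
  keep <- counts %>%
    group_by(.data$region_id) %>%
    summarise(any_expr = any(.data$count > 0), .groups = "drop")
  retained <- keep$region_id[keep$any_expr]
  if (length(retained) == 0L) {
    warn("no region has any cFos-TRAPed cells; returning an empty table.")
    return(counts[0, , drop = FALSE])
  }
  message(length(retained), " of ", nrow(keep),
          " regions retained (expressed in at least one animal).")
  filter(counts, .data$region_id %in% retained)
}

#' Pool animals into two comparison groups
#'
#' The 2x2 design collapses into two pooled groups per scheme:
#' `"condition"` pools across methods into sum_ad_lib vs sum_SD;
#' `"method"` pools across conditions into sum_chamber vs sum_hand.
#'
#' @param data A tibble with `condition` and `method` columns.
#' @param scheme `"condition"` or `"method"`.
#' @return The tibble with a `group` column added.
#' @export
apply_grouping <- function(data, scheme = c("condition", "method")) {
  scheme <- match.arg(scheme)
  mutate(data, group = paste0("sum_", .data[[scheme]]))
}

#' All-pairs Pearson correlations across animals
#'
#' Within each pooled group, computes the Pearson correlation coefficient of
#' the cFos-TRAPed ratio across animals for every unordered pair of regions
#' (m regions yield m(m-1)/2 pairs per group). A region with zero variance
#' within a group — or with missing ratios — yields missing `r` for all its
#' pairs; missing values are excluded from downstream pools.
#'
#' Correlations across so few animals are extremely noisy; a warning is
#' emitted whenever a group has fewer than 10 animals.
#'
#' @param ratios A ratio tibble from [compute_ratios()] (subdivided level),
#'   restricted to expressed regions via [filter_expressed()] upstream.
#' @param scheme Grouping scheme, see [apply_grouping()].
#' @param value_col Column correlated across animals (default `"ratio"`;
#'   `"count"` correlates raw counts).
#' @return A tibble `group`, `region_i`, `region_j` (`region_i < region_j`),
#'   `r`, `n_animals`.
#' @export
pairwise_correlations <- function(ratios, scheme = c("condition", "method"),
                                  value_col = "ratio") {
  scheme <- match.arg(scheme)
  if (!value_col %in% names(ratios))
    abort(paste0("column `", value_col, "` not found."))
  grouped <- apply_grouping(ratios, scheme)
  out <- list()
  for (g in sort(unique(grouped$group))) {
    sub <- filter(grouped, .data$group == g)
    wide <- sub %>%
      select(all_of(c("animal_id", "region_id", value_col))) %>%
      tidyr::pivot_wider(names_from = "region_id",
                         values_from = all_of(value_col))
    m <- as.matrix(wide[, -1, drop = FALSE])
    n_animals <- nrow(m)
    if (n_animals < 3)
      abort(paste0("group ", g, " has ", n_animals,
                   " animals; need at least 3 for correlation."))
    if (n_animals < 10)
      warn(paste0("group ", g, " has only ", n_animals,
                  " animals; correlations are very noisy."))
    sds <- apply(m, 2, stats::sd)
    cm <- suppressWarnings(cor(m, use = "everything"))
    cm[, is.na(sds) | sds == 0] <- NA_real_
    cm[is.na(sds) | sds == 0, ] <- NA_real_
    ids <- as.integer(colnames(wide)[-1])
    ut <- which(upper.tri(cm), arr.ind = TRUE)
    out[[g]] <- tibble(
      group = g,
      region_i = pmin(ids[ut[, 1]], ids[ut[, 2]]),
      region_j = pmax(ids[ut[, 1]], ids[ut[, 2]]),
      r = cm[ut],
      n_animals = n_animals
    )
  }
  bind_rows(out)
}

#' Bin leaf-pair correlations to parent-region pairs
#'
#' Pools the leaf-level correlation coefficients into the symmetric grid of
#' depth-2 parent-region pairs: cell (P, Q) collects every leaf pair with
#' one endpoint under P and the other under Q (P = Q pools within-parent
#' pairs; region self-pairs never exist). Four summaries are computed per
#' cell and group: the arithmetic mean r, the mean of positive r only, the
#' mean of negative r only, and the mean of |r|. Missing correlations are
#' excluded from every pool; an empty pool yields a missing cell.
#'
#' @param correlations Output of [pairwise_correlations()].
#' @param ontology The region ontology.
#' @return A tibble per `group` and parent pair (`parent_i`, `parent_j`,
#'   acronyms, with `parent_i <= parent_j` by region id): `n_pairs`,
#'   `mean_r`, `sem_r`, `positive_mean_r`, `negative_mean_r`,
#'   `absolute_mean_r`.
#' @export
bin_to_parents <- function(correlations, ontology) {
  lut <- parent_lookup(ontology)
  pl <- setNames(lut$parent_region_id, as.character(lut$region_id))
  acr <- setNames(ontology$acronym, as.character(ontology$region_id))
  pi <- unname(pl[as.character(correlations$region_i)])
  pj <- unname(pl[as.character(correlations$region_j)])
  if (anyNA(pi) || anyNA(pj))
    abort("some correlated regions lack a depth-2 ancestor.")
  correlations %>%
    mutate(parent_i = pmin(pi, pj), parent_j = pmax(pi, pj)) %>%
    group_by(.data$group, .data$parent_i, .data$parent_j) %>%
    summarise(
      n_pairs = sum(!is.na(.data$r)),
      mean_r = mean(.data$r, na.rm = TRUE),
      sem_r = stats::sd(.data$r, na.rm = TRUE) /
        sqrt(max(sum(!is.na(.data$r)), 1)),
      positive_mean_r = mean(.data$r[.data$r > 0], na.rm = TRUE),
      negative_mean_r = mean(.data$r[.data$r < 0], na.rm = TRUE),
      absolute_mean_r = mean(abs(.data$r), na.rm = TRUE),
      .groups = "drop"
    ) %>%
    mutate(
      across(all_of(c("mean_r", "sem_r", "positive_mean_r",
                      "negative_mean_r", "absolute_mean_r")),
             ~ ifelse(is.nan(.x), NA_real_, .x)),
      acronym_i = unname(acr[as.character(.data$parent_i)]),
      acronym_j = unname(acr[as.character(.data$parent_j)])
    )
}

#' Extract a parent-pair summary as a symmetric matrix
#'
#' @param binned Output of [bin_to_parents()].
#' @param group Group name to extract.
#' @param stat One of `"mean_r"`, `"positive_mean_r"`, `"negative_mean_r"`,
#'   `"absolute_mean_r"`, `"n_pairs"`.
#' @return A symmetric matrix with parent acronyms as dimnames.
#' @export
mean_r_matrix <- function(binned, group, stat = "mean_r") {
  sub <- filter(binned, .data$group == .env$group)
  acrs <- unique(c(sub$acronym_i, sub$acronym_j))
  ids <- unique(c(sub$parent_i, sub$parent_j))
  ord <- order(ids)
  acrs <- acrs[match(sort(ids), unique(c(sub$parent_i, sub$parent_j))[ord])]
  acrs <- unique(acrs)
  m <- matrix(NA_real_, length(acrs), length(acrs),
              dimnames = list(acrs, acrs))
  for (i in seq_len(nrow(sub))) {
    m[sub$acronym_i[i], sub$acronym_j[i]] <- sub[[stat]][i]
    m[sub$acronym_j[i], sub$acronym_i[i]] <- sub[[stat]][i]
  }
  m
}

#' Kolmogorov-Smirnov comparison of pooled correlations
#'
#' For each parent-region pair, compares the raw pooled correlation
#' coefficients (not the means) of the two groups with a two-sided
#' two-sample Kolmogorov-Smirnov test: D is the supremum difference of the
#' two empirical CDFs. The p-value is exact (by enumeration over ECDF
#' paths) when both pools hold at most `exact_max` values and no ties are
#' present, asymptotic otherwise.
#'
#' @param correlations Output of [pairwise_correlations()] containing
#'   exactly two groups.
#' @param ontology The region ontology.
#' @param exact_max Largest pool size for which the exact small-sample
#'   p-value is used (default 10).
#' @return A tibble per parent pair: `parent_i`, `parent_j`, acronyms,
#'   `group_a`, `group_b`, `n_a`, `n_b`, `statistic` (D), `p.value`;
#'   missing when either pool is empty.
#' @export
ks_compare <- function(correlations, ontology, exact_max = 10L) {
  groups <- sort(unique(correlations$group))
  if (length(groups) != 2L)
    abort("`correlations` must contain exactly two groups.")
  lut <- parent_lookup(ontology)
  pl <- setNames(lut$parent_region_id, as.character(lut$region_id))
  acr <- setNames(ontology$acronym, as.character(ontology$region_id))
  pooled <- correlations %>%
    mutate(parent_i = pmin(unname(pl[as.character(.data$region_i)]),
                           unname(pl[as.character(.data$region_j)])),
           parent_j = pmax(unname(pl[as.character(.data$region_i)]),
                           unname(pl[as.character(.data$region_j)]))) %>%
    filter(!is.na(.data$r))
  cells <- distinct(pooled, .data$parent_i, .data$parent_j)
  res <- purrr::pmap(cells, function(parent_i, parent_j) {
    xa <- pooled$r[pooled$group == groups[1] &
                     pooled$parent_i == parent_i &
                     pooled$parent_j == parent_j]
    xb <- pooled$r[pooled$group == groups[2] &
                     pooled$parent_i == parent_i &
                     pooled$parent_j == parent_j]
    if (length(xa) == 0L || length(xb) == 0L) {
      return(tibble(parent_i = parent_i, parent_j = parent_j,
                    n_a = length(xa), n_b = length(xb),
                    statistic = NA_real_, p.value = NA_real_))
    }
    exact <- length(xa) <= exact_max && length(xb) <= exact_max
    kt <- suppressWarnings(ks.test(xa, xb, exact = exact))
    tibble(parent_i = parent_i, parent_j = parent_j,
           n_a = length(xa), n_b = length(xb),
           statistic = unname(kt$statistic), p.value = kt$p.value)
  }) %>%
    bind_rows() %>%
    mutate(group_a = groups[1], group_b = groups[2],
           acronym_i = unname(acr[as.character(.data$parent_i)]),
           acronym_j = unname(acr[as.character(.data$parent_j)]))
  res
}
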