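#' Published subdivided-region group-mean ratios
#'
#' The group-mean cFos-TRAPed ratio table from a whole-brain
#' sleep-deprivation study with a 2x2 design (condition: ad-libitum sleep
#' vs sleep deprivation; method: dedicated chamber vs gentle handling),
#' covering the 48 subdivided regions with at least one significant two-way
#' ANOVA term. Ratios are within-parent percentages (leaf count over
#' parent-region total), printed to 2-3 decimals; the three p-value columns
#' are the raw two-way ANOVA results. Ships with the package as a plain CSV
#' and serves as the worked example for [fold_change()].
#'
#' @return A tibble with columns `parent_name`, `region_name`, `acronym`,
#'   the four `ratio_*_pct` group means, and `p_condition`, `p_method`,
#'   `p_interaction`.
#' @examples
#' tbl <- published_subdivided_ratios()
#' fold_change(group_means_to_ratios(tbl)) |>
#'   dplyr::filter(acronym == "CP", method == "hand")
#' @export
published_subdivided_ratios <- function() {
  path <- system.file("extdata", "subdivided_group_ratios.csv",
                      package = "trapmap", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    parent_name = readr::col_character(),
    region_name = readr::col_character(),
    acronym = readr::col_character(),
    .default = readr::col_double()
  ))
}

#' Expand group-mean ratios into a per-animal ratio table
#'
#' Turns a table of per-design-cell mean ratios (percent) into the long
#' per-animal ratio layout consumed by [fold_change()], with one synthetic
#' animal per design cell carrying the group mean. Group means are
#' preserved exactly, so fold changes computed from the expansion equal
#' folds computed from the printed means.
#'
#' @param tbl A tibble like [published_subdivided_ratios()].
#' @return A long ratio tibble (`animal_id`, `condition`, `method`,
#'   `region_id`, `acronym`, `ratio`), ratios on \[0, 1\].
#' @export
group_means_to_ratios <- function(tbl) {
  cells <- tibble(
    condition = c("ad_lib", "ad_lib", "SD", "SD"),
    method = c("chamber", "hand", "chamber", "hand"),
    col = c("ratio_adlib_chamber_pct", "ratio_adlib_hand_pct",
            "ratio_sd_chamber_pct", "ratio_sd_hand_pct")
  )
  purrr::pmap(cells, function(condition, method, col) {
    tibble(
      animal_id = paste0("mean_", condition, "_", method),
      condition = condition, method = method,
      region_id = seq_len(nrow(tbl)),
      acronym = tbl$acronym,
      ratio = tbl[[col]] / 100
    )
  }) %>%
    bind_rows()
}
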