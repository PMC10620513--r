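sim_ratio_set <- function(n_parents = 3, leaves_per_parent = 3,
                          n_per_cell = 3, seed = 81) {
  ont <- build_toy_ontology(n_parents, leaves_per_parent)
  counts <- simulate_count_tables(ont, n_per_cell = n_per_cell, seed = seed)
  list(ontology = ont, counts = counts,
       ratios = compute_ratios(counts, ont, "subdivided"))
}

test_that("filter_expressed drops only regions with no cells anywhere", {
  s <- sim_ratio_set()
  # no all-zero regions at these rates: identity
  expect_message(kept <- filter_expressed(s$counts), "retained")
  expect_equal(nrow(kept), nrow(s$counts))
  # force two regions to structural zero
  zero_ids <- unique(s$counts$region_id)[1:2]
  forced <- s$counts |>
    dplyr::mutate(count = ifelse(.data$region_id %in% zero_ids, 0L,
                                 .data$count))
  expect_message(kept <- filter_expressed(forced), "retained")
  expect_false(any(zero_ids %in% kept$region_id))
  # everything zero: empty with a warning
  allzero <- s$counts |> dplyr::mutate(count = 0L)
  expect_warning(out <- filter_expressed(allzero), "no region")
  expect_equal(nrow(out), 0)
})

test_that("pair counts and correlation values match closed forms", {
  s <- sim_ratio_set()
  m <- length(unique(s$ratios$region_id))
  corr <- suppressWarnings(pairwise_correlations(s$ratios, "condition"))
  expect_equal(unname(table(corr$group)), rep(m * (m - 1) / 2, 2),
               ignore_attr = TRUE)
  expect_true(all(corr$region_i < corr$region_j))

  # hand-checkable 4-animal vectors
  toy <- tidyr::expand_grid(
    animal_id = paste0("A", 1:4), region_id = 1:3
  ) |>
    dplyr::mutate(
      condition = "ad_lib",
      method = rep(c("chamber", "chamber", "hand", "hand"), each = 3),
      ratio = dplyr::case_when(
        region_id == 1 ~ c(1, 2, 3, 4)[match(animal_id, paste0("A", 1:4))],
        region_id == 2 ~ c(2, 4, 6, 8)[match(animal_id, paste0("A", 1:4))],
        TRUE ~ c(4, 3, 2, 1)[match(animal_id, paste0("A", 1:4))]
      )
    )
  corr <- suppressWarnings(pairwise_correlations(toy, "condition"))
  r_of <- function(i, j) corr$r[corr$region_i == i & corr$region_j == j]
  expect_equal(r_of(1, 2), 1.0)
  expect_equal(r_of(1, 3), -1.0)
  # a scrambled vector against the closed-form oracle
  toy2 <- toy |>
    dplyr::mutate(ratio = ifelse(region_id == 2,
      c(1, 3, 2, 4)[match(animal_id, paste0("A", 1:4))], ratio))
  corr2 <- suppressWarnings(pairwise_correlations(toy2, "condition"))
  expect_equal(corr2$r[corr2$region_i == 1 & corr2$region_j == 2],
               oracle_pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)))

  # duplicated region: r exactly 1
  dup <- toy |>
    dplyr::mutate(ratio = ifelse(region_id == 2,
      ratio[match(paste0(animal_id, 1), paste0(animal_id, region_id))],
      ratio))
  corrd <- suppressWarnings(pairwise_correlations(dup, "condition"))
  expect_equal(corrd$r[corrd$region_i == 1 & corrd$region_j == 2], 1.0)
})

test_that("groups below three animals are rejected and zero variance is NA", {
  toy <- tidyr::expand_grid(animal_id = paste0("A", 1:2), region_id = 1:2) |>
    dplyr::mutate(condition = "ad_lib", method = "chamber", ratio = 0.5)
  expect_error(suppressWarnings(pairwise_correlations(toy, "condition")),
               "at least 3")
  s <- sim_ratio_set()
  const <- s$ratios |>
    dplyr::mutate(ratio = ifelse(.data$region_id ==
                                   min(.data$region_id), 0.2, .data$ratio))
  corr <- suppressWarnings(pairwise_correlations(const, "condition"))
  expect_true(all(is.na(corr$r[corr$region_i == min(const$region_id)])))
})

test_that("parent-pair binning matches an exhaustive pooling oracle", {
  s <- sim_ratio_set(n_parents = 4, leaves_per_parent = 3, seed = 91)
  corr <- suppressWarnings(pairwise_correlations(s$ratios, "condition"))
  binned <- bin_to_parents(corr, s$ontology)
  lut <- parent_lookup(s$ontology)
  pl <- setNames(lut$parent_region_id, as.character(lut$region_id))
  for (k in sample(nrow(binned), 10)) {
    row <- binned[k, ]
    pool <- corr$r[corr$group == row$group &
      pmin(pl[as.character(corr$region_i)],
           pl[as.character(corr$region_j)]) == row$parent_i &
      pmax(pl[as.character(corr$region_i)],
           pl[as.character(corr$region_j)]) == row$parent_j]
    pool <- pool[!is.na(pool)]
    expect_equal(row$n_pairs, length(pool))
    expect_equal(row$mean_r, mean(pool))
    expect_equal(row$absolute_mean_r, mean(abs(pool)))
    if (any(pool > 0)) expect_equal(row$positive_mean_r, mean(pool[pool > 0]))
    if (any(pool < 0)) expect_equal(row$negative_mean_r, mean(pool[pool < 0]))
  }
  # signed-mean inequality holds everywhere
  expect_true(all(abs(binned$mean_r) <= binned$absolute_mean_r + 1e-12,
                  na.rm = TRUE))
  expect_true(all(binned$positive_mean_r >= 0, na.rm = TRUE))
  expect_true(all(binned$negative_mean_r <= 0, na.rm = TRUE))
  # matrix extraction is symmetric
  mat <- mean_r_matrix(binned, group = binned$group[1])
  expect_true(isSymmetric(mat))
})

test_that("mixed pools summarize to the four advertised means", {
  corr <- tibble::tibble(
    group = "g", region_i = c(3L, 3L), region_j = c(6L, 7L),
    r = c(0.5, -0.5), n_animals = 4L)
  ont <- build_toy_ontology(2, 2)
  binned <- bin_to_parents(corr, ont)
  expect_equal(binned$mean_r, 0)
  expect_equal(binned$positive_mean_r, 0.5)
  expect_equal(binned$negative_mean_r, -0.5)
  expect_equal(binned$absolute_mean_r, 0.5)
  # constant positive pool: negative mean undefined
  corr$r <- c(0.3, 0.3)
  binned <- bin_to_parents(corr, ont)
  expect_equal(binned$mean_r, 0.3)
  expect_true(is.na(binned$negative_mean_r))
})

test_that("KS comparison matches the enumeration oracle on small pools", {
  # identical pools: D = 0, p = 1
  ont <- build_toy_ontology(2, 3)
  mk <- function(rs, grp) tibble::tibble(
    group = grp, region_i = c(4L, 4L, 5L), region_j = c(8L, 9L, 9L),
    r = rs, n_animals = 4L)
  same <- dplyr::bind_rows(mk(c(0.1, 0.2, 0.3), "a"),
                           mk(c(0.1, 0.2, 0.3), "b"))
  ks <- ks_compare(same, ont)
  cell <- ks[ks$parent_i != ks$parent_j, ]
  expect_equal(cell$statistic, 0)
  expect_equal(cell$p.value, 1)
  # fully separated pools: D = 1
  apart <- dplyr::bind_rows(mk(c(0, 0, 0), "a"), mk(c(1, 1, 1), "b"))
  ks <- ks_compare(apart, ont)
  expect_equal(ks$statistic[ks$parent_i != ks$parent_j], 1)

  # random 5-vs-5 pools against exhaustive enumeration
  for (seed in 1:5) {
    set.seed(400 + seed)
    xa <- round(runif(5), 3); xb <- round(runif(5), 3)
    pools <- dplyr::bind_rows(
      tibble::tibble(group = "a", region_i = 4L, region_j = 8:12 * 0 + 8L,
                     r = xa, n_animals = 4L),
      tibble::tibble(group = "b", region_i = 4L, region_j = 8L,
                     r = xb, n_animals = 4L))
    ks <- ks_compare(pools, ont)
    oracle <- oracle_ks(xa, xb)
    expect_equal(ks$statistic, oracle$D)
    expect_equal(ks$p.value, oracle$p, tolerance = 1e-10)
  }
})

test_that("ks_compare needs exactly two groups and tolerates empty pools", {
  ont <- build_toy_ontology(2, 3)
  one <- tibble::tibble(group = "a", region_i = 4L, region_j = 8L,
                        r = 0.5, n_animals = 4L)
  expect_error(ks_compare(one, ont), "two groups")
})
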