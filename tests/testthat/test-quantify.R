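two_parent_counts <- function(a = 30L, b = 70L) {
  ont <- build_toy_ontology(2, 1)
  leaves <- ontology_leaves(ont)
  counts <- tidyr::expand_grid(
    animal_id = "A1", condition = "ad_lib", method = "chamber",
    region_id = leaves
  )
  counts$count <- c(a, b)
  list(ontology = ont, counts = counts)
}

test_that("parent and subdivided ratios divide as advertised", {
  tp <- two_parent_counts()
  r <- compute_ratios(tp$counts, tp$ontology, "parent14")
  expect_equal(sort(r$ratio), c(0.30, 0.70))

  # leaf 55 of parent total 200 -> 27.5%
  ont <- build_toy_ontology(1, 2)
  leaves <- ontology_leaves(ont)
  counts <- tibble::tibble(
    animal_id = "A1", condition = "ad_lib", method = "chamber",
    region_id = leaves, count = c(55L, 145L))
  r <- compute_ratios(counts, ont, "subdivided")
  expect_equal(r$ratio[r$region_id == leaves[1]], 0.275)

  # random tables match plain division, and sum to 1 within each parent
  ont <- build_toy_ontology(4, 3)
  counts <- simulate_count_tables(ont, n_per_cell = 2, seed = 61)
  rs <- compute_ratios(counts, ont, "subdivided")
  joined <- dplyr::left_join(rs, counts,
                             by = c("animal_id", "condition", "method",
                                    "region_id"))
  ptot <- joined |>
    dplyr::group_by(.data$animal_id, .data$parent_acronym) |>
    dplyr::mutate(ptot = sum(.data$count)) |>
    dplyr::ungroup()
  expect_equal(ptot$ratio, ptot$count / ptot$ptot)
  sums <- rs |>
    dplyr::group_by(.data$animal_id, .data$parent_acronym) |>
    dplyr::summarise(s = sum(.data$ratio), .groups = "drop")
  expect_equal(sums$s, rep(1, nrow(sums)))

  # wholebrain level divides by the animal total
  rw <- compute_ratios(counts, ont, "wholebrain")
  totals <- counts |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(tot = sum(.data$count))
  jw <- dplyr::left_join(rw, counts,
                         by = c("animal_id", "condition", "method",
                                "region_id")) |>
    dplyr::left_join(totals, by = "animal_id")
  expect_equal(jw$ratio, jw$count / jw$tot)
})

test_that("an animal with zero cells yields missing ratios and a warning", {
  tp <- two_parent_counts(0L, 0L)
  expect_warning(r <- compute_ratios(tp$counts, tp$ontology, "parent14"),
                 "zero total")
  expect_true(all(is.na(r$ratio)))
})

test_that("fold changes reproduce the published worked examples", {
  ratios <- group_means_to_ratios(published_subdivided_ratios())
  folds <- fold_change(ratios)
  f <- function(acr, meth) {
    round(folds$fold[folds$acronym == acr & folds$method == meth], 2)
  }
  expect_equal(f("CP", "hand"), 1.46)
  expect_equal(f("CP", "chamber"), 1.15)
  expect_equal(f("VTA", "chamber"), 2.02)
  expect_equal(f("VTA", "hand"), 1.78)
  expect_equal(f("MARN", "hand"), 2.36)
  expect_equal(f("LHA", "chamber"), 1.16)
  expect_equal(f("RT", "chamber"), 0.54)
})

test_that("zero group means make folds not determined", {
  ratios <- group_means_to_ratios(published_subdivided_ratios())
  folds <- fold_change(ratios)
  nd <- function(acr, meth)
    folds$determined[folds$acronym == acr & folds$method == meth]
  expect_false(nd("PBG", "chamber"))   # zero baseline
  expect_false(nd("SH", "chamber"))    # zero treatment mean
  expect_false(nd("IIIn", "hand"))     # zero treatment mean
  expect_true(nd("SH", "hand"))        # 0.013/0.063 is determined
  # identical group means give fold 1
  flat <- ratios |> dplyr::mutate(ratio = 0.25)
  expect_equal(unique(fold_change(flat)$fold), 1)
})

test_that("two-way ANOVA matches the hand-coded SS decomposition", {
  base <- tidyr::expand_grid(
    condition = c("ad_lib", "SD"), method = c("chamber", "hand"),
    rep = 1:3
  )
  # all observations equal: every effect SS is 0
  d0 <- base |>
    dplyr::mutate(region_id = 1L, acronym = "X", animal_id = paste0("A", dplyr::row_number()),
                  ratio = 0.4)
  fit0 <- two_way_anova(d0)
  expect_equal(fit0$terms$sumsq[fit0$terms$term != "residual"], rep(0, 3))

  # purely additive cell pattern: zero interaction SS
  addv <- c("ad_lib.chamber" = 10, "SD.chamber" = 20,
            "ad_lib.hand" = 30, "SD.hand" = 40)
  d1 <- base |>
    dplyr::filter(rep <= 2) |>
    dplyr::mutate(region_id = 1L,
                  animal_id = paste0("A", dplyr::row_number()),
                  ratio = (addv[paste(condition, method, sep = ".")] +
                             (rep - 1) * 2) / 100)
  fit1 <- two_way_anova(d1)
  expect_equal(fit1$terms$sumsq[fit1$terms$term == "condition:method"], 0)

  # random balanced tables against the oracle at 1e-10
  for (seed in 1:5) {
    set.seed(300 + seed)
    d <- base |>
      dplyr::mutate(region_id = 1L,
                    animal_id = paste0("A", dplyr::row_number()),
                    ratio = runif(dplyr::n()))
    fit <- two_way_anova(d)
    oracle <- oracle_anova_2x2(d$ratio, d$condition, d$method)
    expect_equal(fit$terms$sumsq, oracle$sumsq, tolerance = 1e-10)
    expect_equal(fit$terms$statistic[1:3], oracle$statistic[1:3],
                 tolerance = 1e-10)
    expect_equal(fit$terms$p.value[1:3], oracle$p.value[1:3],
                 tolerance = 1e-10)
  }
})

test_that("degenerate designs are flagged rather than fit", {
  d <- tibble::tibble(
    animal_id = paste0("A", 1:4),
    condition = c("ad_lib", "ad_lib", "SD", "SD"),
    method = c("chamber", "hand", "chamber", "hand"),
    region_id = 1L, ratio = c(0.1, 0.2, 0.3, 0.4))
  fit <- two_way_anova(d)   # one observation per cell: no residual df
  expect_true(all(is.na(fit$terms$p.value)))
})

test_that("tidy and glance expose the ANOVA in broom shapes", {
  ont <- build_toy_ontology(3, 2)
  counts <- simulate_count_tables(ont, n_per_cell = 3, seed = 71)
  rs <- compute_ratios(counts, ont, "subdivided")
  fit <- two_way_anova(rs)
  td <- generics::tidy(fit)
  expect_setequal(unique(td$term),
                  c("condition", "method", "condition:method", "residual"))
  gl <- generics::glance(fit)
  expect_equal(nrow(gl), length(unique(rs$region_id)))
  expect_true(all(c("p_condition", "p_method", "p_interaction",
                    "fold_chamber", "fold_hand") %in% names(gl)))
  expect_true(all(gl$p_condition >= 0 & gl$p_condition <= 1, na.rm = TRUE))
})
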