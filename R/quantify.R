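#' Compute cFos-TRAPed cell ratios
#'
#' Normalizes an animal-by-region count table into the two ratio layers used
#' throughout the analysis:
#'
#' * `parent14` — each depth-2 parent region's count divided by the animal's
#'   total assigned cells over all sections (the whole-brain ratio);
#' * `subdivided` — each leaf region's count divided by the animal's total
#'   in that leaf's parent region (the within-parent ratio);
#' * `wholebrain` — each leaf region's count divided by the animal's total
#'   assigned cells, a sensitivity normalization used mainly by the
#'   simulation harness (a latent factor shared uniformly by a parent's
#'   leaves cancels in the within-parent ratio but survives here).
#'
#' Within one animal, subdivided ratios across a parent's leaves sum to 1
#' whenever the parent has any cells; a parent with zero cells yields
#' missing ratios for its leaves. An animal with zero total cells yields all
#' missing ratios and a warning.
#'
#' @param counts Long count tibble (`animal_id`, `condition`, `method`,
#'   `region_id`, `count`) at leaf level.
#' @param ontology The region ontology.
#' @param level `"subdivided"` (default), `"parent14"` or `"wholebrain"`.
#' @return A long ratio tibble (`animal_id`, `condition`, `method`,
#'   `region_id`, `acronym`, `parent_acronym`, `ratio`), ratio in \[0, 1\],
#'   with the level stored in the `"level"` attribute.
#' @export
compute_ratios <- function(counts, ontology,
                           level = c("subdivided", "parent14",
                                     "wholebrain")) {
  level <- match.arg(level)
  if (nrow(counts) == 0L) abort("`counts` is empty.")
  lut <- parent_lookup(ontology)
  acr <- setNames(ontology$acronym, as.character(ontology$region_id))
  meta <- intersect(c("condition", "method"), names(counts))

  totals <- counts %>%
    group_by(.data$animal_id) %>%
    summarise(total = sum(.data$count), .groups = "drop")
  if (any(totals$total == 0))
    warn(paste0("animal(s) with zero total cells: ",
                paste(totals$animal_id[totals$total == 0], collapse = ", "),
                "; their ratios are missing."))

  if (level == "parent14") {
    out <- aggregate_to_parents(counts, ontology, "parent14") %>%
      left_join(totals, by = "animal_id") %>%
      mutate(ratio = ifelse(.data$total > 0, .data$count / .data$total,
                            NA_real_),
             acronym = unname(acr[as.character(.data$region_id)]),
             parent_acronym = .data$acronym) %>%
      select(all_of(c("animal_id", meta, "region_id", "acronym",
                      "parent_acronym", "ratio")))
  } else if (level == "wholebrain") {
    out <- counts %>%
      left_join(lut, by = "region_id") %>%
      left_join(totals, by = "animal_id") %>%
      mutate(ratio = ifelse(.data$total > 0, .data$count / .data$total,
                            NA_real_),
             acronym = unname(acr[as.character(.data$region_id)])) %>%
      select(all_of(c("animal_id", meta, "region_id", "acronym",
                      "parent_acronym", "ratio")))
  } else {
    out <- counts %>%
      left_join(lut, by = "region_id") %>%
      group_by(.data$animal_id, .data$parent_region_id) %>%
      mutate(parent_total = sum(.data$count)) %>%
      ungroup() %>%
      mutate(ratio = ifelse(.data$parent_total > 0,
                            .data$count / .data$parent_total, NA_real_),
             acronym = unname(acr[as.character(.data$region_id)])) %>%
      select(all_of(c("animal_id", meta, "region_id", "acronym",
                      "parent_acronym", "ratio")))
  }
  attr(out, "level") <- level
  out
}

#' Fold changes of group-mean ratios
#'
#' For each region and sleep-deprivation method, the fold change is the mean
#' ratio of the sleep-deprived animals divided by the mean ratio of the
#' ad-libitum-sleep animals of the same method. A zero or missing group
#' mean on either side makes the fold "not determined"
#' (`determined = FALSE`, `fold = NA`) rather than an error: a 0/x or x/0
#' collapse carries no meaningful fold.
#'
#' @param ratios A ratio tibble from [compute_ratios()], or any tibble with
#'   `region_id`, `condition`, `method`, `ratio`.
#' @param treatment,baseline Condition levels compared (default `"SD"` over
#'   `"ad_lib"`).
#' @return A tibble `region_id`, (`acronym`,) `method`, `mean_baseline`,
#'   `mean_treatment`, `fold`, `determined`. Fold changes are conventionally
#'   reported rounded to 2 decimals; the returned value is unrounded.
#' @export
fold_change <- function(ratios, treatment = "SD", baseline = "ad_lib") {
  if (!all(c(treatment, baseline) %in% unique(ratios$condition)))
    abort("both condition levels must be present in `ratios`.")
  acr_cols <- intersect(c("acronym", "parent_acronym"), names(ratios))
  gm <- ratios %>%
    filter(.data$condition %in% c(treatment, baseline),
           !is.na(.data$ratio)) %>%
    group_by(across(all_of(c("region_id", acr_cols[acr_cols == "acronym"],
                             "method", "condition")))) %>%
    summarise(m = mean(.data$ratio), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "m")
  for (lv in c(baseline, treatment))
    if (!lv %in% names(gm)) gm[[lv]] <- NA_real_
  gm %>%
    mutate(
      mean_baseline = .data[[baseline]],
      mean_treatment = .data[[treatment]],
      determined = !is.na(.data$mean_baseline) & .data$mean_baseline > 0 &
        !is.na(.data$mean_treatment) & .data$mean_treatment > 0,
      fold = ifelse(.data$determined,
                    .data$mean_treatment / .data$mean_baseline, NA_real_)
    ) %>%
    select(-all_of(c(baseline, treatment)))
}

#' Per-region two-way factorial ANOVA on ratios
#'
#' Fits the fixed-effects 2x2 ANOVA `ratio ~ condition * method` separately
#' for every region, on the per-animal ratios directly (no transform, no
#' multiple-testing correction — the reproduction defaults; see
#' `transform` and `p_adjust`). With a balanced design the classical
#' sequential decomposition is unique (Types I/II/III coincide).
#'
#' @param ratios A ratio tibble from [compute_ratios()].
#' @param regions Optional vector of region ids to restrict to.
#' @param transform Optional variance-stabilizing transform applied to the
#'   ratios before fitting: `"none"` (default), `"arcsine"`
#'   (`asin(sqrt(r))`) or `"logit"` (with a half-minimum offset for 0/1).
#' @param p_adjust Multiple-testing adjustment across regions per term,
#'   passed to [stats::p.adjust()] (`"none"` by default).
#' @return A `trap_anova` object: list with `terms` (long per-region ANOVA
#'   tables), `cell_means` (per design-cell means and ns) and `folds`
#'   (from [fold_change()]). Use [generics::tidy()] for the term table and
#'   [generics::glance()] for a Table-1-style per-region summary.
#' @export
two_way_anova <- function(ratios, regions = NULL,
                          transform = c("none", "arcsine", "logit"),
                          p_adjust = "none") {
  transform <- match.arg(transform)
  dat <- filter(ratios, !is.na(.data$ratio))
  if (!is.null(regions)) dat <- filter(dat, .data$region_id %in% regions)
  if (nrow(dat) == 0L) abort("no non-missing ratios to analyze.")
  dat$y <- switch(transform,
    none = dat$ratio,
    arcsine = asin(sqrt(pmin(pmax(dat$ratio, 0), 1))),
    logit = {
      r <- dat$ratio
      eps <- min(r[r > 0], 0.5) / 2
      stats::qlogis(pmin(pmax(r, eps), 1 - eps))
    }
  )
  terms <- dat %>%
    group_by(.data$region_id) %>%
    dplyr::group_modify(~ .anova_one(.x)) %>%
    ungroup()
  if (p_adjust != "none") {
    terms <- terms %>%
      group_by(.data$term) %>%
      mutate(p.value = stats::p.adjust(.data$p.value, method = p_adjust)) %>%
      ungroup()
  }
  cell_means <- dat %>%
    group_by(.data$region_id, .data$condition, .data$method) %>%
    summarise(mean_ratio = mean(.data$ratio), n = dplyr::n(),
              .groups = "drop")
  folds <- tryCatch(fold_change(ratios), error = function(e) NULL)
  acr <- if ("acronym" %in% names(ratios))
    distinct(ratios, .data$region_id, .data$acronym) else NULL
  structure(list(terms = terms, cell_means = cell_means, folds = folds,
                 acronyms = acr, transform = transform),
            class = "trap_anova")
}

.anova_one <- function(d) {
  d$condition <- factor(d$condition)
  d$method <- factor(d$method)
  empty <- tibble(
    term = c("condition", "method", "condition:method", "residual"),
    df = NA_integer_, sumsq = NA_real_, meansq = NA_real_,
    statistic = NA_real_, p.value = NA_real_
  )
  if (nlevels(d$condition) < 2 || nlevels(d$method) < 2 || nrow(d) <= 4)
    return(empty)
  fit <- stats::lm(y ~ condition * method, data = d)
  # anova.lm warns on essentially perfect fits (e.g. all values equal);
  # the zero-SS table it returns is exactly what we want there
  a <- suppressWarnings(stats::anova(fit))
  out <- tibble(
    term = c("condition", "method", "condition:method", "residual"),
    df = as.integer(a$Df),
    sumsq = a$`Sum Sq`,
    meansq = a$`Mean Sq`,
    statistic = a$`F value`,
    p.value = a$`Pr(>F)`
  )
  if (out$df[out$term == "residual"] == 0) {
    warn("zero residual degrees of freedom; p-values undefined.")
    out$statistic <- NA_real_
    out$p.value <- NA_real_
  }
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a per-region ANOVA
#'
#' @param x A `trap_anova` object.
#' @param ... Unused.
#' @return Long tibble of per-region ANOVA tables: `region_id`, `term`,
#'   `df`, `sumsq`, `meansq`, `statistic`, `p.value`.
#' @exportS3Method generics::tidy
tidy.trap_anova <- function(x, ...) x$terms

#' Per-region ANOVA summary
#'
#' One row per region mirroring the layout of a subdivided-region results
#' table: the four design-cell mean ratios, the three ANOVA p-values
#' (condition, method, interaction) and the per-method fold changes.
#'
#' @param x A `trap_anova` object.
#' @param ... Unused.
#' @return A wide tibble with one row per region.
#' @exportS3Method generics::glance
glance.trap_anova <- function(x, ...) {
  pw <- x$terms %>%
    filter(.data$term != "residual") %>%
    mutate(term = c(condition = "p_condition", method = "p_method",
                    `condition:method` = "p_interaction")[.data$term]) %>%
    select(all_of(c("region_id", "term", "p.value"))) %>%
    tidyr::pivot_wider(names_from = "term", values_from = "p.value")
  cm <- x$cell_means %>%
    mutate(cell = paste0("mean_", .data$condition, "_", .data$method)) %>%
    select(all_of(c("region_id", "cell", "mean_ratio"))) %>%
    tidyr::pivot_wider(names_from = "cell", values_from = "mean_ratio")
  out <- left_join(cm, pw, by = "region_id")
  if (!is.null(x$folds)) {
    fw <- x$folds %>%
      mutate(mcol = paste0("fold_", .data$method)) %>%
      select(all_of(c("region_id", "mcol", "fold"))) %>%
      tidyr::pivot_wider(names_from = "mcol", values_from = "fold")
    out <- left_join(out, fw, by = "region_id")
  }
  if (!is.null(x$acronyms))
    out <- left_join(out, x$acronyms, by = "region_id") %>%
      select(all_of(c("region_id", "acronym")), dplyr::everything())
  out
}

#' @export
print.trap_anova <- function(x, ...) {
  cat("Two-way factorial ANOVA on cFos-TRAPed ratios\n")
  cat("  regions:", length(unique(x$terms$region_id)),
      " transform:", x$transform, "\n")
  print(glance(x), ...)
  invisible(x)
}
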