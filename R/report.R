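#' Bar chart of group-mean ratios with animal points
#'
#' One panel per region: bars are the group means of the cFos-TRAPed ratio
#' in each design cell, points are the individual animals — the standard
#' presentation for small-N whole-brain mapping cohorts.
#'
#' @param ratios A ratio tibble from [compute_ratios()].
#' @param regions Optional region ids to restrict the panels to.
#' @return A ggplot object.
#' @export
plot_region_ratios <- function(ratios, regions = NULL) {
  dat <- filter(ratios, !is.na(.data$ratio))
  if (!is.null(regions)) dat <- filter(dat, .data$region_id %in% regions)
  dat <- mutate(dat,
    cell = interaction(.data$condition, .data$method, sep = "-"),
    panel = if ("acronym" %in% names(dat)) .data$acronym
            else as.character(.data$region_id))
  means <- dat %>%
    group_by(.data$panel, .data$cell, .data$condition) %>%
    summarise(m = mean(.data$ratio), .groups = "drop")
  ggplot2::ggplot(means,
                  ggplot2::aes(x = .data$cell, y = .data$m,
                               fill = .data$condition)) +
    ggplot2::geom_col(width = 0.7, color = "grey30") +
    ggplot2::geom_point(data = dat,
                        ggplot2::aes(y = .data$ratio), size = 1.4,
                        shape = 21, fill = "white") +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::scale_y_continuous(labels = function(x) 100 * x) +
    ggplot2::labs(x = NULL, y = "cFos-TRAPed ratio (%)", fill = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Mean-r bar chart per parent region with significance stars
#'
#' One panel per parent region: bars show the mean inter-regional
#' correlation (mean r) between that region and every other, per group,
#' with SEM error bars; stars mark parent pairs whose pooled correlation
#' distributions differ by the Kolmogorov-Smirnov test
#' (\*p < 0.05, \*\*p < 0.01, \*\*\*p < 0.001).
#'
#' @param binned Output of [bin_to_parents()].
#' @param ks Optional output of [ks_compare()] to place stars.
#' @return A ggplot object.
#' @export
plot_mean_r <- function(binned, ks = NULL) {
  # duplicate each (i, j) cell so every parent owns a full panel
  long <- bind_rows(
    mutate(binned, panel = .data$acronym_i, other = .data$acronym_j),
    binned %>% filter(.data$parent_i != .data$parent_j) %>%
      mutate(panel = .data$acronym_j, other = .data$acronym_i)
  )
  p <- ggplot2::ggplot(long,
         ggplot2::aes(x = .data$other, y = .data$mean_r,
                      fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_r - .data$sem_r,
                   ymax = .data$mean_r + .data$sem_r),
      position = ggplot2::position_dodge(width = 0.8), width = 0.3,
      linewidth = 0.3) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = NULL, y = "mean r", fill = NULL) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  if (!is.null(ks) && nrow(ks) > 0) {
    stars <- ks %>%
      filter(!is.na(.data$p.value), .data$p.value < 0.05) %>%
      mutate(label = case_when(
        .data$p.value < 0.001 ~ "***",
        .data$p.value < 0.01 ~ "**",
        TRUE ~ "*"
      ))
    star_long <- bind_rows(
      mutate(stars, panel = .data$acronym_i, other = .data$acronym_j),
      stars %>% filter(.data$parent_i != .data$parent_j) %>%
        mutate(panel = .data$acronym_j, other = .data$acronym_i)
    )
    ymax <- long %>%
      group_by(.data$panel, .data$other) %>%
      summarise(y = max(.data$mean_r + .data$sem_r, 0, na.rm = TRUE),
                .groups = "drop")
    star_long <- left_join(star_long, ymax, by = c("panel", "other"))
    if (nrow(star_long) > 0) p <- p + ggplot2::geom_text(
      data = star_long,
      ggplot2::aes(x = .data$other, y = .data$y, label = .data$label),
      inherit.aes = FALSE, vjust = -0.2, size = 2.6)
  }
  p
}

#' -log10 p-value overview of a per-region ANOVA
#'
#' @param object A `trap_anova` object.
#' @param ... Unused.
#' @return A ggplot object: per-region -log10 p for the three design terms.
#' @exportS3Method ggplot2::autoplot
autoplot.trap_anova <- function(object, ...) {
  dat <- object$terms %>%
    filter(.data$term != "residual", !is.na(.data$p.value))
  ggplot2::ggplot(dat,
      ggplot2::aes(x = factor(.data$region_id),
                   y = -log10(.data$p.value))) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2) +
    ggplot2::facet_wrap(~term, ncol = 1) +
    ggplot2::labs(x = "region", y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

.save_plot <- function(p, path_base, width = 10, height = 8) {
  ok <- tryCatch({
    grDevices::png(paste0(path_base, ".png"), width = width * 96,
                   height = height * 96, res = 96)
    print(p)
    grDevices::dev.off()
    paste0(path_base, ".png")
  }, error = function(e) {
    try(grDevices::dev.off(), silent = TRUE)
    NULL
  })
  if (is.null(ok)) {
    grDevices::pdf(paste0(path_base, ".pdf"), width = width,
                   height = height)
    print(p)
    grDevices::dev.off()
    ok <- paste0(path_base, ".pdf")
  }
  ok
}

#' Generate figures and a summary from pipeline outputs
#'
#' Reads the stage CSVs written by [run_pipeline()] from `outdir` and
#' produces per-region ratio bar charts, mean-r bar panels with
#' significance stars, and a markdown summary. Missing stage outputs are
#' listed in the summary and the report is still produced for whatever is
#' available.
#'
#' @param outdir Directory holding pipeline outputs.
#' @return Character vector of files written, invisibly.
#' @export
make_report <- function(outdir) {
  written <- character(0)
  missing <- character(0)
  lines <- c("# trapmap run report", "")

  f_rat <- file.path(outdir, "ratios_parent14.csv")
  if (file.exists(f_rat)) {
    ratios <- readr::read_csv(f_rat, show_col_types = FALSE)
    fig <- .save_plot(plot_region_ratios(ratios),
                      file.path(outdir, "fig_region_ratios"))
    written <- c(written, fig)
    lines <- c(lines, paste0("- Parent-region ratio panels: `",
                             basename(fig), "`"))
  } else missing <- c(missing, "ratios_parent14.csv")

  for (scheme in c("condition", "method")) {
    f_mr <- file.path(outdir, paste0("mean_r_", scheme, ".csv"))
    f_ks <- file.path(outdir, paste0("ks_", scheme, ".csv"))
    if (file.exists(f_mr)) {
      binned <- readr::read_csv(f_mr, show_col_types = FALSE)
      ks <- if (file.exists(f_ks))
        readr::read_csv(f_ks, show_col_types = FALSE) else NULL
      fig <- .save_plot(plot_mean_r(binned, ks),
                        file.path(outdir, paste0("fig_mean_r_", scheme)))
      written <- c(written, fig)
      lines <- c(lines, paste0("- Mean-r panels (", scheme, " scheme): `",
                               basename(fig), "`"))
    } else missing <- c(missing, paste0("mean_r_", scheme, ".csv"))
  }

  f_an <- file.path(outdir, "anova_subdivided.csv")
  if (file.exists(f_an)) {
    an <- readr::read_csv(f_an, show_col_types = FALSE)
    n_sig <- sum(an$p_condition < 0.05, na.rm = TRUE)
    lines <- c(lines, paste0(
      "- Subdivided-region ANOVA: ", nrow(an), " regions, ", n_sig,
      " with condition p < 0.05 (`anova_subdivided.csv`)"))
  } else missing <- c(missing, "anova_subdivided.csv")

  if (length(written) == 0 && length(missing) > 0 &&
      !any(file.exists(file.path(outdir,
        c("counts.csv", "ratios_parent14.csv")))))
    lines <- c(lines, "", "no stages found")
  if (length(missing) > 0)
    lines <- c(lines, "", "Missing stage outputs:",
               paste0("- ", missing))
  summary_path <- file.path(outdir, "report.md")
  writeLines(lines, summary_path)
  invisible(c(written, summary_path))
}
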