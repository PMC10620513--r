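#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run: the toy cohort to simulate
#' (ontology shape, per-condition rates, design size), detection and
#' exclusion parameters, analysis level, grouping schemes and the seed.
#' The configuration is a plain list and round-trips through YAML
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' Two input routes exist: `source = "images"` renders synthetic section
#' stacks per animal and runs the full detect-assign-count chain;
#' `source = "counts"` draws animal-by-region count tables directly. Both
#' continue identically through ratios, ANOVA and connectivity.
#'
#' @param outdir Output directory for stage CSVs, figures and the manifest.
#' @param source `"counts"` (default) or `"images"`.
#' @param n_parents,leaves_per_parent Toy ontology shape (defaults 14 x 4
#'   for image runs; pass larger for count-only runs).
#' @param n_per_cell Animals per design cell (default 2).
#' @param n_sections,image_shape Scene geometry for image runs.
#' @param rates Named per-region expected cells per section (image route);
#'   `NULL` spreads `cells_per_section` uniformly over the leaves.
#' @param cells_per_section Expected total cells per section used when
#'   `rates` is `NULL` (default 60).
#' @param sd_effect Named multiplicative sleep-deprivation effects.
#' @param loadings Named latent-factor loadings (count route).
#' @param detection A [detection_params()] list.
#' @param exclusion An [exclusion_spec()] tibble; entries naming parents
#'   absent from the toy ontology are ignored.
#' @param schemes Grouping schemes to run connectivity under.
#' @param seed Integer seed controlling the entire run.
#' @return A `trap_pipeline_config` list.
#' @export
pipeline_config <- function(outdir,
                            source = c("counts", "images"),
                            n_parents = 14,
                            leaves_per_parent = 4,
                            n_per_cell = 2,
                            n_sections = 6,
                            image_shape = c(96, 80),
                            rates = NULL,
                            cells_per_section = 60,
                            sd_effect = NULL,
                            loadings = NULL,
                            detection = detection_params(),
                            exclusion = exclusion_spec(),
                            schemes = c("condition", "method"),
                            seed = 1L) {
  source <- match.arg(source)
  structure(list(
    outdir = outdir, source = source,
    n_parents = n_parents, leaves_per_parent = leaves_per_parent,
    n_per_cell = n_per_cell, n_sections = n_sections,
    image_shape = image_shape, rates = rates,
    cells_per_section = cells_per_section,
    sd_effect = sd_effect, loadings = loadings,
    detection = detection, exclusion = exclusion,
    schemes = schemes, seed = as.integer(seed)
  ), class = "trap_pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `trap_pipeline_config` list.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  plain <- unclass(config)
  plain$detection <- unclass(plain$detection)
  plain$exclusion <- as.list(as_tibble(plain$exclusion))
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  plain <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, c(
    plain[setdiff(names(plain), c("detection", "exclusion"))],
    list(detection = do.call(detection_params, plain$detection),
         exclusion = as_tibble(plain$exclusion))
  ))
  cfg
}

#' Run the whole pipeline end to end
#'
#' Executes every stage — simulate (or render + detect + assign + exclude +
#' count), ratios at both levels, per-region two-way ANOVA with fold
#' changes, and connectivity under each grouping scheme — and writes the
#' stage outputs as CSV into `config$outdir` together with a JSON manifest
#' (package version, seed, config hash, per-file MD5). Outputs are staged
#' in a temporary directory and moved into place only when every stage
#' succeeded, so a failing stage leaves no partial outputs; rerunning with
#' the same configuration is bit-identical.
#'
#' @param config A [pipeline_config()] list.
#' @return The manifest, invisibly, as a list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "trap_pipeline_config"))
  stage <- "setup"
  staging <- tempfile("trapmap-run-")
  dir.create(staging, recursive = TRUE)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)

  result <- tryCatch({
    stage <- "ontology"
    ont <- build_toy_ontology(config$n_parents, config$leaves_per_parent,
                              seed = config$seed)
    write_ontology_csv(ont, file.path(staging, "ontology.csv"))

    stage <- "counts"
    if (config$source == "images") {
      counts <- .pipeline_counts_from_images(config, ont, staging)
    } else {
      counts <- simulate_count_tables(
        ont, n_per_cell = config$n_per_cell,
        sd_effect = config$sd_effect, loadings = config$loadings,
        seed = config$seed
      )
    }
    readr::write_csv(counts, file.path(staging, "counts.csv"))

    stage <- "ratios"
    ratios_sub <- compute_ratios(counts, ont, "subdivided")
    ratios_par <- compute_ratios(counts, ont, "parent14")
    readr::write_csv(ratios_sub, file.path(staging, "ratios_subdivided.csv"))
    readr::write_csv(ratios_par, file.path(staging, "ratios_parent14.csv"))

    stage <- "anova"
    fit <- two_way_anova(ratios_sub)
    readr::write_csv(glance(fit), file.path(staging, "anova_subdivided.csv"))
    fit14 <- two_way_anova(ratios_par)
    readr::write_csv(glance(fit14), file.path(staging, "anova_parent14.csv"))

    stage <- "connectivity"
    expressed <- filter_expressed(counts)
    ratios_expr <- ratios_sub %>%
      filter(.data$region_id %in% unique(expressed$region_id))
    for (scheme in config$schemes) {
      corr <- suppressWarnings(pairwise_correlations(ratios_expr, scheme))
      binned <- bin_to_parents(corr, ont)
      ks <- ks_compare(corr, ont)
      readr::write_csv(corr,
        file.path(staging, paste0("correlations_", scheme, ".csv")))
      readr::write_csv(binned,
        file.path(staging, paste0("mean_r_", scheme, ".csv")))
      readr::write_csv(ks,
        file.path(staging, paste0("ks_", scheme, ".csv")))
    }

    stage <- "manifest"
    cfg_yaml <- file.path(staging, "config.yaml")
    write_pipeline_config(config, cfg_yaml)
    files <- setdiff(list.files(staging), "manifest.json")
    manifest <- list(
      package = "trapmap",
      version = as.character(utils::packageVersion("trapmap")),
      seed = config$seed,
      config_md5 = unname(tools::md5sum(cfg_yaml)),
      outputs = as.list(tools::md5sum(file.path(staging, files))) |>
        setNames(files)
    )
    jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    manifest
  }, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ",
                 conditionMessage(e)))
  })

  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(staging))
    file.copy(file.path(staging, f), file.path(config$outdir, f),
              overwrite = TRUE)
  invisible(result)
}

# image route: render one scene per animal, detect, assign, exclude, count
.pipeline_counts_from_images <- function(config, ont, staging) {
  leaves <- ontology_leaves(ont)
  rates <- config$rates
  if (is.null(rates))
    rates <- setNames(rep(config$cells_per_section / length(leaves),
                          length(leaves)), as.character(leaves))
  sd_effect <- .fill_region_vector(config$sd_effect, leaves, 1, "sd_effect")
  design <- tidyr::expand_grid(
    condition = c("ad_lib", "SD"), method = c("chamber", "hand"),
    rep = seq_len(config$n_per_cell)
  ) %>%
    mutate(animal_id = sprintf("A%03d", row_number()))
  all_cells <- list()
  counts <- purrr::pmap(design, function(condition, method, rep, animal_id) {
    r <- rates
    if (condition == "SD") r <- r * sd_effect[names(r)]
    sp <- scene_spec(
      n_sections = config$n_sections, image_shape = config$image_shape,
      rates = r,
      seed = config$seed + match(animal_id, design$animal_id)
    )
    scene <- render_scene(ont, sp)
    excl <- config$exclusion %>%
      filter(.data$parent_acronym %in% ont$acronym[ont$depth == 2L])
    cells <- detect_cells_stack(scene$images, config$detection) %>%
      assign_regions(scene$labels)
    if (nrow(excl) > 0) cells <- apply_ap_exclusion(cells, ont, excl)
    count_cells(cells, ont) %>%
      mutate(animal_id = animal_id, condition = condition, method = method,
             .before = 1)
  }) %>%
    bind_rows()
  counts
}
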