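#' Simulate animal-by-region count tables
#'
#' Draws per-animal cell counts for every leaf region of an ontology under a
#' 2x2 sleep-deprivation design (condition: ad-libitum sleep vs sleep
#' deprivation; method: dedicated chamber vs gentle handling). Counts follow
#' a Poisson model with a log-normal shared frailty:
#'
#'   count[a, r] ~ Poisson(rate[r] * effect[r]^SD(a) * exp(loading[r] * z[a]))
#'
#' where `z[a] ~ N(0, 1)` is a latent factor drawn once per animal. Regions
#' with same-sign loadings co-fluctuate across animals, inducing positive
#' cross-animal correlation — the structure the connectivity stage estimates.
#' A multiplicative `sd_effect` > 1 raises a region's rate in sleep-deprived
#' animals only, emulating condition-dependent activation.
#'
#' Default base rates are heterogeneous across leaves (log-normal weights,
#' drawn deterministically from `seed`) and scaled so each animal's expected
#' total is `total_rate` cells, matching the scale of whole-brain
#' cFos-TRAPed cell yields (roughly 30,000 cells per animal over a full
#' section series).
#'
#' @param ontology A region ontology; counts are generated for its leaves.
#' @param n_per_cell Animals per design cell (>= 2; the study design used 2).
#' @param conditions,methods Factor levels of the 2x2 design.
#' @param base_rates Optional named numeric vector (names = leaf region ids)
#'   of expected counts per animal; defaults to log-normal weights scaled to
#'   `total_rate`.
#' @param total_rate Expected total cells per animal used to scale default
#'   base rates (default 29621).
#' @param sd_effect Named numeric vector of multiplicative sleep-deprivation
#'   effects per region (default 1 everywhere); must be positive.
#' @param loadings Named numeric vector of latent-factor loadings per region
#'   (default 0 everywhere).
#' @param seed Integer seed; the draw is fully reproducible.
#' @return A long tibble with columns `animal_id`, `condition`, `method`,
#'   `region_id`, `count`, carrying the realized `base_rates`, `sd_effect`
#'   and `loadings` as attributes.
#' @examples
#' ont <- build_toy_ontology(n_parents = 3, leaves_per_parent = 4)
#' counts <- simulate_count_tables(ont, n_per_cell = 2, seed = 42)
#' dplyr::count(counts, condition, method)
#' @export
simulate_count_tables <- function(ontology,
                                  n_per_cell = 2,
                                  conditions = c("ad_lib", "SD"),
                                  methods = c("chamber", "hand"),
                                  base_rates = NULL,
                                  total_rate = 29621,
                                  sd_effect = NULL,
                                  loadings = NULL,
                                  seed = 1L) {
  if (n_per_cell < 2) abort("`n_per_cell` must be at least 2.")
  leaves <- ontology_leaves(ontology)
  if (length(leaves) == 0L) abort("ontology has no leaf regions.")
  set.seed(seed)

  if (is.null(base_rates)) {
    w <- exp(rnorm(length(leaves), 0, 1))
    base_rates <- setNames(total_rate * w / sum(w), as.character(leaves))
  } else {
    base_rates <- .check_region_vector(base_rates, leaves, "base_rates")
    if (any(base_rates < 0)) abort("`base_rates` must be non-negative.")
  }
  sd_effect <- .fill_region_vector(sd_effect, leaves, default = 1,
                                   what = "sd_effect")
  if (any(sd_effect <= 0)) abort("`sd_effect` entries must be positive.")
  loadings <- .fill_region_vector(loadings, leaves, default = 0,
                                  what = "loadings")

  design <- tidyr::expand_grid(
    condition = conditions, method = methods, rep = seq_len(n_per_cell)
  ) %>%
    mutate(animal_id = sprintf("A%03d", row_number()))

  key <- as.character(leaves)
  out <- purrr::pmap(design, function(condition, method, rep, animal_id) {
    z <- rnorm(1)
    lambda <- base_rates[key] *
      (if (condition == "SD") sd_effect[key] else 1) *
      exp(loadings[key] * z)
    tibble(
      animal_id = animal_id, condition = condition, method = method,
      region_id = as.integer(leaves),
      count = rpois(length(leaves), lambda)
    )
  }) %>%
    bind_rows()

  attr(out, "base_rates") <- base_rates
  attr(out, "sd_effect") <- sd_effect
  attr(out, "loadings") <- loadings
  out
}

# named region vector -> validated, ordered by `leaves`
.check_region_vector <- function(x, leaves, what) {
  if (is.null(names(x)) || length(x) != length(leaves))
    abort(paste0("`", what, "` must be named by the ontology's leaf ids."))
  unknown <- setdiff(names(x), as.character(leaves))
  if (length(unknown) > 0)
    abort(paste0("`", what, "` references unknown region ids: ",
                 paste(head(unknown, 5), collapse = ", ")))
  x[as.character(leaves)]
}

# partial named vector -> complete vector over leaves with a default
.fill_region_vector <- function(x, leaves, default, what) {
  out <- setNames(rep(default, length(leaves)), as.character(leaves))
  if (is.null(x)) return(out)
  if (is.null(names(x)))
    abort(paste0("`", what, "` must be a named vector (names = region ids)."))
  unknown <- setdiff(names(x), as.character(leaves))
  if (length(unknown) > 0)
    abort(paste0("`", what, "` references unknown region ids: ",
                 paste(head(unknown, 5), collapse = ", ")))
  out[names(x)] <- x
  out
}
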