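#' Scene specification for synthetic section images
#'
#' Bundles the geometry, optics and noise parameters for rendering a stack
#' of synthetic coronal sections. Defaults mirror a typical fluorescence
#' acquisition of a full mouse-brain series — 25 sections spanning
#' anterior-posterior (AP) +1.3 to -5.9 mm from bregma at 5 um in-plane
#' pixel size — but at a toy image size that keeps simulation cheap; the
#' full-frame camera geometry (2592 x 1944 px) is configurable.
#'
#' @param n_sections Number of coronal sections (default 25).
#' @param ap_range_mm Length-2 AP range in mm, anterior first
#'   (default `c(1.3, -5.9)`).
#' @param image_shape `c(rows, cols)` in pixels (default `c(160, 120)`).
#' @param pixel_size_um In-plane pixel size in micrometers (default 5).
#' @param rates Named numeric vector: expected cells per section for each
#'   leaf region id. `NULL` means 0 everywhere (an empty brain).
#' @param background_offset Constant background intensity (default 8).
#' @param gradient_amplitude Peak of a linear left-to-right illumination
#'   gradient added to the background (default 4).
#' @param noise_sd Gaussian pixel-noise standard deviation (default 2).
#' @param spot_radius_px Radius of the hard-disk spot rendered per cell
#'   (default 2).
#' @param spot_peak Intensity added inside a spot (default 120; well above
#'   the usual detection threshold of 20).
#' @param min_separation_px Minimum center-to-center distance between cells
#'   in a section; default two spot diameters (`4 * spot_radius_px`), which
#'   keeps spots disjoint so detection recall is exactly analyzable. Set to
#'   0 to allow overlap for stress tests.
#' @param seed Integer seed for the render.
#' @return A `trap_scene_spec` list.
#' @export
scene_spec <- function(n_sections = 25,
                       ap_range_mm = c(1.3, -5.9),
                       image_shape = c(160, 120),
                       pixel_size_um = 5,
                       rates = NULL,
                       background_offset = 8,
                       gradient_amplitude = 4,
                       noise_sd = 2,
                       spot_radius_px = 2,
                       spot_peak = 120,
                       min_separation_px = NULL,
                       seed = 1L) {
  if (n_sections < 1) abort("`n_sections` must be >= 1.")
  if (length(image_shape) != 2L || any(image_shape < 8))
    abort("`image_shape` must be c(rows, cols) with both >= 8.")
  if (!is.null(rates) && any(rates < 0))
    abort("`rates` must be non-negative.")
  if (spot_radius_px <= 0) abort("`spot_radius_px` must be positive.")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (is.null(min_separation_px)) min_separation_px <- 4 * spot_radius_px
  structure(list(
    n_sections = as.integer(n_sections),
    ap_range_mm = as.numeric(ap_range_mm),
    image_shape = as.integer(image_shape),
    pixel_size_um = pixel_size_um,
    rates = rates,
    background_offset = background_offset,
    gradient_amplitude = gradient_amplitude,
    noise_sd = noise_sd,
    spot_radius_px = spot_radius_px,
    spot_peak = spot_peak,
    min_separation_px = min_separation_px,
    seed = as.integer(seed)
  ), class = "trap_scene_spec")
}

#' Construct a section image
#'
#' A section image is a numeric matrix (rows = y, cols = x) with attributes
#' `ap_mm`, `section_index` and `pixel_size_um`. Coordinates reported by the
#' pipeline are 0-based with pixel centers at integers: x = column, y = row.
#'
#' @param pixels Numeric matrix, at least 3x3, non-negative.
#' @param ap_mm AP coordinate of the section in mm.
#' @param section_index Integer section index.
#' @param pixel_size_um In-plane pixel size in micrometers.
#' @return The matrix with section attributes attached.
#' @export
section_image <- function(pixels, ap_mm = NA_real_, section_index = 1L,
                          pixel_size_um = 5) {
  if (!is.matrix(pixels) || nrow(pixels) < 3 || ncol(pixels) < 3)
    abort("`pixels` must be a matrix of at least 3 x 3.")
  if (any(pixels < 0)) abort("`pixels` must be non-negative.")
  attr(pixels, "ap_mm") <- ap_mm
  attr(pixels, "section_index") <- as.integer(section_index)
  attr(pixels, "pixel_size_um") <- pixel_size_um
  pixels
}

#' Render a synthetic section stack with ground truth
#'
#' Generates co-registered intensity images and region label maps for one
#' animal. Each section holds an elliptical "brain" mask tiled into
#' contiguous leaf-region patches (a Voronoi tessellation of seed points
#' inside the ellipse — convex cells, so every patch is connected); pixels
#' outside the mask carry label 0. Cells are placed per section and region
#' by Poisson draws from the rate table, at uniformly sampled in-region
#' pixel centers at least `min_separation_px` apart and at least one spot
#' radius from the image border, and rendered as hard disks of
#' `spot_peak` intensity added to a background of constant offset, linear
#' illumination gradient and Gaussian noise. The full render is reproducible
#' from the spec's seed.
#'
#' @param ontology A region ontology; its leaves tile the sections.
#' @param spec A [scene_spec()].
#' @return A `trap_scene` list: `images` (list of section matrices),
#'   `labels` (list of integer label matrices with the same attributes),
#'   `truth` (list with `cells` — tibble of `section_index`, `x_px`, `y_px`,
#'   `region_id` — and `counts` — tibble of `region_id`, `count` over all
#'   leaves), and the `spec`.
#' @export
render_scene <- function(ontology, spec) {
  stopifnot(inherits(spec, "trap_scene_spec"))
  leaves <- ontology_leaves(ontology)
  rates <- .fill_region_vector(spec$rates, leaves, default = 0,
                               what = "rates")
  set.seed(spec$seed)

  nr <- spec$image_shape[1]
  nc <- spec$image_shape[2]
  ap <- if (spec$n_sections == 1L) spec$ap_range_mm[1] else
    seq(spec$ap_range_mm[1], spec$ap_range_mm[2],
        length.out = spec$n_sections)

  # elliptical brain mask shared by all sections (0-based pixel centers)
  xs <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  ys <- matrix(rep(0:(nr - 1), nc), nr, nc)
  cx <- (nc - 1) / 2; cy <- (nr - 1) / 2
  ax <- 0.45 * nc; ay <- 0.45 * nr
  mask <- ((xs - cx) / ax)^2 + ((ys - cy) / ay)^2 <= 1

  # Voronoi tessellation of the mask into leaf patches
  in_idx <- which(mask)
  k <- length(leaves)
  seed_idx <- sample(in_idx, k, replace = length(in_idx) < k)
  nearest <- integer(length(in_idx))
  px <- xs[in_idx]; py <- ys[in_idx]
  best <- rep(Inf, length(in_idx))
  for (j in seq_len(k)) {
    dj <- (px - xs[seed_idx[j]])^2 + (py - ys[seed_idx[j]])^2
    upd <- dj < best
    best[upd] <- dj[upd]
    nearest[upd] <- j
  }
  label_mat <- matrix(0L, nr, nc)
  label_mat[in_idx] <- as.integer(leaves[nearest])

  r <- spec$spot_radius_px
  # candidate cell centers: in-mask pixels at least r+1 px from each border
  interior <- mask & xs >= (r + 1) & xs <= (nc - r - 2) &
    ys >= (r + 1) & ys <= (nr - r - 2)
  disk_off <- .disk_offsets(r)

  grad <- spec$gradient_amplitude * xs / max(nc - 1, 1)

  images <- vector("list", spec$n_sections)
  labels <- vector("list", spec$n_sections)
  cells <- vector("list", spec$n_sections)
  for (s in seq_len(spec$n_sections)) {
    img <- spec$background_offset + grad
    placed_x <- numeric(0); placed_y <- numeric(0); placed_r <- integer(0)
    for (j in seq_len(k)) {
      lam <- rates[[as.character(leaves[j])]]
      if (lam <= 0) next
      n_cells <- rpois(1, lam)
      if (n_cells == 0) next
      cand <- which(interior & label_mat == leaves[j])
      if (length(cand) == 0) next
      for (i in seq_len(n_cells)) {
        for (try in seq_len(50L)) {
          pick <- cand[sample.int(length(cand), 1)]
          x0 <- xs[pick]; y0 <- ys[pick]
          if (length(placed_x) == 0 ||
              all((placed_x - x0)^2 + (placed_y - y0)^2 >=
                  spec$min_separation_px^2)) {
            placed_x <- c(placed_x, x0)
            placed_y <- c(placed_y, y0)
            placed_r <- c(placed_r, leaves[j])
            rows <- y0 + disk_off$dy + 1L
            cols <- x0 + disk_off$dx + 1L
            img[cbind(rows, cols)] <- img[cbind(rows, cols)] + spec$spot_peak
            break
          }
        }
      }
    }
    if (spec$noise_sd > 0)
      img <- img + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    img <- pmin(pmax(round(img), 0), 65535)
    images[[s]] <- section_image(img, ap_mm = ap[s], section_index = s,
                                 pixel_size_um = spec$pixel_size_um)
    lab <- label_mat
    attr(lab, "ap_mm") <- ap[s]
    attr(lab, "section_index") <- s
    labels[[s]] <- lab
    cells[[s]] <- tibble(
      section_index = s, x_px = placed_x, y_px = placed_y,
      region_id = as.integer(placed_r)
    )
  }
  cells <- bind_rows(cells)
  counts <- tibble(region_id = as.integer(leaves)) %>%
    left_join(dplyr::count(cells, .data$region_id, name = "count"),
              by = "region_id") %>%
    mutate(count = tidyr::replace_na(.data$count, 0L))

  structure(list(images = images, labels = labels,
                 truth = list(cells = cells, counts = counts),
                 spec = spec),
            class = "trap_scene")
}

# integer offsets of a hard disk of radius r (dx^2 + dy^2 <= r^2)
.disk_offsets <- function(r) {
  g <- expand.grid(dx = -floor(r):floor(r), dy = -floor(r):floor(r))
  g <- g[g$dx^2 + g$dy^2 <= r^2, ]
  list(dx = as.integer(g$dx), dy = as.integer(g$dy))
}

#' Write / read section images as TIFF
#'
#' Images are written as single-plane grayscale TIFF (16-bit), label maps as
#' 16-bit integer TIFF. The `tiff` package stores samples on \[0, 1\];
#' values are scaled by 65535 on write and restored on read.
#'
#' @param image Numeric matrix (intensities or integer labels).
#' @param path File path.
#' @return `write_section_tiff` returns `path` invisibly;
#'   `read_section_tiff` returns an integer-valued matrix.
#' @export
write_section_tiff <- function(image, path) {
  m <- pmin(pmax(as.matrix(image), 0), 65535) / 65535
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_section_tiff
#' @export
read_section_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  round(m * 65535)
}
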