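#' Detection parameters
#'
#' Parameters of the cell-detection chain, defaulting to the standard
#' ImageJ-style recipe for fluorescent nuclei in widefield sections: 3x3
#' median filter, rolling-ball background subtraction with a 5-pixel ball,
#' intensity threshold of 20 on the background-subtracted image, and
#' exclusion of connected components smaller than 2 pixels.
#'
#' @param median_window Odd window size of the median filter (default 3).
#' @param ball_radius_px Rolling-ball radius in pixels (default 5).
#' @param intensity_threshold Threshold applied to the median-filtered,
#'   background-subtracted image; pixels with intensity `>= threshold` are
#'   foreground (default 20).
#' @param min_component_px Minimum connected-component size kept
#'   (default 2; components smaller than this are excluded).
#' @param connectivity Pixel connectivity for component labeling, 8
#'   (default) or 4.
#' @return A `trap_detection_params` list.
#' @export
detection_params <- function(median_window = 3L,
                             ball_radius_px = 5,
                             intensity_threshold = 20,
                             min_component_px = 2L,
                             connectivity = 8L) {
  if (median_window %% 2 != 1 || median_window < 1)
    abort("`median_window` must be an odd positive integer.")
  if (ball_radius_px <= 0) abort("`ball_radius_px` must be positive.")
  if (min_component_px < 1) abort("`min_component_px` must be >= 1.")
  if (!connectivity %in% c(4L, 8L))
    abort("`connectivity` must be 4 or 8.")
  structure(list(
    median_window = as.integer(median_window),
    ball_radius_px = ball_radius_px,
    intensity_threshold = intensity_threshold,
    min_component_px = as.integer(min_component_px),
    connectivity = as.integer(connectivity)
  ), class = "trap_detection_params")
}

# stack of shifted copies of `m` for window offsets, edge-replicated
.shifted_stack <- function(m, offsets_dy, offsets_dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr * nc, length(offsets_dy))
  for (j in seq_along(offsets_dy)) {
    ri <- pmin(pmax(seq_len(nr) + offsets_dy[j], 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + offsets_dx[j], 1L), nc)
    out[, j] <- m[ri, ci]
  }
  out
}

#' Median filter with edge replication
#'
#' Replaces each pixel by the median of its `window` x `window`
#' neighborhood; borders are handled by edge replication, so the output has
#' the input's shape.
#'
#' @param image Numeric matrix.
#' @param window Odd window size (default 3).
#' @return Filtered matrix; section attributes are preserved.
#' @export
median_filter <- function(image, window = 3L) {
  if (window %% 2 != 1 || window < 1)
    abort("`window` must be an odd positive integer.")
  if (nrow(image) < window || ncol(image) < window)
    abort("image is smaller than the median window.")
  if (window == 1L) return(image)
  h <- (window - 1L) %/% 2L
  off <- expand.grid(dy = -h:h, dx = -h:h)
  stack <- .shifted_stack(image, off$dy, off$dx)
  # row-wise sort via order(row, value): fully vectorized median of k
  k <- ncol(stack)
  srt <- matrix(stack[order(row(stack), stack)], ncol = k, byrow = TRUE)
  med <- srt[, (k + 1L) %/% 2L]
  out <- image
  out[] <- med
  out
}

# offsets and spherical-cap heights of a ball structuring element
.ball_element <- function(radius) {
  ri <- floor(radius)
  g <- expand.grid(dy = -ri:ri, dx = -ri:ri)
  keep <- g$dx^2 + g$dy^2 <= radius^2
  g <- g[keep, ]
  list(dy = as.integer(g$dy), dx = as.integer(g$dx),
       h = sqrt(radius^2 - g$dx^2 - g$dy^2))
}

# grayscale erosion/dilation with a non-flat element, truncated at borders
.gray_morph <- function(image, elem, op = c("erode", "dilate")) {
  op <- match.arg(op)
  nr <- nrow(image); nc <- ncol(image)
  acc <- matrix(if (op == "erode") Inf else -Inf, nr, nc)
  for (j in seq_along(elem$h)) {
    dy <- elem$dy[j]; dx <- elem$dx[j]; h <- elem$h[j]
    # destination rows/cols whose offset source lies inside the image
    dst_r <- max(1L, 1L - dy):min(nr, nr - dy)
    dst_c <- max(1L, 1L - dx):min(nc, nc - dx)
    src <- image[dst_r + dy, dst_c + dx, drop = FALSE]
    if (op == "erode") {
      acc[dst_r, dst_c] <- pmin(acc[dst_r, dst_c], src - h)
    } else {
      acc[dst_r, dst_c] <- pmax(acc[dst_r, dst_c], src + h)
    }
  }
  acc
}

#' Rolling-ball background estimation
#'
#' Estimates the smooth background of a fluorescence image as the grayscale
#' opening (erosion then dilation) with a ball-shaped structuring element: a
#' disk of the given radius whose height profile is the spherical cap
#' `h(dx, dy) = sqrt(r^2 - dx^2 - dy^2)`. Opening is anti-extensive, so the
#' background never exceeds the image at any pixel; structures narrower than
#' the ball (the cell spots) are excluded from the background. The element
#' is truncated at image borders.
#'
#' This is a mathematically exact opening rather than the shrink/enlarge
#' approximation some interactive tools use for speed; the two agree on
#' smooth backgrounds with compact bright spots.
#'
#' @param image Numeric matrix.
#' @param radius_px Ball radius in pixels (> 0).
#' @return Background matrix of the same shape, `<= image` everywhere.
#' @export
rolling_ball_background <- function(image, radius_px = 5) {
  if (radius_px <= 0) abort("`radius_px` must be positive.")
  elem <- .ball_element(radius_px)
  er <- .gray_morph(image, elem, "erode")
  bg <- .gray_morph(er, elem, "dilate")
  out <- image
  out[] <- bg
  out
}

#' Subtract the rolling-ball background
#'
#' @param image Numeric matrix.
#' @param radius_px Ball radius in pixels.
#' @return `image - background`, clipped at 0; attributes preserved.
#' @export
subtract_background <- function(image, radius_px = 5) {
  bg <- rolling_ball_background(image, radius_px)
  out <- image
  out[] <- pmax(image - bg, 0)
  out
}

#' Label connected components of a binary mask
#'
#' @param mask Logical matrix (TRUE = foreground).
#' @param connectivity 4 or 8.
#' @return Integer matrix of component labels (0 = background), labels
#'   numbered from 1 in raster order of each component's first pixel.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) abort("`connectivity` must be 4 or 8.")
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask)
  out <- matrix(0L, nr, nc)
  if (length(fg) == 0L) return(out)
  idx_of <- integer(nr * nc)
  idx_of[fg] <- seq_along(fg)
  rr <- ((fg - 1L) %% nr) + 1L
  cc <- ((fg - 1L) %/% nr) + 1L
  if (connectivity == 4L) {
    off <- cbind(dy = c(-1L, 1L, 0L, 0L), dx = c(0L, 0L, -1L, 1L))
  } else {
    off <- cbind(dy = c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
                 dx = c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))
  }
  edges <- list()
  for (j in seq_len(nrow(off))) {
    nr2 <- rr + off[j, "dy"]; nc2 <- cc + off[j, "dx"]
    ok <- nr2 >= 1L & nr2 <= nr & nc2 >= 1L & nc2 <= nc
    nidx <- (nc2[ok] - 1L) * nr + nr2[ok]
    nb <- idx_of[nidx]
    keep <- nb > 0L
    edges[[j]] <- cbind(idx_of[fg][ok][keep], nb[keep])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(
    rbind(edges, cbind(seq_along(fg), seq_along(fg))), directed = FALSE
  )
  comp <- igraph::components(g)$membership[seq_along(fg)]
  # renumber components by raster order (column-major) of first appearance
  first <- order(fg)
  relab <- integer(max(comp))
  nxt <- 0L
  for (i in first) {
    if (relab[comp[i]] == 0L) {
      nxt <- nxt + 1L
      relab[comp[i]] <- nxt
    }
  }
  out[fg] <- relab[comp]
  out
}

#' Detect labeled cells in a section image
#'
#' Runs the full detection chain: median filter, rolling-ball background
#' subtraction, binarization at the intensity threshold (`>=`), connected
#' component labeling, exclusion of components below the minimum size, and
#' unweighted centroid extraction. Centroids are 0-based pixel-center
#' coordinates (x = column, y = row).
#'
#' @param image A section matrix (use [section_image()] to attach AP and
#'   section metadata; bare matrices are treated as section 1).
#' @param params A [detection_params()] list.
#' @return A tibble of cell records sorted by (section, y, x):
#'   `section_index`, `ap_mm`, `x_px`, `y_px`, `size_px`, `region_id`
#'   (0 until assigned).
#' @examples
#' img <- matrix(0, 32, 32)
#' img[10:12, 10:12] <- 100
#' detect_cells(section_image(img), detection_params())
#' @export
detect_cells <- function(image, params = detection_params()) {
  stopifnot(inherits(params, "trap_detection_params"))
  if (nrow(image) < params$median_window ||
      ncol(image) < params$median_window)
    abort("image is smaller than the median window.")
  sec <- attr(image, "section_index") %||% 1L
  ap <- attr(image, "ap_mm") %||% NA_real_

  filt <- median_filter(image, params$median_window)
  sub <- subtract_background(filt, params$ball_radius_px)
  mask <- sub >= params$intensity_threshold
  lab <- label_components(mask, params$connectivity)
  if (max(lab) == 0L) {
    return(tibble(
      section_index = integer(0), ap_mm = numeric(0), x_px = numeric(0),
      y_px = numeric(0), size_px = integer(0), region_id = integer(0)
    ))
  }
  idx <- which(lab > 0L)
  comp <- lab[idx]
  nr <- nrow(image)
  y0 <- ((idx - 1L) %% nr)        # 0-based row
  x0 <- ((idx - 1L) %/% nr)       # 0-based col
  size <- tabulate(comp)
  cx <- tapply(x0, comp, mean)
  cy <- tapply(y0, comp, mean)
  keep <- size >= params$min_component_px
  out <- tibble(
    section_index = as.integer(sec), ap_mm = ap,
    x_px = as.numeric(cx)[keep], y_px = as.numeric(cy)[keep],
    size_px = as.integer(size[keep]), region_id = 0L
  )
  arrange(out, .data$section_index, .data$y_px, .data$x_px)
}

#' Detect cells across a list of section images
#'
#' @param images List of section matrices (see [section_image()]).
#' @param params A [detection_params()] list.
#' @return A tibble of cell records across sections.
#' @export
detect_cells_stack <- function(images, params = detection_params()) {
  bind_rows(lapply(images, detect_cells, params = params))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
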