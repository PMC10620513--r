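# Brute-force oracles, kept deliberately independent of the package's
# implementations: plain loops, closed forms, exhaustive enumeration.

# per-pixel sort-and-pick median with edge replication
oracle_median_filter <- function(img, window) {
  h <- (window - 1) %/% 2
  nr <- nrow(img); nc <- ncol(img)
  out <- img
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      vals <- numeric(0)
      for (di in -h:h) {
        for (dj in -h:h) {
          ii <- min(max(i + di, 1), nr)
          jj <- min(max(j + dj, 1), nc)
          vals <- c(vals, img[ii, jj])
        }
      }
      out[i, j] <- sort(vals)[(length(vals) + 1) %/% 2]
    }
  }
  out
}

# grayscale erosion/dilation with a spherical-cap ball, truncated at borders
oracle_opening <- function(img, radius) {
  ri <- floor(radius)
  offs <- expand.grid(dy = -ri:ri, dx = -ri:ri)
  offs <- offs[offs$dx^2 + offs$dy^2 <= radius^2, ]
  offs$h <- sqrt(radius^2 - offs$dx^2 - offs$dy^2)
  nr <- nrow(img); nc <- ncol(img)
  morph <- function(m, op) {
    out <- matrix(if (op == "min") Inf else -Inf, nr, nc)
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        for (k in seq_len(nrow(offs))) {
          ii <- i + offs$dy[k]; jj <- j + offs$dx[k]
          if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
            v <- if (op == "min") m[ii, jj] - offs$h[k]
                 else m[ii, jj] + offs$h[k]
            if (op == "min") out[i, j] <- min(out[i, j], v)
            else out[i, j] <- max(out[i, j], v)
          }
        }
      }
    }
    out
  }
  morph(morph(img, "min"), "max")
}

# flood-fill component labeling, labels in column-major first-pixel order
oracle_flood_fill <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  if (connectivity == 4) {
    nb <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    nb <- cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  }
  for (idx in which(mask)) { # column-major scan
    if (lab[idx] != 0L) next
    nxt <- nxt + 1L
    queue <- idx
    lab[idx] <- nxt
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      ci <- ((cur - 1) %% nr) + 1; cj <- ((cur - 1) %/% nr) + 1
      for (k in seq_len(nrow(nb))) {
        ii <- ci + nb[k, 1]; jj <- cj + nb[k, 2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- nxt
          queue <- c(queue, (jj - 1) * nr + ii)
        }
      }
    }
  }
  lab
}

# classical balanced 2x2 sums-of-squares decomposition from cell means
oracle_anova_2x2 <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  n <- length(y) / 4
  grand <- mean(y)
  ma <- tapply(y, a, mean)
  mb <- tapply(y, b, mean)
  mab <- tapply(y, interaction(a, b), mean)
  ss_a <- 2 * n * sum((ma - grand)^2)
  ss_b <- 2 * n * sum((mb - grand)^2)
  cell <- expand.grid(a = levels(a), b = levels(b))
  ss_ab <- n * sum((mab[paste(cell$a, cell$b, sep = ".")] -
                      ma[cell$a] - mb[cell$b] + grand)^2)
  fitted <- mab[paste(a, b, sep = ".")]
  ss_res <- sum((y - fitted)^2)
  df_res <- length(y) - 4
  tibble::tibble(
    term = c("condition", "method", "condition:method", "residual"),
    sumsq = c(ss_a, ss_b, ss_ab, ss_res),
    statistic = c((c(ss_a, ss_b, ss_ab) / 1) / (ss_res / df_res), NA),
    p.value = c(stats::pf((c(ss_a, ss_b, ss_ab)) / (ss_res / df_res),
                          1, df_res, lower.tail = FALSE), NA)
  )
}

# closed-form Pearson correlation
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# two-sample KS: sup ECDF difference on the pooled grid, exact p by
# complete enumeration of all C(n+m, n) group assignments
oracle_ks <- function(xa, xb) {
  grid <- sort(unique(c(xa, xb)))
  ecdf_at <- function(x, g) vapply(g, function(t) mean(x <= t), numeric(1))
  d_of <- function(a, b) max(abs(ecdf_at(a, grid) - ecdf_at(b, grid)))
  D <- d_of(xa, xb)
  pooled <- c(xa, xb)
  na <- length(xa)
  splits <- utils::combn(length(pooled), na)
  hits <- 0
  for (k in seq_len(ncol(splits))) {
    ia <- splits[, k]
    if (d_of(pooled[ia], pooled[-ia]) >= D - 1e-12) hits <- hits + 1
  }
  list(D = D, p = hits / ncol(splits))
}

# independent leaf -> depth-2 ancestor walk and summation
oracle_parent_sums <- function(counts, ontology) {
  anc <- function(id) {
    repeat {
      row <- which(ontology$region_id == id)
      if (ontology$depth[row] == 2) return(id)
      id <- ontology$parent_id[row]
    }
  }
  counts$parent <- vapply(counts$region_id, anc, numeric(1))
  stats::aggregate(count ~ animal_id + parent, data = counts, FUN = sum)
}

# small deterministic scene used by several tests
make_test_scene <- function(n_parents = 3, leaves_per_parent = 2,
                            rate = 1.5, n_sections = 3, noise_sd = 0,
                            seed = 7) {
  ont <- build_toy_ontology(n_parents, leaves_per_parent)
  leaves <- ontology_leaves(ont)
  sp <- scene_spec(
    n_sections = n_sections, image_shape = c(96, 80), noise_sd = noise_sd,
    rates = stats::setNames(rep(rate, length(leaves)), leaves), seed = seed
  )
  list(ontology = ont, spec = sp, scene = render_scene(ont, sp))
}
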