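#' Configuration for the synthetic plant/background image generator
#'
#' Describes a set of square RGB crops emulating field imagery: green leaf-like
#' foreground structures on brown/gray textured soil with stones, plus
#' background-only crops (soil, stones, occasional small green distractors).
#'
#' @param image_size pixels per side (square, >= 8).
#' @param n_plant number of plant images (label 1).
#' @param n_background number of background images (label 0).
#' @param leaf_complexity integer >= 1; number of leaf lobes per plant (1-2
#'   emulates simple entire leaves, larger values dissected rosettes).
#' @param foreground_green_level mean excess-green (2G - R - B) of plant pixels
#'   on the 0-255 channel scale. Default 120.
#' @param background_noise_sd per-channel i.i.d. noise SD. Default 10.
#' @param confound optional [confound_spec()] applied after generation.
#' @param seed master integer seed; every image draws from a child seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(image_size = 32, n_plant = 100, n_background = 100,
                             leaf_complexity = 3, foreground_green_level = 120,
                             background_noise_sd = 10, confound = NULL, seed = 1) {
  if (image_size < 8) stop_param("image_size must be >= 8")
  if (n_plant < 0 || n_background < 0) stop_param("image counts must be >= 0")
  if (leaf_complexity < 1) stop_param("leaf_complexity must be >= 1")
  structure(list(image_size = image_size, n_plant = n_plant,
                 n_background = n_background, leaf_complexity = leaf_complexity,
                 foreground_green_level = foreground_green_level,
                 background_noise_sd = background_noise_sd,
                 confound = confound, seed = seed),
            class = "synthetic_config")
}

#' Confound marker specification
#'
#' A small, label-correlated background marker used to emulate the clever-Hans
#' phenomenon: an image region that predicts the label without being plant
#' foreground. The marker is painted with probability `rho` on plant images and
#' `1 - rho` on background images, and is never added to ground-truth masks.
#'
#' The default color is a saturated green so the marker survives the
#' excess-green conversion (a white or gray marker would map to zero).
#'
#' @param position one of `"topleft"`, `"topright"`, `"bottomleft"`,
#'   `"bottomright"`, or an integer pair `c(row, col)` of the marker's top-left
#'   corner.
#' @param size marker side length in pixels.
#' @param rho label-correlation probability in `[0, 1]`.
#' @param color length-3 RGB vector (0-255).
#' @return object of class `confound_spec`.
#' @export
confound_spec <- function(position = "topleft", size = 4, rho = 1.0,
                          color = c(40, 220, 40)) {
  if (rho < 0 || rho > 1) stop_param("rho must be in [0, 1]")
  if (size < 1) stop_param("size must be >= 1")
  structure(list(position = position, size = size, rho = rho, color = color),
            class = "confound_spec")
}

# --- internal rendering helpers -------------------------------------------

# pixel-center coordinate grids (row = y, col = x), 1-based
.coord_grid <- function(n) {
  list(x = matrix(rep(seq_len(n), each = n), n, n),
       y = matrix(rep(seq_len(n), times = n), n, n))
}

# logical mask of a rotated ellipse
.ellipse_mask <- function(grid, cx, cy, a, b, theta) {
  dx <- grid$x - cx; dy <- grid$y - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  u * u + v * v <= 1
}

# smooth low-frequency texture field in [-1, 1], shared across channels
.texture_field <- function(n) {
  coarse <- matrix(stats::rnorm(ceiling(n / 4)^2), ceiling(n / 4))
  f <- EBImage::resize(coarse, w = n, h = n)
  f / max(abs(f), 1e-9)
}

# soil background with stones; returns list(img = n x n x 3, stones = mask)
.render_soil <- function(n, noise_sd) {
  base <- c(110, 95, 75) + stats::rnorm(3, 0, 8) # brown: R > G > B, ExG ~ 0
  tex <- .texture_field(n) * 12
  img <- array(0, dim = c(n, n, 3))
  for (ch in 1:3) img[, , ch] <- base[ch] + tex + stats::rnorm(n * n, 0, noise_sd)
  grid <- .coord_grid(n)
  stones <- matrix(FALSE, n, n)
  for (s in seq_len(stats::rpois(1, 2))) {
    r <- stats::runif(1, n / 16, n / 8)
    m <- .ellipse_mask(grid, stats::runif(1, 1, n), stats::runif(1, 1, n),
                       r, r * stats::runif(1, 0.6, 1), stats::runif(1, 0, pi))
    gray <- stats::runif(1, 125, 165) # stones gray: ExG ~ 0
    for (ch in 1:3) { p <- img[, , ch]; p[m] <- gray + stats::rnorm(sum(m), 0, noise_sd); img[, , ch] <- p }
    stones <- stones | m
  }
  list(img = img, stones = stones)
}

# leaf rosette: union of `lobes` rotated ellipses radiating from a center
.render_leaf_mask <- function(n, lobes) {
  grid <- .coord_grid(n)
  cx <- n / 2 + stats::runif(1, -n / 8, n / 8)
  cy <- n / 2 + stats::runif(1, -n / 8, n / 8)
  mask <- .ellipse_mask(grid, cx, cy, n / 12, n / 12, 0) # central disc, never empty
  base_angle <- stats::runif(1, 0, 2 * pi)
  for (k in seq_len(lobes)) {
    theta <- base_angle + 2 * pi * (k - 1) / lobes + stats::rnorm(1, 0, 0.15)
    r <- stats::runif(1, 0.12, 0.22) * n
    a <- stats::runif(1, 0.12, 0.2) * n
    b <- stats::runif(1, 0.05, 0.1) * n
    mask <- mask | .ellipse_mask(grid, cx + r * cos(theta), cy + r * sin(theta),
                                 a, b, theta)
  }
  mask
}

# paint green foreground pixels so that mean ExG ~ green_level
.paint_green <- function(img, mask, green_level, noise_sd) {
  k <- sum(mask)
  if (k == 0) return(img)
  R <- 60 + stats::rnorm(k, 0, noise_sd)
  B <- 50 + stats::rnorm(k, 0, noise_sd)
  G <- (green_level + R + B) / 2 + stats::rnorm(k, 0, noise_sd)
  p <- img[, , 1]; p[mask] <- R; img[, , 1] <- p
  p <- img[, , 2]; p[mask] <- G; img[, , 2] <- p
  p <- img[, , 3]; p[mask] <- B; img[, , 3] <- p
  img
}

.clamp255 <- function(img) { img[img < 0] <- 0; img[img > 255] <- 255; round(img) }

#' Generate a labeled synthetic plant/background image set
#'
#' Plant images contain a connected green leaf rosette whose pixels are
#' recorded in a ground-truth mask; background images contain textured soil,
#' stones, and occasionally small green distractor blobs (capped at 5% of the
#' image area) that are *not* counted as foreground. Output is deterministic
#' under the configuration seed.
#'
#' @param config a [synthetic_config()].
#' @return object of class `labeled_image_set`: list with `images` (list of
#'   `n x n x 3` integer arrays, 0-255), `labels` (1 = plant, 0 = background),
#'   `masks` (list of logical matrices), `seed`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$image_size
  n_img <- config$n_plant + config$n_background
  labels <- c(rep(1L, config$n_plant), rep(0L, config$n_background))
  images <- vector("list", n_img)
  masks <- vector("list", n_img)
  for (i in seq_len(n_img)) {
    res <- with_seed(child_seed(config$seed, i), {
      soil <- .render_soil(n, config$background_noise_sd)
      img <- soil$img
      if (labels[i] == 1L) {
        mask <- .render_leaf_mask(n, config$leaf_complexity)
        img <- .paint_green(img, mask, config$foreground_green_level,
                            config$background_noise_sd)
      } else {
        mask <- matrix(FALSE, n, n)
        # occasional small green distractors ("other plants"), <= 5% of area
        if (stats::runif(1) < 0.5) {
          grid <- .coord_grid(n)
          budget <- 0.05 * n * n
          for (s in seq_len(sample(1:2, 1))) {
            r <- stats::runif(1, n / 20, n / 12)
            dm <- .ellipse_mask(grid, stats::runif(1, 1, n), stats::runif(1, 1, n),
                                r, r * 0.7, stats::runif(1, 0, pi))
            if (sum(dm) <= budget) {
              img <- .paint_green(img, dm, config$foreground_green_level,
                                  config$background_noise_sd)
              budget <- budget - sum(dm)
            }
          }
        }
      }
      list(img = .clamp255(img), mask = mask)
    })
    images[[i]] <- res$img
    masks[[i]] <- res$mask
  }
  out <- structure(list(images = images, labels = labels, masks = masks,
                        seed = config$seed),
                   class = "labeled_image_set")
  if (!is.null(config$confound)) out <- inject_confound(out, config$confound)
  out
}

#' @export
print.labeled_image_set <- function(x, ...) {
  cat(sprintf("labeled_image_set: %d images (%d plant / %d background), %dx%d px\n",
              length(x$images), sum(x$labels == 1), sum(x$labels == 0),
              nrow(x$images[[1]]), ncol(x$images[[1]])))
  invisible(x)
}

# resolve marker top-left corner; errors if out of bounds
.confound_corner <- function(position, size, n) {
  if (is.character(position)) {
    m <- 2L # margin
    corner <- switch(position,
      topleft = c(m, m), topright = c(m, n - m - size + 1),
      bottomleft = c(n - m - size + 1, m),
      bottomright = c(n - m - size + 1, n - m - size + 1),
      stop_param("unknown confound position: ", position))
  } else corner <- as.integer(position)
  if (corner[1] < 1 || corner[2] < 1 || corner[1] + size - 1 > n || corner[2] + size - 1 > n) {
    stop_param("confound marker exceeds image bounds")
  }
  corner
}

#' Inject a label-correlated background confound
#'
#' Paints the marker described by `spec` with probability `rho` on class-1
#' (plant) images and probability `1 - rho` on class-0 images. Ground-truth
#' masks are left untouched: the marker is never foreground. Marker presence is
#' returned so tests can audit the correlation.
#'
#' @param dataset a [labeled_image_set].
#' @param spec a [confound_spec()].
#' @return the dataset with markers painted and an added logical vector
#'   `confound_present`.
#' @export
inject_confound <- function(dataset, spec) {
  stopifnot(inherits(dataset, "labeled_image_set"), inherits(spec, "confound_spec"))
  n <- nrow(dataset$images[[1]])
  corner <- .confound_corner(spec$position, spec$size, n)
  rows <- corner[1]:(corner[1] + spec$size - 1)
  cols <- corner[2]:(corner[2] + spec$size - 1)
  present <- logical(length(dataset$images))
  for (i in seq_along(dataset$images)) {
    p_mark <- if (dataset$labels[i] == 1L) spec$rho else 1 - spec$rho
    present[i] <- with_seed(child_seed(dataset$seed, 1000000L + i),
                            stats::runif(1) < p_mark)
    if (present[i]) {
      img <- dataset$images[[i]]
      for (ch in 1:3) img[rows, cols, ch] <- spec$color[ch]
      dataset$images[[i]] <- img
    }
  }
  dataset$confound_present <- present
  dataset$confound_region <- list(rows = rows, cols = cols)
  dataset
}

#' Null-map specification for the saliency test's null model
#'
#' Describes a marked homogeneous spatial Poisson process on a pixel grid: a
#' Poisson number of points, locations uniform over the grid, and i.i.d.
#' nonnegative marks.
#'
#' @param shape integer pair `c(rows, cols)`.
#' @param n_points expected number of marked points (Poisson intensity x area).
#' @param mark_distribution list with `name` in `{"exponential", "uniform"}`
#'   and its parameters (`rate`; or `min`, `max`).
#' @param seed integer seed.
#' @return object of class `null_map_spec`.
#' @export
null_map_spec <- function(shape = c(32, 32), n_points = 50,
                          mark_distribution = list(name = "exponential", rate = 1),
                          seed = 1) {
  if (n_points < 0) stop_param("n_points must be >= 0")
  structure(list(shape = shape, n_points = n_points,
                 mark_distribution = mark_distribution, seed = seed),
            class = "null_map_spec")
}

#' Draw a saliency map from the marked homogeneous Poisson null
#'
#' The number of points is Poisson(`n_points`); locations are i.i.d. uniform
#' over the pixel grid (coincident points accumulate their marks); marks are
#' i.i.d. draws from the mark distribution; all other pixels are zero.
#'
#' @param spec a [null_map_spec()].
#' @return a [saliency_map()] with source `"null"`.
#' @export
generate_null_map <- function(spec) {
  stopifnot(inherits(spec, "null_map_spec"))
  md <- spec$mark_distribution
  with_seed(spec$seed, {
    m <- matrix(0, spec$shape[1], spec$shape[2])
    k <- stats::rpois(1, spec$n_points)
    if (k > 0) {
      loc <- sample.int(length(m), k, replace = TRUE)
      marks <- switch(md$name,
        exponential = stats::rexp(k, rate = md$rate %||% 1),
        uniform = stats::runif(k, md$min %||% 0, md$max %||% 1),
        stop_param("unknown mark distribution: ", md$name))
      for (j in seq_len(k)) m[loc[j]] <- m[loc[j]] + marks[j]
    }
    saliency_map(m, source = "null")
  })
}

#' Write a labeled image set to disk (PNG + CSV manifest)
#'
#' Writes each image as an 8-bit PNG, each mask's foreground pixel indices as a
#' CSV of (row, col), and a manifest CSV listing filename, label, mask path and
#' the generator seed.
#'
#' @param dataset a [labeled_image_set].
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_image_set <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(dataset$images), function(i) {
    img_file <- sprintf("img_%04d.png", i)
    png::writePNG(dataset$images[[i]] / 255, file.path(dir, img_file))
    mask_file <- ""
    if (!is.null(dataset$masks[[i]])) {
      mask_file <- sprintf("mask_%04d.csv", i)
      idx <- which(dataset$masks[[i]], arr.ind = TRUE)
      utils::write.csv(data.frame(row = idx[, 1], col = idx[, 2]),
                       file.path(dir, mask_file), row.names = FALSE)
    }
    data.frame(filename = img_file, label = dataset$labels[i],
               mask = mask_file, seed = dataset$seed)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a labeled image set written by [write_image_set()]
#' @param dir directory containing `manifest.csv`.
#' @return a [labeled_image_set].
#' @export
read_image_set <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  images <- lapply(manifest$filename, function(f) {
    a <- png::readPNG(file.path(dir, f))
    round(a[, , 1:3, drop = FALSE] * 255)
  })
  masks <- lapply(seq_len(nrow(manifest)), function(i) {
    n <- dim(images[[i]])[1]
    m <- matrix(FALSE, n, dim(images[[i]])[2])
    mf <- manifest$mask[i]
    if (nzchar(mf)) {
      idx <- utils::read.csv(file.path(dir, mf))
      if (nrow(idx) > 0) m[cbind(idx$row, idx$col)] <- TRUE
    }
    m
  })
  structure(list(images = images, labels = as.integer(manifest$label),
                 masks = masks, seed = manifest$seed[1]),
            class = "labeled_image_set")
}
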