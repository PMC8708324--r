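#' Excess-green index of an RGB image
#'
#' Converts a 3-channel RGB image into a single-channel vegetation-index image
#' using the excess green index \eqn{I_{ExG} = 2 G - R - B}. Green vegetation
#' appears bright; soil and stones appear dark. Values are kept real-valued in
#' \eqn{[-510, 510]} (for 0-255 input); no clipping or rescaling is applied.
#'
#' @param rgb_image numeric array `height x width x 3`, channel order (R, G, B),
#'   values on the 0-255 scale (real-valued inputs are accepted; the index is
#'   linear).
#' @return numeric matrix `height x width` of excess-green values.
#' @export
#' @examples
#' px <- array(c(10, 100, 30), dim = c(1, 1, 3))
#' excess_green(px) # 2*100 - 10 - 30 = 160
excess_green <- function(rgb_image) {
  if (length(dim(rgb_image)) != 3 || dim(rgb_image)[3] != 3) {
    stop_data("excess_green() expects a height x width x 3 array (R,G,B)")
  }
  2.0 * rgb_image[, , 2] - rgb_image[, , 1] - rgb_image[, , 3]
}

#' Build the data matrix Y from a set of images
#'
#' Each image is converted to its excess-green representation, resized to
#' `target_size` x `target_size` with bilinear interpolation, optionally mapped
#' affinely to the unit interval, and flattened row-major into one row of the
#' `N x D` matrix `Y` (`D = target_size^2`).
#'
#' @param images a [labeled_image_set] or a plain list of RGB arrays.
#' @param target_size output side length in pixels (>= 8). Default 32.
#' @param normalization `"none"` keeps raw excess-green values (used for the
#'   GP-LVM, which centers columns itself); `"unit_interval"` applies
#'   `(x + 510) / 1020` so values lie in `[0, 1]` as required by the
#'   binary-cross-entropy autoencoder loss.
#' @return an object of class `data_matrix`: list with `Y` (`N x D`),
#'   `image_shape = c(rows, cols)` and `normalization` (name, offset, scale).
#' @export
build_data_matrix <- function(images, target_size = 32,
                              normalization = c("none", "unit_interval")) {
  normalization <- match.arg(normalization)
  if (inherits(images, "labeled_image_set")) images <- images$images
  if (!is.list(images) || length(images) == 0) {
    stop_data("build_data_matrix() needs a nonempty list of images")
  }
  if (target_size < 8) stop_param("target_size must be >= 8")
  rows <- lapply(images, function(img) {
    g <- excess_green(img)
    if (nrow(g) != target_size || ncol(g) != target_size) {
      g <- EBImage::resize(g, w = target_size, h = target_size)
    }
    flatten_rowmajor(g)
  })
  Y <- do.call(rbind, rows)
  off <- 0; sc <- 1
  if (normalization == "unit_interval") {
    off <- 510; sc <- 1 / 1020
    Y <- (Y + off) * sc
  }
  structure(list(Y = Y,
                 image_shape = c(target_size, target_size),
                 normalization = list(name = normalization, offset = off, scale = sc)),
            class = "data_matrix")
}

#' Unflatten one row of a data matrix back into an image
#'
#' Inverse of the row-major flattening used by [build_data_matrix()].
#'
#' @param v numeric vector of length `rows * cols`.
#' @param shape integer pair `c(rows, cols)`.
#' @return numeric matrix of dimension `shape`.
#' @export
unflatten_image <- function(v, shape) {
  if (length(v) != prod(shape)) stop_param("length(v) != prod(shape)")
  unflatten_rowmajor(v, shape)
}

#' Reshuffled repeated cross-validation plan
#'
#' Builds fold assignments for `n_iterations` independent `n_folds`-fold
#' cross-validations, each on a freshly reshuffled sample order (default
#' 10 x 5-fold). Within an iteration the folds partition the samples and fold
#' sizes differ by at most one; assignments are not stratified by class.
#'
#' @param n_samples number of samples (>= `n_folds`).
#' @param n_folds folds per iteration (default 5).
#' @param n_iterations number of reshuffled iterations (default 10).
#' @param seed integer seed; each iteration draws its shuffle from a child seed.
#' @return object of class `cv_plan`: list with `assignments`
#'   (`n_samples x n_iterations` integer matrix of fold indices), `n_samples`,
#'   `n_folds`, `n_iterations`, `seed`.
#' @export
make_cv_plan <- function(n_samples, n_folds = 5, n_iterations = 10, seed = 1) {
  if (n_folds < 2) stop_param("n_folds must be >= 2")
  if (n_folds > n_samples) stop_param("n_folds must not exceed n_samples")
  assignments <- matrix(NA_integer_, nrow = n_samples, ncol = n_iterations)
  base_folds <- rep(seq_len(n_folds), length.out = n_samples)
  for (it in seq_len(n_iterations)) {
    ord <- with_seed(child_seed(seed, it), sample.int(n_samples))
    assignments[ord, it] <- base_folds
  }
  structure(list(assignments = assignments, n_samples = n_samples,
                 n_folds = n_folds, n_iterations = n_iterations, seed = seed),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("cv_plan: %d samples, %d folds x %d reshuffled iterations (seed %d)\n",
              x$n_samples, x$n_folds, x$n_iterations, x$seed))
  invisible(x)
}

#' Write a CV plan to CSV (iteration, sample_index, fold)
#' @param plan a [make_cv_plan()] object.
#' @param path output CSV path.
#' @export
write_cv_plan <- function(plan, path) {
  df <- do.call(rbind, lapply(seq_len(plan$n_iterations), function(it) {
    data.frame(iteration = it, sample_index = seq_len(plan$n_samples),
               fold = plan$assignments[, it])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
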