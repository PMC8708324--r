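#' Saliency map container
#'
#' A nonnegative per-pixel importance map. Sources: `"bgplvm_variance"` or
#' `"cae_variance"` (pixel-wise variance under latent-dimension sampling),
#' `"null"` (Poisson-process draw) or `"external"` (e.g., a relevance map
#' produced elsewhere). Negative entries of external maps are clipped at zero
#' before significance testing, since the null model assumes nonnegative marks.
#'
#' @param values numeric matrix.
#' @param source character tag.
#' @param feature_id optional latent dimension index the map visualizes.
#' @return object of class `saliency_map`.
#' @export
saliency_map <- function(values, source = "external", feature_id = NULL) {
  if (!is.matrix(values) || any(!is.finite(values))) {
    stop_param("values must be a finite numeric matrix")
  }
  structure(list(values = values, source = source, feature_id = feature_id),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("saliency_map [%s%s]: %dx%d, range [%.4g, %.4g]\n", x$source,
              if (!is.null(x$feature_id)) paste0(", feature ", x$feature_id) else "",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

# default sigma convention for a k x k Gaussian kernel (approx. 1.1 at k = 5)
.default_sigma <- function(k) 0.3 * ((k - 1) / 2 - 1) + 0.8

#' Sparse linear operator for k x k Gaussian smoothing with zero padding
#'
#' Returns the `(rows*cols) x (rows*cols)` sparse matrix `S` such that
#' `S %*% as.vector(m)` equals the zero-padded convolution of the matrix `m`
#' with a unit-sum `k x k` Gaussian kernel. Out-of-image kernel mass is dropped
#' (zero padding), so total mass is conserved up to boundary effects only.
#'
#' @param rows,cols map dimensions.
#' @param kernel_size odd kernel side length k (>= 3).
#' @param sigma Gaussian SD in pixels; default `0.3*((k-1)/2 - 1) + 0.8`.
#' @return a `dgCMatrix`.
#' @export
gaussian_smoothing_matrix <- function(rows, cols, kernel_size = 5, sigma = NULL) {
  if (kernel_size %% 2 != 1 || kernel_size < 3) stop_param("kernel_size must be odd >= 3")
  sigma <- sigma %||% .default_sigma(kernel_size)
  h <- (kernel_size - 1) / 2
  off <- -h:h
  w <- outer(off, off, function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  w <- w / sum(w)
  ii <- jj <- xx <- vector("list", kernel_size^2)
  idx <- 1
  ri <- rep(seq_len(rows), times = cols)
  ci <- rep(seq_len(cols), each = rows)
  for (a in seq_along(off)) for (b in seq_along(off)) {
    r2 <- ri + off[a]; c2 <- ci + off[b]
    ok <- r2 >= 1 & r2 <= rows & c2 >= 1 & c2 <= cols
    ii[[idx]] <- which(ok)                          # output pixel (column-major)
    jj[[idx]] <- (c2[ok] - 1) * rows + r2[ok]       # input pixel
    xx[[idx]] <- rep(w[a, b], sum(ok))
    idx <- idx + 1
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(rows * cols, rows * cols))
}

#' Sampling-based saliency map of one latent dimension
#'
#' Visualizes what a latent dimension encodes: build `N` latent vectors whose
#' entries are the across-sample means of the latent expectations except for
#' dimension `dim`, which takes each sample's actual expectation; project all
#' `N` vectors into image space (GP posterior mean or autoencoder decoder);
#' the per-pixel variance of the projections is the saliency map.
#'
#' @param projector function mapping an `N x d` latent matrix to an `N x D`
#'   image-space matrix (e.g. `model$projector` of [fit_bgplvm()] or a decoder
#'   wrapper from [cae_projector()]).
#' @param latent_expectations `N x d` matrix of latent means (or codes).
#' @param dim latent dimension index to visualize.
#' @param image_shape integer pair used to unflatten the D-vector (row-major).
#' @param source tag stored on the map.
#' @return a [saliency_map()].
#' @export
latent_feature_variance_map <- function(projector, latent_expectations, dim,
                                        image_shape,
                                        source = "bgplvm_variance") {
  latent_expectations <- as.matrix(latent_expectations)
  d <- ncol(latent_expectations)
  if (dim < 1 || dim > d) stop_param("dim out of range")
  if (nrow(latent_expectations) < 2) stop_param("need N >= 2 samples")
  F <- matrix(colMeans(latent_expectations), nrow(latent_expectations), d,
              byrow = TRUE)
  F[, dim] <- latent_expectations[, dim]
  proj <- projector(F)
  v <- apply(proj, 2, stats::var)
  saliency_map(unflatten_rowmajor(v, image_shape), source = source,
               feature_id = dim)
}

#' Randomization significance test for saliency maps
#'
#' Tests, pixel by pixel, whether a saliency map's local mass exceeds what a
#' marked homogeneous spatial Poisson process would produce. The map is
#' smoothed with a `k x k` Gaussian kernel giving `s_alt(x,y)`; each of
#' `n_randomizations` null samples relocates the map's entries uniformly at
#' random and is smoothed identically, giving `s_null(x,y)`; a null sample at
#' a pixel supports the null when `s_alt <= s_null`. The p-value is
#' `(n_null + 1) / (N + 1)` so it is never zero and reproduces the plain
#' `n_null / N` fraction as `N` grows.
#'
#' @param map a [saliency_map()] (negative entries are clipped at zero).
#' @param n_randomizations number of randomizations `N` (study-scale default
#'   10000).
#' @param kernel_size odd Gaussian kernel side `k` (default 5).
#' @param kernel_sigma kernel SD; default `0.3*((k-1)/2 - 1) + 0.8`.
#' @param alpha significance threshold stored on the result (default 0.001).
#' @param permute `"all"` permutes every pixel value (the default; realizes
#'   the homogeneous null exactly for any map); `"nonzero"` relocates only the
#'   nonzero marks, equivalent for sparse maps.
#' @param seed integer seed for the randomizations.
#' @return object of class `pvalue_map`: `smoothed_alt`, `p_values`, `mask`
#'   (`p <= alpha`), plus the test's parameters.
#' @export
saliency_significance <- function(map, n_randomizations = 10000,
                                  kernel_size = 5, kernel_sigma = NULL,
                                  alpha = 0.001, permute = c("all", "nonzero"),
                                  seed = 1) {
  stopifnot(inherits(map, "saliency_map"))
  permute <- match.arg(permute)
  v <- map$values
  if (any(v < 0)) v[v < 0] <- 0
  rows <- nrow(v); cols <- ncol(v); npix <- rows * cols
  sigma <- kernel_sigma %||% .default_sigma(kernel_size)
  S <- gaussian_smoothing_matrix(rows, cols, kernel_size, sigma)
  vec <- as.vector(v)
  s_alt <- as.vector(S %*% vec)
  degenerate <- all(vec == 0)
  if (degenerate) warning("all-zero saliency map: p = 1 everywhere")
  eps <- 1e-9 * max(vec, 1)
  nz_idx <- which(vec > 0); nz_val <- vec[nz_idx]
  n_null <- numeric(npix)
  with_seed(seed, {
    chunk <- 1000L
    done <- 0L
    while (done < n_randomizations) {
      b <- min(chunk, n_randomizations - done)
      P <- matrix(0, npix, b)
      if (!degenerate) {
        if (permute == "all") {
          for (r in seq_len(b)) P[, r] <- vec[sample.int(npix)]
        } else {
          for (r in seq_len(b)) P[sample.int(npix, length(nz_idx)), r] <- nz_val
        }
      }
      s_null <- as.matrix(S %*% P)
      n_null <- n_null + rowSums(s_null >= s_alt - eps)
      done <- done + b
    }
  })
  p <- matrix((n_null + 1) / (n_randomizations + 1), rows, cols)
  structure(list(smoothed_alt = matrix(s_alt, rows, cols),
                 p_values = p, n_randomizations = n_randomizations,
                 kernel_size = kernel_size, kernel_sigma = sigma,
                 alpha = alpha, mask = p <= alpha, seed = seed,
                 permute = permute),
            class = "pvalue_map")
}

#' @export
print.pvalue_map <- function(x, ...) {
  cat(sprintf("pvalue_map: %dx%d, N=%d, k=%d (sigma=%.3f), alpha=%g, %d significant pixels\n",
              nrow(x$p_values), ncol(x$p_values), x$n_randomizations,
              x$kernel_size, x$kernel_sigma, x$alpha, sum(x$mask)))
  invisible(x)
}

#' Threshold a p-value map
#'
#' @param pmap a [saliency_significance()] result.
#' @param alpha threshold in (0, 1); masks are nested in `alpha`.
#' @return logical matrix, `TRUE` where `p <= alpha`.
#' @export
threshold_map <- function(pmap, alpha) {
  stopifnot(inherits(pmap, "pvalue_map"))
  if (alpha <= 0 || alpha > 1) stop_param("alpha must be in (0, 1]")
  pmap$p_values <= alpha
}

#' Read/write saliency maps as exact-valued CSV
#'
#' CSVs hold the raw matrix (no header row/col); PNG export min-max scales to
#' 8 bit and records the scale in a sidecar CSV.
#'
#' @param map a [saliency_map()]; `path` file path.
#' @return the path, invisibly (`read_saliency_csv` returns a [saliency_map()]).
#' @export
write_saliency_csv <- function(map, path) {
  utils::write.table(map$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_saliency_csv
#' @param source,feature_id metadata for the map read back.
#' @export
read_saliency_csv <- function(path, source = "external", feature_id = NULL) {
  saliency_map(as.matrix(utils::read.table(path, sep = ",")), source = source,
               feature_id = feature_id)
}

#' @rdname write_saliency_csv
#' @export
write_saliency_png <- function(map, path) {
  v <- map$values
  rng <- range(v)
  scaled <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  png::writePNG(scaled, path)
  utils::write.csv(data.frame(min = rng[1], max = rng[2]),
                   sub("\\.png$", "_scale.csv", path), row.names = FALSE)
  invisible(path)
}
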