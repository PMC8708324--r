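#' Convolutional autoencoder configuration
#'
#' Encoder: a stack of stride-2 3x3 convolutions with ReLU activations,
#' followed by a linear bottleneck (the *code*). Decoder: the stage-wise
#' inverse — a linear layer back to the last convolutional shape, then
#' stride-2 4x4 transposed convolutions with ReLU, and a final sigmoid layer
#' producing reconstructions in `[0, 1]`. The compact default stack (16-32-64
#' channels) keeps training tractable on a CPU; deeper encoder stacks can be
#' supplied through `encoder_spec`.
#'
#' @param code_size bottleneck width (>= 1).
#' @param encoder_spec list of stages, each `list(channels = ...)`; every
#'   stage halves the spatial resolution.
#' @param epochs training epochs (default 30).
#' @param batch_size minibatch size (default 8).
#' @param learning_rate Adam step size (default 1e-3).
#' @param loss `"binary_cross_entropy"` (default; inputs must be in `[0,1]`)
#'   or `"mse"`.
#' @param seed integer seed (weight init + batch shuffling).
#' @return object of class `cae_config`.
#' @export
cae_config <- function(code_size = 20,
                       encoder_spec = list(list(channels = 16),
                                           list(channels = 32),
                                           list(channels = 64)),
                       epochs = 30, batch_size = 8, learning_rate = 1e-3,
                       loss = c("binary_cross_entropy", "mse"), seed = 1) {
  loss <- match.arg(loss)
  if (code_size < 1) stop_param("code_size must be >= 1")
  if (batch_size < 1) stop_param("batch_size must be >= 1")
  structure(list(code_size = code_size, encoder_spec = encoder_spec,
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, loss = loss, seed = seed),
            class = "cae_config")
}

# ---- conv primitives (shift-and-multiply im2col) -------------------------
# tensors are H x W x C x B arrays

.pad_hw <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

# stride-2 convolution, kernel 3, pad 1: H -> H/2
.conv_fwd <- function(x, W, b, stride = 2, pad = 1) {
  k <- dim(W)[1]; cin <- dim(W)[3]; cout <- dim(W)[4]
  d <- dim(x); B <- d[4]
  xp <- .pad_hw(x, pad)
  Ho <- (d[1] + 2 * pad - k) %/% stride + 1
  Wo <- (d[2] + 2 * pad - k) %/% stride + 1
  ri <- seq(1, by = stride, length.out = Ho)
  ci <- seq(1, by = stride, length.out = Wo)
  out <- matrix(rep(b, each = Ho * Wo * B), Ho * Wo * B, cout)
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    sub <- xp[ri + di - 1, ci + dj - 1, , , drop = FALSE]
    sm <- matrix(aperm(sub, c(1, 2, 4, 3)), Ho * Wo * B, cin)
    out <- out + sm %*% matrix(W[di, dj, , ], cin, cout)
  }
  aperm(array(out, c(Ho, Wo, B, cout)), c(1, 2, 4, 3))
}

.conv_bwd <- function(x, W, dout, stride = 2, pad = 1) {
  k <- dim(W)[1]; cin <- dim(W)[3]; cout <- dim(W)[4]
  d <- dim(x); B <- d[4]
  xp <- .pad_hw(x, pad)
  Ho <- dim(dout)[1]; Wo <- dim(dout)[2]
  ri <- seq(1, by = stride, length.out = Ho)
  ci <- seq(1, by = stride, length.out = Wo)
  dm <- matrix(aperm(dout, c(1, 2, 4, 3)), Ho * Wo * B, cout)
  dW <- array(0, dim(W)); db <- colSums(dm)
  dxp <- array(0, dim(xp))
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    sub <- xp[ri + di - 1, ci + dj - 1, , , drop = FALSE]
    sm <- matrix(aperm(sub, c(1, 2, 4, 3)), Ho * Wo * B, cin)
    dW[di, dj, , ] <- crossprod(sm, dm)
    dsub <- aperm(array(dm %*% t(matrix(W[di, dj, , ], cin, cout)),
                        c(Ho, Wo, B, cin)), c(1, 2, 4, 3))
    dxp[ri + di - 1, ci + dj - 1, , ] <-
      dxp[ri + di - 1, ci + dj - 1, , , drop = FALSE] + dsub
  }
  dx <- if (pad > 0) dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , , drop = FALSE] else dxp
  list(dx = dx, dW = dW, db = db)
}

# transposed convolution, kernel 4, stride 2, pad 1: H -> 2H (adjoint of conv)
.convt_fwd <- function(x, W, b, stride = 2, pad = 1) {
  k <- dim(W)[1]; cin <- dim(W)[3]; cout <- dim(W)[4]
  d <- dim(x); B <- d[4]
  Ho <- (d[1] - 1) * stride + k - 2 * pad
  Wo <- (d[2] - 1) * stride + k - 2 * pad
  ri <- seq(1, by = stride, length.out = d[1])
  ci <- seq(1, by = stride, length.out = d[2])
  outp <- array(0, c(Ho + 2 * pad, Wo + 2 * pad, cout, B))
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * B, cin)
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    contrib <- aperm(array(xm %*% matrix(W[di, dj, , ], cin, cout),
                           c(d[1], d[2], B, cout)), c(1, 2, 4, 3))
    outp[ri + di - 1, ci + dj - 1, , ] <-
      outp[ri + di - 1, ci + dj - 1, , , drop = FALSE] + contrib
  }
  out <- outp[pad + seq_len(Ho), pad + seq_len(Wo), , , drop = FALSE]
  sweep(out, 3, b, "+")
}

.convt_bwd <- function(x, W, dout, stride = 2, pad = 1) {
  k <- dim(W)[1]; cin <- dim(W)[3]; cout <- dim(W)[4]
  d <- dim(x); B <- d[4]
  ri <- seq(1, by = stride, length.out = d[1])
  ci <- seq(1, by = stride, length.out = d[2])
  doutp <- .pad_hw(dout, pad)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * B, cin)
  dW <- array(0, dim(W))
  dxm <- matrix(0, d[1] * d[2] * B, cin)
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    dsub <- doutp[ri + di - 1, ci + dj - 1, , , drop = FALSE]
    dm <- matrix(aperm(dsub, c(1, 2, 4, 3)), d[1] * d[2] * B, cout)
    dW[di, dj, , ] <- crossprod(xm, dm)
    dxm <- dxm + dm %*% t(matrix(W[di, dj, , ], cin, cout))
  }
  db <- as.vector(apply(dout, 3, sum))
  dx <- aperm(array(dxm, c(d[1], d[2], B, cin)), c(1, 2, 4, 3))
  list(dx = dx, dW = dW, db = db)
}

.relu <- function(x) { x[x < 0] <- 0; x }
.sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- parameter init, forward, backward -----------------------------------

.cae_init <- function(config, input_size) {
  ns <- length(config$encoder_spec)
  if (input_size %% (2^ns) != 0) {
    stop_param("input size must be divisible by 2^", ns)
  }
  he <- function(dims, fan_in) array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
  params <- list(enc = list(), dec = list())
  cin <- 1
  for (s in seq_len(ns)) {
    cout <- config$encoder_spec[[s]]$channels
    params$enc[[s]] <- list(W = he(c(3, 3, cin, cout), 9 * cin), b = numeric(cout))
    cin <- cout
  }
  side <- input_size / 2^ns
  nflat <- side * side * cin
  params$fc_enc <- list(W = he(c(nflat, config$code_size), nflat),
                        b = numeric(config$code_size))
  params$fc_dec <- list(W = he(c(config$code_size, nflat), config$code_size),
                        b = numeric(nflat))
  for (s in seq_len(ns)) {
    cin_t <- config$encoder_spec[[ns - s + 1]]$channels
    cout_t <- if (s == ns) 1 else config$encoder_spec[[ns - s]]$channels
    params$dec[[s]] <- list(W = he(c(4, 4, cin_t, cout_t), 16 * cin_t),
                            b = numeric(cout_t))
  }
  attr(params, "conv_shape") <- c(side, side, cin)
  params
}

# full forward pass; keeps intermediates when `keep = TRUE`
.cae_forward <- function(x, params, config, keep = FALSE) {
  ns <- length(params$enc)
  acts <- list(x = x)
  h <- x
  pre <- list()
  for (s in seq_len(ns)) {
    z <- .conv_fwd(h, params$enc[[s]]$W, params$enc[[s]]$b)
    pre[[s]] <- z
    h <- .relu(z)
    acts[[paste0("enc", s)]] <- h
  }
  cs <- attr(params, "conv_shape")
  B <- dim(h)[4]
  hm <- t(matrix(h, prod(cs), B))                     # B x nflat
  code <- sweep(hm %*% params$fc_enc$W, 2, params$fc_enc$b, "+")
  acts$hm <- hm; acts$code <- code
  g <- sweep(code %*% params$fc_dec$W, 2, params$fc_dec$b, "+")
  gz <- g; g <- .relu(g)
  acts$g_pre <- gz; acts$g <- g
  hd <- array(t(g), c(cs[1], cs[2], cs[3], B))
  pre_d <- list()
  for (s in seq_len(ns)) {
    z <- .convt_fwd(hd, params$dec[[s]]$W, params$dec[[s]]$b)
    pre_d[[s]] <- z
    hd_in <- hd
    acts[[paste0("dec_in", s)]] <- hd_in
    hd <- if (s == ns) .sigmoid(z) else .relu(z)
    acts[[paste0("dec", s)]] <- hd
  }
  out <- list(recon = hd, code = code)
  if (keep) { out$acts <- acts; out$pre <- pre; out$pre_d <- pre_d }
  out
}

.cae_loss_grad <- function(x, params, config) {
  fw <- .cae_forward(x, params, config, keep = TRUE)
  y <- fw$recon
  n <- length(y)
  eps <- 1e-7
  if (config$loss == "binary_cross_entropy") {
    yc <- pmin(pmax(y, eps), 1 - eps)
    loss <- -mean(x * log(yc) + (1 - x) * log(1 - yc))
    dz_out <- (y - x) / n                             # sigmoid + BCE shortcut
  } else {
    loss <- mean((y - x)^2)
    dz_out <- 2 * (y - x) * y * (1 - y) / n
  }
  grads <- list(enc = list(), dec = list())
  ns <- length(params$enc)
  dh <- dz_out
  for (s in rev(seq_len(ns))) {
    if (s < ns) dh <- dh * (fw$pre_d[[s]] > 0)        # ReLU for inner stages
    bw <- .convt_bwd(fw$acts[[paste0("dec_in", s)]], params$dec[[s]]$W, dh)
    grads$dec[[s]] <- list(W = bw$dW, b = bw$db)
    dh <- bw$dx
  }
  cs <- attr(params, "conv_shape")
  B <- dim(x)[4]
  dg <- t(matrix(dh, prod(cs), B))                    # B x nflat
  dg <- dg * (fw$acts$g_pre > 0)
  grads$fc_dec <- list(W = crossprod(fw$acts$code, dg), b = colSums(dg))
  dcode <- dg %*% t(params$fc_dec$W)
  grads$fc_enc <- list(W = crossprod(fw$acts$hm, dcode), b = colSums(dcode))
  dhm <- dcode %*% t(params$fc_enc$W)
  dh <- array(t(dhm), c(cs[1], cs[2], cs[3], B))
  for (s in rev(seq_len(ns))) {
    dh <- dh * (fw$pre[[s]] > 0)
    xin <- if (s == 1) fw$acts$x else fw$acts[[paste0("enc", s - 1)]]
    bw <- .conv_bwd(xin, params$enc[[s]]$W, dh)
    grads$enc[[s]] <- list(W = bw$dW, b = bw$db)
    dh <- bw$dx
  }
  list(loss = loss, grads = grads)
}

# flatten params/grads to a named list of arrays for the Adam update
.cae_walk <- function(params, grads, state, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, st) {
    if (is.null(st)) st <- list(m = p * 0, v = p * 0)
    st$m <- b1 * st$m + (1 - b1) * g
    st$v <- b2 * st$v + (1 - b2) * g^2
    mh <- st$m / (1 - b1^t); vh <- st$v / (1 - b2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), st = st)
  }
  for (grp in c("enc", "dec")) {
    for (s in seq_along(params[[grp]])) {
      for (nm in c("W", "b")) {
        key <- paste(grp, s, nm)
        r <- upd(params[[grp]][[s]][[nm]], grads[[grp]][[s]][[nm]], state[[key]])
        params[[grp]][[s]][[nm]] <- r$p; state[[key]] <- r$st
      }
    }
  }
  for (grp in c("fc_enc", "fc_dec")) {
    for (nm in c("W", "b")) {
      key <- paste(grp, nm)
      r <- upd(params[[grp]][[nm]], grads[[grp]][[nm]], state[[key]])
      params[[grp]][[nm]] <- r$p; state[[key]] <- r$st
    }
  }
  list(params = params, state = state)
}

# coerce inputs (list of matrices / data_matrix rows in [0,1]) to H x W x 1 x N
.cae_tensor <- function(images) {
  if (inherits(images, "data_matrix")) {
    if (images$normalization$name != "unit_interval") {
      stop_param("autoencoder inputs must be normalized to [0,1]; ",
                 "use build_data_matrix(..., normalization = 'unit_interval')")
    }
    sh <- images$image_shape
    images <- lapply(seq_len(nrow(images$Y)),
                     function(i) unflatten_rowmajor(images$Y[i, ], sh))
  }
  if (is.array(images) && length(dim(images)) == 4) return(images)
  h <- nrow(images[[1]]); w <- ncol(images[[1]])
  x <- array(0, c(h, w, 1, length(images)))
  for (i in seq_along(images)) x[, , 1, i] <- images[[i]]
  if (min(x) < -1e-9 || max(x) > 1 + 1e-9) {
    stop_param("autoencoder inputs must lie in [0,1]")
  }
  x
}

#' Train the convolutional autoencoder
#'
#' Minimizes the reconstruction loss (binary cross entropy by default) with
#' Adam on shuffled minibatches. Training is deterministic under the
#' configuration seed (single-threaded numerics).
#'
#' @param images a [build_data_matrix()] result with `unit_interval`
#'   normalization, a list of `[0,1]` matrices, or an `H x W x 1 x N` array.
#' @param config a [cae_config()].
#' @return object of class `cae_model` with `params`, `config`,
#'   `epoch_losses`, `reconstruction_mse` (on the training images) and
#'   `input_shape`.
#' @export
train_cae <- function(images, config) {
  stopifnot(inherits(config, "cae_config"))
  x <- .cae_tensor(images)
  N <- dim(x)[4]
  if (dim(x)[1] != dim(x)[2]) stop_param("images must be square")
  params <- with_seed(child_seed(config$seed, 0), .cae_init(config, dim(x)[1]))
  state <- list()
  t <- 0
  epoch_losses <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(child_seed(config$seed, ep), sample.int(N))
    bl <- numeric(0)
    for (start in seq(1, N, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, N)]
      xb <- x[, , , idx, drop = FALSE]
      lg <- .cae_loss_grad(xb, params, config)
      if (!is.finite(lg$loss)) stop_data("non-finite training loss")
      t <- t + 1
      r <- .cae_walk(params, lg$grads, state, config$learning_rate, t)
      params <- r$params; state <- r$state
      bl <- c(bl, lg$loss)
    }
    epoch_losses[ep] <- mean(bl)
  }
  fw <- .cae_forward(x, params, config)
  model <- structure(list(params = params, config = config,
                          epoch_losses = epoch_losses,
                          reconstruction_mse = mean((fw$recon - x)^2),
                          input_shape = dim(x)[1:2]),
                     class = "cae_model")
  model
}

#' @export
print.cae_model <- function(x, ...) {
  cat(sprintf("cae_model: code size %d, %d epochs, final loss %.5f, recon MSE %.5f\n",
              x$config$code_size, x$config$epochs,
              x$epoch_losses[length(x$epoch_losses)], x$reconstruction_mse))
  invisible(x)
}

#' Encode images to the autoencoder code
#'
#' @param model a [train_cae()] result.
#' @param images images as accepted by [train_cae()].
#' @return object of class `code_matrix`: `codes` (`N x code_size`) and
#'   `reconstruction_mse` on the encoded images.
#' @export
cae_encode <- function(model, images) {
  x <- .cae_tensor(images)
  fw <- .cae_forward(x, model$params, model$config)
  structure(list(codes = fw$code,
                 reconstruction_mse = mean((fw$recon - x)^2)),
            class = "code_matrix")
}

#' Decode codes back to images
#'
#' @param model a [train_cae()] result.
#' @param codes `n x code_size` matrix.
#' @return `H x W x 1 x n` array of reconstructions in `[0, 1]`.
#' @export
cae_decode <- function(model, codes) {
  codes <- as.matrix(codes)
  if (ncol(codes) != model$config$code_size) stop_param("code width mismatch")
  params <- model$params; config <- model$config
  cs <- attr(params, "conv_shape")
  B <- nrow(codes)
  g <- .relu(sweep(codes %*% params$fc_dec$W, 2, params$fc_dec$b, "+"))
  hd <- array(t(g), c(cs[1], cs[2], cs[3], B))
  ns <- length(params$dec)
  for (s in seq_len(ns)) {
    z <- .convt_fwd(hd, params$dec[[s]]$W, params$dec[[s]]$b)
    hd <- if (s == ns) .sigmoid(z) else .relu(z)
  }
  hd
}

#' Decoder as a flat image-space projector
#'
#' Wraps [cae_decode()] as a function from an `n x code_size` matrix to an
#' `n x D` matrix of row-major-flattened decoded images, the interface
#' [latent_feature_variance_map()] expects.
#'
#' @param model a [train_cae()] result.
#' @return function: codes matrix -> `n x D` matrix.
#' @export
cae_projector <- function(model) {
  function(codes) {
    rec <- cae_decode(model, codes)
    t(vapply(seq_len(dim(rec)[4]),
             function(i) flatten_rowmajor(rec[, , 1, i]),
             numeric(prod(model$input_shape))))
  }
}

#' Select the autoencoder code size by held-out reconstruction error
#'
#' Trains `n_iterations` autoencoders per candidate code size with distinct
#' seeds, evaluates the mean squared reconstruction error on a held-out 20%
#' split, and returns the code size (and seed) of the model with the lowest
#' MSE. The full MSE table is retained; candidate sizes whose runs all fail
#' are excluded.
#'
#' @param images as accepted by [train_cae()].
#' @param grid candidate code sizes; the study-scale default is
#'   `c(10, 20, 50, 75, 100)`.
#' @param n_iterations models per code size (study-scale default 10).
#' @param config_base a [cae_config()] supplying epochs/batch/learning rate.
#' @param seed integer seed (split + per-run seeds).
#' @return list with `chosen` (code size), `best_seed`, `table`
#'   (code_size, iteration, seed, mse) and `best_mse`.
#' @export
select_code_size <- function(images, grid = c(10, 20, 50, 75, 100),
                             n_iterations = 10, config_base = cae_config(),
                             seed = 1) {
  if (length(grid) == 0 || n_iterations < 1) stop_param("empty grid or iterations < 1")
  x <- .cae_tensor(images)
  N <- dim(x)[4]
  n_hold <- max(1, round(0.2 * N))
  hold <- with_seed(child_seed(seed, 0), sample.int(N, n_hold))
  x_tr <- x[, , , -hold, drop = FALSE]
  x_ho <- x[, , , hold, drop = FALSE]
  rows <- list()
  for (g in grid) for (it in seq_len(n_iterations)) {
    run_seed <- child_seed(seed, g * 1000 + it)
    mse <- tryCatch({
      cfg <- config_base
      cfg$code_size <- g
      cfg$seed <- run_seed
      mod <- train_cae(x_tr, cfg)
      fw <- .cae_forward(x_ho, mod$params, cfg)
      mean((fw$recon - x_ho)^2)
    }, error = function(e) NA_real_)
    rows[[length(rows) + 1]] <- data.frame(code_size = g, iteration = it,
                                           seed = run_seed, mse = mse)
  }
  tab <- do.call(rbind, rows)
  .select_from_mse_table(tab)
}

# argmin over the (code_size, iteration, seed, mse) table; NA runs excluded
.select_from_mse_table <- function(tab) {
  ok <- tab[!is.na(tab$mse), ]
  if (nrow(ok) == 0) stop_data("all autoencoder trainings failed")
  best <- ok[which.min(ok$mse), ]
  list(chosen = best$code_size, best_seed = best$seed, best_mse = best$mse,
       table = tab)
}
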