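#' Bayesian GP-LVM with ARD kernel and sparse variational inference
#'
#' The model maps a latent space \eqn{X \in R^{N \times d}} to the data
#' \eqn{Y \in R^{N \times D}} through D independent Gaussian processes with a
#' shared radial basis function kernel with automatic relevance determination,
#' \deqn{k(x, x') = \sigma_f^2 \exp(-\tfrac12 \sum_q \alpha_q (x_q - x'_q)^2),}
#' plus i.i.d. Gaussian observation noise with precision \eqn{\beta}. The
#' latent prior is standard normal; inference uses the factorized Gaussian
#' variational posterior \eqn{Q(X) = \prod_n N(x_n | \mu_n, S_n)} (diagonal
#' \eqn{S_n}) and a set of auxiliary (inducing) points, giving the collapsed
#' sparse variational lower bound on the marginal likelihood. The bound and its
#' analytic gradients with respect to \eqn{\mu, S}, the inducing inputs, the
#' ARD weights \eqn{\alpha_q} (the *relevances*, inverse squared lengthscales),
#' \eqn{\sigma_f^2} and \eqn{\beta} are maximized jointly with L-BFGS-B.
#'
#' @name bgplvm
#' @keywords internal
NULL

# ---- psi statistics and collapsed bound ----------------------------------
#
# Parameter vector layout (all unconstrained):
#   mu (N*d), log S (N*d), Z (m*d), log alpha (d), log sf2, log beta

.bgplvm_unpack <- function(par, N, d, m) {
  i <- 0
  mu <- matrix(par[i + seq_len(N * d)], N, d); i <- i + N * d
  S <- matrix(exp(par[i + seq_len(N * d)]), N, d); i <- i + N * d
  Z <- matrix(par[i + seq_len(m * d)], m, d); i <- i + m * d
  alpha <- exp(par[i + seq_len(d)]); i <- i + d
  sf2 <- exp(par[i + 1]); beta <- exp(par[i + 2])
  list(mu = mu, S = S, Z = Z, alpha = alpha, sf2 = sf2, beta = beta)
}

.bgplvm_pack <- function(mu, S, Z, alpha, sf2, beta) {
  c(as.vector(mu), as.vector(log(S)), as.vector(Z), log(alpha), log(sf2), log(beta))
}

# Evaluate the negative bound and its gradient at `par`.
# Yc: column-centered N x D data; trYY = sum(Yc^2).
.bgplvm_objective <- function(par, Yc, trYY, N, D, d, m, jitter = 1e-6) {
  p <- .bgplvm_unpack(par, N, d, m)
  mu <- p$mu; S <- p$S; Z <- p$Z; alpha <- p$alpha; sf2 <- p$sf2; beta <- p$beta

  # --- Kmm (with jitter proportional to sf2) ---
  logK <- matrix(0, m, m)
  for (q in seq_len(d)) {
    dz <- outer(Z[, q], Z[, q], "-")
    logK <- logK - 0.5 * alpha[q] * dz * dz
  }
  E_K <- exp(logK)
  Kmm <- sf2 * E_K + diag(jitter * sf2, m)

  # --- psi0 ---
  psi0 <- N * sf2

  # --- Psi1 (N x m) ---
  logP1 <- matrix(log(sf2), N, m)
  for (q in seq_len(d)) {
    den <- 1 + alpha[q] * S[, q]                     # length N
    Dq <- outer(mu[, q], Z[, q], "-")                # N x m
    logP1 <- logP1 - 0.5 * log(den) - 0.5 * alpha[q] * Dq * Dq / den
  }
  Psi1 <- exp(logP1)

  # --- Psi2 via m^2 x N log matrix ---
  Zb <- vector("list", d); Zb2 <- vector("list", d); dz2 <- vector("list", d)
  tmat <- matrix(0, N, d)
  Lmat <- matrix(0, m * m, N)
  for (q in seq_len(d)) {
    zq <- Z[, q]
    Zb[[q]] <- as.vector(outer(zq, zq, "+") / 2)
    Zb2[[q]] <- Zb[[q]]^2
    dzq <- outer(zq, zq, "-")
    dz2[[q]] <- as.vector(dzq * dzq)
    tq <- 1 + 2 * alpha[q] * S[, q]
    tmat[, q] <- tq
    Lmat <- Lmat +
      outer(Zb2[[q]], -alpha[q] / tq) +
      outer(Zb[[q]], 2 * alpha[q] * mu[, q] / tq) +
      rep(-alpha[q] * mu[, q]^2 / tq - 0.5 * log(tq), each = m * m) +
      (-alpha[q] / 4) * dz2[[q]]
  }
  Pmat <- sf2 * sf2 * exp(Lmat)                       # m^2 x N
  Psi2 <- matrix(rowSums(Pmat), m, m)

  # --- collapsed bound ---
  A <- beta * Psi2 + Kmm
  cK <- tryCatch(chol(Kmm), error = function(e) NULL)
  cA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(cK) || is.null(cA)) {
    return(list(value = 1e10, grad = rep(0, length(par)), ok = FALSE))
  }
  Kinv <- chol2inv(cK); Ainv <- chol2inv(cA)
  logdetK <- 2 * sum(log(diag(cK))); logdetA <- 2 * sum(log(diag(cA)))
  Tm <- crossprod(Psi1, Yc)                           # m x D
  C <- Ainv %*% Tm                                    # m x D
  trKinvPsi2 <- sum(Kinv * Psi2)
  Flik <- D * (0.5 * N * log(beta) - 0.5 * N * log(2 * pi) +
               0.5 * logdetK - 0.5 * logdetA) -
          0.5 * beta * trYY + 0.5 * beta^2 * sum(Tm * C) -
          0.5 * beta * D * psi0 + 0.5 * beta * D * trKinvPsi2
  KL <- 0.5 * sum(mu * mu + S - log(S) - 1)
  Fb <- Flik - KL
  if (!is.finite(Fb)) {
    return(list(value = 1e10, grad = rep(0, length(par)), ok = FALSE))
  }

  # --- gradients of F wrt matrix-level quantities ---
  G_A <- -0.5 * D * Ainv - 0.5 * beta^2 * tcrossprod(C)
  dPsi2 <- beta * G_A + 0.5 * beta * D * Kinv
  dKmm <- 0.5 * D * Kinv + G_A - 0.5 * beta * D * (Kinv %*% Psi2 %*% Kinv)
  dKmm <- (dKmm + t(dKmm)) / 2
  dPsi2 <- (dPsi2 + t(dPsi2)) / 2
  dPsi1 <- beta^2 * (Yc %*% t(C))                     # N x m
  dpsi0 <- -0.5 * beta * D
  dbeta <- 0.5 * D * N / beta - 0.5 * trYY + beta * sum(Tm * C) -
           0.5 * D * psi0 + 0.5 * D * trKinvPsi2 + sum(G_A * Psi2)

  # --- chain rule to parameters ---
  gmu <- -mu                                          # from -KL
  gS <- -0.5 * (1 - 1 / S)
  gZ <- matrix(0, m, d)
  galpha <- numeric(d)
  gsf2 <- 0

  # Kmm terms
  Knj <- sf2 * E_K
  WK <- dKmm
  gsf2 <- gsf2 + sum(WK * Kmm) / sf2
  for (q in seq_len(d)) {
    dzq <- outer(Z[, q], Z[, q], "-")
    galpha[q] <- galpha[q] - 0.5 * sum(WK * Knj * dzq * dzq)
    Mq <- WK * Knj
    gZ[, q] <- gZ[, q] - 2 * alpha[q] * (rowSums(Mq) * Z[, q] - Mq %*% Z[, q])
  }

  # psi0 term
  gsf2 <- gsf2 + dpsi0 * N

  # Psi1 terms
  H1 <- dPsi1 * Psi1
  gsf2 <- gsf2 + sum(H1) / sf2
  for (q in seq_len(d)) {
    den <- 1 + alpha[q] * S[, q]
    Dq <- outer(mu[, q], Z[, q], "-")
    DqOverDen <- Dq / den                             # recycles den by row
    gmu[, q] <- gmu[, q] - alpha[q] * rowSums(H1 * DqOverDen)
    gS[, q] <- gS[, q] + rowSums(H1 * (-0.5 * alpha[q] / den +
                                        0.5 * alpha[q]^2 * Dq * DqOverDen / den))
    gZ[, q] <- gZ[, q] + alpha[q] * colSums(H1 * DqOverDen)
    galpha[q] <- galpha[q] + sum(H1 * (-0.5 * S[, q] / den - 0.5 * Dq * DqOverDen / den))
  }

  # Psi2 terms
  W2v <- as.vector(dPsi2)
  Bmat <- Pmat * W2v                                  # m^2 x N
  sB <- colSums(Bmat)                                 # per-n total
  Btot <- matrix(rowSums(Bmat), m, m)
  gsf2 <- gsf2 + 2 * sum(dPsi2 * Psi2) / sf2
  for (q in seq_len(d)) {
    tq <- tmat[, q]
    sBZ <- as.vector(Zb[[q]] %*% Bmat)                # per-n sum(B_n * Zb)
    sBZ2 <- as.vector(Zb2[[q]] %*% Bmat)
    muq <- mu[, q]
    quad <- sBZ2 - 2 * muq * sBZ + muq^2 * sB         # per-n sum(B_n (Zb - mu)^2)
    gmu[, q] <- gmu[, q] + (2 * alpha[q] / tq) * (sBZ - muq * sB)
    gS[, q] <- gS[, q] - alpha[q] * sB / tq + 2 * alpha[q]^2 * quad / tq^2
    galpha[q] <- galpha[q] + sum(-S[, q] * sB / tq - quad / tq^2) -
                 0.25 * sum(Btot * matrix(dz2[[q]], m, m))
    Btq <- matrix(Bmat %*% (1 / tq), m, m)
    Btmu <- matrix(Bmat %*% (muq / tq), m, m)
    Zbm <- matrix(Zb[[q]], m, m)
    gZ[, q] <- gZ[, q] - 2 * alpha[q] * rowSums(Zbm * Btq - Btmu) -
               alpha[q] * (Z[, q] * rowSums(Btot) - Btot %*% Z[, q])
  }

  grad <- c(as.vector(gmu),
            as.vector(gS * S),                        # chain through log S
            as.vector(gZ),
            galpha * alpha,                           # chain through log alpha
            gsf2 * sf2, dbeta * beta)
  list(value = -Fb, grad = -grad, ok = TRUE)
}

# ---- public operations ----------------------------------------------------

.as_Y <- function(Y) if (inherits(Y, "data_matrix")) Y$Y else as.matrix(Y)

#' Initial latent dimensionality from PCA explained variance
#'
#' Returns the smallest number of principal components whose cumulative
#' explained variance reaches `var_fraction` (default 75%), used as the
#' initial guess of the number of latent plant features.
#'
#' @param Y a [build_data_matrix()] result or plain `N x D` matrix.
#' @param var_fraction target explained-variance fraction (default 0.75).
#' @return integer number of components.
#' @export
pca_initial_dim <- function(Y, var_fraction = 0.75) {
  Ym <- .as_Y(Y)
  if (nrow(Ym) < 2) stop_data("need N >= 2")
  pc <- stats::prcomp(Ym, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  tot <- sum(ev)
  if (tot <= 0) stop_data("zero total variance")
  unname(which(cumsum(ev) / tot >= var_fraction - 1e-12)[1])
}

#' Fit the Bayesian GP-LVM
#'
#' Maximizes the sparse variational lower bound jointly over the variational
#' latent means and variances, the inducing inputs, the ARD kernel parameters
#' and the noise precision. Latent means are initialized from PCA scores
#' (rescaled to unit variance per dimension), latent variances at 0.5, and the
#' inducing inputs at a random subset of the initialized latent points.
#'
#' @param Y `N x D` data matrix (or [build_data_matrix()] result). Columns are
#'   centered internally; the centering is folded back by the projector.
#' @param d latent dimensionality (`1 <= d < N`).
#' @param n_auxiliary number of auxiliary (inducing) points (`<= N`).
#' @param seed integer seed (initialization subset + restarts).
#' @param maxit L-BFGS-B iteration cap (default 1000).
#' @param reltol relative bound-change convergence tolerance (default 1e-6).
#' @param restarts number of random restarts; the best bound wins (default 1).
#' @return object of class `bgplvm_model`: `latent_means` (`N x d`),
#'   `latent_variances` (`N x d`), `relevances` (ARD inverse squared
#'   lengthscales, damped by the fitted signal fraction so a pure-noise fit
#'   reports vanishing relevance), `kernel_params`, `noise_precision`,
#'   `inducing_points`,
#'   `n_auxiliary`, `bound`, `trace` (incumbent bound per evaluation) and a
#'   `projector` mapping latent points to image-space mean vectors.
#' @export
fit_bgplvm <- function(Y, d, n_auxiliary, seed = 1, maxit = 1000,
                       reltol = 1e-6, restarts = 1) {
  Ym <- .as_Y(Y)
  N <- nrow(Ym); D <- ncol(Ym)
  if (d < 1 || d >= N) stop_param("need 1 <= d < N")
  m <- min(n_auxiliary, N)
  col_means <- colMeans(Ym)
  Yc <- sweep(Ym, 2, col_means)
  tot_var <- mean(apply(Yc, 2, stats::var))
  if (tot_var <= 0) stop_data("zero-variance data")
  # standardize the overall scale so the optimization is well conditioned;
  # the projector folds the scale back
  y_scale <- sqrt(tot_var)
  Yc <- Yc / y_scale
  trYY <- sum(Yc * Yc)
  pc <- stats::prcomp(Yc, center = FALSE, rank. = d)
  X0 <- pc$x
  if (ncol(X0) < d) X0 <- cbind(X0, matrix(0, N, d - ncol(X0)))
  sds <- apply(X0, 2, stats::sd)
  sds[sds < 1e-8] <- 1
  X0 <- sweep(X0, 2, sds, "/")
  # noise precision initialized at the d-component PCA residual variance, so
  # the initial noise model is consistent with what the initial latents explain
  resid_var <- max((sum(Yc^2) / (N - 1) - sum(pc$sdev^2)) / ncol(Yc), 1e-3)
  sf2_0 <- max(1 - resid_var, 0.1)
  beta0 <- 1 / resid_var

  best <- NULL
  for (r in seq_len(restarts)) {
    init <- with_seed(child_seed(seed, r), {
      Z0 <- X0[sample.int(N, m), , drop = FALSE] +
        matrix(stats::rnorm(m * d, 0, 0.01), m, d)
      X0r <- X0 + if (r > 1) matrix(stats::rnorm(N * d, 0, 0.1), N, d) else 0
      .bgplvm_pack(X0r, matrix(0.5, N, d), Z0, rep(1, d), sf2_0, beta0)
    })
    cache <- new.env()
    cache$trace <- numeric(0)
    compute <- function(par) {
      if (is.null(cache$par) || !identical(par, cache$par)) {
        cache$par <- par
        cache$o <- .bgplvm_objective(par, Yc, trYY, N, D, d, m)
      }
      cache$o
    }
    fn <- function(par) {
      o <- compute(par)
      b <- -o$value
      prev <- if (length(cache$trace)) cache$trace[length(cache$trace)] else -Inf
      cache$trace <- c(cache$trace, max(b, prev))
      o$value
    }
    gr <- function(par) compute(par)$grad
    # phase 1: noise precision frozen, so the signal variance cannot collapse
    # before the latent coordinates and kernel have adapted
    np <- length(init)
    o1 <- stats::optim(init[-np],
                       fn = function(p) fn(c(p, init[np])),
                       gr = function(p) gr(c(p, init[np]))[-np],
                       method = "L-BFGS-B",
                       control = list(maxit = min(100, maxit),
                                      factr = reltol / .Machine$double.eps))
    # phase 2: all parameters free
    opt <- stats::optim(c(o1$par, init[np]), fn = fn, gr = gr,
                        method = "L-BFGS-B",
                        control = list(maxit = maxit,
                                       factr = reltol / .Machine$double.eps))
    if (is.null(best) || -opt$value > best$bound) {
      best <- list(par = opt$par, bound = -opt$value, trace = cache$trace)
    }
  }
  if (!is.finite(best$bound) || best$bound <= -1e9) {
    stop_data("B-GP-LVM fit failed: non-finite bound")
  }
  p <- .bgplvm_unpack(best$par, N, d, m)

  # projector precomputation: E[f(x*)] = beta * K(x*, Z) A^{-1} Psi1' Yc + mean;
  # the coefficient absorbs the internal standardization
  proj_parts <- .bgplvm_projection_parts(p, Yc, N, D, d, m)
  proj_parts$coef <- proj_parts$coef * y_scale

  # ARD relevances: inverse squared lengthscales, damped by the fitted
  # signal fraction sf2/(sf2 + 1/beta). For any fit with appreciable signal
  # the factor is ~1 and the relevances are the plain inverse squared
  # lengthscales; when the model explains the data as pure noise (sf2 -> 0)
  # the kernel lengthscales are unidentifiable and the damping reports the
  # relevances as ~0, which is what a no-signal fit means. The factor is
  # shared across dimensions, so orderings and the increase rule are
  # unaffected.
  signal_frac <- p$sf2 / (p$sf2 + 1 / p$beta)
  model <- structure(list(latent_means = p$mu, latent_variances = p$S,
                          relevances = p$alpha * signal_frac,
                          kernel_params = list(variance = p$sf2,
                                               lengthscales = 1 / sqrt(p$alpha)),
                          noise_precision = p$beta,
                          inducing_points = p$Z, n_auxiliary = m,
                          bound = best$bound, trace = best$trace,
                          col_means = col_means, d = d, D = D,
                          proj_coef = proj_parts$coef, seed = seed),
                     class = "bgplvm_model")
  model$projector <- bgplvm_projector(model)
  model
}

# m x D coefficient matrix of the sparse-GP posterior mean
.bgplvm_projection_parts <- function(p, Yc, N, D, d, m, jitter = 1e-6) {
  alpha <- p$alpha; sf2 <- p$sf2; Z <- p$Z
  logK <- matrix(0, m, m)
  for (q in seq_len(d)) {
    dz <- outer(Z[, q], Z[, q], "-")
    logK <- logK - 0.5 * alpha[q] * dz * dz
  }
  Kmm <- sf2 * exp(logK) + diag(jitter * sf2, m)
  logP1 <- matrix(log(sf2), N, m)
  for (q in seq_len(d)) {
    den <- 1 + alpha[q] * p$S[, q]
    Dq <- outer(p$mu[, q], Z[, q], "-")
    logP1 <- logP1 - 0.5 * log(den) - 0.5 * alpha[q] * Dq * Dq / den
  }
  Psi1 <- exp(logP1)
  Lmat <- matrix(0, m * m, N)
  for (q in seq_len(d)) {
    zq <- Z[, q]
    Zbv <- as.vector(outer(zq, zq, "+") / 2)
    dzq <- outer(zq, zq, "-")
    tq <- 1 + 2 * alpha[q] * p$S[, q]
    Lmat <- Lmat + outer(Zbv^2, -alpha[q] / tq) +
      outer(Zbv, 2 * alpha[q] * p$mu[, q] / tq) +
      rep(-alpha[q] * p$mu[, q]^2 / tq - 0.5 * log(tq), each = m * m) +
      (-alpha[q] / 4) * as.vector(dzq * dzq)
  }
  Psi2 <- matrix(rowSums(sf2 * sf2 * exp(Lmat)), m, m)
  A <- p$beta * Psi2 + Kmm
  coef <- p$beta * solve(A, crossprod(Psi1, Yc))
  list(coef = coef)
}

#' Image-space projector of a fitted B-GP-LVM
#'
#' Returns a function mapping latent points (rows) to the GP posterior mean in
#' image space (`D` columns), with the column centering folded back in.
#'
#' @param model a [fit_bgplvm()] result.
#' @return function: `n x d` matrix -> `n x D` matrix.
#' @export
bgplvm_projector <- function(model) {
  Z <- model$inducing_points; alpha <- model$relevances
  sf2 <- model$kernel_params$variance
  coef <- model$proj_coef; col_means <- model$col_means; d <- model$d
  function(latent_points) {
    X <- as.matrix(latent_points)
    if (ncol(X) != d) stop_param("latent points must have ", d, " columns")
    logK <- matrix(0, nrow(X), nrow(Z))
    for (q in seq_len(d)) {
      dx <- outer(X[, q], Z[, q], "-")
      logK <- logK - 0.5 * alpha[q] * dx * dx
    }
    sweep(sf2 * exp(logK) %*% coef, 2, col_means, "+")
  }
}

#' Project latent points to image space
#'
#' @param model a [fit_bgplvm()] result.
#' @param latent_points `n x d` matrix of latent coordinates.
#' @return `n x D` matrix of posterior-mean image vectors.
#' @export
project_to_image_space <- function(model, latent_points) {
  stopifnot(inherits(model, "bgplvm_model"))
  model$projector(latent_points)
}

#' @export
print.bgplvm_model <- function(x, ...) {
  cat(sprintf("bgplvm_model: N=%d, D=%d, d=%d, %d auxiliary points, bound %.2f\n",
              nrow(x$latent_means), x$D, x$d, x$n_auxiliary, x$bound))
  cat("relevances:", paste(signif(sort(x$relevances, decreasing = TRUE), 3),
                           collapse = " "), "\n")
  invisible(x)
}

# 95% rule on (typically negative) bounds: smallest grid value whose bound
# reaches max_bound - 0.05*|max_bound|; reduces to the literal 95% rule for
# positive bounds
.choose_95 <- function(grid, bounds) {
  mx <- max(bounds)
  grid[which(bounds >= mx - 0.05 * abs(mx))[1]]
}

# fit one model per grid value, collecting bounds (-Inf on failure)
.grid_bounds <- function(Ym, grid, fit_fun) {
  vapply(grid, function(g) {
    tryCatch(fit_fun(g)$bound, error = function(e) -Inf)
  }, numeric(1))
}

#' Select the number of auxiliary points
#'
#' Fits one model per grid value at fixed latent dimensionality and picks the
#' *smallest* number of auxiliary points whose bound reaches 95% of the
#' maximum. Because log-likelihood bounds are typically negative, "95% of the
#' maximum" is realized as `bound >= max_bound - 0.05 * |max_bound|`, which
#' reduces to the literal rule for positive bounds.
#'
#' @param Y data matrix (or [build_data_matrix()] result).
#' @param d latent dimensionality (e.g. from [pca_initial_dim()]).
#' @param grid candidate auxiliary-point counts; the study-scale default is
#'   `c(50, 75, 100, 125, 150)`.
#' @param seed,maxit passed to [fit_bgplvm()].
#' @return object of class `hyperparam_search`: `grid`, `objective` (bounds),
#'   `chosen`, `rule`.
#' @export
select_auxiliary_points <- function(Y, d, grid = c(50, 75, 100, 125, 150),
                                    seed = 1, maxit = 300) {
  Ym <- .as_Y(Y)
  if (any(grid >= nrow(Ym))) stop_param("grid values must be < N")
  bounds <- .grid_bounds(Ym, grid, function(g)
    fit_bgplvm(Ym, d = d, n_auxiliary = g, seed = seed, maxit = maxit))
  structure(list(grid = grid, objective = bounds, chosen = .choose_95(grid, bounds),
                 rule = "smallest m with bound >= max - 0.05*|max| (95% rule)"),
            class = "hyperparam_search")
}

#' Select the latent dimensionality
#'
#' Fits one model per candidate dimensionality at a fixed number of auxiliary
#' points and returns the bound maximizer.
#'
#' @param Y data matrix (or [build_data_matrix()] result).
#' @param n_auxiliary auxiliary-point count (e.g. from
#'   [select_auxiliary_points()]).
#' @param grid candidate dimensionalities; the study-scale default is
#'   `c(10, 25, 50, 75, 100, 150)`.
#' @param seed,maxit passed to [fit_bgplvm()].
#' @return a `hyperparam_search` object.
#' @export
select_latent_dim <- function(Y, n_auxiliary, grid = c(10, 25, 50, 75, 100, 150),
                              seed = 1, maxit = 300) {
  Ym <- .as_Y(Y)
  if (any(grid >= min(dim(Ym)))) stop_param("grid values must be < min(N, D)")
  bounds <- .grid_bounds(Ym, grid, function(g)
    fit_bgplvm(Ym, d = g, n_auxiliary = n_auxiliary, seed = seed, maxit = maxit))
  chosen <- grid[which.max(bounds)]
  structure(list(grid = grid, objective = bounds, chosen = chosen,
                 rule = "argmax of variational bound"),
            class = "hyperparam_search")
}

#' @export
print.hyperparam_search <- function(x, ...) {
  cat("hyperparam_search:", x$rule, "\n")
  print(data.frame(value = x$grid, objective = x$objective,
                   chosen = x$grid == x$chosen))
  invisible(x)
}

#' Write a hyperparameter search result as CSV
#' @param search a `hyperparam_search` object; `path` output path.
#' @export
write_search_csv <- function(search, path) {
  utils::write.csv(data.frame(value = search$grid, objective = search$objective,
                              chosen = search$grid == search$chosen),
                   path, row.names = FALSE)
  invisible(path)
}
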