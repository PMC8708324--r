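# shared in-code fixtures; everything is generated at test time

# small labeled image set used across modules
tiny_dataset <- function(n_plant = 10, n_background = 10, seed = 1, size = 32, ...) {
  generate_dataset(synthetic_config(image_size = size, n_plant = n_plant,
                                    n_background = n_background, seed = seed, ...))
}

# low-dimensional 2-factor data with a linear map, for GP-LVM recovery checks
two_factor_data <- function(N = 60, D = 64, noise_sd = 0.2, seed = 1) {
  with_seed(seed, {
    X <- matrix(stats::rnorm(N * 2), N, 2)
    W <- matrix(stats::rnorm(2 * D), 2, D)
    list(Y = X %*% W + matrix(stats::rnorm(N * D, 0, noise_sd), N, D),
         X = X, noise_var = noise_sd^2)
  })
}

# independent Spearman oracle: Pearson correlation on average ranks
spearman_oracle <- function(x, y) stats::cor(rank(x), rank(y))

# prediction_record built directly from vectors, for metric unit tests
fake_record <- function(true, predicted, p1 = NULL, iteration = 1, model_id = "fake") {
  n <- length(true)
  structure(data.frame(iteration = iteration, fold = 1, sample = seq_len(n),
                       true = true, predicted = predicted,
                       p_class1 = p1 %||% ifelse(predicted == 1, 0.9, 0.1)),
            class = c("prediction_record", "data.frame"),
            model_id = model_id, n_iterations = max(iteration), n_folds = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
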