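test_that("autoencoder gradients match finite differences on a tiny network", {
  cfg <- cae_config(code_size = 3,
                    encoder_spec = list(list(channels = 2), list(channels = 3)),
                    seed = 7)
  with_seed(3, x <- array(runif(8 * 8 * 1 * 4), c(8, 8, 1, 4)))
  params <- with_seed(1, plantlatent:::.cae_init(cfg, 8))
  lg <- plantlatent:::.cae_loss_grad(x, params, cfg)
  check_block <- function(get, set) {
    p0 <- get(params)
    idx <- with_seed(5, sample(length(p0), min(4, length(p0))))
    num <- vapply(idx, function(j) {
      h <- 1e-5
      pp <- params; v <- get(pp); v[j] <- v[j] + h; pp <- set(pp, v)
      pm <- params; v <- get(pm); v[j] <- v[j] - h; pm <- set(pm, v)
      (plantlatent:::.cae_loss_grad(x, pp, cfg)$loss -
       plantlatent:::.cae_loss_grad(x, pm, cfg)$loss) / (2 * h)
    }, numeric(1))
    max(abs(num - get(lg$grads)[idx]) / pmax(abs(num), 1e-8))
  }
  expect_lt(check_block(function(p) p$enc[[1]]$W,
                        function(p, v) { p$enc[[1]]$W[] <- v; p }), 1e-4)
  expect_lt(check_block(function(p) p$fc_enc$W,
                        function(p, v) { p$fc_enc$W[] <- v; p }), 1e-4)
  expect_lt(check_block(function(p) p$fc_dec$b,
                        function(p, v) { p$fc_dec$b[] <- v; p }), 1e-4)
  expect_lt(check_block(function(p) p$dec[[2]]$W,
                        function(p, v) { p$dec[[2]]$W[] <- v; p }), 1e-4)
})

test_that("training reduces the loss and reconstructs degenerate data", {
  img <- with_seed(1, matrix(runif(256), 16, 16))
  identical_imgs <- rep(list(img), 24)
  cfg <- cae_config(code_size = 4,
                    encoder_spec = list(list(channels = 8), list(channels = 16)),
                    epochs = 60, learning_rate = 3e-3, seed = 2)
  mod <- train_cae(identical_imgs, cfg)
  expect_lt(mod$epoch_losses[length(mod$epoch_losses)], mod$epoch_losses[1])
  expect_lt(mod$reconstruction_mse, 1e-3)
})

test_that("training is deterministic under a fixed seed", {
  ds <- tiny_dataset(n_plant = 6, n_background = 6, seed = 2, size = 16)
  dm <- build_data_matrix(ds, 16, "unit_interval")
  cfg <- cae_config(code_size = 4,
                    encoder_spec = list(list(channels = 4), list(channels = 8)),
                    epochs = 3, seed = 11)
  m1 <- train_cae(dm, cfg)
  m2 <- train_cae(dm, cfg)
  expect_identical(m1$epoch_losses, m2$epoch_losses)
  expect_identical(m1$params$fc_enc$W, m2$params$fc_enc$W)
})

test_that("encode/decode respect shapes, ranges and bookkeeping", {
  ds <- tiny_dataset(n_plant = 8, n_background = 8, seed = 3, size = 16)
  dm <- build_data_matrix(ds, 16, "unit_interval")
  cfg <- cae_config(code_size = 5,
                    encoder_spec = list(list(channels = 4), list(channels = 8)),
                    epochs = 5, seed = 4)
  mod <- train_cae(dm, cfg)
  cm <- cae_encode(mod, dm)
  expect_equal(dim(cm$codes), c(16, 5))
  rec <- cae_decode(mod, cm$codes)
  expect_equal(dim(rec), c(16, 16, 1, 16))
  expect_true(all(rec >= 0 & rec <= 1))
  # round-trip MSE equals the model's reported reconstruction error
  expect_equal(cm$reconstruction_mse, mod$reconstruction_mse)
  expect_error(cae_decode(mod, matrix(0, 2, 3)), "width")
  # inputs outside [0,1] are rejected
  expect_error(train_cae(build_data_matrix(ds, 16, "none"), cfg), "0,1|\\[0,1\\]")
  # projector returns row-major flattened images
  pr <- cae_projector(mod)(cm$codes[1:2, ])
  expect_equal(dim(pr), c(2, 256))
  expect_equal(pr[1, ], as.vector(t(rec[, , 1, 1])))
})

test_that("code-size selection takes the argmin of the held-out MSE table", {
  tab <- data.frame(code_size = c(10, 20, 50), iteration = 1,
                    seed = c(101, 102, 103), mse = c(0.02, 0.01, 0.03))
  sel <- plantlatent:::.select_from_mse_table(tab)
  expect_equal(sel$chosen, 20)
  expect_equal(sel$best_seed, 102)
  # failed runs (NA) are excluded
  tab$mse[2] <- NA
  expect_equal(plantlatent:::.select_from_mse_table(tab)$chosen, 10)
  expect_error(plantlatent:::.select_from_mse_table(transform(tab, mse = NA)),
               "failed")
  # a single-element grid with one iteration returns that element
  ds <- tiny_dataset(n_plant = 5, n_background = 5, seed = 5, size = 16)
  dm <- build_data_matrix(ds, 16, "unit_interval")
  sel1 <- select_code_size(dm, grid = 4, n_iterations = 1,
                           config_base = cae_config(
                             encoder_spec = list(list(channels = 4), list(channels = 8)),
                             epochs = 2), seed = 1)
  expect_equal(sel1$chosen, 4)
  expect_equal(nrow(sel1$table), 1)
})

test_that("larger codes reconstruct at least as well in expectation", {
  # images driven by 3 generative factors: a 1-dim code must lose information
  # that an 8-dim code can keep
  imgs <- with_seed(5, {
    X <- matrix(rnorm(32 * 3), 32, 3)
    Y <- X %*% matrix(rnorm(3 * 256), 3, 256)
    Y <- (Y - min(Y)) / diff(range(Y))
    lapply(1:32, function(i) matrix(Y[i, ], 16, 16))
  })
  mses <- vapply(1:5, function(s) {
    vapply(c(1, 8), function(k) {
      cfg <- cae_config(code_size = k,
                        encoder_spec = list(list(channels = 4), list(channels = 8)),
                        epochs = 30, learning_rate = 3e-3, seed = s)
      train_cae(imgs, cfg)$reconstruction_mse
    }, numeric(1))
  }, numeric(2))
  # small-code MSE >= large-code MSE, allowing one seed to violate
  expect_gte(sum(mses[1, ] >= mses[2, ]), 4)
})
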