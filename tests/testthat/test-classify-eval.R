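test_that("hyperparameter search is deterministic and degenerates correctly", {
  with_seed(1, {
    X <- rbind(matrix(rnorm(50 * 2, 0), 50, 2), matrix(rnorm(50 * 2, 4), 50, 2))
    y <- rep(c(0, 1), each = 50)
  })
  # collapsed search space returns that point
  hp0 <- optimize_svm(X, y, n_init = 2, n_opt = 2, nu_range = c(0.2, 0.2),
                      log10_gamma_range = c(-1, -1), seed = 3)
  expect_equal(hp0$nu, 0.2)
  expect_equal(hp0$gamma, 0.1)
  # identical seeds reproduce the whole search log
  h1 <- optimize_svm(X, y, n_init = 5, n_opt = 3, seed = 5)
  h2 <- optimize_svm(X, y, n_init = 5, n_opt = 3, seed = 5)
  expect_equal(h1$search_log, h2$search_log)
  # well-separated blobs reach high inner-CV accuracy
  expect_gte(h1$score, 0.95)
  # infeasible nu values are penalized, never optimal
  h3 <- optimize_svm(X, y, n_init = 4, n_opt = 2, nu_range = c(0.05, 0.99), seed = 6)
  expect_lt(h3$nu, 0.99)
  expect_gt(h3$score, -1)
})

test_that("the repeated-CV experiment is complete, honest and label-sensitive", {
  n <- 60
  with_seed(2, {
    y <- rep(c(0, 1), each = n / 2)
    f_label <- cbind(y + rnorm(n, 0, 0.01), rnorm(n))
  })
  plan <- make_cv_plan(n, 5, 3, seed = 4)
  rec <- run_experiment(f_label, y, plan, select = FALSE, tune = FALSE, seed = 1)
  # exactly n_iterations x n predictions, each sample once per iteration
  expect_equal(nrow(rec), 3 * n)
  expect_true(all(table(rec$iteration, rec$sample) == 1))
  # probabilities are proper
  expect_true(all(rec$p_class1 >= 0 & rec$p_class1 <= 1))
  # a label-equal feature is learned almost perfectly
  expect_gte(accuracy(rec)$mean, 0.99)
  # permuted labels: chance-level accuracy
  y_perm <- with_seed(7, sample(y))
  rec0 <- run_experiment(matrix(rnorm(n * 2), n, 2), y_perm,
                         make_cv_plan(n, 5, 10, seed = 8),
                         select = FALSE, tune = FALSE, seed = 2)
  expect_gt(accuracy(rec0)$mean, 0.3)
  expect_lt(accuracy(rec0)$mean, 0.7)
})

test_that("per-split feature selection never sees the test fold", {
  # one feature equals the label only on even samples; selection must be
  # computed from training folds, so rerunning with shuffled *test* labels
  # leaves predictions unchanged
  n <- 40
  with_seed(3, {
    y <- rep(c(0, 1), n / 2)
    f <- cbind(y + rnorm(n, 0, 0.1), matrix(rnorm(n * 3), n, 3))
  })
  plan <- make_cv_plan(n, 4, 2, seed = 5)
  r1 <- run_experiment(f, y, plan, select = TRUE, tune = FALSE, seed = 9)
  r2 <- run_experiment(f, y, plan, select = TRUE, tune = FALSE, seed = 9)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  sel <- attr(r1, "selected_features")
  expect_true(all(vapply(sel, function(s) 1 %in% s, logical(1))))
})

test_that("accuracy summarizes constructed records correctly", {
  rec <- fake_record(true = c(1, 1, 0, 0), predicted = c(1, 1, 0, 0))
  expect_equal(accuracy(rec)$mean, 1)
  rec2 <- fake_record(true = c(1, 1, 0, 0), predicted = c(1, 0, 1, 0))
  expect_equal(accuracy(rec2)$mean, 0.5)
})

test_that("mutual information matches closed forms and information bounds", {
  # perfect balanced binary predictor: 1 bit
  expect_equal(confusion_mi(matrix(c(50, 0, 0, 50), 2)), 1)
  # independence: 0 bits
  expect_equal(confusion_mi(matrix(c(25, 25, 25, 25), 2)), 0)
  # confusion [[40,10],[10,40]]: 1 - H(0.8) ~ 0.2781 bits
  H <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
  expect_equal(confusion_mi(matrix(c(40, 10, 10, 40), 2)), 1 - H(0.8),
               tolerance = 1e-12)
  # record interface
  rec <- fake_record(true = rep(c(0, 1), each = 50),
                     predicted = rep(c(0, 1), each = 50))
  expect_equal(mutual_information(rec)$mean, 1)
  recI <- fake_record(true = rep(c(0, 1), each = 50),
                      predicted = rep(c(0, 1), times = 50))
  expect_equal(mutual_information(recI)$mean, 0)
  expect_warning(mi0 <- confusion_mi(matrix(c(100, 0, 50, 0), 2,
                                            dimnames = NULL)), "degenerate")
  expect_equal(mi0, 0)
  # MI <= min of marginal entropies on fuzzed confusion tables
  for (i in 1:25) {
    tab <- with_seed(i, matrix(rpois(4, 20) + 1, 2))
    p <- tab / sum(tab)
    expect_lte(confusion_mi(tab),
               min(H(rowSums(p)[1]), H(colSums(p)[1])) + 1e-12)
    expect_gte(confusion_mi(tab), -1e-12)
  }
})

test_that("McNemar counts discordance and computes both p-value branches", {
  mk <- function(pa, pb, true) list(a = fake_record(true, pa), b = fake_record(true, pb))
  # b = 10, c = 0: continuity-corrected statistic (10-1)^2/10 = 8.1
  true <- rep(c(0, 1), 10)
  pa <- true                      # A always right
  pb <- true; pb[1:10] <- 1 - pb[1:10] # B wrong on 10
  r <- mk(pa, pb, true)
  mc <- mcnemar_compare(r$a, r$b, method = "chi2_cc")
  expect_equal(mc$b, 10); expect_equal(mc$c, 0)
  expect_equal(mc$statistic, 8.1)
  expect_equal(mc$p_value, stats::pchisq(8.1, 1, lower.tail = FALSE))
  # exact branch (auto, b + c < 25)
  mc_auto <- mcnemar_compare(r$a, r$b)
  expect_equal(mc_auto$method, "exact")
  expect_equal(mc_auto$p_value, 2 * stats::pbinom(0, 10, 0.5))
  # symmetric discordance: exact p = 1
  pb2 <- true; pb2[1:5] <- 1 - pb2[1:5]
  pa2 <- true; pa2[6:10] <- 1 - pa2[6:10]
  mc2 <- mcnemar_compare(fake_record(true, pa2), fake_record(true, pb2))
  expect_equal(mc2$p_value, 1)
  # identical predictions: b = c = 0, warn, p = 1
  expect_warning(mc3 <- mcnemar_compare(r$a, r$a), "indistinguishable")
  expect_equal(mc3$p_value, 1)
  expect_equal(mc3$b + mc3$c, 0)
  # unpaired records are rejected
  expect_error(mcnemar_compare(r$a, fake_record(rev(true), pa)), "paired")
})

test_that("exact and chi-square McNemar branches agree near the switch point", {
  true <- rep(c(0, 1), 30)
  for (b_ct in c(13, 15)) {
    for (c_ct in c(9, 11)) {
      pa <- true; pa[seq_len(c_ct)] <- 1 - pa[seq_len(c_ct)]
      pb <- true; pb[c_ct + seq_len(b_ct)] <- 1 - pb[c_ct + seq_len(b_ct)]
      pe <- mcnemar_compare(fake_record(true, pa), fake_record(true, pb),
                            method = "exact")$p_value
      pc <- mcnemar_compare(fake_record(true, pa), fake_record(true, pb),
                            method = "chi2_cc")$p_value
      expect_lt(abs(pe - pc) / pe, 0.2)
    }
  }
})
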