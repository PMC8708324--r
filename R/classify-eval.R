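#' Bayesian optimization of nu-SVM hyperparameters
#'
#' Tunes `(nu, gamma)` of a nu-support-vector machine with RBF kernel by
#' maximizing inner cross-validation accuracy with a Gaussian-process
#' surrogate and the expected-improvement acquisition: `n_init` random
#' initialization points followed by `n_opt` acquisition points (study-scale
#' default ten and ten). Infeasible `nu` values (the nu formulation has a
#' data-dependent upper bound) receive a penalized score and are never
#' returned as the optimum. Deterministic under `seed`.
#'
#' @param features `N x k` numeric matrix.
#' @param labels binary vector (both classes present).
#' @param inner_folds inner CV folds for scoring (default 3).
#' @param n_init,n_opt random and acquisition evaluations (default 10 each).
#' @param nu_range search interval for nu (default `c(0.01, 0.5)`).
#' @param log10_gamma_range search interval for `log10(gamma)` (default
#'   `c(-4, 1)`).
#' @param seed integer seed.
#' @return object of class `svm_hyperparams`: `nu`, `gamma`, `score`,
#'   `search_log` (data frame of evaluated points and scores).
#' @export
optimize_svm <- function(features, labels, inner_folds = 3, n_init = 10,
                         n_opt = 10, nu_range = c(0.01, 0.5),
                         log10_gamma_range = c(-4, 1), seed = 1) {
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop_data("need both classes")
  N <- nrow(features)
  folds <- with_seed(child_seed(seed, 1),
                     sample(rep(seq_len(inner_folds), length.out = N)))
  score_point <- function(nu, gamma) {
    accs <- vapply(seq_len(inner_folds), function(f) {
      tr <- folds != f
      if (length(unique(labels[tr])) < 2) return(NA_real_)
      fit <- tryCatch(e1071::svm(features[tr, , drop = FALSE], labels[tr],
                                 type = "nu-classification", kernel = "radial",
                                 nu = nu, gamma = gamma, scale = FALSE),
                      error = function(e) NULL)
      if (is.null(fit)) return(-1)
      mean(stats::predict(fit, features[!tr, , drop = FALSE]) == labels[!tr])
    }, numeric(1))
    if (any(accs < 0, na.rm = TRUE)) return(-1) # infeasible nu penalized
    mean(accs, na.rm = TRUE)
  }
  lo <- c(nu_range[1], log10_gamma_range[1])
  hi <- c(nu_range[2], log10_gamma_range[2])
  span <- pmax(hi - lo, .Machine$double.eps)
  X <- with_seed(child_seed(seed, 2),
                 matrix(stats::runif(n_init * 2), n_init, 2))
  pts <- sweep(sweep(X, 2, span, "*"), 2, lo, "+")
  y <- vapply(seq_len(nrow(pts)),
              function(i) score_point(pts[i, 1], 10^pts[i, 2]), numeric(1))
  phase <- rep("init", n_init)
  # GP surrogate on the unit square; fixed smooth kernel
  gp_post <- function(Xe, ye, Xc) {
    ell <- 0.25; s2 <- max(stats::var(ye), 1e-6); nug <- 1e-4 * s2 + 1e-8
    k <- function(A, B) {
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
      s2 * exp(-pmax(d2, 0) / (2 * ell^2))
    }
    K <- k(Xe, Xe) + diag(nug, nrow(Xe))
    L <- chol(K)
    a <- backsolve(L, backsolve(L, ye - mean(ye), transpose = TRUE))
    Ks <- k(Xc, Xe)
    mu <- mean(ye) + Ks %*% a
    v <- backsolve(L, t(Ks), transpose = TRUE)
    s <- sqrt(pmax(s2 - colSums(v^2), 1e-12))
    list(mu = as.vector(mu), s = s)
  }
  for (j in seq_len(n_opt)) {
    cand <- with_seed(child_seed(seed, 10 + j),
                      matrix(stats::runif(500 * 2), 500, 2))
    post <- gp_post(X, y, cand)
    best <- max(y)
    z <- (post$mu - best) / post$s
    ei <- (post$mu - best) * stats::pnorm(z) + post$s * stats::dnorm(z)
    xn <- cand[which.max(ei), , drop = FALSE]
    pn <- lo + xn[1, ] * span
    X <- rbind(X, xn)
    pts <- rbind(pts, pn)
    y <- c(y, score_point(pn[1], 10^pn[2]))
    phase <- c(phase, "opt")
  }
  feasible <- y > -1
  if (!any(feasible)) stop_data("no feasible (nu, gamma) point found")
  ib <- which(feasible)[which.max(y[feasible])]
  structure(list(nu = unname(pts[ib, 1]), gamma = unname(10^pts[ib, 2]),
                 score = unname(y[ib]),
                 search_log = data.frame(nu = pts[, 1], gamma = 10^pts[, 2],
                                         score = y, phase = phase)),
            class = "svm_hyperparams")
}

#' Repeated cross-validated nu-SVM experiment
#'
#' Runs the classification stage under a [make_cv_plan()] protocol (default
#' 10 x 5-fold on reshuffled data). Within every training split, and before
#' the test fold is touched: features are (optionally) selected by the
#' Spearman rule, SVM hyperparameters are tuned by [optimize_svm()] on the
#' training folds only, and the nu-SVM is fitted with Platt-style logistic
#' probability calibration. Test-fold predicted labels and class probabilities
#' are recorded per iteration and fold.
#'
#' The ARD relevance rule, being label-free, may be applied once up front by
#' passing `relevances`; the label-dependent Spearman selection is refit per
#' training split unless `paper_faithful = TRUE`, which performs the selection
#' once on the full data before cross-validation (the pipeline-diagram
#' ordering) at the cost of selection leakage.
#'
#' @param features `N x k` matrix of latent features (rows aligned with
#'   `labels` and the CV plan).
#' @param labels binary vector (0/1).
#' @param cv_plan a [make_cv_plan()] object with `n_samples == nrow(features)`.
#' @param select apply Spearman feature selection inside each training split
#'   (default TRUE).
#' @param relevances optional ARD relevances for the label-free pre-selection.
#' @param alpha Spearman selection level (default 0.1).
#' @param tune tune `(nu, gamma)` per split with [optimize_svm()] (default
#'   TRUE); otherwise `nu = 0.2`, `gamma = 1/k`.
#' @param n_init,n_opt,inner_folds passed to [optimize_svm()].
#' @param paper_faithful select once on the full data before CV (default
#'   FALSE).
#' @param seed integer seed for the tuners.
#' @param model_id label stored on the record.
#' @return object of class `prediction_record`: data frame with columns
#'   `iteration`, `fold`, `sample`, `true`, `predicted`, `p_class1`, plus
#'   attributes (`model_id`, `selected_features` per iteration/fold).
#' @export
run_experiment <- function(features, labels, cv_plan, select = TRUE,
                           relevances = NULL, alpha = 0.1, tune = TRUE,
                           inner_folds = 3, n_init = 10, n_opt = 10,
                           paper_faithful = FALSE, seed = 1,
                           model_id = "model") {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(inherits(cv_plan, "cv_plan"))
  if (nrow(features) != cv_plan$n_samples) stop_param("features/cv_plan misaligned")
  candidates <- seq_len(ncol(features))
  relsel <- NULL
  if (!is.null(relevances)) {
    relsel <- relevance_threshold_select(relevances)
    candidates <- relsel$relevance_kept
  }
  global_sel <- NULL
  if (select && paper_faithful) {
    global_sel <- spearman_select(features, labels, alpha = alpha,
                                  relevance_result = relsel)$selected
    if (length(global_sel) == 0) global_sel <- candidates
  }
  rows <- list(); sel_log <- list()
  for (it in seq_len(cv_plan$n_iterations)) {
    fold_of <- cv_plan$assignments[, it]
    for (f in seq_len(cv_plan$n_folds)) {
      tr <- which(fold_of != f); te <- which(fold_of == f)
      if (length(unique(labels[tr])) < 2) {
        warning(sprintf("iteration %d fold %d: single-class training set, skipped", it, f))
        next
      }
      sel <- if (!select) candidates
        else if (paper_faithful) global_sel
        else {
          s <- spearman_select(features[tr, , drop = FALSE], labels[tr],
                               alpha = alpha, relevance_result = relsel)$selected
          if (length(s) == 0) candidates else s
        }
      Xtr <- features[tr, sel, drop = FALSE]
      Xte <- features[te, sel, drop = FALSE]
      hp <- if (tune) {
        optimize_svm(Xtr, labels[tr], inner_folds = inner_folds,
                     n_init = n_init, n_opt = n_opt,
                     seed = child_seed(seed, it * 100 + f))
      } else list(nu = 0.2, gamma = 1 / ncol(Xtr))
      fit <- e1071::svm(Xtr, factor(labels[tr], levels = c(0, 1)),
                        type = "nu-classification", kernel = "radial",
                        nu = hp$nu, gamma = hp$gamma, scale = FALSE)
      # Platt-style probabilities: logistic regression of the training labels
      # on the SVM decision values, fitted on the training folds only
      ftr <- attr(stats::predict(fit, Xtr, decision.values = TRUE),
                  "decision.values")[, 1]
      calib <- suppressWarnings(stats::glm(labels[tr] ~ ftr,
                                           family = stats::binomial()))
      pr <- stats::predict(fit, Xte, decision.values = TRUE)
      fte <- attr(pr, "decision.values")[, 1]
      p1 <- unname(stats::predict(calib, newdata = data.frame(ftr = fte),
                                  type = "response"))
      rows[[length(rows) + 1]] <- data.frame(
        iteration = it, fold = f, sample = te, true = labels[te],
        predicted = as.integer(as.character(pr)), p_class1 = p1)
      sel_log[[paste(it, f)]] <- sel
    }
  }
  rec <- do.call(rbind, rows)
  rownames(rec) <- NULL
  structure(rec, class = c("prediction_record", "data.frame"),
            model_id = model_id, selected_features = sel_log,
            n_iterations = cv_plan$n_iterations, n_folds = cv_plan$n_folds)
}

#' Per-fold and mean prediction accuracy
#'
#' @param record a [run_experiment()] result.
#' @return list with `per_fold` (iteration, fold, accuracy), `per_iteration`
#'   and `mean` (grand mean over folds).
#' @export
accuracy <- function(record) {
  stopifnot(inherits(record, "prediction_record"))
  per_fold <- stats::aggregate(correct ~ iteration + fold,
                               data = transform(as.data.frame(record),
                                                correct = true == predicted),
                               FUN = mean)
  names(per_fold)[3] <- "accuracy"
  per_iter <- stats::aggregate(accuracy ~ iteration, per_fold, mean)
  list(per_fold = per_fold, per_iteration = per_iter,
       mean = mean(per_fold$accuracy))
}

#' Plug-in mutual information of a confusion matrix, in bits
#'
#' @param tab 2x2 (or general) contingency table of true vs predicted counts.
#' @return MI in bits (0 for degenerate marginals).
#' @export
confusion_mi <- function(tab) {
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  if (any(px == 1) || any(py == 1)) {
    warning("degenerate marginal distribution: MI = 0")
    return(0)
  }
  terms <- p * log2(p / outer(px, py))
  sum(terms[p > 0])
}

#' Mutual information between true and predicted labels
#'
#' Plug-in estimate of the mutual information of the empirical joint
#' distribution of (true label, predicted label), pooled per iteration, in
#' bits. A perfect balanced binary predictor attains 1 bit; predictions
#' independent of the truth give 0 bits; any accuracy above 50% on balanced
#' labels gives MI > 0. With `probabilistic = TRUE`, predicted-class counts
#' are replaced by expected counts under the predictive class probabilities.
#'
#' @param record a [run_experiment()] result.
#' @param probabilistic use class probabilities instead of hard labels
#'   (default FALSE).
#' @return list with `per_iteration` (iteration, mi_bits) and `mean`.
#' @export
mutual_information <- function(record, probabilistic = FALSE) {
  stopifnot(inherits(record, "prediction_record"))
  df <- as.data.frame(record)
  mis <- vapply(sort(unique(df$iteration)), function(it) {
    d <- df[df$iteration == it, ]
    if (probabilistic) {
      tab <- rbind(`0` = c(sum((1 - d$p_class1)[d$true == 0]),
                           sum(d$p_class1[d$true == 0])),
                   `1` = c(sum((1 - d$p_class1)[d$true == 1]),
                           sum(d$p_class1[d$true == 1])))
    } else {
      tab <- table(factor(d$true, c(0, 1)), factor(d$predicted, c(0, 1)))
    }
    confusion_mi(as.matrix(tab))
  }, numeric(1))
  list(per_iteration = data.frame(iteration = sort(unique(df$iteration)),
                                  mi_bits = mis),
       mean = mean(mis))
}

#' McNemar comparison of two paired classifiers
#'
#' Counts the discordant pairs over the shared cross-validation predictions —
#' `b`: model A correct and model B wrong; `c`: A wrong and B correct — and
#' tests H0 that the two error rates are equal. The continuity-corrected
#' statistic `(max(|b-c|-1, 0))^2 / (b+c)` is always reported; the p-value
#' uses the chi-square(1) tail for `method = "chi2_cc"`, the exact two-sided
#' binomial for `method = "exact"`, and (default `"auto"`) the exact branch
#' below `b + c = 25`. With `b + c = 0` the models are indistinguishable and
#' p = 1.
#'
#' @param record_a,record_b [run_experiment()] results sharing true labels
#'   and CV plan.
#' @param method `"auto"`, `"chi2_cc"` or `"exact"`.
#' @return object of class `mcnemar_result`: `b`, `c`, `statistic`,
#'   `p_value`, `method`.
#' @export
mcnemar_compare <- function(record_a, record_b,
                            method = c("auto", "chi2_cc", "exact")) {
  method <- match.arg(method)
  a <- as.data.frame(record_a); bdf <- as.data.frame(record_b)
  key <- c("iteration", "fold", "sample")
  a <- a[do.call(order, a[key]), ]; bdf <- bdf[do.call(order, bdf[key]), ]
  if (nrow(a) != nrow(bdf) || !all(a$sample == bdf$sample) ||
      !all(a$iteration == bdf$iteration) || !all(a$true == bdf$true)) {
    stop_data("records are not paired (different samples, plans or labels)")
  }
  ca <- a$true == a$predicted; cb <- bdf$true == bdf$predicted
  b <- sum(ca & !cb); cc <- sum(!ca & cb)
  n_disc <- b + cc
  statistic <- if (n_disc > 0) max(abs(b - cc) - 1, 0)^2 / n_disc else 0
  used <- if (method == "auto") { if (n_disc >= 25) "chi2_cc" else "exact" } else method
  p <- if (n_disc == 0) {
    warning("no discordant pairs: models indistinguishable, p = 1")
    1
  } else if (used == "chi2_cc") {
    stats::pchisq(statistic, df = 1, lower.tail = FALSE)
  } else {
    min(1, 2 * stats::pbinom(min(b, cc), n_disc, 0.5))
  }
  structure(list(b = b, c = cc, statistic = statistic, p_value = p,
                 method = used),
            class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("McNemar: b=%d, c=%d, statistic=%.4g, p=%.4g (%s)\n",
              x$b, x$c, x$statistic, x$p_value, x$method))
  invisible(x)
}

#' Write a prediction record as CSV
#' @param record a [run_experiment()] result; `path` output path.
#' @export
write_prediction_record <- function(record, path) {
  utils::write.csv(as.data.frame(record), path, row.names = FALSE)
  invisible(path)
}
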