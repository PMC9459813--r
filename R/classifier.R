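# Training/evaluation protocol for the two binary activity classifiers
# (stair walking vs. gait; stair ascent vs. descent): class balancing per
# subject and visit, a greedy correlation filter, recursive feature
# elimination with grouped-CV scoring, and grouped k-fold evaluation of
# knn, random forest, regularised logistic regression and a
# probability-averaging voting ensemble, with inner grid search per fold.

#' Build a labeled window dataset from a feature matrix
#'
#' @param feature_df Output of [extract_feature_matrix()]: provenance
#'   columns plus features.
#' @param task `"stairs_vs_gait"` (positive class: ascent and descent
#'   windows, negative: gait) or `"ascent_vs_descent"` (positive: ascent,
#'   negative: descent; gait windows are dropped).
#' @return A `labeled_dataset`: feature matrix `x`, binary factor `y`
#'   (positive class last), `positive` label, and `subject`, `visit`,
#'   `task_id` provenance vectors.
#' @export
as_labeled_dataset <- function(feature_df,
                               task = c("stairs_vs_gait", "ascent_vs_descent")) {
  task <- match.arg(task)
  prov <- c("subject_id", "visit_id", "task_id", "label", "start_time")
  stopifnot(all(prov %in% names(feature_df)))
  feats <- setdiff(names(feature_df), prov)
  if (task == "stairs_vs_gait") {
    y <- factor(ifelse(feature_df$label %in% c("ascent", "descent"), "stairs", "gait"),
                levels = c("gait", "stairs"))
    keep <- rep(TRUE, nrow(feature_df))
    positive <- "stairs"
  } else {
    keep <- feature_df$label %in% c("ascent", "descent")
    y <- factor(feature_df$label, levels = c("descent", "ascent"))
    positive <- "ascent"
  }
  x <- as.matrix(feature_df[keep, feats, drop = FALSE])
  if (anyNA(x)) stop("feature matrix contains missing values")
  structure(
    list(x = x, y = y[keep], positive = positive,
         subject = feature_df$subject_id[keep],
         visit = feature_df$visit_id[keep],
         task_id = feature_df$task_id[keep]),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d windows x %d features, %d subjects; positive '%s' (%s)\n",
              nrow(x$x), ncol(x$x), length(unique(x$subject)), x$positive,
              paste(sprintf("%s: %d", levels(x$y), table(x$y)), collapse = ", ")))
  invisible(x)
}

subset_rows <- function(ds, keep) {
  ds$x <- ds$x[keep, , drop = FALSE]
  ds$y <- factor(as.character(ds$y[keep]), levels = levels(ds$y))
  ds$subject <- ds$subject[keep]
  ds$visit <- ds$visit[keep]
  ds$task_id <- ds$task_id[keep]
  ds
}

#' Balance classes within subject/visit strata
#'
#' Within each stratum (by default each subject and visit), negatives are
#' subsampled without replacement to match the positive count, mirroring
#' the protocol of drawing the same number of gait windows performed
#' during the same visit by the same subject. Strata with more positives
#' than available negatives are dropped with a warning. Deterministic
#' given `seed`.
#'
#' @param ds A `labeled_dataset`.
#' @param seed Integer seed.
#' @param strata Character vector of stratum fields among
#'   `c("subject", "visit", "task_id")`.
#' @return The balanced `labeled_dataset`.
#' @export
balance_classes <- function(ds, seed = 1, strata = c("subject", "visit")) {
  stopifnot(inherits(ds, "labeled_dataset"))
  key <- do.call(paste, c(lapply(strata, function(f) ds[[f]]), sep = "\r"))
  pos <- ds$y == ds$positive
  with_seed(seed, {
    keep <- logical(length(ds$y))
    for (k in unique(key)) {
      in_k <- which(key == k)
      p <- in_k[pos[in_k]]
      n <- in_k[!pos[in_k]]
      if (!length(p)) next
      if (length(n) < length(p)) {
        warning("stratum '", gsub("\r", "/", k), "' dropped: ", length(n),
                " negatives for ", length(p), " positives")
        next
      }
      keep[p] <- TRUE
      keep[if (length(n) == length(p)) n else sample(n, length(p))] <- TRUE
    }
    subset_rows(ds, keep)
  })
}

#' Remove highly correlated features
#'
#' Greedy scan in canonical feature order: a feature is dropped when its
#' absolute Pearson correlation with any earlier retained feature exceeds
#' `threshold`.
#'
#' @param ds A `labeled_dataset` with >= 2 features.
#' @param threshold Absolute correlation threshold (default 0.90).
#' @return The filtered `labeled_dataset`; dropped names are recorded in
#'   the `"dropped_features"` attribute.
#' @export
drop_correlated_features <- function(ds, threshold = 0.90) {
  stopifnot(inherits(ds, "labeled_dataset"), ncol(ds$x) >= 2)
  p <- ncol(ds$x)
  keep <- 1L
  for (j in 2:p) {
    r <- suppressWarnings(stats::cor(ds$x[, j], ds$x[, keep, drop = FALSE]))
    r[is.na(r)] <- 0
    if (all(abs(r) <= threshold)) keep <- c(keep, j)
  }
  dropped <- colnames(ds$x)[-keep]
  ds$x <- ds$x[, keep, drop = FALSE]
  attr(ds, "dropped_features") <- dropped
  ds
}

grouped_fold_assignment <- function(subjects, k) {
  us <- unique(subjects)
  if (length(us) < k) {
    warning("only ", length(us), " subjects; reducing fold count from ", k)
    k <- length(us)
  }
  shuffled <- sample(us)
  fold_of <- stats::setNames(rep(seq_len(k), length.out = length(us)), shuffled)
  unname(fold_of[subjects])
}

scale_fit <- function(x) {
  mu <- colMeans(x)
  sdev <- apply(x, 2, stats::sd)
  sdev[sdev == 0] <- 1
  list(mu = mu, sd = sdev)
}
scale_apply <- function(x, sc) sweep(sweep(x, 2, sc$mu), 2, sc$sd, "/")

# node cap only binds when below the number of observations
fit_rf <- function(x, y, params) {
  if (is.finite(params$maxnodes) && params$maxnodes < nrow(x)) {
    randomForest::randomForest(x, y, ntree = params$ntree, maxnodes = params$maxnodes)
  } else {
    randomForest::randomForest(x, y, ntree = params$ntree)
  }
}

# probability of the positive class (last level of y_train)
predict_prob <- function(model, x_train, y_train, x_test, params) {
  pos <- levels(y_train)[nlevels(y_train)]
  switch(model,
    knn = {
      pr <- class::knn(x_train, x_test, y_train, k = params$k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == pos, p, 1 - p)
    },
    random_forest = {
      fit <- fit_rf(x_train, y_train, params)
      stats::predict(fit, x_test, type = "prob")[, pos]
    },
    logistic_regression = {
      xtr <- x_train
      xte <- x_test
      if (ncol(xtr) < 2) {  # glmnet needs >= 2 predictors
        xtr <- cbind(xtr, .pad = 0)
        xte <- cbind(xte, .pad = 0)
      }
      lam <- 1 / (params$C * nrow(xtr))
      fit <- glmnet::glmnet(xtr, y_train, family = "binomial", alpha = 0,
                            lambda = lam, standardize = FALSE)
      as.numeric(stats::predict(fit, xte, type = "response"))
    },
    stop("unknown model ", model)
  )
}

binary_metrics <- function(truth, prob, positive) {
  pred <- ifelse(prob > 0.5, positive, setdiff(levels(truth), positive))
  tp <- sum(pred == positive & truth == positive)
  fn <- sum(pred != positive & truth == positive)
  tn <- sum(pred != positive & truth != positive)
  fp <- sum(pred == positive & truth != positive)
  c(accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Default hyperparameter grids
#'
#' Grids searched inside each training fold: knn neighbourhood size,
#' random-forest tree count and node cap (a `maxnodes` of 1024
#' corresponds to unrestricted depth-10 trees; `Inf` leaves trees
#' unrestricted), and the inverse regularisation strength of ridge
#' logistic regression.
#' @return A named list of grids.
#' @export
classifier_grids <- function() {
  list(
    knn = expand.grid(k = c(3, 5, 7, 11)),
    random_forest = expand.grid(ntree = c(100, 300), maxnodes = c(Inf, 1024)),
    logistic_regression = expand.grid(C = c(0.1, 1, 10))
  )
}

tune_model <- function(model, x, y, subjects, grid, inner_k = 3) {
  if (nrow(grid) == 1) return(as.list(grid[1, , drop = FALSE]))
  folds <- grouped_fold_assignment(subjects, inner_k)
  acc <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    params <- as.list(grid[gi, , drop = FALSE])
    fold_acc <- vapply(unique(folds), function(f) {
      tr <- folds != f
      if (nlevels(droplevels(y[tr])) < 2 || !any(!tr)) return(NA_real_)
      prob <- predict_prob(model, x[tr, , drop = FALSE], y[tr], x[!tr, , drop = FALSE], params)
      binary_metrics(y[!tr], prob, levels(y)[nlevels(y)])[["accuracy"]]
    }, 0.0)
    acc[gi] <- mean(fold_acc, na.rm = TRUE)
  }
  as.list(grid[which.max(acc), , drop = FALSE])
}

#' Recursive feature elimination with grouped cross-validation
#'
#' Starting from all features, the least important feature by
#' random-forest impurity importance (fit on the full dataset with the
#' current set) is eliminated one per iteration; every candidate subset is
#' scored by subject-grouped k-fold accuracy of a random forest, and the
#' subset maximising mean cross-validated accuracy is returned (smallest
#' subset on ties).
#'
#' @param ds A `labeled_dataset` with >= 2 features and both classes.
#' @param seed Integer seed (fold assignment and forests).
#' @param n_folds Grouped folds for scoring (default 5).
#' @param ntree Trees per forest (default 100).
#' @return Character vector of selected feature names; the per-size score
#'   trace is attached as attribute `"history"`.
#' @export
select_features_rfecv <- function(ds, seed = 1, n_folds = 5, ntree = 100) {
  stopifnot(inherits(ds, "labeled_dataset"), ncol(ds$x) >= 2)
  if (nlevels(droplevels(ds$y)) < 2) stop("protocol error: both classes must be present")
  with_seed(seed, {
    current <- colnames(ds$x)
    history <- list()
    repeat {
      folds <- grouped_fold_assignment(ds$subject, n_folds)
      acc <- vapply(unique(folds), function(f) {
        tr <- folds != f
        if (nlevels(droplevels(ds$y[tr])) < 2) return(NA_real_)
        fit <- randomForest::randomForest(ds$x[tr, current, drop = FALSE], ds$y[tr],
                                          ntree = ntree)
        pred <- stats::predict(fit, ds$x[!tr, current, drop = FALSE])
        mean(pred == ds$y[!tr])
      }, 0.0)
      history[[length(history) + 1]] <- list(features = current,
                                             accuracy = mean(acc, na.rm = TRUE))
      if (length(current) == 1) break
      rank_fit <- randomForest::randomForest(ds$x[, current, drop = FALSE], ds$y,
                                             ntree = ntree, importance = FALSE)
      imp <- randomForest::importance(rank_fit)[, 1]
      current <- current[-which.min(imp)]
    }
    accs <- vapply(history, `[[`, 0.0, "accuracy")
    sizes <- vapply(history, function(h) length(h$features), 0L)
    best <- which(accs == max(accs))
    best <- best[which.min(sizes[best])]
    structure(history[[best]]$features,
              history = data.frame(n_features = sizes, cv_accuracy = accs))
  })
}

#' Train and evaluate the activity classifiers
#'
#' Outer subject-grouped k-fold cross-validation (no subject contributes
#' to both sides of a fold — asserted): per fold, features are z-scored on
#' the training side, each base model (knn, random forest, ridge logistic
#' regression) is tuned by an inner grouped grid search on the training
#' subjects, and fold metrics (accuracy, sensitivity on the positive
#' class, specificity) are computed on the held-out subjects, together
#' with a soft voting ensemble that averages the three tuned models'
#' class probabilities. `mode = "holdout"` instead performs a single
#' 80/20 split by subject.
#'
#' @param ds A balanced, feature-selected `labeled_dataset`.
#' @param seed Integer seed controlling fold assignment and all model
#'   randomness.
#' @param n_folds Outer folds (default 10; reduced with a warning when
#'   there are fewer subjects).
#' @param grids Hyperparameter grids, see [classifier_grids()].
#' @param mode `"cv"` or `"holdout"`.
#' @param holdout_fraction Test fraction of subjects in holdout mode.
#' @return A `model_report`: per-model, per-metric mean and sd across
#'   folds, per-fold values, selected hyperparameters, random-forest
#'   impurity importances per fold, and the fold assignment.
#' @export
train_and_evaluate <- function(ds, seed = 1, n_folds = 10,
                               grids = classifier_grids(),
                               mode = c("cv", "holdout"),
                               holdout_fraction = 0.2) {
  stopifnot(inherits(ds, "labeled_dataset"))
  mode <- match.arg(mode)
  if (nlevels(droplevels(ds$y)) < 2) stop("protocol error: both classes must be present")
  positive <- levels(ds$y)[nlevels(ds$y)]
  models <- c("knn", "random_forest", "logistic_regression", "voting_ensemble")
  with_seed(seed, {
    if (mode == "cv") {
      folds <- grouped_fold_assignment(ds$subject, n_folds)
      fold_ids <- sort(unique(folds))
    } else {
      us <- sample(unique(ds$subject))
      n_test <- max(1L, round(holdout_fraction * length(us)))
      folds <- ifelse(ds$subject %in% us[seq_len(n_test)], 1L, 0L)
      fold_ids <- 1L
    }
    metrics <- array(NA_real_,
                     dim = c(length(models), 3, length(fold_ids)),
                     dimnames = list(models, c("accuracy", "sensitivity", "specificity"),
                                     paste0("fold", fold_ids)))
    importances <- matrix(NA_real_, ncol(ds$x), length(fold_ids),
                          dimnames = list(colnames(ds$x), paste0("fold", fold_ids)))
    chosen <- vector("list", length(fold_ids))
    for (fi in seq_along(fold_ids)) {
      f <- fold_ids[fi]
      tr <- folds != f
      te <- !tr
      stopifnot(length(intersect(ds$subject[tr], ds$subject[te])) == 0)
      sc <- scale_fit(ds$x[tr, , drop = FALSE])
      xtr <- scale_apply(ds$x[tr, , drop = FALSE], sc)
      xte <- scale_apply(ds$x[te, , drop = FALSE], sc)
      ytr <- ds$y[tr]
      probs <- list()
      chosen[[fi]] <- list()
      for (m in setdiff(models, "voting_ensemble")) {
        params <- tune_model(m, xtr, ytr, ds$subject[tr], grids[[m]])
        chosen[[fi]][[m]] <- params
        probs[[m]] <- predict_prob(m, xtr, ytr, xte, params)
        metrics[m, , fi] <- binary_metrics(ds$y[te], probs[[m]], positive)
      }
      ens <- Reduce(`+`, probs) / length(probs)
      metrics["voting_ensemble", , fi] <- binary_metrics(ds$y[te], ens, positive)
      rf_fit <- fit_rf(xtr, ytr, chosen[[fi]][["random_forest"]])
      importances[, fi] <- randomForest::importance(rf_fit)[colnames(ds$x), 1]
    }
    summary_df <- do.call(rbind, lapply(models, function(m) {
      do.call(rbind, lapply(dimnames(metrics)[[2]], function(met) {
        v <- metrics[m, met, ]
        data.frame(model = m, metric = met, mean = mean(v, na.rm = TRUE),
                   sd = stats::sd(v))
      }))
    }))
    structure(
      list(summary = summary_df, metrics = metrics, importances = importances,
           params = chosen, folds = folds, positive = positive,
           selected_features = colnames(ds$x), mode = mode, n_folds = length(fold_ids)),
      class = "model_report"
    )
  })
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> positive class '%s', %s over %d fold(s), %d features\n",
              x$positive, x$mode, x$n_folds, length(x$selected_features)))
  s <- x$summary
  s$value <- sprintf("%.3f (%.3f)", s$mean, s$sd)
  wide <- stats::reshape(s[, c("model", "metric", "value")], direction = "wide",
                         idvar = "model", timevar = "metric")
  names(wide) <- sub("^value\\.", "", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Ranked random-forest feature importances
#'
#' Impurity importances averaged across folds and normalised to sum to 1
#' over all features, sorted descending.
#'
#' @param report A `model_report`.
#' @param top_k Number of features to return (default 20).
#' @return A `data.frame` with `feature` and `importance` columns.
#' @export
compute_feature_importances <- function(report, top_k = 20) {
  stopifnot(inherits(report, "model_report"))
  imp <- rowMeans(report$importances, na.rm = TRUE)
  imp <- pmax(imp, 0)
  imp <- imp / sum(imp)
  ord <- order(-imp)
  utils::head(data.frame(feature = names(imp)[ord], importance = unname(imp[ord])), top_k)
}
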