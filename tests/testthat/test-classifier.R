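test_that("class balancing subsamples negatives per stratum, deterministically", {
  set.seed(1)
  y <- factor(c(rep("stairs", 10), rep("gait", 25)), levels = c("gait", "stairs"))
  ds <- make_toy_dataset(matrix(rnorm(35 * 2), ncol = 2), y,
                         subject = rep("S01", 35), positive = "stairs")
  b1 <- balance_classes(ds, seed = 4)
  expect_equal(sum(b1$y == "stairs"), 10)
  expect_equal(sum(b1$y == "gait"), 10)
  b2 <- balance_classes(ds, seed = 4)
  expect_identical(b1$x, b2$x)
  # already balanced stratum is untouched
  y2 <- factor(rep(c("stairs", "gait"), each = 10), levels = c("gait", "stairs"))
  ds2 <- make_toy_dataset(matrix(rnorm(20 * 2), ncol = 2), y2,
                          subject = rep("S01", 20), positive = "stairs")
  expect_equal(nrow(balance_classes(ds2, seed = 1)$x), 20)
  # stratum with too few negatives is dropped with a warning
  y3 <- factor(c(rep("stairs", 5), rep("gait", 3)), levels = c("gait", "stairs"))
  ds3 <- make_toy_dataset(matrix(rnorm(8 * 2), ncol = 2), y3,
                          subject = rep("S01", 8), positive = "stairs")
  expect_warning(b3 <- balance_classes(ds3, seed = 1), "dropped")
  expect_equal(nrow(b3$x), 0)
})

test_that("the correlation filter drops collinear features greedily in order", {
  set.seed(7)
  A <- rnorm(200)
  B <- 2 * A + rnorm(200, sd = 1e-6)
  C <- rnorm(200)
  ds <- make_toy_dataset(cbind(A = A, B = B, C = C),
                         factor(rep(c("a", "b"), 100)), subject = rep("S01", 200))
  out <- drop_correlated_features(ds, 0.90)
  expect_identical(colnames(out$x), c("A", "C"))
  expect_identical(attr(out, "dropped_features"), "B")
  # chain A~B~C with r(A, C) below threshold keeps the endpoints
  set.seed(15)
  A <- rnorm(5000)
  B2 <- 0.93 * A + rnorm(5000, sd = sqrt(1 - 0.93^2))
  C2 <- 0.93 * B2 + rnorm(5000, sd = sqrt(1 - 0.93^2))
  r_ab <- pearson_sum_formula(A, B2)
  r_bc <- pearson_sum_formula(B2, C2)
  r_ac <- pearson_sum_formula(A, C2)
  expect_true(r_ab > 0.9 && r_bc > 0.9 && r_ac <= 0.9)  # construction check
  ds2 <- make_toy_dataset(cbind(A = A, B = B2, C = C2),
                          factor(rep(c("a", "b"), 2500)), subject = rep("S01", 5000))
  expect_identical(colnames(drop_correlated_features(ds2, 0.90)$x), c("A", "C"))
  # orthogonal features are untouched
  ds3 <- make_toy_dataset(cbind(A = A, C = C), factor(rep(c("a", "b"), 100)),
                          subject = rep("S01", 200))
  expect_identical(colnames(drop_correlated_features(ds3, 0.90)$x), c("A", "C"))
})

make_informative_dataset <- function(n_subjects = 10, per_subject = 20,
                                     n_noise = 20, margin = 3, sd = 1, seed = 100) {
  set.seed(seed)
  n <- n_subjects * per_subject
  subject <- rep(sprintf("S%02d", seq_len(n_subjects)), each = per_subject)
  y <- factor(rep(rep(c("neg", "pos"), each = per_subject / 2), n_subjects),
              levels = c("neg", "pos"))
  subj_shift <- rep(rnorm(n_subjects, sd = 0.3), each = per_subject)
  f1 <- ifelse(y == "pos", margin, 0) + rnorm(n, sd = sd) + subj_shift
  f2 <- ifelse(y == "pos", -margin, 0) + rnorm(n, sd = sd) + subj_shift
  noise <- matrix(rnorm(n * n_noise), ncol = n_noise,
                  dimnames = list(NULL, sprintf("noise%02d", seq_len(n_noise))))
  make_toy_dataset(cbind(inf1 = f1, inf2 = f2, noise), y, subject = subject,
                   positive = "pos")
}

test_that("recursive feature elimination retains the informative features", {
  ds <- make_informative_dataset()
  sel <- select_features_rfecv(ds, seed = 2)
  expect_true(all(c("inf1", "inf2") %in% sel))
  expect_lt(length(sel), ncol(ds$x))
  # determinism
  sel2 <- select_features_rfecv(ds, seed = 2)
  expect_identical(as.character(sel), as.character(sel2))
  hist <- attr(sel, "history")
  expect_equal(nrow(hist), ncol(ds$x))
  # degenerate single-class input is a protocol error
  ds1 <- ds
  ds1$y <- factor(rep("pos", length(ds$y)), levels = c("neg", "pos"))
  expect_error(select_features_rfecv(ds1, seed = 1), "both classes")
})

test_that("separable classes reach high grouped-CV accuracy for all four models", {
  ds <- make_informative_dataset(n_noise = 5)
  rep <- train_and_evaluate(ds, seed = 3)
  acc <- rep$summary[rep$summary$metric == "accuracy", ]
  expect_setequal(acc$model,
                  c("knn", "random_forest", "logistic_regression", "voting_ensemble"))
  expect_true(all(acc$mean >= 0.95))
  expect_equal(rep$n_folds, 10)
})

test_that("no subject appears on both sides of any fold", {
  ds <- make_informative_dataset(n_noise = 3)
  rep <- train_and_evaluate(ds, seed = 5)
  for (f in sort(unique(rep$folds))) {
    expect_length(intersect(ds$subject[rep$folds == f], ds$subject[rep$folds != f]), 0)
  }
})

test_that("a perfect single predictive feature gives sensitivity and specificity 1", {
  set.seed(8)
  n <- 120
  subject <- rep(sprintf("S%02d", 1:10), each = 12)
  y <- factor(rep(rep(c("neg", "pos"), each = 6), 10), levels = c("neg", "pos"))
  x <- matrix(ifelse(y == "pos", 1, 0) + rnorm(n, sd = 0.01), ncol = 1,
              dimnames = list(NULL, "f"))
  ds <- make_toy_dataset(x, y, subject = subject, positive = "pos")
  rep <- train_and_evaluate(ds, seed = 1)
  expect_true(all(rep$summary$mean == 1))
})

test_that("fewer subjects than folds reduces the fold count with a warning", {
  ds <- make_informative_dataset(n_subjects = 4, per_subject = 10, n_noise = 2)
  expect_warning(rep <- train_and_evaluate(ds, seed = 1), "reducing fold count")
  expect_equal(rep$n_folds, 4)
})

test_that("holdout mode evaluates a single 80/20 split by subject", {
  ds <- make_informative_dataset(n_noise = 2)
  rep <- train_and_evaluate(ds, seed = 1, mode = "holdout")
  expect_equal(rep$n_folds, 1)
  expect_equal(sum(unique(ds$subject) %in% ds$subject[rep$folds == 1]), 2)
})

test_that("feature importances are normalised, ranked and rank the informative feature first", {
  ds <- make_informative_dataset(n_noise = 8)
  rep <- train_and_evaluate(ds, seed = 2)
  imp_all <- compute_feature_importances(rep, top_k = ncol(ds$x))
  expect_equal(sum(imp_all$importance), 1, tolerance = 1e-9)
  expect_true(imp_all$feature[1] %in% c("inf1", "inf2"))
  expect_false(is.unsorted(rev(imp_all$importance)))
  expect_equal(nrow(compute_feature_importances(rep, top_k = 5)), 5)
})
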