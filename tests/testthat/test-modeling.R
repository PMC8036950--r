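test_that("pruning drops one of an identical pair and nothing orthogonal", {
  set.seed(20)
  x <- matrix(rnorm(600), 100, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  x[, 2] <- x[, 1]
  pr <- correlation_prune(x, 0.95)
  expect_length(pr$retained, 5L)
  expect_true(xor("f1" %in% pr$retained, "f2" %in% pr$retained))
  C <- abs(cor(x[, pr$retained]))
  diag(C) <- 0
  expect_lte(max(C), 0.95)

  x2 <- matrix(rnorm(500), 100, 5, dimnames = list(NULL, paste0("g", 1:5)))
  expect_lt(max(abs(cor(x2)) - diag(5)), 0.5)
  expect_length(correlation_prune(x2, 0.95)$retained, 5L)
})

test_that("pruning matches an independently re-implemented greedy oracle", {
  set.seed(21)
  for (i in 1:50) {
    n <- 60
    p <- 8
    x <- matrix(rnorm(n * p), n, p)
    # plant correlated clusters
    x[, 2] <- x[, 1] + rnorm(n, sd = 0.05)
    x[, 5] <- -x[, 4] + rnorm(n, sd = runif(1, 0.01, 0.5))
    x[, 7] <- x[, 1] + rnorm(n, sd = 0.2)
    colnames(x) <- paste0("f", 1:p)
    expect_identical(correlation_prune(x, 0.95)$retained,
                     oracle_greedy_prune(x, 0.95))
  }
})

test_that("constant columns are flagged and treated as uncorrelated", {
  set.seed(22)
  x <- cbind(a = rnorm(50), b = rep(1, 50), c = rnorm(50))
  pr <- correlation_prune(x)
  expect_equal(pr$constant, "b")
  expect_length(pr$retained, 3L)
})

test_that("standardization centers/scales on train and only train", {
  x <- matrix(c(1, 2, 3, 10, 20, 30), 3, 2,
              dimnames = list(NULL, c("a", "b")))
  p <- standardize_fit(x)
  expect_equal(unname(p$center), c(2, 20))
  expect_equal(unname(p$scale), c(1, 10))
  z <- standardize_apply(p, x)
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1), tolerance = 1e-9)
  held <- matrix(c(4, 40), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(standardize_apply(p, held)), matrix(c(2, 2), 1, 2))
  # constant column: scale 1, flagged
  xc <- cbind(a = rep(5, 4), b = 1:4)
  pc <- standardize_fit(xc)
  expect_equal(pc$zero_var, "a")
  expect_equal(unname(standardize_apply(pc, xc)[, "a"]), rep(0, 4))
  expect_error(standardize_apply(p, x[, c("b", "a")]), "contract error")
})

test_that("tuning returns a single-point grid untouched and is seeded", {
  set.seed(23)
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- factor(rep(c("a", "b"), 25))
  spec1 <- model_spec("SVM_L", "classify_windup", grid = data.frame(cost = 2),
                      seed = 9)
  expect_equal(tune(spec1, x, y)$params$cost, 2)

  spec2 <- model_spec("SVM_L", "classify_windup",
                      grid = data.frame(cost = c(0.1, 1, 10)),
                      tune_k = 5, seed = 9)
  t1 <- tune(spec2, x, y)
  t2 <- tune(spec2, x, y)
  expect_identical(t1, t2)
})

test_that("tuning prefers the hyperparameters that can fit the signal", {
  # XOR labels: depth-1 trees cannot represent the interaction, depth-3 can
  set.seed(24)
  n <- 120
  x1 <- sample(c(-1, 1), n, replace = TRUE)
  x2 <- sample(c(-1, 1), n, replace = TRUE)
  x <- cbind(f1 = x1 + rnorm(n, sd = 0.05), f2 = x2 + rnorm(n, sd = 0.05))
  y <- factor(ifelse(x1 * x2 > 0, "pos", "neg"))
  spec <- model_spec("GBM", "classify_windup",
                     grid = expand.grid(nrounds = 60, max_depth = c(1, 3),
                                        eta = 0.3),
                     tune_k = 5, seed = 7)
  tuned <- tune(spec, x, y)
  expect_equal(tuned$params$max_depth, 3)
})

test_that("each model family fits and predicts through one interface", {
  set.seed(25)
  n <- 90
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y_cls <- factor(ifelse(x[, 1] + 0.2 * rnorm(n) > 0, "hi", "lo"))
  y_reg <- 2 * x[, 1] + rnorm(n, sd = 0.1)
  for (family in c("RF", "SVM_L", "SVM_P", "GBM")) {
    m <- fit_model(family, x, y_cls, as.list(fast_grids[[family]]), seed = 1)
    p <- predict(m, x)
    expect_s3_class(p, "factor")
    expect_gt(mean(p == y_cls), 0.9)
    mr <- fit_model(family, x, y_reg, as.list(fast_grids[[family]]), seed = 1)
    pr <- predict(mr, x)
    expect_type(pr, "double")
    expect_lt(mean(abs(pr - y_reg)), 0.6)
  }
})

test_that("classification metrics reproduce confusion-matrix arithmetic", {
  # counts TP=89, FN=11, TN=75, FP=25
  truth <- c(rep("pos", 100), rep("neg", 100))
  pred <- c(rep("pos", 89), rep("neg", 11), rep("neg", 75), rep("pos", 25))
  m <- class_metrics(truth, pred, "pos")
  expect_equal(m[["sensitivity"]], 0.89)
  expect_equal(m[["specificity"]], 0.75)
  expect_equal(m[["balanced_accuracy"]], 0.82)
  perfect <- class_metrics(truth, truth, "pos")
  expect_equal(unname(perfect), rep(1, 4))
  # balanced-accuracy identity holds per class on a random table
  set.seed(26)
  t3 <- sample(c("a", "b", "c"), 200, replace = TRUE)
  p3 <- sample(c("a", "b", "c"), 200, replace = TRUE)
  tab <- classification_metrics(t3, p3)
  expect_equal(tab$balanced_accuracy,
               (tab$sensitivity + tab$specificity) / 2)
})

test_that("regression metrics are MAE/RMSE/MAPE with RMSE >= MAE", {
  expect_equal(unname(reg_metrics(c(20, 20), c(20, 20))), c(0, 0, 0))
  m <- reg_metrics(c(20, 20), c(21, 19))
  expect_equal(m[["mae"]], 1)
  expect_equal(m[["rmse"]], 1)
  expect_equal(m[["mape"]], 5)
  set.seed(27)
  truth <- runif(100, 15, 25)
  pred <- truth + rnorm(100)
  m2 <- reg_metrics(truth, pred)
  expect_gte(m2[["rmse"]], m2[["mae"]])
  expect_warning(reg_metrics(c(0, 1), c(1, 1)), "MAPE")
})

test_that("LOSO predicts every subject exactly once, never by its own model", {
  sets <- range_feature_sets()
  spec <- model_spec("GBM", "classify_approach", grid = fast_grids$GBM,
                     seed = 3)
  res <- loso_evaluate(spec, tiny_fm, sets$low_g, "approach")
  expect_equal(nrow(res$predictions), nrow(tiny_fm))
  expect_equal(sort(unique(res$predictions$subject_id)),
               sort(unique(tiny_fm$subject_id)))
  counts <- table(res$predictions$subject_id)
  expect_equal(unname(counts),
               unname(table(tiny_fm$subject_id)))
  expect_equal(nrow(res$folds), length(unique(tiny_fm$subject_id)))

  # leakage check: corrupting a held-out subject's labels cannot change the
  # predictions made for that subject
  fm2 <- tiny_fm
  s <- "S02"
  rows <- fm2$subject_id == s
  set.seed(28)
  fm2$approach[rows] <- sample(fm2$approach[rows])
  res2 <- loso_evaluate(spec, fm2, sets$low_g, "approach")
  expect_identical(res2$predictions$prediction[res2$predictions$subject_id == s],
                   res$predictions$prediction[res$predictions$subject_id == s])
})

test_that("LOSO recovers class-separated synthetic labels perfectly", {
  sets <- range_feature_sets()
  spec <- model_spec("GBM", "classify_approach", grid = fast_grids$GBM,
                     seed = 3)
  res <- loso_evaluate(spec, tiny_fm, sets$low_g, "approach")
  expect_equal(res$metrics$balanced_accuracy, rep(1, 3))
})

test_that("permutation importance isolates the used feature, scaled to 100", {
  set.seed(29)
  n <- 150
  x <- cbind(signal = rnorm(n), noise = rnorm(n))
  y <- 3 * x[, "signal"] + rnorm(n, sd = 0.2)
  m <- fit_model("RF", x, y, list(ntree = 300, mtry_kind = "sqrt"), seed = 2)
  imp <- permutation_importance(m, x, y, reps = 5, seed = 4)
  expect_equal(imp$importance[imp$feature == "signal"], 100)
  expect_lt(imp$importance[imp$feature == "noise"], 20)
  expect_true(all(imp$importance >= 0 & imp$importance <= 100))
  imp2 <- permutation_importance(m, x, y, reps = 5, seed = 4)
  expect_identical(imp, imp2)
})
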