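test_that("the ridge penalty keeps separable logistic fits finite", {
  X <- matrix(c(rep(1, 10), rep(-1, 10)), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- rep(c("case", "control"), each = 10)
  model <- train_classifier(X, y)
  expect_true(all(is.finite(tidy(model)$estimate)))
  rep <- evaluate_classifier(model, X, y, dataset = "train")
  expect_equal(rep$auc, 1)
})

test_that("training is deterministic given the seed", {
  set.seed(10)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c("case", "control"), 25)
  for (kind in c("logistic", "svm", "random_forest")) {
    m1 <- train_classifier(X, y, kind = kind, seed = 11)
    m2 <- train_classifier(X, y, kind = kind, seed = 11)
    expect_identical(predict(m1, X), predict(m2, X))
  }
})

test_that("null labels give unremarkable training AUC", {
  set.seed(12)
  aucs <- replicate(15, {
    X <- matrix(rnorm(200 * 4), 200, 4,
                dimnames = list(NULL, paste0("f", 1:4)))
    y <- sample(rep(c(1, 0), 100))
    evaluate_classifier(train_classifier(X, y), X, y)$auc
  })
  expect_gte(mean(aucs < 0.75), 0.95)
})

test_that("an intercept-only model is a constant no-skill predictor", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c("case", "control"), 10)
  m <- train_classifier(X, y, features = character(0))
  p <- predict(m, X)
  expect_equal(length(unique(p)), 1L)
  expect_equal(evaluate_classifier(m, X, y)$auc, 0.5)
})

test_that("prediction demands the trained features", {
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(c("case", "control"), 10)
  m <- train_classifier(X, y, features = c("a", "c"))
  expect_error(predict(m, X[, c("a", "b"), drop = FALSE]), "c")
  expect_error(train_classifier(X, rep("case", 20)), "both classes")
})

test_that("the metric suite matches direct formula evaluation", {
  # perfect separation
  rep1 <- evaluate_classifier(NULL, NULL, c(1, 1, 0, 0),
                              scores = c(0.9, 0.8, 0.1, 0.2))
  expect_equal(rep1$auc, 1)
  expect_equal(rep1$sensitivity, 1)
  expect_equal(rep1$specificity, 1)
  expect_equal(rep1$mcc, 1)
  expect_equal(rep1$f1, 1)

  # all scores tied
  expect_equal(auc_score(rep(0.3, 10), rep(c(1, 0), 5)), 0.5)

  # hand-computed counts: tp 3, fp 1, tn 4, fn 2
  cm <- confusion_metrics(3, 1, 4, 2)
  expect_equal(cm$sensitivity, 0.6)
  expect_equal(cm$specificity, 0.8)
  expect_equal(cm$f1, 2 / 3)
  expect_equal(cm$mcc, 10 / sqrt(600))

  # MCC degenerate-denominator convention
  expect_equal(confusion_metrics(0, 0, 5, 5)$mcc, 0)

  expect_error(auc_score(1:4, rep(1, 4)), "one class")
})

test_that("AUC equals the exhaustive pairwise statistic and pROC agrees", {
  set.seed(14)
  for (r in 1:40) {
    n <- sample(6:50, 1)
    y <- c(1, 0, sample(c(1, 0), n - 2, replace = TRUE))
    scores <- round(rnorm(n), sample(0:2, 1))  # induce ties
    expect_equal(auc_score(scores, y), pairwise_auc(scores, y))
  }
  for (r in 1:10) {
    n <- 40
    y <- sample(rep(c(1, 0), n / 2))
    scores <- rnorm(n)
    expect_equal(auc_score(scores, y),
                 as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("MCC is symmetric under simultaneous class and prediction swap", {
  set.seed(15)
  for (r in 1:20) {
    cnt <- sample(0:20, 4, replace = TRUE)
    m1 <- confusion_metrics(cnt[1], cnt[2], cnt[3], cnt[4])$mcc
    m2 <- confusion_metrics(cnt[3], cnt[4], cnt[1], cnt[2])$mcc
    expect_equal(m1, m2)
  }
})

test_that("ROC points are monotone from (0,0) to (1,1)", {
  set.seed(16)
  rep <- evaluate_classifier(NULL, NULL, sample(rep(c(1, 0), 25)),
                             scores = round(rnorm(50), 1))
  roc <- attr(rep, "roc")
  expect_equal(unlist(roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("single-variate models rank and flag features correctly", {
  set.seed(17)
  n <- 60
  y <- rep(c(1, 0), each = n / 2)
  X <- cbind(ind = y + rnorm(n, sd = 1e-3),
             weak = 0.8 * y + rnorm(n),
             flat = rep(2, n),
             noise = rnorm(n))
  uni <- univariate_models(X, y)
  expect_equal(uni$feature[1], "ind")
  expect_lt(uni$p_value[1], 1e-10)
  expect_true(uni$degenerate[uni$feature == "flat"])
  expect_equal(uni$p_value[uni$feature == "flat"], 1)
  expect_equal(uni$coefficient[uni$feature == "flat"], 0)
  expect_lt(which(uni$feature == "weak"), which(uni$feature == "noise"))
})

test_that("univariate p-values are calibrated under the null", {
  set.seed(18)
  y <- rep(c(1, 0), 20)
  pvals <- replicate(200, {
    uni <- univariate_models(matrix(rnorm(40), dimnames = list(NULL, "f")), y)
    uni$p_value
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})
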