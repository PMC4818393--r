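test_that("the merit formula matches hand evaluation and its invariants", {
  set.seed(21)
  n <- 60
  y <- rep(c(1, 0), each = n / 2)
  X <- cbind(f1 = y + rnorm(n), f2 = rnorm(n), f3 = 0.5 * y + rnorm(n))

  # k = 1: merit equals that feature's absolute class correlation
  m1 <- cfs_merit(X, y, "f1")
  expect_equal(m1$merit, abs(cor(X[, "f1"], y)))
  expect_equal(m1$k, 1L)

  # k = 2: merit from the definition, recomputed by hand
  m2 <- cfs_merit(X, y, c("f1", "f3"))
  rcf <- mean(abs(cor(X[, c("f1", "f3")], y)))
  rff <- abs(cor(X[, "f1"], X[, "f3"]))
  expect_equal(m2$merit, 2 * rcf / sqrt(2 + 2 * rff))

  # k exact copies of one feature: merit stays at the single-feature merit
  Xdup <- cbind(g = X[, "f1"], g2 = X[, "f1"], g3 = X[, "f1"])
  expect_equal(cfs_merit(Xdup, y, 1:3)$merit, m1$merit, tolerance = 1e-12)
})

test_that("best-first search finds the exhaustive optimum on a structured instance", {
  set.seed(33)
  n <- 80
  y <- rep(c(1, 0), each = n / 2)
  f1 <- 2 * y + rnorm(n, sd = 0.9)
  X <- cbind(f1 = f1, f2 = f1, f3 = rnorm(n) + 0.4 * y, f4 = rnorm(n))
  sel <- cfs_search(X, y)
  expect_equal(attr(sel, "merit"), exhaustive_cfs_merit(X, y),
               tolerance = 1e-12)
  expect_true("f1" %in% sel || "f2" %in% sel)
})

test_that("a single informative feature among noise is reliably selected", {
  hits <- sum(sapply(1:30, function(s) {
    set.seed(400 + s)
    n <- 60
    y <- rep(c(1, 0), each = n / 2)
    X <- cbind(sig = 1.5 * y + rnorm(n),
               matrix(rnorm(n * 6), n,
                      dimnames = list(NULL, paste0("n", 1:6))))
    "sig" %in% cfs_search(X, y)
  }))
  expect_gte(hits, 29)
})

test_that("permuted labels give no more merit than the permutation null", {
  set.seed(55)
  n <- 80
  X <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("f", 1:6)))
  y <- sample(rep(c(1, 0), each = n / 2))
  observed <- attr(cfs_search(X, y), "merit")
  null <- replicate(60, attr(cfs_search(X, sample(y)), "merit"))
  expect_lte(observed, quantile(null, 0.99))
})

test_that("consensus selection is stratified, deterministic, and strict", {
  set.seed(77)
  n <- 100
  y <- rep(c("case", "control"), each = n / 2)
  X <- cbind(strong = 3 * (y == "case") + rnorm(n, sd = 0.5),
             matrix(rnorm(n * 5), n,
                    dimnames = list(NULL, paste0("noise", 1:5))))
  sel <- consensus_select(X, y, n_folds = 10, seed = 9)
  expect_s3_class(sel, "consensus_selection")
  expect_equal(length(attr(sel, "per_fold")), 10L)
  expect_equal(sel$frequency[sel$feature == "strong"], 10L)
  expect_true("strong" %in% retained_features(sel))

  # retained features appear in every per-fold subset
  for (s in attr(sel, "per_fold")) {
    expect_true(all(retained_features(sel) %in% s))
  }

  sel2 <- consensus_select(X, y, n_folds = 10, seed = 9)
  expect_identical(as.data.frame(sel), as.data.frame(sel2))
  expect_identical(attr(sel, "per_fold"), attr(sel2, "per_fold"))

  small_y <- rep(c("case", "control"), 6)
  expect_error(consensus_select(X[1:12, ], small_y, n_folds = 10),
               "stratification")
})

test_that("a feature missing from one fold is not retained", {
  # engineered: informative only in fold-specific samples removed in one
  # training split, so it is picked at most 9/10 times
  set.seed(88)
  n <- 60
  y <- rep(c(1, 0), each = n / 2)
  X <- cbind(f = rnorm(n), g = 2 * y + rnorm(n, sd = 0.4))
  sel <- consensus_select(X, y, n_folds = 10, seed = 3)
  freq <- sel$frequency[sel$feature == "f"]
  expect_true(freq < 10)
  expect_false("f" %in% retained_features(sel))
})

test_that("mutual information matches plug-in hand calculations", {
  # feature identical to a balanced class: MI = H(Y) = 1 bit
  y <- rep(c(1, 0), each = 100)
  expect_equal(mutual_information(as.numeric(y), y), 1)

  # hand-computed 4 x 2 table (100,0 / 0,100 / 50,50 / 50,50): 0.5 bit
  x <- rep(c(1, 2, 3, 4), each = 200)
  y2 <- c(rep(1, 200), rep(0, 200), rep(c(1, 0), 100), rep(c(1, 0), 100))
  expect_equal(mutual_information(x, y2, bins = 4), 0.5)

  # fewer distinct values than bins: bins shrink instead of failing
  expect_no_error(mutual_information(rep(c(0, 1, 2), 20),
                                     rep(c(1, 0), 30), bins = 10))
  expect_error(mutual_information(rep(1, 10), rep(c(1, 0), 5)), "distinct")
})

test_that("mutual information is bounded and vanishes under independence", {
  set.seed(99)
  mis <- replicate(20, {
    y <- rep(c(1, 0), 1000)
    mutual_information(rnorm(2000), y)
  })
  expect_gte(mean(mis < 0.02), 0.9)
  # bounds: 0 <= MI <= min(H(bins), H(y)) = 1 bit here
  for (r in 1:10) {
    x <- rnorm(100)
    y <- sample(rep(c(1, 0), 50))
    mi <- mutual_information(x, y)
    expect_gte(mi, 0)
    expect_lte(mi, 1)
  }
})
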