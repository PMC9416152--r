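test_that("gini impurity follows the closed form", {
  expect_equal(gini_impurity(c(3, 3)), 0.5)
  expect_equal(gini_impurity(c(4, 0)), 0)
  expect_equal(gini_impurity(c(1, 3)), 0.375)
  expect_error(gini_impurity(c(0, 0)), "empty node")
  expect_error(gini_impurity(c(-1, 2)), "non-negative")
})

test_that("a perfectly separating predictor yields a depth-one pure tree", {
  X <- cbind(noise = c(5, 1, 4, 2, 3, 6), sig = c(-2, -1, -1.5, 1, 2, 1.2))
  y <- c(0, 0, 0, 1, 1, 1)
  tree <- grow_tree(X, y, params = forest_params(mtry = 2, seed = 1))
  expect_equal(length(tree$var), 3)              # root + two leaves
  expect_equal(attr(tree, "predictors")[tree$var[1]], "sig")
  expect_equal(tree$n0[2] * tree$n1[2], 0)
  expect_equal(tree$n0[3] * tree$n1[3], 0)

  const <- matrix(1, 6, 2, dimnames = list(NULL, c("a", "b")))
  t2 <- grow_tree(const, y, params = forest_params(mtry = 2, seed = 1))
  expect_equal(length(t2$var), 1)
  expect_true(is.na(t2$var[1]))
  expect_equal(t2$pred[1], 1)                    # tie at (3,3) -> present
})

test_that("root splits match exhaustive enumeration on tiny datasets", {
  set.seed(17)
  for (i in 1:60) {
    n <- sample(4:8, 1); p <- sample(1:3, 1)
    X <- matrix(round(rnorm(n * p), 2), n, p,
                dimnames = list(NULL, paste0("v", seq_len(p))))
    y <- rbinom(n, 1, 0.5)
    if (min(sum(y), n - sum(y)) == 0) next
    tree <- grow_tree(X, y, params = forest_params(mtry = p, seed = i))
    oracle <- brute_force_best_split(X, y)
    if (is.null(oracle)) {
      expect_true(is.na(tree$var[1]))
    } else {
      expect_equal(tree$var[1], oracle$var)
      expect_equal(tree$threshold[1], oracle$threshold)
    }
  }
})

test_that("forest fitting is seed-deterministic and validates inputs", {
  set.seed(4)
  X <- matrix(rnorm(120), 30, 4, dimnames = list(NULL, paste0("m", 1:4)))
  y <- X[, 2] > 0
  m1 <- fit_random_forest(X, y, forest_params(n_trees = 50, seed = 9))
  m2 <- fit_random_forest(X, y, forest_params(n_trees = 50, seed = 9))
  expect_identical(m1$trees, m2$trees)
  expect_identical(m1$oob_votes, m2$oob_votes)
  expect_identical(m1$importance, m2$importance)

  expect_error(fit_random_forest(X, rep(1, 30)), "each class")
  expect_error(fit_random_forest(X, y, forest_params(mtry = 9)),
               "cannot exceed")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(fit_random_forest(Xna, y), "complete")
})

test_that("a separating predictor dominates importance and drives OOB accuracy", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("m", 1:4)))
    y <- c(rep(FALSE, 15), rep(TRUE, 15))
    X[, 3] <- ifelse(y, 1, -1) + rnorm(30, 0, 0.1)
    m <- fit_random_forest(X, y, forest_params(seed = s))
    expect_gte(balanced_accuracy(y, oob_predict(m)), 0.95)
    expect_equal(names(which.max(m$importance)), "m3")
  }
})

test_that("label-independent predictors give chance-level OOB balanced accuracy", {
  bas <- vapply(1:10, function(s) {
    set.seed(100 + s)
    X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("m", 1:5)))
    y <- rep(c(TRUE, FALSE), each = 30)
    m <- fit_random_forest(X, y, forest_params(n_trees = 300, seed = s))
    balanced_accuracy(y, oob_predict(m))
  }, numeric(1))
  expect_gt(mean(bas), 0.4)
  expect_lt(mean(bas), 0.6)
})

test_that("OOB voting follows the majority with the documented tie rule", {
  m <- single_split_model()
  m$oob_votes <- matrix(c(10L, 2L, 5L, 0L,
                          2L, 10L, 5L, 0L), 4, 2,
                        dimnames = list(paste0("s", 1:4), c("absent", "present")))
  expect_warning(pred <- oob_predict(m), "no out-of-bag votes")
  expect_identical(unname(pred[1:3]), c(FALSE, TRUE, TRUE))  # tie -> present
  expect_true(is.na(pred[4]))
  expect_identical(unname(suppressWarnings(oob_predict(m, "absent"))[3]), FALSE)

  # at 500 trees every sample collects OOB votes
  set.seed(6)
  X <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, paste0("m", 1:4)))
  y <- rep(c(TRUE, FALSE), 10)
  fit <- fit_random_forest(X, y, forest_params(seed = 2))
  expect_true(all(rowSums(fit$oob_votes) > 0))
})

test_that("mean decrease in Gini matches hand arithmetic and the grown forest's accumulator", {
  mdg <- mean_decrease_gini(single_split_model())
  expect_equal(mdg, c(metA = 5, metB = 0))       # 10*0.5 - 0 - 0; unused -> 0

  set.seed(12)
  X <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("m", 1:5)))
  y <- X[, 4] + rnorm(40, 0, 0.5) > 0
  m <- fit_random_forest(X, y, forest_params(n_trees = 100, seed = 5))
  expect_equal(mean_decrease_gini(m), m$importance, tolerance = 1e-12)
})

test_that("training is invariant to predictor column order", {
  set.seed(19)
  X <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("m", 1:5)))
  y <- X[, 2] + rnorm(40, 0, 0.4) > 0
  m1 <- fit_random_forest(X, y, forest_params(n_trees = 60, seed = 8))
  m2 <- fit_random_forest(X[, c(4, 2, 5, 1, 3)], y,
                          forest_params(n_trees = 60, seed = 8))
  expect_identical(m1$importance, m2$importance)
  expect_identical(m1$oob_votes, m2$oob_votes)
  expect_identical(m1$trees, m2$trees)
})

test_that("duplicating an informative predictor keeps the pair at the top of the ranking", {
  top2 <- vapply(1:10, function(s) {
    set.seed(400 + s)
    X <- matrix(rnorm(50 * 8), 50, 8, dimnames = list(NULL, paste0("m", 1:8)))
    y <- X[, 5] + rnorm(50, 0, 0.3) > 0
    Xd <- cbind(X, m5copy = X[, 5])
    m <- fit_random_forest(Xd, y, forest_params(seed = s))
    ranked <- names(sort(m$importance, decreasing = TRUE))
    all(c("m5", "m5copy") %in% ranked[1:2])
  }, logical(1))
  expect_gte(mean(top2), 0.8)
})

test_that("forest agrees with the reference ensemble implementation on informative-predictor recovery", {
  agree <- 0; derr <- numeric(0)
  for (s in 1:20) {
    set.seed(500 + s)
    X <- matrix(rnorm(50 * 10), 50, 10, dimnames = list(NULL, sprintf("m%02d", 1:10)))
    y <- X[, 3] + rnorm(50, 0, 0.4) > 0
    if (min(sum(y), sum(!y)) < 5) next
    mine <- fit_random_forest(X, y, forest_params(seed = s))
    ref <- randomForest::randomForest(X, factor(y))
    agree <- agree + (names(which.max(mine$importance)) ==
                        rownames(ref$importance)[which.max(ref$importance[, 1])])
    mine_err <- mean(oob_predict(mine) != y)
    ref_err <- mean(predict(ref) != factor(y))
    derr <- c(derr, mine_err - ref_err)
  }
  expect_gte(agree / length(derr), 0.95)
  expect_lt(abs(mean(derr)), 0.1)
})
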