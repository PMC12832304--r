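test_that("LASSO finds a planted near-perfect predictor and shrinks fully at
           the top of the path", {
  set.seed(51)
  n <- 100L
  y <- rep(0:1, each = n / 2)
  x <- cbind(matrix(rnorm(n * 9), n, 9), y + rnorm(n, sd = 0.05))
  colnames(x) <- c(sprintf("NOISE%d", 1:9), "SIGNAL")
  res <- lasso_select(x, y, folds = 10L, seed = 52L)
  expect_s3_class(res, "selector_result")
  expect_true("SIGNAL" %in% res$selected)
  expect_identical(res$selected[1], "SIGNAL")
  # path start (largest lambda) carries zero features: full-shrinkage limit
  expect_identical(res$diagnostics$nzero[1], 0L)
  expect_error(lasso_select(x, rep(0L, n)), "both classes")
})

test_that("LASSO selection is stable under row duplication", {
  set.seed(53)
  n <- 60L
  y <- rep(0:1, each = n / 2)
  x <- cbind(SIGNAL = y + rnorm(n, sd = 0.1),
             matrix(rnorm(n * 4), n, 4,
                    dimnames = list(NULL, sprintf("NOISE%d", 1:4))))
  a <- lasso_select(x, y, folds = 5L, seed = 54L)
  b <- lasso_select(rbind(x, x), c(y, y), folds = 5L, seed = 54L)
  expect_setequal(a$selected, b$selected)
})

test_that("SVM-RFE ranks by squared weights from an independent refit", {
  set.seed(55)
  n <- 40L
  y <- rep(0:1, each = n / 2)
  x <- cbind(matrix(rnorm(n * 2), n, 2) + outer(y, c(2, 1)),
             matrix(rnorm(n * 2), n, 2))
  colnames(x) <- paste0("F", 1:4)
  res <- svm_rfe(x, y, C = 1, seed = 56L)
  # oracle: refit the full-feature SVM and square the weights by hand
  fit <- e1071::svm(x, factor(y, levels = 0:1), kernel = "linear",
                    cost = 1, scale = FALSE)
  w <- crossprod(fit$SV, fit$coefs)[, 1]
  expect_equal(res$diagnostics$ranks[[1]], (w^2)[colnames(x)],
               tolerance = 1e-10)
  # first elimination removes the smallest squared weight
  expect_identical(res$diagnostics$elimination_order[1],
                   names(which.min(w^2)))
  # full path recorded: sizes p, p-1, ..., 1
  expect_identical(res$diagnostics$path_sizes, c(4L, 3L, 2L, 1L))
})

test_that("SVM-RFE keeps planted informative features and is reproducible", {
  set.seed(57)
  n <- 60L
  y <- rep(0:1, each = n / 2)
  x <- cbind(matrix(rnorm(n * 2), n, 2) + outer(y, c(3, 3)),
             matrix(rnorm(n * 8), n, 8))
  colnames(x) <- c("INF1", "INF2", sprintf("NOISE%d", 1:8))
  res <- svm_rfe(x, y, seed = 58L)
  expect_true(all(c("INF1", "INF2") %in% res$selected))
  res2 <- svm_rfe(x, y, seed = 58L)
  expect_identical(res$diagnostics$elimination_order,
                   res2$diagnostics$elimination_order)
  expect_identical(res$selected, res2$selected)
  # eliminate_per_round exceeding the remaining count keeps one feature
  res3 <- svm_rfe(x, y, eliminate_per_round = 100L, seed = 58L)
  expect_identical(res3$diagnostics$path_sizes, c(10L, 1L))
})

test_that("forest importances follow the degenerate-feature identities", {
  set.seed(59)
  n <- 60L
  y <- rep(0:1, each = n / 2)
  x <- cbind(LABELCOPY = as.numeric(y),
             CONST = rep(1, n),
             matrix(rnorm(n * 3), n, 3,
                    dimnames = list(NULL, sprintf("NOISE%d", 1:3))))
  res <- rf_importance(x, y, n_trees = 100L, seed = 60L)
  mdi <- res$diagnostics$mdi
  fi <- res$diagnostics$permutation_importance
  # constant feature: never split on, unaffected by permutation
  expect_equal(unname(mdi["CONST"]), 0)
  expect_equal(unname(fi["CONST"]), 0)
  # label copy dominates both importances
  expect_identical(names(which.max(mdi)), "LABELCOPY")
  expect_identical(res$selected[1], "LABELCOPY")
  expect_equal(unname(res$diagnostics$oob_error), 0, tolerance = 0.05)
})

test_that("structure-derived MDI and OOB error reproduce the forest's own report", {
  set.seed(61)
  n <- 80L
  y <- rep(0:1, each = n / 2)
  x <- cbind(matrix(rnorm(n * 2), n, 2) + outer(y, c(2, 2)),
             matrix(rnorm(n * 6), n, 6))
  colnames(x) <- paste0("F", 1:8)
  res <- rf_importance(x, y, n_trees = 100L, seed = 62L)
  set.seed(62L)
  rf <- randomForest::randomForest(x, factor(y, levels = 0:1), ntree = 100L,
                                   keep.forest = TRUE, keep.inbag = TRUE)
  expect_equal(unname(res$diagnostics$mean_decrease_gini),
               unname(rf$importance[, "MeanDecreaseGini"]),
               tolerance = 1e-10)
  expect_equal(res$diagnostics$oob_error,
               unname(rf$err.rate[100L, "OOB"]), tolerance = 1e-12)
})

test_that("consensus intersection is a set intersection in the first list's order", {
  a <- c("G1", "G2", "G3", "G4")
  b <- c("G4", "G2", "G9")
  c3 <- c("G2", "G4", "G7")
  expect_identical(consensus_intersect(a, b, c3), c("G2", "G4"))
  expect_identical(consensus_intersect(a, a, a), a)          # idempotence
  expect_identical(consensus_intersect(a, "X", "Y"), character(0))
  # contained in each input regardless of argument order
  for (perm in list(list(a, b, c3), list(b, c3, a), list(c3, a, b))) {
    out <- do.call(consensus_intersect, perm)
    expect_true(all(out %in% a) && all(out %in% b) && all(out %in% c3))
  }
})

test_that("the AUC screen is direction-aware with a strict threshold", {
  set.seed(63)
  n <- 200L
  y <- rep(0:1, each = n / 2)
  x <- cbind(PERFECT = as.numeric(y),
             DOWN = -y + rnorm(n, sd = 0.1),
             SHUFFLED = sample(rnorm(n)))
  res <- auc_screen(x, y)
  expect_equal(res$auc[res$gene == "PERFECT"], 1)
  expect_true(res$pass[res$gene == "PERFECT"])
  expect_identical(res$direction[res$gene == "DOWN"], "down")
  expect_gt(res$auc[res$gene == "DOWN"], 0.9)
  expect_lt(abs(res$auc[res$gene == "SHUFFLED"] - 0.5), 0.1)
  expect_false(res$pass[res$gene == "SHUFFLED"])
  # AUC exactly at the threshold fails (strict inequality)
  xb <- cbind(BORDER = c(0, 3.5, 1, 2, 3, 4, 5))
  yb <- c(0L, 0L, 1L, 1L, 1L, 1L, 1L)
  resb <- auc_screen(xb, yb, threshold = 0.7)
  expect_equal(resb$auc, 0.7)
  expect_false(resb$pass)
  expect_error(auc_screen(x, rep(1L, n)), "both classes")
})
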