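test_that("episodes draw disjoint support and query sets of the right size", {
  cfg <- train_config(seed = 31L)
  labels <- rep(0:1, each = 10)
  ep <- sample_episode(labels, cfg, seed = 5L)
  expect_length(ep$support[[1]], 5L)
  expect_length(ep$support[[2]], 5L)
  expect_length(ep$query, 10L)
  all_idx <- c(ep$support[[1]], ep$support[[2]], ep$query)
  expect_length(unique(all_idx), 20L)             # all 20 indices distinct
  expect_true(all(labels[ep$support[[1]]] == 0))
  expect_true(all(labels[ep$support[[2]]] == 1))
  expect_identical(ep, sample_episode(labels, cfg, seed = 5L))  # seeded
  # pigeonhole: 9 samples cannot host K=5 support + Q=5 queries
  expect_error(sample_episode(rep(0:1, c(9, 10)), cfg, seed = 1L),
               "class 0 has 9")
})

test_that("episode loss matches its closed forms", {
  # equal scores for every query: uniform softmax, loss = ln 2
  R <- rbind(c(0.3, 0.3), c(-1, -1))
  expect_equal(episode_loss(R, c(0, 1)), log(2), tolerance = 1e-12)
  # single query, scores (0, 1), true class 1
  expect_equal(episode_loss(c(0, 1), 1L, tau = 1), log(1 + exp(-1)),
               tolerance = 1e-12)
  expect_equal(episode_loss(c(0, 1), 1L, tau = 0.5), log(1 + exp(-2)),
               tolerance = 1e-12)
  expect_error(episode_loss(c(0, 1), 1L, tau = 0), "tau")
})

test_that("a freshly initialized model scores near the no-information baseline", {
  set.seed(32)
  enc <- encoder_params(12L, dropout_rate = 0)
  rel <- relation_params()
  act <- matrix(rnorm(12 * 30), 12, 30)
  labels <- rep(0:1, each = 15)
  cfg <- train_config(k_shot = 4L, queries_per_class = 4L)
  losses <- replicate(30, {
    ep <- sample_episode(labels, cfg)
    fewshotDx:::episode_grad(enc, rel, act, ep, tau = 1)$loss
  })
  se <- stats::sd(losses) / sqrt(length(losses))
  expect_lt(abs(mean(losses) - log(2)), 3 * se + 1e-3)
})

test_that("training log is bounded and stagnation triggers early stopping", {
  set.seed(33)
  act <- matrix(rnorm(8 * 24), 8, 24)
  y <- rep(0:1, each = 12)
  vact <- matrix(rnorm(8 * 8), 8, 8)
  vy <- rep(0:1, each = 4)
  # zeroed learning rate: scores never change, AUC cannot improve,
  # patience = 1 stops at the second checkpoint
  cfg <- train_config(k_shot = 3L, queries_per_class = 3L,
                      max_episodes = 200L, eval_every = 10L, patience = 1L,
                      learning_rate = 0, seed = 34L)
  fit <- train_relation(act, y, vact, vy, cfg)
  expect_equal(nrow(fit$log), 2L)
  cfg2 <- train_config(k_shot = 3L, queries_per_class = 3L,
                       max_episodes = 60L, eval_every = 10L, patience = 50L,
                       seed = 34L)
  fit2 <- train_relation(act, y, vact, vy, cfg2)
  expect_lte(nrow(fit2$log), 6L)                  # <= max_episodes / eval_every
  expect_error(train_relation(act, y, vact, rep(1L, 8), cfg2), "single class")
})

test_that("training loss decreases on the separable benchmark", {
  b <- bench_model()
  log <- b$model$log
  expect_gte(nrow(log), 20)
  k <- nrow(log)
  expect_lt(mean(log$train_loss[(k - 9):k]), mean(log$train_loss[1:10]))
})

test_that("held-out case queries outscore control queries", {
  b <- bench_model()
  pr <- predict(b$model, b$dataset$expression[, b$split$test], seed = 3L)
  y <- b$dataset$labels[b$split$test]
  expect_gt(mean(pr$score[y == 1]), mean(pr$score[y == 0]))
})

test_that("prediction is deterministic given seed and strategies agree on labels", {
  b <- bench_model()
  X <- b$dataset$expression[, b$split$test]
  p1 <- predict(b$model, X, strategy = "kshot_ensemble", seed = 17L)
  p2 <- predict(b$model, X, strategy = "kshot_ensemble", seed = 17L)
  expect_identical(p1, p2)
  pf <- predict(b$model, X, strategy = "full_set")
  expect_gte(mean(p1$class == pf$class), 0.95)
  expect_true(all(is.finite(p1$score)))
})

test_that("a single ensemble draw equals a direct relation-score call", {
  b <- bench_model()
  m <- b$model
  X <- b$dataset$expression[, b$split$test[1:2]]
  pr <- predict(m, X, strategy = "kshot_ensemble", M = 1L, seed = 41L)
  # reproduce the one support draw the ensemble made
  qact <- fewshotDx:::model_activities(m, X)
  ract <- m$reference$activities
  i0 <- which(m$reference$labels == 0); i1 <- which(m$reference$labels == 1)
  set.seed(41L)
  K <- min(m$config$k_shot, length(i0), length(i1))
  s0 <- sample(i0, K); s1 <- sample(i1, K)
  Hq <- encode(qact, m$encoder)
  Hr <- encode(ract, m$encoder)
  r <- relation_scores(Hq[1, ], list(Hr[s0, ], Hr[s1, ]), m$relation)
  expect_equal(unname(pr$r0[1]), unname(r["r0"]), tolerance = 1e-10)
  expect_equal(unname(pr$r1[1]), unname(r["r1"]), tolerance = 1e-10)
})

test_that("prediction requires a two-class reference and model-covered genes", {
  b <- bench_model()
  X <- b$dataset$expression[, b$split$test[1:2]]
  ref <- list(expression = b$dataset$expression[, b$split$train[1:4]],
              labels = rep(0L, 4))
  expect_error(predict(b$model, X, reference = ref), "both classes")
  expect_error(predict(b$model, X[1:10, ]), "lacks")
})

test_that("a saved model reloads with identical predictions", {
  b <- bench_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_fewshot_model(b$model, path)
  m2 <- read_fewshot_model(path)
  X <- b$dataset$expression[, b$split$test[1:5]]
  expect_equal(predict(b$model, X, seed = 7L), predict(m2, X, seed = 7L),
               tolerance = 1e-12)
  expect_equal(m2$gate$weights, b$model$gate$weights)
  expect_identical(m2$schema, "fewshotDx-model/1")
})
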