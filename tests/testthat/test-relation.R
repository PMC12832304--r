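test_that("evaluation-mode encoding is deterministic with the documented shape", {
  enc <- encoder_params(20L, seed = 21L)
  x <- rnorm(20)
  h1 <- encode(x, enc)
  h2 <- encode(x, enc)
  expect_identical(h1, h2)
  expect_length(h1, 64L)
  # matrix input: one embedding per column
  M <- matrix(rnorm(60), 20, 3)
  H <- encode(M, enc)
  expect_equal(dim(H), c(3L, 64L))
  expect_equal(H[2, ], encode(M[, 2], enc))
  expect_error(encode(rnorm(5), enc), "expects 20")
})

test_that("zero input with zero biases propagates to a zero embedding", {
  enc <- encoder_params(10L, seed = 22L)
  enc$l1$b[] <- 0; enc$l2$b[] <- 0
  expect_equal(encode(rep(0, 10), enc), rep(0, 64))
})

test_that("training-mode dropout is stochastic but eval mode ignores it", {
  enc <- encoder_params(10L, dropout_rate = 0.5, seed = 23L)
  x <- rnorm(10)
  set.seed(1); a <- encode(x, enc, train_mode = TRUE)
  set.seed(2); b <- encode(x, enc, train_mode = TRUE)
  expect_false(identical(a, b))
  set.seed(1); a2 <- encode(x, enc, train_mode = TRUE)
  expect_identical(a, a2)
})

test_that("Hadamard similarity is the element-wise product", {
  expect_equal(hadamard_similarity(c(1, 2, 3), c(4, 5, 6)), c(4, 10, 18))
  h <- rnorm(8); g <- rnorm(8)
  expect_equal(hadamard_similarity(h, g), hadamard_similarity(g, h))
  expect_equal(hadamard_similarity(rep(1, 8), g), g)
  expect_error(hadamard_similarity(1:3, 1:4), "lengths differ")
})

test_that("relation scores are exactly invariant to support permutations", {
  rel <- relation_params(d = 16L, seed = 24L)
  set.seed(25)
  h_q <- rnorm(16)
  for (K in c(1L, 3L, 7L, 20L)) {
    s0 <- matrix(rnorm(K * 16), K, 16)
    s1 <- matrix(rnorm(K * 16), K, 16)
    base <- relation_scores(h_q, list(s0, s1), rel)
    for (i in 1:25) {
      p0 <- sample(K); p1 <- sample(K)
      perm <- relation_scores(h_q, list(s0[p0, , drop = FALSE],
                                        s1[p1, , drop = FALSE]), rel)
      expect_identical(perm, base)
    }
  }
})

test_that("linear heads reduce the relation score to a closed form", {
  d <- 6L
  rel <- linear_relation_params(d)
  set.seed(26)
  h_q <- rnorm(d)
  s0 <- matrix(rnorm(3 * d), 3, d)
  s1 <- matrix(rnorm(5 * d), 5, d)
  r <- relation_scores(h_q, list(s0, s1), rel)
  # oracle: explicit double loop over supports and coordinates
  oracle <- function(S) {
    tot <- 0
    for (s in seq_len(nrow(S))) for (i in seq_len(d))
      tot <- tot + h_q[i] * S[s, i]
    tot
  }
  expect_equal(unname(r), c(oracle(s0), oracle(s1)), tolerance = 1e-10)
})

test_that("support duplication doubles sum-aggregated scores under linear heads
           and leaves mean aggregation unchanged", {
  d <- 5L
  set.seed(27)
  h_q <- rnorm(d)
  s <- matrix(rnorm(4 * d), 4, d)
  lin <- linear_relation_params(d)
  r1 <- relation_scores(h_q, list(s, s), lin)
  r2 <- relation_scores(h_q, list(rbind(s, s), rbind(s, s)), lin)
  expect_equal(unname(r2), 2 * unname(r1), tolerance = 1e-10)
  relm <- relation_params(d = d, aggregation = "mean", seed = 28L)
  m1 <- relation_scores(h_q, list(s, s), relm)
  m2 <- relation_scores(h_q, list(rbind(s, s), rbind(s, s)), relm)
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("empty class support is rejected", {
  rel <- relation_params(d = 4L, seed = 29L)
  expect_error(relation_scores(rnorm(4),
                               list(matrix(0, 0, 4), matrix(rnorm(4), 1, 4)),
                               rel),
               "empty support")
})

test_that("episode backprop matches finite differences", {
  set.seed(30)
  enc <- encoder_params(6L, hidden_dims = c(5L, 4L), dropout_rate = 0)
  rel <- relation_params(d = 4L, phi_hidden = 3L, rho_hidden = 3L)
  act <- matrix(rnorm(6 * 12), 6, 12)
  ep <- list(support = list(1:3, 4:6), query = 7:12,
             query_labels = c(0, 0, 0, 1, 1, 1))
  res <- fewshotDx:::episode_grad(enc, rel, act, ep, tau = 1)
  theta <- fewshotDx:::flatten_blocks(fewshotDx:::param_blocks(enc, rel))
  f <- function(v) {
    upd <- fewshotDx:::unflatten_into(v, enc, rel)
    fewshotDx:::episode_grad(upd$enc, upd$rel, act, ep, tau = 1)$loss
  }
  h <- 1e-6
  idx <- sample(length(theta), 30)
  num <- vapply(idx, function(i) {
    e <- theta; e[i] <- theta[i] + h; fp <- f(e)
    e[i] <- theta[i] - h; fm <- f(e)
    (fp - fm) / (2 * h)
  }, 1)
  expect_lt(max(abs(num - res$grad[idx])), 1e-6)
  # gradient flows into the encoder weights on a generic episode
  n_enc <- length(enc$l1$W) + length(enc$l1$b) +
    length(enc$l2$W) + length(enc$l2$b)
  expect_gt(sum(abs(res$grad[seq_len(n_enc)])), 0)
})
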