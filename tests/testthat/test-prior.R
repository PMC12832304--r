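test_that("identity prior at lambda = 0 returns the expression unchanged", {
  X <- matrix(rnorm(9), 3, 3,
              dimnames = list(paste0("G", 1:3), paste0("S", 1:3)))
  Z <- diag(3)
  dimnames(Z) <- list(paste0("G", 1:3), paste0("LV", 1:3))
  B <- project_to_latent(X, Z, lambda = 0)
  expect_false(B$gated)
  expect_equal(unname(B$activities), unname(X), tolerance = 1e-12)
})

test_that("ridge solution matches the hand-solved normal equations", {
  Z <- matrix(c(1, 0, 1, 0, 1, 1), 3, 2,
              dimnames = list(paste0("G", 1:3), c("LV1", "LV2")))
  X <- matrix(c(1, 2, 3), 3, 1, dimnames = list(paste0("G", 1:3), "S1"))
  B <- project_to_latent(X, Z, lambda = 0.5)
  expect_equal(unname(B$activities[, 1]), c(20 / 21, 34 / 21),
               tolerance = 1e-12)
})

test_that("projection agrees with an independent dense solve on random instances", {
  set.seed(10)
  worst <- 0
  for (i in 1:50) {
    G <- sample(2:20, 1); L <- sample(1:8, 1); n <- sample(1:10, 1)
    Z <- matrix(rnorm(G * L), G, L,
                dimnames = list(paste0("G", 1:G), paste0("LV", 1:L)))
    X <- matrix(rnorm(G * n), G, n,
                dimnames = list(rownames(Z), paste0("S", 1:n)))
    lam <- runif(1, 0.01, 2)
    B <- project_to_latent(X, Z, lambda = lam)$activities
    oracle <- solve(t(Z) %*% Z + lam * diag(L)) %*% t(Z) %*% X
    worst <- max(worst, max(abs(B - oracle)))
  }
  expect_lt(worst, 1e-8)
})

test_that("activity norm shrinks monotonically as lambda grows", {
  set.seed(11)
  for (i in 1:5) {
    Z <- matrix(rnorm(40), 8, 5,
                dimnames = list(paste0("G", 1:8), paste0("LV", 1:5)))
    X <- matrix(rnorm(24), 8, 3,
                dimnames = list(rownames(Z), paste0("S", 1:3)))
    lam <- runif(1, 0.05, 1)
    n1 <- norm(project_to_latent(X, Z, lam)$activities, "F")
    n2 <- norm(project_to_latent(X, Z, 10 * lam)$activities, "F")
    expect_lt(n2, n1)
  }
})

test_that("projection rejects misaligned genes and a singular system at lambda 0", {
  Z <- matrix(1, 2, 2, dimnames = list(c("A", "B"), c("LV1", "LV2")))
  X <- matrix(1, 2, 1, dimnames = list(c("B", "A"), "S1"))
  expect_error(project_to_latent(X, Z), "align")
  X2 <- matrix(1, 2, 1, dimnames = list(c("A", "B"), "S1"))
  expect_error(project_to_latent(X2, Z, lambda = 0), "lambda > 0")
})

test_that("gate weights follow the mean absolute hub loading", {
  Z <- matrix(c(0.2, 0.4, 0.8, 0.0), 2, 2,
              dimnames = list(c("H1", "H2"), c("LV1", "LV2")))
  g <- compute_gate(Z, c("H1", "H2"), norm_mode = "max")
  expect_equal(unname(g$raw), c(0.3, 0.4))
  expect_equal(unname(g$weights), c(0.75, 1.0))
  g1 <- compute_gate(Z, c("H1", "H2"), norm_mode = "l1")
  expect_equal(unname(g1$weights), c(3 / 7, 4 / 7))
  # single hub gene: weights proportional to its own |loadings|
  gs <- compute_gate(Z, "H1", norm_mode = "max")
  expect_equal(unname(gs$raw), abs(unname(Z["H1", ])))
})

test_that("gate is invariant to hub-list order and duplication", {
  set.seed(12)
  Z <- matrix(abs(rnorm(40)), 8, 5,
              dimnames = list(paste0("G", 1:8), paste0("LV", 1:5)))
  a <- compute_gate(Z, c("G1", "G3", "G5"))
  b <- compute_gate(Z, c("G5", "G1", "G3", "G1"))
  expect_equal(a$weights, b$weights)
  expect_equal(a$hub_genes, b$hub_genes)
})

test_that("gate errors name missing hubs and reject an all-zero gate", {
  Z <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("LV1", "LV2")))
  expect_error(compute_gate(Z, c("A", "ZZZ")), "ZZZ")
  expect_error(compute_gate(Z, "A"), "zero")
  expect_error(compute_gate(Z, character(0)), "empty")
})

test_that("apply_gate scales rows, flags the result, and contracts in max mode", {
  set.seed(13)
  Z <- matrix(abs(rnorm(40)) + 0.1, 10, 4,
              dimnames = list(paste0("G", 1:10), paste0("LV", 1:4)))
  X <- matrix(rnorm(30), 10, 3,
              dimnames = list(rownames(Z), paste0("S", 1:3)))
  B <- project_to_latent(X, Z, lambda = 1)
  g <- compute_gate(Z, c("G1", "G2"), norm_mode = "max")
  Bg <- apply_gate(B, g)
  expect_true(Bg$gated)
  expect_equal(Bg$activities, B$activities * g$weights)
  # max-mode weights lie in [0,1]: every gated row norm is a contraction
  rn <- function(m) sqrt(rowSums(m^2))
  expect_true(all(rn(Bg$activities) <= rn(B$activities) + 1e-12))
  # identity gate leaves activities untouched; zeroed channel vanishes
  gid <- g; gid$weights[] <- 1
  expect_equal(apply_gate(B, gid)$activities, B$activities)
  g0 <- g; g0$weights[] <- c(1, 0, 0, 0)
  expect_true(all(apply_gate(B, g0)$activities[2:4, ] == 0))
  # mismatched LV ids are a contract error
  gbad <- g; gbad$lv_ids <- rev(gbad$lv_ids)
  expect_error(apply_gate(B, gbad), "ids")
})

test_that("downstream benchmark AUC is insensitive to the ridge penalty", {
  aucs <- c(bench_heldout_auc(lambda = 0.1),
            bench_heldout_auc(lambda = 1),
            bench_heldout_auc(lambda = 10))
  expect_lt(max(aucs) - min(aucs), 0.02)
})
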