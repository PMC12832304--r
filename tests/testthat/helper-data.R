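# Shared fixtures, all generated in code under fixed seeds.

# Planted-signal feature table: two clearly separable informative
# features (class shift 3 noise-SDs, single-feature AUC ~ 0.98) among
# pure-noise features.
make_planted <- function(seed, n = 100L, p_noise = 18L, delta = 3) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  x <- cbind(matrix(stats::rnorm(n * 2), n, 2) + outer(y, c(delta, delta)),
             matrix(stats::rnorm(n * p_noise), n, p_noise))
  colnames(x) <- c("INF1", "INF2", sprintf("NOISE%02d", seq_len(p_noise)))
  list(x = x, y = y)
}

# Synthetic expression benchmark: 60 samples/class generated, 20/class
# held out, 40/class handed to the trainer (which splits off its own
# stratified validation set). Trained models are cached so several test
# files can interrogate the same fit.
.bench_cache <- new.env(parent = emptyenv())

bench_dataset <- function(effect_size = 1.5, data_seed = 7L) {
  make_dataset(synthetic_config(n_per_class = 60L,
                                effect_size = effect_size,
                                seed = data_seed))
}

bench_split <- function(ds, split_seed = 99L) {
  set.seed(split_seed)
  test_idx <- c(sample(which(ds$labels == 0), 20L),
                sample(which(ds$labels == 1), 20L))
  list(test = test_idx, train = setdiff(seq_along(ds$labels), test_idx))
}

bench_model <- function(effect_size = 1.5, lambda = 1, data_seed = 7L,
                        train_seed = 11L) {
  key <- sprintf("d%s_l%s_s%d_t%d", effect_size, lambda, data_seed, train_seed)
  if (!is.null(.bench_cache[[key]])) return(.bench_cache[[key]])
  ds <- bench_dataset(effect_size, data_seed)
  sp <- bench_split(ds)
  cfg <- train_config(seed = train_seed, lambda = lambda)
  model <- suppressMessages(
    fewshot_train(ds$expression[, sp$train], ds$labels[sp$train],
                  ds$loadings, ds$true_hub_genes, cfg))
  out <- list(model = model, dataset = ds, split = sp)
  .bench_cache[[key]] <- out
  out
}

bench_heldout_auc <- function(effect_size = 1.5, lambda = 1, ...) {
  b <- bench_model(effect_size, lambda, ...)
  pr <- predict(b$model, b$dataset$expression[, b$split$test], seed = 3L)
  roc_auc(pr$score, b$dataset$labels[b$split$test])$auc
}

# Brute-force AUC oracle: count positive-negative pairs, ties one half.
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Exact-linear relation heads despite ReLU hidden layers:
# phi(x) = x via [relu(x); relu(-x)] recombined, rho(x) = sum(x).
linear_relation_params <- function(d) {
  rel <- relation_params(d = d, phi_hidden = 2L * d, rho_hidden = 2L * d,
                         aggregation = "sum", seed = 1L)
  I <- diag(d)
  rel$phi1$W <- cbind(I, -I); rel$phi1$b <- rep(0, 2 * d)
  rel$phi2$W <- rbind(I, -I); rel$phi2$b <- rep(0, d)
  rel$rho1$W <- cbind(I, -I); rel$rho1$b <- rep(0, 2 * d)
  rel$rho2$W <- matrix(c(rep(1, d), rep(-1, d)), ncol = 1L)
  rel$rho2$b <- 0
  rel
}
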