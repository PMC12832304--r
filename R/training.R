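#' Training configuration for the episodic few-shot trainer
#'
#' Defaults follow the 2-way 5-shot episodic design: 5 support and 5
#' query samples per class per episode, up to 1000 episodes (one Adam
#' step per episode), validation AUC checked every `eval_every` episodes
#' with early stopping after `patience` consecutive checkpoints without
#' improvement.
#'
#' @param k_shot Support samples per class per episode.
#' @param queries_per_class Query samples per class per episode.
#' @param max_episodes Upper bound on training episodes.
#' @param temperature Softmax temperature \eqn{\tau > 0} in the episode
#'   loss.
#' @param learning_rate,weight_decay Adam step size and L2 weight decay
#'   (applied to weight matrices, not biases).
#' @param dropout Encoder dropout rate during training.
#' @param eval_every Episodes between validation checkpoints.
#' @param patience Consecutive non-improving checkpoints tolerated
#'   before stopping.
#' @param aggregation Deep-Sets aggregation, `"sum"` or `"mean"`.
#' @param norm_mode Gate normalization, `"max"` or `"l1"`.
#' @param lambda Ridge penalty for the latent projection.
#' @param val_fraction Fraction of samples held out (stratified) for the
#'   early-stopping validation set in [fewshot_train()].
#' @param ensemble_draws Number of seeded K-shot support draws averaged
#'   by the `"kshot_ensemble"` prediction strategy.
#' @param seed Seed governing initialization, episode sampling, dropout
#'   and the validation split.
#' @return A `"train_config"` list.
#' @export
train_config <- function(k_shot = 5L, queries_per_class = 5L,
                         max_episodes = 1000L, temperature = 1,
                         learning_rate = 1e-3, weight_decay = 1e-4,
                         dropout = 0.3, eval_every = 10L, patience = 10L,
                         aggregation = c("sum", "mean"),
                         norm_mode = c("max", "l1"),
                         lambda = 1, val_fraction = 0.25,
                         ensemble_draws = 20L, seed = 1L) {
  aggregation <- match.arg(aggregation)
  norm_mode <- match.arg(norm_mode)
  stopifnot(k_shot >= 1, queries_per_class >= 1, max_episodes >= 1,
            temperature > 0, learning_rate >= 0, weight_decay >= 0,
            dropout >= 0, dropout < 1, eval_every >= 1, patience >= 1,
            lambda >= 0, val_fraction > 0, val_fraction < 1,
            ensemble_draws >= 1)
  structure(list(k_shot = as.integer(k_shot),
                 queries_per_class = as.integer(queries_per_class),
                 max_episodes = as.integer(max_episodes),
                 temperature = temperature,
                 learning_rate = learning_rate,
                 weight_decay = weight_decay, dropout = dropout,
                 eval_every = as.integer(eval_every),
                 patience = as.integer(patience),
                 aggregation = aggregation, norm_mode = norm_mode,
                 lambda = lambda, val_fraction = val_fraction,
                 ensemble_draws = as.integer(ensemble_draws),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Sample a 2-way K-shot episode
#'
#' Draws, without replacement and independently per class, `k_shot`
#' support and `queries_per_class` query indices; support and query sets
#' are disjoint by construction.
#'
#' @param labels Integer 0/1 vector over the available samples.
#' @param config A [train_config()]; only `k_shot` and
#'   `queries_per_class` are used.
#' @param seed Optional seed; if `NULL` the current RNG stream is used
#'   (as inside the training loop).
#' @return List with `support` (list of index vectors for class 0 and
#'   class 1), `query` (index vector) and `query_labels`.
#' @export
sample_episode <- function(labels, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- config$k_shot; Q <- config$queries_per_class
  need <- K + Q
  sup <- vector("list", 2L); qry <- integer(0); qlab <- integer(0)
  for (c in 0:1) {
    idx <- which(labels == c)
    if (length(idx) < need)
      stop(sprintf("class %d has %d samples but an episode needs %d (K=%d + Q=%d)",
                   c, length(idx), need, K, Q))
    draw <- sample(idx, need, replace = FALSE)
    sup[[c + 1L]] <- draw[seq_len(K)]
    qry <- c(qry, draw[K + seq_len(Q)])
    qlab <- c(qlab, rep(c, Q))
  }
  list(support = sup, query = qry, query_labels = qlab)
}

#' Episodic cross-entropy loss on query predictions
#'
#' Mean over queries of the negative log softmax probability of the true
#' class, with relation scores divided by the temperature \eqn{\tau}
#' before the softmax. The mean (rather than sum) convention makes the
#' loss magnitude independent of the number of queries.
#'
#' @param scores Numeric matrix with one row per query and columns
#'   `(r_0, r_1)`, or a length-2 vector for a single query.
#' @param labels Integer 0/1 vector of true query classes.
#' @param tau Temperature, strictly positive.
#' @return Non-negative scalar loss.
#' @export
episode_loss <- function(scores, labels, tau = 1) {
  if (tau <= 0) stop("temperature tau must be > 0")
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  stopifnot(ncol(scores) == 2L, nrow(scores) == length(labels),
            all(labels %in% 0:1))
  Z <- scores / tau
  m <- pmax(Z[, 1L], Z[, 2L])           # log-sum-exp stabilization
  lse <- m + log(exp(Z[, 1L] - m) + exp(Z[, 2L] - m))
  mean(lse - Z[cbind(seq_along(labels), labels + 1L)])
}

# softmax gradient of episode_loss w.r.t. the score matrix
episode_loss_grad <- function(scores, labels, tau) {
  Z <- scores / tau
  m <- apply(Z, 1L, max)
  P <- exp(Z - m)
  P <- P / rowSums(P)
  Y <- cbind(1 - labels, labels)
  (P - Y) / (tau * nrow(scores))
}

# Forward + backward of one episode; returns loss and the flat gradient.
episode_grad <- function(enc, rel, activities, ep, tau) {
  Qt <- length(ep$query)
  K0 <- length(ep$support[[1L]]); K1 <- length(ep$support[[2L]])
  idx <- c(ep$query, ep$support[[1L]], ep$support[[2L]])
  X <- t(activities[, idx, drop = FALSE])
  ec <- enc_forward(enc, X, train_mode = TRUE)
  Hq <- ec$H[seq_len(Qt), , drop = FALSE]
  Hs <- list(ec$H[Qt + seq_len(K0), , drop = FALSE],
             ec$H[Qt + K0 + seq_len(K1), , drop = FALSE])
  fwd <- relation_forward(rel, Hq, Hs)
  loss <- episode_loss(fwd$R, ep$query_labels, tau)
  dR <- episode_loss_grad(fwd$R, ep$query_labels, tau)
  back <- relation_backward(rel, Hq, Hs, fwd, dR)
  dH <- rbind(back$dHq, back$dHs[[1L]], back$dHs[[2L]])
  genc <- enc_backward(enc, ec, dH)
  gblocks <- list(enc_l1 = genc$l1, enc_l2 = genc$l2,
                  phi1 = back$grads$phi1, phi2 = back$grads$phi2,
                  rho1 = back$grads$rho1, rho2 = back$grads$rho2)
  list(loss = loss, grad = flatten_blocks(gblocks), scores = fwd$R)
}

# Score queries against a labeled reference in eval mode.
# query_act / ref_act: L x n gated activity matrices.
score_against_reference <- function(enc, rel, query_act, ref_act, ref_labels,
                                    strategy = c("kshot_ensemble", "full_set"),
                                    k_shot = 5L, draws = 20L, seed = NULL) {
  strategy <- match.arg(strategy)
  if (length(unique(ref_labels)) < 2L)
    stop("reference set must contain both classes")
  Hq <- enc_forward(enc, t(query_act))$H
  Href <- enc_forward(enc, t(ref_act))$H
  i0 <- which(ref_labels == 0); i1 <- which(ref_labels == 1)
  if (strategy == "full_set") {
    R <- relation_forward(rel, Hq, list(Href[i0, , drop = FALSE],
                                        Href[i1, , drop = FALSE]))$R
  } else {
    if (!is.null(seed)) set.seed(seed)
    K <- min(k_shot, length(i0), length(i1))
    R <- matrix(0, nrow(Hq), 2L)
    for (m in seq_len(draws)) {
      s0 <- sample(i0, K); s1 <- sample(i1, K)
      R <- R + relation_forward(rel, Hq, list(Href[s0, , drop = FALSE],
                                              Href[s1, , drop = FALSE]))$R
    }
    R <- R / draws
  }
  R
}

#' Train the relation network on gated latent activities
#'
#' Core episodic trainer: one Adam step per episode on the query
#' cross-entropy loss, with L2 weight decay and encoder dropout. Every
#' `eval_every` episodes the validation samples are scored (evaluation
#' mode, full training set as support reference) and the validation AUC
#' is recorded; training stops early after `patience` consecutive
#' checkpoints without AUC improvement, and the parameters of the
#' best-AUC checkpoint are returned.
#'
#' @param train_activities,val_activities Gated LVs-by-samples activity
#'   matrices (see [apply_gate()]).
#' @param train_labels,val_labels Integer 0/1 vectors.
#' @param config A [train_config()].
#' @return A `"relation_fit"`: `encoder`, `relation`, `log` (data frame
#'   of checkpoints: episode, mean train loss, validation AUC),
#'   `best_checkpoint`, `config`.
#' @export
train_relation <- function(train_activities, train_labels,
                           val_activities, val_labels, config) {
  stopifnot(inherits(config, "train_config"))
  if (length(unique(val_labels)) < 2L)
    stop("validation set has a single class: validation AUC undefined")
  need <- config$k_shot + config$queries_per_class
  for (c in 0:1)
    if (sum(train_labels == c) < need)
      stop(sprintf("class %d has %d training samples; episodes need %d",
                   c, sum(train_labels == c), need))
  set.seed(config$seed)
  L <- nrow(train_activities)
  enc <- encoder_params(L, dropout_rate = config$dropout)
  rel <- relation_params(aggregation = config$aggregation)
  theta <- flatten_blocks(param_blocks(enc, rel))
  dmask <- decay_mask(param_blocks(enc, rel))
  adam <- adam_init(length(theta))

  log_ep <- integer(0); log_loss <- numeric(0); log_auc <- numeric(0)
  best_auc <- -Inf; best_theta <- theta; best_ckpt <- NA_integer_
  stall <- 0L; window <- numeric(0)

  for (ep_i in seq_len(config$max_episodes)) {
    ep <- sample_episode(train_labels, config)
    res <- episode_grad(enc, rel, train_activities, ep, config$temperature)
    grad <- res$grad + config$weight_decay * dmask * theta
    st <- adam_step(adam, theta, grad, config$learning_rate)
    theta <- st$theta; adam <- st$state
    upd <- unflatten_into(theta, enc, rel)
    enc <- upd$enc; rel <- upd$rel
    window <- c(window, res$loss)

    if (ep_i %% config$eval_every == 0L) {
      R <- score_against_reference(enc, rel, val_activities,
                                   train_activities, train_labels,
                                   strategy = "full_set")
      auc <- roc_auc(R[, 2L] - R[, 1L], val_labels)$auc
      log_ep <- c(log_ep, ep_i)
      log_loss <- c(log_loss, mean(window)); window <- numeric(0)
      log_auc <- c(log_auc, auc)
      if (auc > best_auc) {
        best_auc <- auc; best_theta <- theta
        best_ckpt <- length(log_ep); stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
  }
  upd <- unflatten_into(best_theta, enc, rel)
  structure(list(encoder = upd$enc, relation = upd$rel,
                 log = data.frame(episode = log_ep, train_loss = log_loss,
                                  val_auc = log_auc),
                 best_checkpoint = best_ckpt, best_val_auc = best_auc,
                 config = config),
            class = "relation_fit")
}

#' Train the full prior-informed few-shot diagnostic model
#'
#' End-to-end pipeline: align expression with the prior, z-score genes
#' (training-derived parameters), project onto the latent space by ridge
#' regression, gate the latent channels by the hub-gene loadings, split
#' off a stratified validation set for early stopping, and train the
#' relation network episodically. The returned model carries everything
#' inference needs: network weights, the gate, standardization
#' parameters, the aligned prior, the ridge penalty, and the gated
#' training activities as the stored support reference.
#'
#' @param expression Genes-by-samples log2 expression matrix (training
#'   cohort).
#' @param labels Integer 0/1 vector (0 = control, 1 = case), named or in
#'   column order of `expression`.
#' @param loadings Genes-by-LVs prior loading matrix (kept fixed).
#' @param hub_genes Character vector of hub gene symbols.
#' @param config A [train_config()].
#' @return A `"fewshot_model"` object.
#' @export
fewshot_train <- function(expression, labels, loadings, hub_genes,
                          config = train_config()) {
  if (!is.null(names(labels))) {
    missing <- setdiff(colnames(expression), names(labels))
    if (length(missing) > 0L)
      stop("unlabeled samples: ", paste(utils::head(missing, 5), collapse = ", "))
    labels <- labels[colnames(expression)]
  }
  labels <- as.integer(labels)
  al <- align_to_prior(expression, loadings)
  std <- standardize_genes(al$expression)
  Z <- al$loadings[rownames(std$values), , drop = FALSE]
  act <- project_to_latent(std$values, Z, lambda = config$lambda)
  gate <- compute_gate(Z, hub_genes, norm_mode = config$norm_mode)
  gact <- apply_gate(act, gate)

  set.seed(config$seed)
  val_idx <- integer(0)
  for (c in 0:1) {
    idx <- which(labels == c)
    n_val <- max(1L, round(length(idx) * config$val_fraction))
    val_idx <- c(val_idx, sample(idx, n_val))
  }
  tr_idx <- setdiff(seq_along(labels), val_idx)
  fit <- train_relation(gact$activities[, tr_idx, drop = FALSE], labels[tr_idx],
                        gact$activities[, val_idx, drop = FALSE], labels[val_idx],
                        config)
  structure(list(encoder = fit$encoder, relation = fit$relation,
                 gate = gate, standardization = std$params,
                 loadings = Z, lambda = config$lambda,
                 reference = list(activities = gact$activities[, tr_idx, drop = FALSE],
                                  labels = labels[tr_idx],
                                  sample_ids = colnames(expression)[tr_idx]),
                 log = fit$log, best_checkpoint = fit$best_checkpoint,
                 best_val_auc = fit$best_val_auc,
                 config = config, schema = "fewshotDx-model/1"),
            class = "fewshot_model")
}

#' @export
print.fewshot_model <- function(x, ...) {
  cat(sprintf(paste0("fewshot_model: %d genes -> %d LVs -> d=%d embedding\n",
                     "  hub genes: %s\n  best validation AUC %.3f at checkpoint %d (%d logged)\n"),
              nrow(x$loadings), ncol(x$loadings), x$relation$d,
              paste(x$gate$hub_genes, collapse = ", "),
              x$best_val_auc, x$best_checkpoint, nrow(x$log)))
  invisible(x)
}

# Run new expression through the stored preprocessing into gated activities.
model_activities <- function(model, expression) {
  genes <- rownames(model$loadings)
  missing <- setdiff(genes, rownames(expression))
  if (length(missing) > 0L)
    stop("query expression lacks ", length(missing),
         " model gene(s), e.g. ", paste(utils::head(missing, 5), collapse = ", "))
  X <- expression[genes, , drop = FALSE]
  std <- standardize_genes(X, params = model$standardization)
  act <- project_to_latent(std$values,
                           model$loadings[rownames(std$values), , drop = FALSE],
                           lambda = model$lambda)
  apply_gate(act, model$gate)$activities
}

#' Predict case-vs-control for new samples
#'
#' Applies the stored preprocessing (z-scoring with training parameters,
#' ridge projection, hub-gene gating), encodes the queries in evaluation
#' mode, and scores them against a labeled support reference. The raw
#' diagnostic score is \eqn{s(x) = r_{q,1} - r_{q,0}}, the binary
#' log-odds under the softmax head at temperature 1; the hard class is
#' \eqn{\arg\max_c r_{q,c}}.
#'
#' Strategies: `"kshot_ensemble"` (default) averages relation scores
#' over `M` seeded draws of `k_shot` support samples per class, so the
#' aggregator sees the support-set size it was trained with;
#' `"full_set"` uses every reference sample of each class at once.
#'
#' @param object A `"fewshot_model"`.
#' @param expression Genes-by-samples log2 expression of the queries.
#' @param strategy `"kshot_ensemble"` or `"full_set"`.
#' @param reference Optional external reference: a list with
#'   `expression` (genes x samples) and `labels` (0/1). Defaults to the
#'   training activities stored in the model.
#' @param M Number of ensemble draws.
#' @param seed Seed for the ensemble support draws.
#' @param ... Unused.
#' @return Data frame: `sample_id`, `r0`, `r1`, `score` (s(x)),
#'   `class`.
#' @export
predict.fewshot_model <- function(object, expression,
                                  strategy = c("kshot_ensemble", "full_set"),
                                  reference = NULL, M = NULL, seed = 1L, ...) {
  strategy <- match.arg(strategy)
  if (is.null(M)) M <- object$config$ensemble_draws
  qact <- model_activities(object, expression)
  if (is.null(reference)) {
    ract <- object$reference$activities
    rlab <- object$reference$labels
  } else {
    ract <- model_activities(object, reference$expression)
    rlab <- as.integer(reference$labels)
  }
  R <- score_against_reference(object$encoder, object$relation, qact,
                               ract, rlab, strategy = strategy,
                               k_shot = object$config$k_shot,
                               draws = M, seed = seed)
  data.frame(sample_id = colnames(expression),
             r0 = R[, 1L], r1 = R[, 2L],
             score = R[, 2L] - R[, 1L],
             class = as.integer(R[, 2L] > R[, 1L]))
}
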