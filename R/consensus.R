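## Consensus machine-learning feature selection: three complementary
## selectors (L1-penalized logistic regression, linear-SVM recursive
## feature elimination, random-forest importance) whose gene lists are
## intersected into a consensus biomarker panel, plus a per-gene ROC-AUC
## screen. Solvers (glmnet, e1071, randomForest) are delegated; the RFE
## loop, the w^2 ranking, the out-of-bag voting error, the mean-decrease-
## Gini and permutation importances are computed here from the fitted
## model structures.

check_feature_table <- function(x, y) {
  stopifnot(is.matrix(x), length(y) == nrow(x))
  if (any(!is.finite(x))) stop("feature matrix contains missing/non-finite values")
  if (!all(y %in% 0:1) || length(unique(y)) < 2L)
    stop("labels must be 0/1 with both classes present")
  if (is.null(colnames(x))) stop("feature matrix needs column names")
  invisible(TRUE)
}

#' LASSO feature selection by cross-validated penalized logistic regression
#'
#' Fits the L1-penalized binomial model along a regularization path
#' (coordinate descent via glmnet) and selects the features with
#' nonzero coefficients at the cross-validation-chosen penalty —
#' `lambda.min` (default) or the one-standard-error rule `lambda.1se`.
#' Fold assignment is seeded and stratified.
#'
#' @param x Samples-by-features numeric matrix.
#' @param y Integer 0/1 labels.
#' @param folds Number of CV folds (the classic choice is 10).
#' @param rule `"lambda_min"` or `"lambda_1se"`.
#' @param seed Seed for the fold assignment.
#' @return A `"selector_result"`: `method = "lasso"`, `selected`
#'   (ordered by decreasing absolute coefficient), `diagnostics`
#'   (lambda path, CV deviance curve, chosen lambda, coefficients).
#' @export
lasso_select <- function(x, y, folds = 10L, rule = c("lambda_min", "lambda_1se"),
                         seed = 1L) {
  rule <- match.arg(rule)
  check_feature_table(x, y)
  if (min(table(y)) < folds)
    stop("need at least `folds` samples in each class")
  foldid <- stratified_folds(y, folds, seed)
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                          foldid = foldid)
  s <- if (rule == "lambda_min") cv$lambda.min else cv$lambda.1se
  co <- as.numeric(stats::coef(cv, s = s))[-1L]  # drop intercept
  names(co) <- colnames(x)
  sel <- names(sort(abs(co[co != 0]), decreasing = TRUE))
  structure(list(method = "lasso", selected = sel,
                 diagnostics = list(lambda = cv$lambda, cvm = cv$cvm,
                                    nzero = as.integer(cv$nzero),
                                    lambda_min = cv$lambda.min,
                                    lambda_1se = cv$lambda.1se,
                                    rule = rule, chosen_lambda = s,
                                    coefficients = co)),
            class = "selector_result")
}

# weight vector of a fitted linear SVM: w = sum_i alpha_i y_i x_i
linear_svm_weights <- function(fit) {
  w <- crossprod(fit$SV, fit$coefs)[, 1L]
  stats::setNames(w, colnames(fit$SV))
}

#' SVM-RFE: recursive feature elimination by squared SVM weights
#'
#' Iteratively fits a linear soft-margin SVM, ranks each remaining
#' feature by the square of its weight-vector component \eqn{w_j^2},
#' removes the lowest-ranked features, and repeats until one feature
#' remains. The selected subset is the point on the elimination path
#' with the highest cross-validated accuracy; ties go to the smaller
#' subset. Features are not rescaled internally, so \eqn{w_j^2} refers
#' to the features as given.
#'
#' @param x Samples-by-features matrix.
#' @param y Integer 0/1 labels.
#' @param C Soft-margin cost parameter.
#' @param eliminate_per_round Features removed per iteration (classical
#'   RFE removes 1). If it meets or exceeds the remaining count, the
#'   final round keeps the single top-ranked feature.
#' @param folds CV folds for the path accuracy.
#' @param seed Seed for the fold assignment.
#' @return A `"selector_result"`: `selected` (most important first),
#'   `diagnostics` (`elimination_order`, per-step subsets and ranks,
#'   `cv_accuracy` along the path).
#' @export
svm_rfe <- function(x, y, C = 1, eliminate_per_round = 1L, folds = 5L,
                    seed = 1L) {
  check_feature_table(x, y)
  stopifnot(C > 0, eliminate_per_round >= 1L)
  yf <- factor(y, levels = 0:1)
  remaining <- colnames(x)
  elimination <- character(0)
  path <- list()      # subsets from largest to smallest
  ranks <- list()
  while (length(remaining) > 1L) {
    fit <- e1071::svm(x[, remaining, drop = FALSE], yf, kernel = "linear",
                      cost = C, scale = FALSE)
    w2 <- linear_svm_weights(fit)[remaining]^2
    path[[length(path) + 1L]] <- remaining
    ranks[[length(ranks) + 1L]] <- w2
    k <- min(eliminate_per_round, length(remaining) - 1L)
    drop_feats <- names(sort(w2))[seq_len(k)]
    elimination <- c(elimination, drop_feats)
    remaining <- setdiff(remaining, drop_feats)
  }
  path[[length(path) + 1L]] <- remaining

  foldid <- stratified_folds(y, folds, seed)
  cv_acc <- vapply(path, function(feats) {
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- foldid != f; te <- foldid == f
      fit <- e1071::svm(x[tr, feats, drop = FALSE], yf[tr],
                        kernel = "linear", cost = C, scale = FALSE)
      pred <- stats::predict(fit, x[te, feats, drop = FALSE])
      correct <- correct + sum(pred == yf[te])
    }
    correct / length(y)
  }, 1)
  sizes <- lengths(path)
  best_acc <- max(cv_acc)
  best <- which(cv_acc == best_acc)
  best <- best[which.min(sizes[best])]          # tie -> smaller subset
  selected_set <- path[[best]]
  # order: survivors first (by final-round w^2 if available), then by
  # reverse elimination order
  order_all <- c(remaining, rev(elimination))
  selected <- order_all[order_all %in% selected_set]
  structure(list(method = "svm_rfe", selected = selected,
                 diagnostics = list(elimination_order = elimination,
                                    path_sizes = sizes,
                                    cv_accuracy = cv_acc,
                                    best_size = sizes[best],
                                    ranks = ranks, C = C, folds = folds)),
            class = "selector_result")
}

# Route samples through one randomForest tree (matrix from getTree);
# returns terminal-node index per sample.
route_tree <- function(tree, x) {
  cur <- rep.int(1L, nrow(x))
  repeat {
    active <- tree[cur, "status"] != -1L
    if (!any(active)) break
    rows <- which(active)
    nd <- cur[rows]
    v <- tree[nd, "split var"]
    left <- x[cbind(rows, v)] <= tree[nd, "split point"]
    cur[rows] <- ifelse(left, tree[nd, "left daughter"],
                        tree[nd, "right daughter"])
  }
  cur
}

# Weighted class counts (n_nodes x 2) at every node of a tree: walk the
# in-bag samples down and accumulate their bootstrap multiplicities.
node_class_counts <- function(tree, x, y, w) {
  counts <- matrix(0, nrow(tree), 2L)
  cur <- rep.int(1L, nrow(x))
  add <- function(counts, nodes, y, w) {
    for (k in 0:1) {
      sel <- y == k
      if (any(sel)) {
        inc <- rowsum(w[sel], group = nodes[sel])
        idx <- as.integer(rownames(inc))
        counts[idx, k + 1L] <- counts[idx, k + 1L] + inc[, 1L]
      }
    }
    counts
  }
  keep <- w > 0
  cur <- cur[keep]; yk <- y[keep]; wk <- w[keep]; xk <- x[keep, , drop = FALSE]
  counts <- add(counts, cur, yk, wk)
  repeat {
    active <- tree[cur, "status"] != -1L
    if (!any(active)) break
    rows <- which(active)
    nd <- cur[rows]
    v <- tree[nd, "split var"]
    left <- xk[cbind(rows, v)] <= tree[nd, "split point"]
    cur[rows] <- ifelse(left, tree[nd, "left daughter"],
                        tree[nd, "right daughter"])
    counts <- add(counts, cur[rows], yk[rows], wk[rows])
  }
  counts
}

gini <- function(counts) {
  n <- rowSums(counts)
  p <- counts / pmax(n, 1)
  1 - rowSums(p^2)
}

# OOB majority-vote predictions over a fitted forest (Eq.-7 style):
# vote k that maximizes the count of OOB trees predicting k.
oob_votes <- function(trees, x, inbag) {
  votes <- matrix(0L, nrow(x), 2L)
  for (t in seq_along(trees)) {
    oob <- inbag[, t] == 0L
    if (!any(oob)) next
    leaf <- route_tree(trees[[t]], x[oob, , drop = FALSE])
    pred <- trees[[t]][leaf, "prediction"]       # 1 or 2
    votes[cbind(which(oob), pred)] <- votes[cbind(which(oob), pred)] + 1L
  }
  votes
}

oob_error <- function(votes, y) {
  covered <- rowSums(votes) > 0L
  pred <- max.col(votes, ties.method = "first") - 1L
  mean(pred[covered] != y[covered])
}

#' Random-forest feature importance from the fitted forest's structure
#'
#' Grows a bagged forest of Gini-split CART trees (tree induction via
#' randomForest with `keep.inbag`), then computes three quantities
#' directly from the stored trees:
#' \itemize{
#' \item out-of-bag error: each sample is predicted by majority vote
#'   over the trees whose bootstrap missed it;
#' \item mean decrease in impurity (MDI): for every node split on gene
#'   j, the Gini decrease weighted by the fraction of in-bag samples
#'   reaching the node, summed per tree and averaged over the forest;
#' \item permutation importance: the increase in out-of-bag error after
#'   one seeded permutation of gene j's values (difference form;
#'   a feature whose permutation leaves the error unchanged scores 0).
#' }
#' Two MDI scales are reported: `mdi` weights each node by the fraction
#' of in-bag samples reaching it (so a tree contributes at most ~0.5),
#' while `mean_decrease_gini` weights by the sample count — the scale
#' on which forest reports conventionally print importance, equal to
#' `n * mdi`. Features are selected above an absolute
#' `mean_decrease_gini` cutoff (default 3, the conventional
#' report-scale threshold) or, alternatively, at a fraction of the
#' maximum MDI; the absolute cutoff is cohort-scale-dependent, which is
#' why the relative rule is offered.
#'
#' @param x Samples-by-features matrix.
#' @param y Integer 0/1 labels.
#' @param n_trees Number of trees.
#' @param mdi_threshold Absolute cutoff on the `mean_decrease_gini`
#'   (report) scale when `threshold_type = "absolute"`.
#' @param threshold_type `"absolute"` or `"fraction_of_max"`.
#' @param fraction Cutoff as a fraction of the largest MDI when
#'   `threshold_type = "fraction_of_max"`.
#' @param seed Seed for forest growth and the permutations.
#' @return A `"selector_result"`: `selected` (by decreasing MDI),
#'   `diagnostics` (`mdi`, `mean_decrease_gini`,
#'   `permutation_importance`, `oob_error`, `n_trees`).
#' @export
rf_importance <- function(x, y, n_trees = 500L, mdi_threshold = 3,
                          threshold_type = c("absolute", "fraction_of_max"),
                          fraction = 0.05, seed = 1L) {
  threshold_type <- match.arg(threshold_type)
  check_feature_table(x, y)
  stopifnot(n_trees >= 1L)
  set.seed(seed)
  rf <- randomForest::randomForest(x, factor(y, levels = 0:1),
                                   ntree = n_trees, keep.forest = TRUE,
                                   keep.inbag = TRUE)
  inbag <- rf$inbag
  trees <- lapply(seq_len(n_trees), function(t)
    randomForest::getTree(rf, t, labelVar = FALSE))
  n <- nrow(x); p <- ncol(x)

  mdi <- numeric(p)
  for (t in seq_len(n_trees)) {
    tr <- trees[[t]]
    counts <- node_class_counts(tr, x, y, inbag[, t])
    nu <- rowSums(counts)
    imp <- gini(counts)
    internal <- which(tr[, "status"] != -1L)
    for (u in internal) {
      lu <- tr[u, "left daughter"]; ru <- tr[u, "right daughter"]
      if (nu[u] == 0) next
      di <- imp[u] - (nu[lu] / nu[u]) * imp[lu] - (nu[ru] / nu[u]) * imp[ru]
      j <- tr[u, "split var"]
      mdi[j] <- mdi[j] + (nu[u] / sum(inbag[, t])) * di
    }
  }
  mdi <- mdi / n_trees
  names(mdi) <- colnames(x)

  if (!any(inbag == 0L)) {
    warning("no out-of-bag coverage; OOB error and permutation importance undefined")
    e_orig <- NA_real_
    fi <- rep(NA_real_, p)
  } else {
    e_orig <- oob_error(oob_votes(trees, x, inbag), y)
    fi <- numeric(p)
    for (j in seq_len(p)) {
      xp <- x
      xp[, j] <- x[sample.int(n), j]
      fi[j] <- oob_error(oob_votes(trees, xp, inbag), y) - e_orig
    }
  }
  names(fi) <- colnames(x)

  mdg <- mdi * n   # report scale: node weight = sample count, not fraction
  sel <- if (threshold_type == "absolute") {
    names(sort(mdg[mdg > mdi_threshold], decreasing = TRUE))
  } else {
    cutoff <- fraction * max(mdi)
    names(sort(mdi[mdi >= cutoff], decreasing = TRUE))
  }
  structure(list(method = "random_forest", selected = sel,
                 diagnostics = list(mdi = mdi, mean_decrease_gini = mdg,
                                    permutation_importance = fi,
                                    oob_error = e_orig, n_trees = n_trees,
                                    threshold_type = threshold_type,
                                    mdi_threshold = mdi_threshold,
                                    fraction = fraction)),
            class = "selector_result")
}

#' @export
print.selector_result <- function(x, ...) {
  cat(sprintf("selector_result [%s]: %d feature(s): %s\n", x$method,
              length(x$selected), paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Venn intersection of three selector results
#'
#' The consensus biomarker panel: genes retained by all three selectors,
#' reported in the first argument's order.
#'
#' @param a,b,c `"selector_result"` objects or plain character vectors.
#' @return Character vector (possibly empty).
#' @export
consensus_intersect <- function(a, b, c) {
  get <- function(s) if (inherits(s, "selector_result")) s$selected else s
  a <- get(a); b <- get(b); c <- get(c)
  a[a %in% b & a %in% c]
}

#' Per-gene diagnostic AUC screen
#'
#' Computes each gene's single-marker ROC-AUC for case vs control. The
#' reported AUC is direction-specific: the larger of the two
#' orientations (gene up in cases vs gene down in cases) together with
#' its direction. A gene passes only if its AUC strictly exceeds the
#' threshold.
#'
#' @param x Samples-by-features matrix.
#' @param y Integer 0/1 labels.
#' @param genes Genes to screen; defaults to all columns.
#' @param threshold Pass cutoff (strict inequality).
#' @return Data frame `(gene, auc, direction, pass)`.
#' @export
auc_screen <- function(x, y, genes = colnames(x), threshold = 0.7) {
  check_feature_table(x, y)
  missing <- setdiff(genes, colnames(x))
  if (length(missing) > 0L)
    stop("genes not in matrix: ", paste(missing, collapse = ", "))
  res <- lapply(genes, function(g) {
    a <- roc_auc(x[, g], y)$auc
    if (a >= 1 - a) data.frame(gene = g, auc = a, direction = "up")
    else data.frame(gene = g, auc = 1 - a, direction = "down")
  })
  out <- do.call(rbind, res)
  out$pass <- out$auc > threshold
  out
}
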