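#' ROC curve and AUC by the tie-corrected rank statistic
#'
#' AUC is the probability that a randomly chosen positive outscores a
#' randomly chosen negative, with ties counted one half — the
#' Mann-Whitney form, computed from midranks. ROC points are returned
#' for every distinct score threshold.
#'
#' @param scores Numeric vector.
#' @param labels Integer 0/1 vector (1 = positive).
#' @return List with `auc` and `roc`, a data frame of
#'   `(threshold, fpr, tpr)` sorted from the strictest cutoff.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute an ROC curve")
  r <- rank(scores)  # midranks: ties counted 1/2
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  s_ord <- scores[ord]
  ends <- c(which(diff(s_ord) != 0), length(s_ord))  # last index per tie block
  tpr <- cumsum(labels[ord] == 1)[ends] / n1
  fpr <- cumsum(labels[ord] == 0)[ends] / n0
  list(auc = auc,
       roc = data.frame(threshold = c(Inf, s_ord[ends]), fpr = c(0, fpr),
                        tpr = c(0, tpr)))
}

#' Brier score
#'
#' Mean squared difference between predicted probability and the binary
#' outcome; lower is better, 0.25 for a constant 0.5 forecast.
#'
#' @param probs Probabilities in \[0, 1\].
#' @param labels Integer 0/1 vector.
#' @return Non-negative scalar.
#' @export
brier <- function(probs, labels) {
  stopifnot(length(probs) == length(labels), all(labels %in% 0:1))
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  mean((probs - labels)^2)
}

# Seeded stratified fold assignment (each class spread across folds).
stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (c in unique(labels)) {
    idx <- sample(which(labels == c))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

platt_fit <- function(scores, labels) {
  fit <- suppressWarnings(stats::glm(labels ~ scores,
                                     family = stats::binomial()))
  as.numeric(stats::coef(fit))  # (intercept, slope)
}

platt_predict <- function(coefs, scores) {
  stats::plogis(coefs[1L] + coefs[2L] * scores)
}

isotonic_fit <- function(scores, labels) {
  o <- order(scores)
  fit <- stats::isoreg(scores[o], labels[o])
  # collapse to unique score knots (isoreg output is non-decreasing)
  knots_x <- fit$x; knots_y <- fit$yf
  agg <- tapply(knots_y, knots_x, mean)
  list(x = as.numeric(names(agg)), y = as.numeric(agg))
}

isotonic_predict <- function(iso, scores) {
  if (length(iso$x) == 1L) return(rep(iso$y, length(scores)))
  p <- stats::approx(iso$x, iso$y, xout = scores, method = "linear",
                     rule = 2, ties = "ordered")$y
  pmin(pmax(p, 0), 1)
}

#' Fit a monotone score-to-probability calibration map
#'
#' Fits both Platt scaling (a logistic sigmoid on the raw score) and
#' isotonic regression (a nonparametric monotone step map, linearly
#' interpolated between knots), estimates each method's cross-validated
#' Brier score with seeded stratified folds, refits the lower-Brier
#' method on all data and returns it. Ties favor Platt (the simpler
#' map). If the scores have fewer than two distinct values isotonic
#' regression is undefined and the function falls back to Platt with a
#' warning.
#'
#' @param scores Raw diagnostic scores s(x).
#' @param labels Integer 0/1 outcomes.
#' @param folds Number of CV folds.
#' @param seed Seed for the fold assignment.
#' @return A `"calibration_map"`: `method`, fitted map, `cv_brier`
#'   (named vector, both methods), `folds`, `seed`.
#' @export
fit_calibration <- function(scores, labels, folds = 5L, seed = 1L) {
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  if (length(unique(labels)) < 2L) stop("both classes required")
  if (length(scores) < folds) stop("need at least `folds` samples")
  if (length(unique(scores)) < 2L) {
    warning("fewer than 2 distinct scores; falling back to Platt scaling")
    co <- platt_fit(scores, labels)
    return(structure(list(method = "platt", platt = co, isotonic = NULL,
                          cv_brier = c(platt = NA_real_, isotonic = NA_real_),
                          folds = folds, seed = seed),
                     class = "calibration_map"))
  }
  fold <- stratified_folds(labels, folds, seed)
  pred_p <- numeric(length(scores)); pred_i <- numeric(length(scores))
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- fold == f
    pred_p[te] <- platt_predict(platt_fit(scores[tr], labels[tr]), scores[te])
    pred_i[te] <- isotonic_predict(isotonic_fit(scores[tr], labels[tr]),
                                   scores[te])
  }
  cv <- c(platt = brier(pred_p, labels), isotonic = brier(pred_i, labels))
  method <- if (cv["isotonic"] < cv["platt"]) "isotonic" else "platt"
  structure(list(method = method,
                 platt = platt_fit(scores, labels),
                 isotonic = isotonic_fit(scores, labels),
                 cv_brier = cv, folds = folds, seed = seed),
            class = "calibration_map")
}

#' Map raw scores to calibrated probabilities
#'
#' @param object A `"calibration_map"`.
#' @param scores Raw scores.
#' @param ... Unused.
#' @return Probabilities in \[0, 1\], monotone non-decreasing in the
#'   score.
#' @export
predict.calibration_map <- function(object, scores, ...) {
  if (object$method == "platt") platt_predict(object$platt, scores)
  else isotonic_predict(object$isotonic, scores)
}

#' @export
print.calibration_map <- function(x, ...) {
  cat(sprintf("calibration_map: %s (CV Brier platt=%.4f isotonic=%.4f, %d folds)\n",
              x$method, x$cv_brier["platt"], x$cv_brier["isotonic"], x$folds))
  invisible(x)
}

#' Decision-curve analysis
#'
#' Net benefit of calling positives at probability threshold \eqn{p_t}:
#' \deqn{NB(p_t) = TP/n - (FP/n) \, p_t / (1 - p_t),}
#' with positives called where \eqn{\hat p \ge p_t}, compared against
#' the treat-all policy (everyone called positive) and treat-none
#' (net benefit identically zero).
#'
#' @param probs Calibrated probabilities.
#' @param labels Integer 0/1 outcomes.
#' @param grid Threshold grid in (0, 1); endpoints 0 and 1 are excluded
#'   with a warning.
#' @return Data frame `(threshold, nb_model, nb_all, nb_none)`.
#' @export
decision_curve <- function(probs, labels, grid = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(length(probs) == length(labels), all(labels %in% 0:1))
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  bad <- grid <= 0 | grid >= 1
  if (any(bad)) {
    warning("dropping ", sum(bad), " threshold(s) outside (0, 1)")
    grid <- grid[!bad]
  }
  n <- length(labels)
  prev <- mean(labels)
  nb_model <- vapply(grid, function(pt) {
    call_pos <- probs >= pt
    tp <- sum(call_pos & labels == 1) / n
    fp <- sum(call_pos & labels == 0) / n
    tp - fp * pt / (1 - pt)
  }, 1)
  nb_all <- prev - (1 - prev) * grid / (1 - grid)
  data.frame(threshold = grid, nb_model = nb_model, nb_all = nb_all,
             nb_none = 0)
}
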