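## Relation-network core: two-branch encoder, Hadamard similarity map and
## permutation-invariant Deep-Sets relation head. Forward and backward
## passes are written out explicitly (plain matrix algebra); gradients are
## verified against finite differences in the test suite.

# Dense layer with uniform fan-in init: U(-1/sqrt(n_in), +1/sqrt(n_in)).
# Draws from the current RNG stream so a run is reproducible from its seed.
dense_init <- function(n_in, n_out) {
  s <- 1 / sqrt(n_in)
  list(W = matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out),
       b = stats::runif(n_out, -s, s))
}

#' Initialize encoder parameters
#'
#' The encoder \eqn{f_\theta: R^L \to R^d} is a 2-layer fully connected
#' network: input (L latent activities) to 128 hidden units (ReLU,
#' dropout) to 64 units (ReLU). The 64-unit layer is the embedding, so
#' \eqn{d = 64} by default.
#'
#' @param input_dim Number of latent variables L.
#' @param hidden_dims Integer pair, widths of the two layers.
#' @param dropout_rate Dropout probability after the first ReLU, active
#'   only in training mode.
#' @param seed Optional seed for the weight draw; if `NULL` the current
#'   RNG stream is used.
#' @return An `"encoder_params"` object.
#' @export
encoder_params <- function(input_dim, hidden_dims = c(128L, 64L),
                           dropout_rate = 0.3, seed = NULL) {
  stopifnot(length(hidden_dims) == 2L, dropout_rate >= 0, dropout_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dims = as.integer(hidden_dims),
                 dropout_rate = dropout_rate,
                 l1 = dense_init(input_dim, hidden_dims[1L]),
                 l2 = dense_init(hidden_dims[1L], hidden_dims[2L])),
            class = "encoder_params")
}

#' Initialize relation-module parameters
#'
#' The Deep-Sets head \eqn{r_{q,c} = \rho_\psi(\sum_{s \in S_c}
#' \phi(m_{q,s}))}: \eqn{\phi} is a one-hidden-layer perceptron
#' d -> 64 (ReLU) -> d, \eqn{\rho_\psi} a perceptron d -> 32 (ReLU) -> 1.
#' Aggregation over the support set is `"sum"` (the canonical symmetric
#' set function) or `"mean"` (invariant to support duplication, useful
#' when inference support sizes differ from the training shot count).
#'
#' @param d Embedding dimension (must match the encoder output).
#' @param phi_hidden,rho_hidden Hidden widths of the two perceptrons.
#' @param aggregation `"sum"` or `"mean"`.
#' @param seed Optional seed for the weight draw.
#' @return A `"relation_params"` object.
#' @export
relation_params <- function(d = 64L, phi_hidden = 64L, rho_hidden = 32L,
                            aggregation = c("sum", "mean"), seed = NULL) {
  aggregation <- match.arg(aggregation)
  if (!is.null(seed)) set.seed(seed)
  structure(list(d = as.integer(d), aggregation = aggregation,
                 phi1 = dense_init(d, phi_hidden),
                 phi2 = dense_init(phi_hidden, d),
                 rho1 = dense_init(d, rho_hidden),
                 rho2 = dense_init(rho_hidden, 1L)),
            class = "relation_params")
}

# ---- forward passes (row-major: one sample per row) ----

enc_forward <- function(enc, X, train_mode = FALSE) {
  Z1 <- X %*% enc$l1$W
  Z1 <- sweep(Z1, 2, enc$l1$b, "+")
  A1 <- pmax(Z1, 0)
  mask <- NULL
  if (train_mode && enc$dropout_rate > 0) {
    p <- enc$dropout_rate
    mask <- matrix(stats::rbinom(length(A1), 1L, 1 - p) / (1 - p),
                   nrow(A1), ncol(A1))
    A1 <- A1 * mask
  }
  Z2 <- A1 %*% enc$l2$W
  Z2 <- sweep(Z2, 2, enc$l2$b, "+")
  H <- pmax(Z2, 0)
  list(H = H, X = X, Z1 = Z1, A1 = A1, Z2 = Z2, mask = mask)
}

enc_backward <- function(enc, cache, dH) {
  dZ2 <- dH * (cache$Z2 > 0)
  gW2 <- crossprod(cache$A1, dZ2)
  gb2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(enc$l2$W)
  if (!is.null(cache$mask)) dA1 <- dA1 * cache$mask
  dZ1 <- dA1 * (cache$Z1 > 0)
  gW1 <- crossprod(cache$X, dZ1)
  gb1 <- colSums(dZ1)
  list(l1 = list(W = gW1, b = gb1), l2 = list(W = gW2, b = gb2))
}

mlp2_forward <- function(p1, p2, X) {
  Z1 <- sweep(X %*% p1$W, 2, p1$b, "+")
  A1 <- pmax(Z1, 0)
  Out <- sweep(A1 %*% p2$W, 2, p2$b, "+")  # linear output layer
  list(Out = Out, X = X, Z1 = Z1, A1 = A1)
}

mlp2_backward <- function(p1, p2, cache, dOut) {
  gW2 <- crossprod(cache$A1, dOut)
  gb2 <- colSums(dOut)
  dA1 <- dOut %*% t(p2$W)
  dZ1 <- dA1 * (cache$Z1 > 0)
  gW1 <- crossprod(cache$X, dZ1)
  gb1 <- colSums(dZ1)
  list(g1 = list(W = gW1, b = gb1), g2 = list(W = gW2, b = gb2),
       dX = dZ1 %*% t(p1$W))
}

# Relation scores for a block of queries against per-class support
# embeddings. Hq: Q x d; Hs: list of two matrices (class 0, class 1),
# K_c x d each. Returns R (Q x 2) plus caches for backward.
relation_forward <- function(rel, Hq, Hs) {
  Q <- nrow(Hq)
  caches <- vector("list", 2L)
  R <- matrix(NA_real_, Q, 2L)
  for (c in 1:2) {
    K <- nrow(Hs[[c]])
    qi <- rep(seq_len(Q), each = K)
    si <- rep(seq_len(K), times = Q)
    M <- Hq[qi, , drop = FALSE] * Hs[[c]][si, , drop = FALSE]
    phi <- mlp2_forward(rel$phi1, rel$phi2, M)
    G <- rowsum(phi$Out, group = qi)
    if (rel$aggregation == "mean") G <- G / K
    rho <- mlp2_forward(rel$rho1, rel$rho2, G)
    R[, c] <- rho$Out[, 1L]
    caches[[c]] <- list(qi = qi, si = si, K = K, phi = phi, rho = rho)
  }
  list(R = R, caches = caches)
}

relation_backward <- function(rel, Hq, Hs, fwd, dR) {
  zero_like <- function(l) list(W = l$W * 0, b = l$b * 0)
  g <- list(phi1 = zero_like(rel$phi1), phi2 = zero_like(rel$phi2),
            rho1 = zero_like(rel$rho1), rho2 = zero_like(rel$rho2))
  dHq <- Hq * 0
  dHs <- lapply(Hs, function(m) m * 0)
  add <- function(a, b) list(W = a$W + b$W, b = a$b + b$b)
  for (c in 1:2) {
    cc <- fwd$caches[[c]]
    drho <- mlp2_backward(rel$rho1, rel$rho2, cc$rho,
                          matrix(dR[, c], ncol = 1L))
    g$rho1 <- add(g$rho1, drho$g1); g$rho2 <- add(g$rho2, drho$g2)
    dG <- drho$dX
    if (rel$aggregation == "mean") dG <- dG / cc$K
    dPhiOut <- dG[cc$qi, , drop = FALSE]
    dphi <- mlp2_backward(rel$phi1, rel$phi2, cc$phi, dPhiOut)
    g$phi1 <- add(g$phi1, dphi$g1); g$phi2 <- add(g$phi2, dphi$g2)
    dM <- dphi$dX
    dHq <- dHq + rowsum(dM * Hs[[c]][cc$si, , drop = FALSE], group = cc$qi)
    dHs[[c]] <- dHs[[c]] + rowsum(dM * Hq[cc$qi, , drop = FALSE], group = cc$si)
  }
  list(grads = g, dHq = dHq, dHs = dHs)
}

# ---- exported eval-mode operations ----

#' Encode gated latent activities into the embedding space
#'
#' Runs the shared two-branch encoder in evaluation mode (deterministic)
#' or training mode (dropout mask drawn from the current RNG stream).
#'
#' @param activities A length-L numeric vector, or an L-by-n matrix with
#'   one sample per column (as stored in a `"latent_activity"`).
#' @param params An `"encoder_params"` object.
#' @param train_mode Logical; draw a dropout mask if `TRUE`.
#' @return A length-d vector (vector input) or n-by-d matrix of
#'   embeddings.
#' @export
encode <- function(activities, params, train_mode = FALSE) {
  stopifnot(inherits(params, "encoder_params"))
  vec <- is.null(dim(activities))
  X <- if (vec) matrix(activities, nrow = 1L) else t(activities)
  if (ncol(X) != params$input_dim)
    stop(sprintf("encoder expects %d latent inputs, got %d",
                 params$input_dim, ncol(X)))
  H <- enc_forward(params, X, train_mode = train_mode)$H
  if (vec) H[1L, ] else H
}

#' Hadamard similarity between two embeddings
#'
#' The element-wise product \eqn{m_{q,s} = h_q \odot h_s}: a
#' d-dimensional similarity vector capturing pairwise feature
#' interactions between a query and a support embedding. Symmetric in
#' its arguments.
#'
#' @param h_q,h_s Numeric vectors of equal length.
#' @return Numeric vector of the same length.
#' @export
hadamard_similarity <- function(h_q, h_s) {
  if (length(h_q) != length(h_s))
    stop("embedding lengths differ: ", length(h_q), " vs ", length(h_s))
  h_q * h_s
}

#' Relation scores of a query against per-class support sets
#'
#' Computes \eqn{r_{q,c} = \rho_\psi(\mathrm{agg}_{s \in S_c}
#' \phi(h_q \odot h_s))} for \eqn{c \in \{0, 1\}}. Because the
#' aggregation is a symmetric set function, the result is invariant to
#' any reordering of each class's support list.
#'
#' @param h_q Query embedding (length-d vector).
#' @param support List of two elements (class 0, class 1), each either a
#'   K-by-d matrix of support embeddings or a list of length-d vectors;
#'   both classes must be non-empty.
#' The support sets are summed in a canonical (lexicographic) element
#' order, so the returned scores are bit-identical — not merely equal to
#' rounding — under any permutation of each support list.
#'
#' @param params A `"relation_params"` object.
#' @return Named numeric vector `c(r0, r1)`.
#' @export
relation_scores <- function(h_q, support, params) {
  stopifnot(inherits(params, "relation_params"), length(support) == 2L)
  Hs <- lapply(support, function(s) {
    if (is.list(s)) s <- do.call(rbind, s)
    if (is.null(dim(s))) s <- matrix(s, nrow = 1L)
    if (nrow(s) > 1L) {
      ord <- do.call(order, as.data.frame(s))
      s <- s[ord, , drop = FALSE]
    }
    s
  })
  if (any(vapply(Hs, nrow, 1L) == 0L))
    stop("empty support set for one class: relation score undefined")
  fwd <- relation_forward(params, matrix(h_q, nrow = 1L), Hs)
  stats::setNames(fwd$R[1L, ], c("r0", "r1"))
}

# ---- parameter flattening & Adam (shared by the trainer) ----

param_blocks <- function(enc, rel) {
  list(enc_l1 = enc$l1, enc_l2 = enc$l2,
       phi1 = rel$phi1, phi2 = rel$phi2,
       rho1 = rel$rho1, rho2 = rel$rho2)
}

flatten_blocks <- function(blocks) {
  unlist(lapply(blocks, function(l) c(as.numeric(l$W), as.numeric(l$b))),
         use.names = FALSE)
}

# mask = 1 for weight-matrix entries, 0 for biases (L2 decay skips biases)
decay_mask <- function(blocks) {
  unlist(lapply(blocks, function(l)
    c(rep(1, length(l$W)), rep(0, length(l$b)))), use.names = FALSE)
}

unflatten_into <- function(vec, enc, rel) {
  blocks <- param_blocks(enc, rel)
  pos <- 0L
  out <- lapply(blocks, function(l) {
    nw <- length(l$W); nb <- length(l$b)
    W <- matrix(vec[pos + seq_len(nw)], nrow(l$W), ncol(l$W))
    b <- vec[pos + nw + seq_len(nb)]
    pos <<- pos + nw + nb
    list(W = W, b = b)
  })
  enc$l1 <- out$enc_l1; enc$l2 <- out$enc_l2
  rel$phi1 <- out$phi1; rel$phi2 <- out$phi2
  rel$rho1 <- out$rho1; rel$rho2 <- out$rho2
  list(enc = enc, rel = rel)
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, theta, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}
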