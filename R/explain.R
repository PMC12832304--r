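## Shapley attribution of the raw diagnostic score over the gated latent
## inputs, and its aggregation into an additive 0-100 point gene-level
## scorecard (a nomogram-style chart for the few-shot model).

# Batched evaluation of s(x) = r1 - r0 on gated latent vectors (columns of
# `states`), against the model's stored reference in full-set mode.
score_fn <- function(model, ref_emb, i0, i1) {
  rel <- model$relation; enc <- model$encoder
  Hs <- list(ref_emb[i0, , drop = FALSE], ref_emb[i1, , drop = FALSE])
  function(states) {
    Hq <- enc_forward(enc, t(states))$H
    R <- relation_forward(rel, Hq, Hs)$R
    R[, 2L] - R[, 1L]
  }
}

#' Shapley attribution of the diagnostic score over latent variables
#'
#' Estimates Shapley values of each gated latent input to the raw score
#' \eqn{s(x)} by complete permutations: for each sampled feature
#' ordering, latent variables are switched one at a time from the
#' background mean to the sample's value and the marginal change in
#' \eqn{s} is credited to the switched variable. Orderings are drawn
#' antithetically (each permutation together with its reverse). Because
#' every permutation telescopes from \eqn{s(\bar b)} to \eqn{s(b)}, the
#' efficiency identity \eqn{base + \sum_\ell \phi_\ell = s(b)} holds
#' exactly, not just in expectation.
#'
#' @param model A `"fewshot_model"`; the explained function is its raw
#'   score against the stored reference support (full-set, evaluation
#'   mode, hence deterministic).
#' @param sample Gated latent vector (length L) to explain.
#' @param background Gated latent matrix (L x n, one sample per column)
#'   whose row means replace "absent" features.
#' @param n_permutations Number of permutations (rounded up to even for
#'   antithetic pairing).
#' @param seed Seed for the permutation draws.
#' @return List: `attributions` (named per-LV vector), `base`
#'   (score at the background mean), `prediction` (s at the sample).
#' @export
shap_attribution <- function(model, sample, background,
                             n_permutations = 128L, seed = 1L) {
  stopifnot(inherits(model, "fewshot_model"))
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  if (is.null(dim(background)) || ncol(background) < 1L)
    stop("background must be a non-empty L x n matrix")
  L <- length(sample)
  stopifnot(nrow(background) == L)
  ref_emb <- enc_forward(model$encoder, t(model$reference$activities))$H
  i0 <- which(model$reference$labels == 0)
  i1 <- which(model$reference$labels == 1)
  s_of <- score_fn(model, ref_emb, i0, i1)
  bg <- rowMeans(background)
  base <- s_of(matrix(bg, ncol = 1L))
  pred <- s_of(matrix(sample, ncol = 1L))

  set.seed(seed)
  n_perm <- as.integer(2L * ceiling(n_permutations / 2L))
  perms <- vector("list", n_perm)
  for (i in seq_len(n_perm / 2L)) {
    p <- sample.int(L)
    perms[[2L * i - 1L]] <- p
    perms[[2L * i]] <- rev(p)
  }
  phi <- numeric(L)
  for (p in perms) {
    # states[, k+1] = background with the first k features of the ordering
    # switched to the sample's values; the background itself is evaluated
    # inside the same batch so that a switch of an inert feature yields a
    # marginal contribution of exactly zero
    states <- matrix(bg, L, L + 1L)
    for (k in seq_len(L))
      states[p[seq_len(k)], k + 1L] <- sample[p[seq_len(k)]]
    v <- s_of(states)
    phi[p] <- phi[p] + diff(v)
  }
  phi <- phi / n_perm
  names(phi) <- rownames(background) %||% model$gate$lv_ids
  list(attributions = phi, base = base, prediction = pred)
}

#' Aggregate latent attributions into an additive gene scorecard
#'
#' Each latent variable's attribution is shared among the hub genes in
#' proportion to their absolute prior loadings on that variable,
#' \eqn{|Z_{g\ell}| / \sum_{g' \in hub} |Z_{g'\ell}|}; latent variables
#' carrying no hub-gene loading are pooled into an `"other"` term, so
#' the additive identity \eqn{base + other + \sum_g c_g = s(x)} is
#' preserved. Gene contributions are on the log-odds scale of
#' \eqn{s(x)}.
#'
#' The point scale maps the anchor cohort's range of summed positive
#' contributions linearly onto 0-100: the anchor sample with the largest
#' positive total scores 100 points, the smallest 0. New samples outside
#' that range are clipped and flagged.
#'
#' @param attributions Per-LV attribution matrix (LVs x samples) or a
#'   single named vector; typically one [shap_attribution()] result per
#'   column. The first call's cohort anchors the point scale.
#' @param base Numeric base value(s) from [shap_attribution()].
#' @param loadings Genes-by-LVs prior matrix.
#' @param gate The model's `"gate_vector"` (supplies the hub set and LV
#'   order).
#' @param hub_genes Hub genes to score; defaults to the gate's hub set.
#' @return A `"scorecard"`: `contributions` ((genes, other) x samples),
#'   `base`, `gene_points`, `total_points`, `scale`, `offset`,
#'   `clipped`, `hub_genes`.
#' @export
gene_scorecard <- function(attributions, base, loadings, gate,
                           hub_genes = gate$hub_genes) {
  if (is.null(dim(attributions)))
    attributions <- matrix(attributions, ncol = 1L,
                           dimnames = list(names(attributions), NULL))
  if (!identical(rownames(attributions), colnames(loadings)))
    stop("attribution LV ids do not match the loading matrix columns")
  missing <- setdiff(hub_genes, rownames(loadings))
  if (length(missing) > 0L)
    stop("hub gene(s) absent from loading matrix: ",
         paste(missing, collapse = ", "))
  A <- abs(loadings[hub_genes, , drop = FALSE])   # hub x LV
  tot <- colSums(A)
  loaded <- tot > 0
  share <- A
  share[, loaded] <- sweep(A[, loaded, drop = FALSE], 2, tot[loaded], "/")
  share[, !loaded] <- 0
  contrib <- share %*% attributions                # hub x samples
  other <- colSums(attributions[!loaded, , drop = FALSE])
  contributions <- rbind(contrib, other = other)
  s_x <- base + colSums(attributions)

  pos_total <- colSums(pmax(contrib, 0))
  lo <- min(pos_total); hi <- max(pos_total)
  scale <- if (hi > lo) 100 / (hi - lo) else 0
  raw_points <- (pos_total - lo) * scale
  clipped <- raw_points < 0 | raw_points > 100
  total_points <- pmin(pmax(raw_points, 0), 100)
  gene_points <- pmax(contrib, 0) * scale
  structure(list(contributions = contributions, base = base,
                 prediction = s_x,
                 gene_points = gene_points, total_points = total_points,
                 scale = scale, offset = lo, clipped = clipped,
                 hub_genes = hub_genes),
            class = "scorecard")
}

#' Points for a new sample on an existing scorecard scale
#'
#' Applies a fitted scorecard's anchor scale to new per-gene
#' contributions; out-of-range totals clip to \[0, 100\] with a flag.
#'
#' @param card A `"scorecard"`.
#' @param contributions Hub-gene contribution matrix (genes x samples)
#'   on the log-odds scale.
#' @return List with `total_points` and `clipped`.
#' @export
scorecard_points <- function(card, contributions) {
  pos_total <- colSums(pmax(contributions[card$hub_genes, , drop = FALSE], 0))
  raw <- (pos_total - card$offset) * card$scale
  list(total_points = pmin(pmax(raw, 0), 100),
       clipped = raw < 0 | raw > 100)
}
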