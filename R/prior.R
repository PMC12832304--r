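#' Project expression onto a fixed latent prior by ridge regression
#'
#' Given a gene-aligned expression matrix \eqn{X} (genes x samples) and a
#' frozen loading matrix \eqn{Z} (genes x LVs), estimates latent-variable
#' activities \eqn{B} (LVs x samples) as the ridge solution
#' \deqn{B = (Z^\top Z + \lambda I)^{-1} Z^\top X.}
#' The loading matrix is treated as read-only: it carries the biological
#' alignment of the latent space and is never updated from the data.
#'
#' @param expression Genes-by-samples numeric matrix, rows matching
#'   `loadings` exactly (use [align_to_prior()] first).
#' @param loadings Genes-by-LVs numeric matrix.
#' @param lambda Ridge penalty \eqn{\lambda \ge 0}; default 1. At
#'   `lambda = 0` the Gram matrix must be non-singular.
#' @return A `"latent_activity"` object: list with `activities`
#'   (LVs x samples matrix) and `gated = FALSE`.
#' @export
project_to_latent <- function(expression, loadings, lambda = 1) {
  stopifnot(is.matrix(expression), is.matrix(loadings), lambda >= 0)
  if (!identical(rownames(expression), rownames(loadings)))
    stop("expression and loadings are not gene-aligned; run align_to_prior()")
  L <- ncol(loadings)
  gram <- crossprod(loadings) + diag(lambda, L)
  rhs <- crossprod(loadings, expression)
  B <- tryCatch(solve(gram, rhs), error = function(e)
    stop("normal equations singular (Z'Z + lambda*I not invertible); ",
         "use lambda > 0", call. = FALSE))
  dimnames(B) <- list(colnames(loadings), colnames(expression))
  structure(list(activities = B, gated = FALSE), class = "latent_activity")
}

#' @export
print.latent_activity <- function(x, ...) {
  cat(sprintf("latent_activity: %d LVs x %d samples (%s)\n",
              nrow(x$activities), ncol(x$activities),
              if (x$gated) "gated" else "ungated"))
  invisible(x)
}

#' Hub-gene channel gate over latent variables
#'
#' Computes a per-LV weight from the prior's loadings of a hub-gene set
#' \eqn{G^{*\prime}}: the raw weight of LV \eqn{\ell} is the mean
#' absolute loading \eqn{\alpha_\ell = |G^{*\prime}|^{-1}
#' \sum_{g \in G^{*\prime}} |Z_{g\ell}|}, normalized either to a maximum
#' of 1 (`"max"`, the default) or onto the simplex (`"l1"`). The gate
#' prioritizes latent channels heavily loaded by the hub genes while
#' retaining the full prior space. It depends only on the prior and the
#' hub set, so it is computed once and stored with a trained model,
#' never re-derived from data at inference time.
#'
#' @param loadings Genes-by-LVs matrix.
#' @param hub_genes Character vector of hub gene symbols; every symbol
#'   must be present in `rownames(loadings)`. Order and duplicates are
#'   irrelevant (the set is used).
#' @param norm_mode `"max"` or `"l1"`.
#' @return A `"gate_vector"` object: `lv_ids`, `raw` (alpha),
#'   `weights` (normalized alpha-hat), `norm_mode`, `hub_genes`.
#' @export
compute_gate <- function(loadings, hub_genes, norm_mode = c("max", "l1")) {
  norm_mode <- match.arg(norm_mode)
  hub_genes <- unique(hub_genes)
  if (length(hub_genes) == 0L) stop("hub gene set is empty")
  missing <- setdiff(hub_genes, rownames(loadings))
  if (length(missing) > 0L)
    stop("hub gene(s) absent from loading matrix: ",
         paste(missing, collapse = ", "))
  sub <- abs(loadings[hub_genes, , drop = FALSE])
  alpha <- colMeans(sub)
  if (all(alpha == 0))
    stop("all gate weights are zero: hub genes have no loading on any LV")
  weights <- switch(norm_mode,
                    max = alpha / max(alpha),
                    l1  = alpha / sum(alpha))
  structure(list(lv_ids = colnames(loadings), raw = alpha,
                 weights = weights, norm_mode = norm_mode,
                 hub_genes = sort(hub_genes)),
            class = "gate_vector")
}

#' @export
print.gate_vector <- function(x, ...) {
  cat(sprintf("gate_vector: %d LVs, norm = %s, hub genes: %s\n",
              length(x$weights), x$norm_mode,
              paste(x$hub_genes, collapse = ", ")))
  invisible(x)
}

#' Apply a channel gate to latent activities
#'
#' Scales each LV row of the activity matrix by its normalized gate
#' weight: \eqn{\tilde B = \mathrm{diag}(\hat\alpha) B}.
#'
#' @param activity A `"latent_activity"` object.
#' @param gate A `"gate_vector"` whose `lv_ids` match the activity rows.
#' @return Gated `"latent_activity"` (`gated = TRUE`).
#' @export
apply_gate <- function(activity, gate) {
  stopifnot(inherits(activity, "latent_activity"),
            inherits(gate, "gate_vector"))
  if (!identical(rownames(activity$activities), gate$lv_ids))
    stop("latent-variable ids of activity and gate do not match")
  structure(list(activities = activity$activities * gate$weights,
                 gated = TRUE),
            class = "latent_activity")
}
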