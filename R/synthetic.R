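#' Configuration for the synthetic two-class cohort generator
#'
#' The generator emulates the statistical structure the diagnostic
#' method assumes: a sparse non-negative pathway-style loading matrix, a
#' two-class log2 expression cohort whose class signal flows through a
#' small set of disease-associated latent variables, and a hub-gene set
#' defined as the top-loading genes of those variables (four genes,
#' mirroring the size of a typical validated biomarker panel). Defaults
#' describe a clearly separable benchmark cohort: 1000 genes, 50 latent
#' variables of 20 genes each, 40 samples per class, a latent-mean shift
#' of 1.5 noise-SD units on 5 disease LVs, unit gene-level noise.
#'
#' @param n_genes,n_lvs Genome and latent-space size.
#' @param genes_per_lv Genes loaded by each LV (plus a small overlap
#'   with the next block).
#' @param n_per_class Samples per class.
#' @param effect_size Class-mean shift on the disease LVs, in units of
#'   the latent activity SD.
#' @param n_disease_lvs Number of LVs carrying the class signal.
#' @param noise_sd Gene-level Gaussian noise SD.
#' @param n_hub_genes Size of the designated hub set.
#' @param overlap Genes shared between adjacent LV blocks.
#' @param seed Seed; generation is fully determined by it.
#' @return A `"synthetic_config"` list.
#' @export
synthetic_config <- function(n_genes = 1000L, n_lvs = 50L,
                             genes_per_lv = 20L, n_per_class = 40L,
                             effect_size = 1.5, n_disease_lvs = min(5L, n_lvs),
                             noise_sd = 1, n_hub_genes = 4L,
                             overlap = 2L, seed = 1L) {
  stopifnot(n_genes >= 1, n_lvs >= 1, genes_per_lv >= 1, n_per_class >= 1,
            effect_size >= 0, noise_sd > 0, n_hub_genes >= 1, overlap >= 0,
            n_disease_lvs <= n_lvs)
  if (n_genes < n_lvs * genes_per_lv)
    stop(sprintf("infeasible block layout: %d genes cannot host %d LVs of %d genes",
                 n_genes, n_lvs, genes_per_lv))
  structure(list(n_genes = as.integer(n_genes), n_lvs = as.integer(n_lvs),
                 genes_per_lv = as.integer(genes_per_lv),
                 n_per_class = as.integer(n_per_class),
                 effect_size = effect_size,
                 n_disease_lvs = as.integer(n_disease_lvs),
                 noise_sd = noise_sd, n_hub_genes = as.integer(n_hub_genes),
                 overlap = as.integer(overlap), seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a block-sparse non-negative loading matrix
#'
#' Each latent variable loads a contiguous block of `genes_per_lv`
#' genes plus the first `overlap` genes of the next block (the last
#' block wraps around), with magnitudes \eqn{|N(0,1)|} rescaled to mean
#' 0.5. Deterministic given the config seed.
#'
#' @param config A [synthetic_config()].
#' @return Genes-by-LVs matrix with symbolic gene and LV names.
#' @export
make_loading_matrix <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  G <- config$n_genes; L <- config$n_lvs; gpl <- config$genes_per_lv
  genes <- sprintf("G%04d", seq_len(G))
  lvs <- sprintf("LV%03d", seq_len(L))
  Z <- matrix(0, G, L, dimnames = list(genes, lvs))
  scale <- 0.5 / sqrt(2 / pi)     # |N(0,1)| has mean sqrt(2/pi)
  for (l in seq_len(L)) {
    block <- (l - 1L) * gpl + seq_len(gpl)
    if (config$overlap > 0L) {
      nxt <- (l %% L) * gpl + seq_len(config$overlap)
      nxt <- ((nxt - 1L) %% G) + 1L
      block <- unique(c(block, nxt))
    }
    Z[block, l] <- abs(stats::rnorm(length(block))) * scale
  }
  Z
}

#' Generate a synthetic two-class expression cohort
#'
#' Latent activities are standard Gaussian per sample; on the designated
#' disease LVs (the first `n_disease_lvs`), case samples receive a mean
#' shift of `effect_size`. Expression is the loading-matrix image of the
#' activities plus i.i.d. Gaussian gene-level noise:
#' \eqn{X = Z B + \epsilon}. Hub genes are the `n_hub_genes` genes with
#' the largest total absolute loading on the disease LVs. Labels are
#' balanced; everything is determined by the config seed.
#'
#' @param config A [synthetic_config()].
#' @return A `"synthetic_dataset"`: `expression` (genes x samples),
#'   `labels` (named 0/1), `loadings`, `true_activities`,
#'   `true_hub_genes`, `true_disease_lvs`, `config`.
#' @export
make_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  Z <- make_loading_matrix(config)    # seeds the stream, then we continue
  G <- config$n_genes; L <- config$n_lvs
  N <- 2L * config$n_per_class
  labels <- rep(0:1, each = config$n_per_class)
  samples <- sprintf("S%03d", seq_len(N))
  names(labels) <- samples
  B <- matrix(stats::rnorm(L * N), L, N, dimnames = list(colnames(Z), samples))
  disease <- colnames(Z)[seq_len(config$n_disease_lvs)]
  B[disease, labels == 1] <- B[disease, labels == 1] + config$effect_size
  X <- Z %*% B + matrix(stats::rnorm(G * N, sd = config$noise_sd), G, N)
  dimnames(X) <- list(rownames(Z), samples)
  hub_score <- rowSums(abs(Z[, disease, drop = FALSE]))
  hubs <- names(sort(hub_score, decreasing = TRUE))[seq_len(config$n_hub_genes)]
  structure(list(expression = X, labels = labels, loadings = Z,
                 true_activities = B, true_hub_genes = hubs,
                 true_disease_lvs = disease, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("synthetic_dataset: %d genes x %d samples, %d LVs ",
                     "(%d disease), effect %.2g, seed %d\n"),
              nrow(x$expression), ncol(x$expression), ncol(x$loadings),
              length(x$true_disease_lvs), x$config$effect_size,
              x$config$seed))
  invisible(x)
}
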