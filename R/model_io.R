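## Model archive: a single JSON file holding all weight tensors as named
## arrays plus metadata and a schema-version string. Text-based and
## byte-layout free; numbers are written at full precision so a
## save/load round trip reproduces predictions exactly.

mat2l <- function(m) list(dim = dim(m), rownames = rownames(m),
                          colnames = colnames(m), data = as.numeric(m))

l2mat <- function(l) {
  m <- matrix(as.numeric(l$data), l$dim[1L], l$dim[2L])
  rn <- if (length(l$rownames)) as.character(l$rownames) else NULL
  cn <- if (length(l$colnames)) as.character(l$colnames) else NULL
  dimnames(m) <- list(rn, cn)
  m
}

layer2l <- function(l) list(W = mat2l(l$W), b = as.numeric(l$b))
l2layer <- function(l) list(W = l2mat(l$W), b = as.numeric(l$b))

#' Save a trained few-shot model to a JSON archive
#'
#' @param model A `"fewshot_model"` from [fewshot_train()].
#' @param path Output path (conventionally `.json`).
#' @export
write_fewshot_model <- function(model, path) {
  stopifnot(inherits(model, "fewshot_model"))
  enc <- model$encoder; rel <- model$relation
  obj <- list(
    schema = model$schema,
    config = unclass(model$config),
    lambda = model$lambda,
    encoder = list(input_dim = enc$input_dim, hidden_dims = enc$hidden_dims,
                   dropout_rate = enc$dropout_rate,
                   l1 = layer2l(enc$l1), l2 = layer2l(enc$l2)),
    relation = list(d = rel$d, aggregation = rel$aggregation,
                    phi1 = layer2l(rel$phi1), phi2 = layer2l(rel$phi2),
                    rho1 = layer2l(rel$rho1), rho2 = layer2l(rel$rho2)),
    gate = list(lv_ids = model$gate$lv_ids,
                raw = as.numeric(model$gate$raw),
                weights = as.numeric(model$gate$weights),
                norm_mode = model$gate$norm_mode,
                hub_genes = model$gate$hub_genes),
    standardization = list(genes = names(model$standardization$mean),
                           mean = as.numeric(model$standardization$mean),
                           sd = as.numeric(model$standardization$sd),
                           dropped = model$standardization$dropped),
    loadings = mat2l(model$loadings),
    reference = list(activities = mat2l(model$reference$activities),
                     labels = model$reference$labels,
                     sample_ids = model$reference$sample_ids),
    log = as.list(model$log),
    best_checkpoint = model$best_checkpoint,
    best_val_auc = model$best_val_auc)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a few-shot model saved by [write_fewshot_model()]
#'
#' @param path Path to the JSON archive.
#' @return A `"fewshot_model"`.
#' @export
read_fewshot_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "fewshotDx-model/1"))
    stop("unrecognized model schema: ", obj$schema)
  cfg <- obj$config
  config <- train_config(k_shot = cfg$k_shot,
                         queries_per_class = cfg$queries_per_class,
                         max_episodes = cfg$max_episodes,
                         temperature = cfg$temperature,
                         learning_rate = cfg$learning_rate,
                         weight_decay = cfg$weight_decay,
                         dropout = cfg$dropout, eval_every = cfg$eval_every,
                         patience = cfg$patience,
                         aggregation = cfg$aggregation,
                         norm_mode = cfg$norm_mode, lambda = cfg$lambda,
                         val_fraction = cfg$val_fraction,
                         ensemble_draws = cfg$ensemble_draws,
                         seed = cfg$seed)
  enc <- structure(list(input_dim = as.integer(obj$encoder$input_dim),
                        hidden_dims = as.integer(obj$encoder$hidden_dims),
                        dropout_rate = obj$encoder$dropout_rate,
                        l1 = l2layer(obj$encoder$l1),
                        l2 = l2layer(obj$encoder$l2)),
                   class = "encoder_params")
  rel <- structure(list(d = as.integer(obj$relation$d),
                        aggregation = obj$relation$aggregation,
                        phi1 = l2layer(obj$relation$phi1),
                        phi2 = l2layer(obj$relation$phi2),
                        rho1 = l2layer(obj$relation$rho1),
                        rho2 = l2layer(obj$relation$rho2)),
                   class = "relation_params")
  gate <- structure(list(lv_ids = obj$gate$lv_ids,
                         raw = stats::setNames(obj$gate$raw, obj$gate$lv_ids),
                         weights = stats::setNames(obj$gate$weights,
                                                   obj$gate$lv_ids),
                         norm_mode = obj$gate$norm_mode,
                         hub_genes = obj$gate$hub_genes),
                    class = "gate_vector")
  std <- structure(list(mean = stats::setNames(obj$standardization$mean,
                                               obj$standardization$genes),
                        sd = stats::setNames(obj$standardization$sd,
                                             obj$standardization$genes),
                        dropped = as.character(obj$standardization$dropped %||% character(0))),
                   class = "standardization")
  structure(list(encoder = enc, relation = rel, gate = gate,
                 standardization = std, loadings = l2mat(obj$loadings),
                 lambda = obj$lambda,
                 reference = list(activities = l2mat(obj$reference$activities),
                                  labels = as.integer(obj$reference$labels),
                                  sample_ids = obj$reference$sample_ids),
                 log = as.data.frame(obj$log),
                 best_checkpoint = obj$best_checkpoint,
                 best_val_auc = obj$best_val_auc,
                 config = config, schema = obj$schema),
            class = "fewshot_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
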