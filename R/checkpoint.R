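#' Save and restore a fitted model as plain text
#'
#' Serializes a `cegcn_fit` to a single JSON file: every parameter matrix
#' (with its shape), the configuration, the split, the feature vocabulary
#' and the training curve. `load_cegcn()` reconstructs a fit that scores and
#' evaluates identically.
#'
#' @param fit A `cegcn_fit`.
#' @param path Path of the JSON checkpoint.
#' @return `save_cegcn()` returns `path` invisibly; `load_cegcn()` a
#'   `cegcn_fit`.
#' @export
save_cegcn <- function(fit, path) {
  obj <- list(
    params = lapply(fit$params, function(m) list(dim = dim(m),
                                                 data = as.vector(m))),
    config = unclass(fit$config),
    mode = fit$mode,
    split = unclass(fit$split),
    vocab_values = fit$vocab$values,
    vocab_ages = fit$vocab_ages,
    train_t = fit$train_t,
    best_epoch = fit$best_epoch,
    loss_curve = fit$loss_curve,
    catalog = list(disease_id = fit$catalog$disease_id,
                   name = fit$catalog$name)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_cegcn
#' @export
load_cegcn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(p) {
    matrix(p$data, p$dim[1], p$dim[2])
  })
  config <- do.call(cegcn_config, obj$config[c("hidden", "mlp_hidden",
                                               "pos_weight", "neg_ratio", "lr",
                                               "epochs", "patience", "evolve",
                                               "seed")])
  split <- structure(obj$split, class = "split_spec")
  split$train_ages <- as.integer(split$train_ages)
  split$val_ages <- as.integer(split$val_ages)
  split$test_ages <- as.integer(split$test_ages)
  structure(
    list(params = params, config = config, mode = obj$mode, split = split,
         vocab = build_vocabulary(list(as.integer(obj$vocab_values))),
         vocab_ages = as.integer(obj$vocab_ages),
         train_t = as.integer(obj$train_t),
         loss_curve = tibble::as_tibble(obj$loss_curve),
         best_epoch = obj$best_epoch,
         catalog = disease_catalog(tibble::tibble(
           disease_id = obj$catalog$disease_id, name = obj$catalog$name))),
    class = "cegcn_fit"
  )
}
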