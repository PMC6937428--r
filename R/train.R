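#' Training configuration
#'
#' Defaults follow the standard recipe for this model family: Adam with
#' beta1 = 0.9 and beta2 = 0.99, batch size 1024, 100 epochs, one corrupted
#' negative per positive resampled every epoch, learning rate tuned over
#' \{0.001, 0.005, 0.01\} on validation mean squared error, and early
#' stopping with patience 5 (validation evaluated each epoch, best model
#' returned). The reference dimensionality for literature-scale graphs is
#' d = 128; desk-scale runs use smaller d.
#'
#' @param d embedding dimension.
#' @param epochs,batch_size training schedule.
#' @param learning_rate Adam step size.
#' @param lr_grid candidate learning rates for [tune_learning_rate()].
#' @param adam_beta1,adam_beta2 Adam decay rates.
#' @param negatives_per_positive corrupted triples per positive per epoch.
#' @param early_stop_patience evaluations without validation improvement
#'   tolerated before stopping.
#' @param resample_negatives if `FALSE`, negatives are drawn once and
#'   reused every epoch.
#' @param type_constrained_corruption corrupt tails within the original
#'   tail's entity type.
#' @param filter_collisions drop corrupted triples that coincide with an
#'   observed positive pair+theme.
#' @param val_include_negatives include freshly sampled negatives in the
#'   validation mean squared error (default: positives only).
#' @param leaky_gradient keep a full-slope gradient for clamped
#'   predictions whose target lies inside the bounds, so examples never
#'   die at the rectifier's kinks (the objective is unchanged; this only
#'   alters the search direction at clamped points).
#' @param seed integer seed controlling initialisation, batching and
#'   negative sampling.
#' @export
train_config <- function(d = 128L, epochs = 100L, batch_size = 1024L,
                         learning_rate = 0.01,
                         lr_grid = c(0.001, 0.005, 0.01),
                         adam_beta1 = 0.9, adam_beta2 = 0.99,
                         negatives_per_positive = 1L,
                         early_stop_patience = 5L,
                         resample_negatives = TRUE,
                         type_constrained_corruption = FALSE,
                         filter_collisions = FALSE,
                         val_include_negatives = FALSE,
                         leaky_gradient = TRUE,
                         seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(d >= 1, epochs >= 1, batch_size >= 1, learning_rate > 0,
            length(lr_grid) >= 1, adam_beta1 > 0, adam_beta1 < 1,
            adam_beta2 > 0, adam_beta2 < 1, negatives_per_positive >= 1,
            early_stop_patience >= 1)
  structure(cfg, class = "train_config")
}

validation_mse <- function(model, triples) {
  if (!nrow(triples)) return(NA_real_)
  f <- train_confidence(model, triples$head, triples$theme, triples$tail)
  mean((f - triples$support)^2)
}

#' Train the embedding model
#'
#' Minibatch Adam on the squared-error objective: each epoch the training
#' triples are shuffled, each positive gets freshly corrupted negative
#' tails with target support 0, and parameters (entity vectors, relation
#' vectors, and the global rectifier scalars w, b) are updated per batch.
#' Validation mean squared error (training-mode confidence on the
#' held-out positives) is evaluated each epoch; training stops at the
#' epoch limit or once validation fails to improve for
#' `early_stop_patience` consecutive evaluations, and the parameters with
#' the best validation error are returned. Deterministic given
#' `config$seed`.
#'
#' @param split a `data_split` from [split_triples()] (uses `train` and
#'   `validation`).
#' @param config a [train_config()].
#' @param entities optional character vector of all entity ids to embed
#'   (defaults to every id appearing in the split); entities beyond the
#'   training triples keep their random initial vectors.
#' @return list with `model` (a [ukge_model()]), `log` (data.frame:
#'   epoch, train_loss, val_mse) and `best_epoch`.
#' @export
ukge_train <- function(split, config = train_config(), entities = NULL) {
  stopifnot(inherits(config, "train_config"))
  train <- split$train
  if (!nrow(train)) stop("empty training set")
  if (is.null(entities))
    entities <- sort(unique(unlist(lapply(
      split[c("train", "validation", "test")],
      function(x) c(x$head, x$tail)))))
  themes <- sort(unique(unlist(lapply(
    split[c("train", "validation", "test")], function(x) x$theme))))

  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(config$seed)
  d <- config$d
  lim <- 0.5 / sqrt(d)
  E <- matrix(stats::runif(length(entities) * d, -lim, lim), ncol = d,
              dimnames = list(entities, NULL))
  R <- matrix(stats::runif(length(themes) * d, -lim, lim), ncol = d,
              dimnames = list(themes, NULL))
  model <- ukge_model(E, R, w = 1, b = 0)

  # dense Adam state
  zero <- list(entities = E * 0, relations = R * 0, w = 0, b = 0)
  m1 <- zero; m2 <- zero; step <- 0L
  b1 <- config$adam_beta1; b2 <- config$adam_beta2
  eps <- 1e-8; lr <- config$learning_rate

  adam_update <- function(grad) {
    step <<- step + 1L
    for (nm in names(zero)) {
      m1[[nm]] <<- b1 * m1[[nm]] + (1 - b1) * grad[[nm]]
      m2[[nm]] <<- b2 * m2[[nm]] + (1 - b2) * grad[[nm]]^2
      mhat <- m1[[nm]] / (1 - b1^step)
      vhat <- m2[[nm]] / (1 - b2^step)
      model[[c(entities = "entities", relations = "relations",
               w = "w", b = "b")[[nm]]]] <<-
        model[[c(entities = "entities", relations = "relations",
                 w = "w", b = "b")[[nm]]]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }

  pos_keys <- paste(pmin(train$head, train$tail), train$theme,
                    pmax(train$head, train$tail))
  ent_types <- attr(split, "entity_types")
  draw_negatives <- function(pos) {
    do.call(rbind, replicate(
      config$negatives_per_positive,
      sample_negative(pos, entities,
                      type_constrained = config$type_constrained_corruption,
                      entity_types = ent_types),
      simplify = FALSE))
  }
  drop_collisions <- function(neg) {
    if (!config$filter_collisions) return(neg)
    k <- paste(pmin(neg$head, neg$tail), neg$theme,
               pmax(neg$head, neg$tail))
    neg[!k %in% pos_keys, , drop = FALSE]
  }
  # fixed negatives stay aligned to training rows; collision filtering is
  # applied per batch so alignment is never broken
  fixed_neg <- if (!config$resample_negatives) draw_negatives(train)

  n <- nrow(train)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_mse = numeric(0))
  best <- list(mse = Inf, model = model, epoch = 0L)
  stall <- 0L

  # epoch-0 validation defines the baseline the returned model must beat
  best$mse <- validation_mse(model, split$validation)
  if (is.na(best$mse)) best$mse <- Inf

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(n)
    epoch_loss <- 0
    starts <- seq(1, n, by = config$batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1, n)]
      pos <- train[idx, , drop = FALSE]
      neg <- if (config$resample_negatives) draw_negatives(pos)
             else fixed_neg[rep(idx, config$negatives_per_positive) +
                              rep((seq_len(config$negatives_per_positive)
                                   - 1) * n, each = length(idx)), ,
                            drop = FALSE]
      neg <- drop_collisions(neg)
      grad <- ukge_gradient(model, pos, neg,
                            leaky = config$leaky_gradient)
      batch_loss <- ukge_loss(model, pos, neg)
      if (!is.finite(batch_loss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      epoch_loss <- epoch_loss + batch_loss
      adam_update(grad)
    }
    vm <- validation_mse(model, split$validation)
    if (config$val_include_negatives && nrow(split$validation)) {
      vneg <- sample_negative(split$validation, entities)
      fv <- train_confidence(model, vneg$head, vneg$theme, vneg$tail)
      vm <- (vm * nrow(split$validation) + sum(fv^2)) /
        (2 * nrow(split$validation))
    }
    log <- rbind(log, data.frame(epoch = epoch, train_loss = epoch_loss,
                                 val_mse = vm))
    if (is.na(vm)) next  # no validation set: run to the epoch limit
    if (vm < best$mse) {
      best <- list(mse = vm, model = model, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$early_stop_patience) break
    }
  }
  out_model <- if (is.finite(best$mse) && best$epoch > 0) best$model
               else model
  list(model = out_model, log = log,
       best_epoch = if (best$epoch > 0) best$epoch else nrow(log))
}

#' Select the learning rate by validation error
#'
#' Trains once per value of `config$lr_grid` and returns the config with
#' `learning_rate` set to the grid value achieving the lowest validation
#' mean squared error; ties (and runs that diverge) resolve toward the
#' smaller rate.
#'
#' @inheritParams ukge_train
#' @param tune_epochs optional reduced epoch budget for the grid runs.
#' @return the winning [train_config()], with attribute `"tuning"` holding
#'   the per-rate validation errors.
#' @export
tune_learning_rate <- function(split, config = train_config(),
                               entities = NULL, tune_epochs = NULL) {
  grid <- sort(config$lr_grid)
  mses <- vapply(grid, function(lr) {
    cfg <- config
    cfg$learning_rate <- lr
    if (!is.null(tune_epochs)) cfg$epochs <- as.integer(tune_epochs)
    fit <- tryCatch(ukge_train(split, cfg, entities),
                    error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    vm <- validation_mse(fit$model, split$validation)
    if (is.na(vm)) Inf else vm
  }, numeric(1))
  if (all(!is.finite(mses))) stop("every learning rate in the grid failed")
  config$learning_rate <- grid[which.min(mses)]  # which.min: first = smallest
  attr(config, "tuning") <- data.frame(learning_rate = grid, val_mse = mses)
  config
}

#' Serialize a trained model to TSV sidecar files
#'
#' Writes `<prefix>_meta.tsv` (d, w, b plus any extra key-values),
#' `<prefix>_entities.tsv` and `<prefix>_relations.tsv` (id then d numeric
#' columns).
#'
#' @param model a [ukge_model()].
#' @param prefix path prefix.
#' @param extra named list of additional metadata (e.g. seed, config).
#' @export
write_ukge_model <- function(model, prefix, extra = list()) {
  meta <- c(list(d = model$d, w = model$w, b = model$b), extra)
  utils::write.table(
    data.frame(key = names(meta),
               value = vapply(meta, function(v)
                 paste(format(v, digits = 17), collapse = ","),
                 character(1))),
    paste0(prefix, "_meta.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wv <- function(m, path) {
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    names(df) <- c("id", paste0("v", seq_len(ncol(m))))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wv(model$entities, paste0(prefix, "_entities.tsv"))
  wv(model$relations, paste0(prefix, "_relations.tsv"))
  invisible(prefix)
}

#' Read a model written by [write_ukge_model()]
#'
#' @param prefix path prefix used at write time.
#' @return a [ukge_model()].
#' @export
read_ukge_model <- function(prefix) {
  meta <- utils::read.delim(paste0(prefix, "_meta.tsv"),
                            colClasses = "character")
  kv <- stats::setNames(meta$value, meta$key)
  rv <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            colClasses = c(id = "character"))
    m <- as.matrix(df[, -1, drop = FALSE])
    dimnames(m) <- list(df$id, NULL)
    m
  }
  ukge_model(rv(paste0(prefix, "_entities.tsv")),
             rv(paste0(prefix, "_relations.tsv")),
             w = as.numeric(kv[["w"]]), b = as.numeric(kv[["b"]]))
}
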