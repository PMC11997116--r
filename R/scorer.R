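#' Architecture of the modification scoring network
#'
#' The scorer is a hybrid network over measurement windows: a stack of
#' 1-d convolutional layers (ReLU, batch normalization between successive
#' convolutions) extracts local kinetic patterns; sinusoidal positional
#' embeddings are added to the convolutional output, which then passes
#' through transformer encoder layers (multi-head scaled dot-product
#' attention, GELU feed-forward) capturing context across the window; a
#' flatten plus fully-connected ReLU layer feeds a 2-unit softmax output
#' whose modified-class probability is the modification score.
#'
#' @param width Window width the network accepts (odd, default 21).
#' @param channels Number of input channels; defaults to the layout of
#'   `strand_mode`.
#' @param n_conv Number of Conv1d layers (default 4).
#' @param filters Filters per conv layer and transformer model dimension
#'   (default 64).
#' @param kernel Conv kernel size (default 5, same-padding).
#' @param n_transformer Number of transformer layers (default 3).
#' @param n_heads Attention heads (default 4; must divide `filters`).
#' @param ff_dim Transformer feed-forward width (default 128).
#' @param fc_units Units of the fully-connected head (default 128).
#' @param dropout Dropout rate inside transformer blocks (default 0.1).
#' @param mod_type Modification the scorer is (to be) trained for.
#' @param strand_mode Window layout the scorer accepts.
#' @return An object of class `"scorer_config"`.
#' @export
scorer_config <- function(width = 21L, channels = NULL, n_conv = 4L, filters = 64L,
                          kernel = 5L, n_transformer = 3L, n_heads = 4L,
                          ff_dim = 128L, fc_units = 128L, dropout = 0.1,
                          mod_type = NA_character_,
                          strand_mode = c("duplex", "watson", "crick")) {
  strand_mode <- match.arg(strand_mode)
  layout <- window_layout(strand_mode)
  if (is.null(channels)) channels <- length(layout)
  if (filters %% n_heads != 0L) stop("filters must be divisible by n_heads")
  if (width %% 2L != 1L) stop("width must be odd")
  structure(list(width = as.integer(width), channels = as.integer(channels),
                 n_conv = as.integer(n_conv), filters = as.integer(filters),
                 kernel = as.integer(kernel),
                 n_transformer = as.integer(n_transformer),
                 n_heads = as.integer(n_heads), ff_dim = as.integer(ff_dim),
                 fc_units = as.integer(fc_units), dropout = dropout,
                 mod_type = mod_type, strand_mode = strand_mode,
                 layout_id = attr(layout, "layout_id")),
            class = "scorer_config")
}

#' Training control parameters
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Maximum epochs.
#' @param patience Early-stopping patience on validation AUC.
#' @param val_fraction Fraction of examples held out for validation,
#'   stratified by class.
#' @param balance Balance classes in the training split by resampling the
#'   minority class.
#' @param seed Seed fixing initialisation, splits, shuffling and dropout.
#' @return An object of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 256L, epochs = 20L,
                         patience = 3L, val_fraction = 0.2, balance = TRUE,
                         seed = 1L) {
  stopifnot(val_fraction > 0, val_fraction < 1, epochs >= 1, batch_size >= 2)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 val_fraction = val_fraction, balance = isTRUE(balance),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build an untrained scorer
#'
#' @param config A [scorer_config()].
#' @param seed Seed for parameter initialisation (two builds with the same
#'   seed have identical parameters).
#' @return An object of class `"smrt_scorer"`.
#' @export
build_scorer <- function(config = scorer_config(), seed = 1L) {
  set.seed(seed)
  structure(list(config = config, params = init_params(config),
                 bn_stats = init_bn_stats(config), trained = FALSE,
                 history = NULL,
                 meta = list(init_seed = as.integer(seed), train_seed = NA_integer_,
                             n_train = NA_integer_, data_hash = NA_character_)),
            class = "smrt_scorer")
}

as_feature_array <- function(x, cfg, what = "windows") {
  if (is.list(x) && !is.array(x)) x <- windows_to_array(x)
  if (length(dim(x)) != 3L) stop(what, " must be a window list or a 3-d array")
  lid <- attr(x, "layout_id")
  if (!is.null(lid) && !identical(lid, cfg$layout_id))
    stop(sprintf("layout mismatch: scorer expects '%s' windows, got '%s'",
                 cfg$layout_id, lid))
  if (dim(x)[2L] != cfg$width || dim(x)[3L] != cfg$channels)
    stop(sprintf("shape mismatch: scorer expects %d x %d windows, got %d x %d",
                 cfg$width, cfg$channels, dim(x)[2L], dim(x)[3L]))
  x
}

predict_scores <- function(model, x, batch_size = 1024L) {
  n <- dim(x)[1L]
  out <- numeric(n)
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(s + batch_size - 1L, n)
    fw <- nn_forward(model$params, model$config, x[s:e, , , drop = FALSE],
                     train = FALSE, bn_stats = model$bn_stats)
    out[s:e] <- fw$probs[, 2L]
  }
  out
}

#' Train a scorer on labelled measurement windows
#'
#' Minimises two-class cross-entropy with Adam; tracks validation ROC AUC
#' per epoch and returns the parameters of the best-validation checkpoint.
#' Fully reproducible for a fixed `control$seed` on one machine.
#'
#' @param model An untrained (or previously trained) [build_scorer()] object.
#' @param x Window list or 3-d feature array (see [windows_to_array()]).
#' @param y Binary labels (1 = modified class).
#' @param control A [train_config()].
#' @param quiet Suppress per-epoch progress messages.
#' @return The trained `"smrt_scorer"`, with a `history` data frame
#'   (epoch, train_loss, val_auc).
#' @export
train_scorer <- function(model, x, y, control = train_config(), quiet = FALSE) {
  cfg <- model$config
  x <- as_feature_array(x, cfg)
  y <- as.integer(y)
  if (length(y) != dim(x)[1L]) stop("labels do not match the number of windows")
  if (length(unique(y)) < 2L) stop("training data contain a single class")
  set.seed(control$seed)
  n <- length(y)
  val <- unlist(lapply(split(seq_len(n), y), function(ix)
    sample(ix, max(1L, round(length(ix) * control$val_fraction)))))
  tr <- setdiff(seq_len(n), val)
  if (control$balance) {
    by_class <- split(tr, y[tr])
    n_max <- max(lengths(by_class))
    tr <- unlist(lapply(by_class, function(ix)
      if (length(ix) < n_max) c(ix, sample(ix, n_max - length(ix), replace = TRUE)) else ix))
  }
  xv <- x[val, , , drop = FALSE]
  yv <- y[val]
  opt <- adam_init(model$params)
  best <- list(auc = -Inf, params = model$params, bn_stats = model$bn_stats)
  hist <- NULL
  stale <- 0L
  for (epoch in seq_len(control$epochs)) {
    ord <- sample(tr)
    losses <- numeric(0)
    for (s in seq(1L, length(ord), by = control$batch_size)) {
      e <- min(s + control$batch_size - 1L, length(ord))
      if (e - s < 1L) next   # a 1-window batch breaks batch statistics
      bi <- ord[s:e]
      fw <- nn_forward(model$params, cfg, x[bi, , , drop = FALSE],
                       train = TRUE, bn_stats = model$bn_stats)
      model$bn_stats <- fw$bn_stats
      loss <- ce_loss(fw$probs, y[bi])
      if (!is.finite(loss))
        stop(sprintf("training diverged (loss %g at epoch %d); lower the learning rate",
                     loss, epoch))
      losses <- c(losses, loss)
      grads <- nn_backward(model$params, cfg, fw, y[bi])
      upd <- adam_step(model$params, grads, opt, control$learning_rate)
      model$params <- upd$params
      opt <- upd$state
    }
    val_auc <- roc_auc(predict_scores(model, xv), yv)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = mean(losses),
                                   val_auc = val_auc))
    if (!quiet)
      message(sprintf("epoch %d: train loss %.4f, validation AUC %.4f",
                      epoch, mean(losses), val_auc))
    if (val_auc > best$auc) {
      best <- list(auc = val_auc, params = model$params, bn_stats = model$bn_stats)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= control$patience) break
    }
  }
  model$params <- best$params
  model$bn_stats <- best$bn_stats
  model$trained <- TRUE
  model$history <- hist
  model$meta$train_seed <- control$seed
  model$meta$n_train <- length(tr)
  model$meta$data_hash <- sprintf("%d:%.6g:%.6g", n, sum(x) / length(x), mean(y))
  model
}

#' Fit a modification scorer
#'
#' One-call interface: builds the network described by `config` and trains
#' it on the labelled windows. See [scorer_config()] for the architecture
#' and [train_config()] for the optimisation settings.
#'
#' @inheritParams train_scorer
#' @param config A [scorer_config()]; its width/channels must match `x`.
#' @param seed Initialisation seed (the training seed lives in `control`).
#' @return A trained `"smrt_scorer"`.
#' @export
fit_scorer <- function(x, y, config = scorer_config(), control = train_config(),
                       seed = control$seed, quiet = FALSE) {
  train_scorer(build_scorer(config, seed), x, y, control, quiet = quiet)
}

#' Predict modification scores for measurement windows
#'
#' @param object A trained `"smrt_scorer"`.
#' @param newdata Window list or 3-d feature array; layout and width must
#'   match the scorer (no-call windows must be filtered out first).
#' @param type `"score"` (softmax probability of the modified class) or
#'   `"label"` (thresholded at `cutoff`).
#' @param cutoff Score cutoff for `type = "label"`.
#' @param ... Unused.
#' @return Numeric scores in `[0, 1]`, or a `"modified"`/`"unmodified"`
#'   character vector.
#' @export
predict.smrt_scorer <- function(object, newdata, type = c("score", "label"),
                                cutoff = 0.5, ...) {
  type <- match.arg(type)
  x <- as_feature_array(newdata, object$config, "newdata")
  s <- predict_scores(object, x)
  if (type == "score") s else ifelse(s > cutoff, "modified", "unmodified")
}

#' @export
print.smrt_scorer <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<smrt_scorer> %s/%s windows %d x %d (%s)\n",
              ifelse(is.na(cfg$mod_type), "untyped", cfg$mod_type),
              cfg$strand_mode, cfg$width, cfg$channels, cfg$layout_id))
  cat(sprintf("  %d conv layers (%d filters, kernel %d) + %d transformer layers (%d heads, ff %d)\n",
              cfg$n_conv, cfg$filters, cfg$kernel, cfg$n_transformer,
              cfg$n_heads, cfg$ff_dim))
  cat(sprintf("  %s; %d parameters\n",
              if (x$trained) sprintf("trained (best validation AUC %.4f)",
                                     max(x$history$val_auc)) else "untrained",
              sum(vapply(x$params, length, 0L))))
  invisible(x)
}

#' @export
summary.smrt_scorer <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("training history:\n")
    print(object$history, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.smrt_scorer <- function(object, ...) object$params

#' Plot the training history of a scorer
#'
#' @param x A trained `"smrt_scorer"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.smrt_scorer <- function(x, ...) {
  if (is.null(x$history)) stop("no training history to plot")
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$train_loss, type = "b", xlab = "epoch",
                 ylab = "training loss", ...)
  graphics::plot(h$epoch, h$val_auc, type = "b", xlab = "epoch",
                 ylab = "validation AUC", ...)
  invisible(x)
}

#' Save / load a scorer checkpoint
#'
#' The checkpoint embeds the architecture, the learned parameters, the
#' batch-normalization statistics, the feature layout id and the training
#' metadata; a reloaded scorer reproduces predictions exactly.
#'
#' @param model A `"smrt_scorer"`.
#' @param path Checkpoint path.
#' @return `path` (save) or the scorer (load).
#' @export
save_scorer <- function(model, path) {
  stopifnot(inherits(model, "smrt_scorer"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_scorer
#' @export
load_scorer <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "smrt_scorer")) stop("not a scorer checkpoint: ", path)
  m
}
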