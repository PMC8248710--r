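# The detector zoo: twelve recurrent sequence labelers mapping a 938 x 193
# feature matrix to a per-frame detection score (length 938, or 469 when
# the convolutional front end halves the time axis).
#
# Architecture (common to all variants):
#   [optional Conv2D(32, 3x5) + BatchNorm + Conv2D(64, 3x11) + MaxPool 2x2]
#   -> 2 stacked recurrent layers, 128 units each (bidirectional: 128 per
#      direction; simplified bidirectional: 64 per direction)
#   -> TimeDistributed Dense(32, relu) -> Dense(1, sigmoid).

#' Specify a detector variant
#'
#' @param cell recurrent cell, `"lstm"` or `"gru"`.
#' @param bidirectional use bidirectional recurrent layers.
#' @param cnn_front prepend the convolutional front end (halves the output
#'   length from 938 to 469).
#' @param simplified halve the recurrent width (only valid for
#'   bidirectional models, giving the SIMP variants whose parameter budget
#'   roughly matches the unidirectional models).
#' @return a `model_spec` object.
#' @export
model_spec <- function(cell = c("gru", "lstm"), bidirectional = FALSE,
                       cnn_front = FALSE, simplified = FALSE) {
  cell <- match.arg(cell)
  if (simplified && !bidirectional) {
    stop("simplified variants are defined only for bidirectional models")
  }
  units <- if (simplified) 64L else 128L
  name <- paste0(
    if (simplified) "SIMP " else "",
    if (cnn_front) "CNN-" else "",
    if (bidirectional) "Bi" else "",
    toupper(cell)
  )
  structure(list(cell = cell, bidirectional = bidirectional,
                 cnn_front = cnn_front, simplified = simplified,
                 units = units, name = name),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$name, "-", x$units, "units/direction, 2 layers\n")
  invisible(x)
}

#' Build a detector
#'
#' Initializes all weights (Glorot-uniform input kernels, orthogonal
#' recurrent kernels, zero biases with LSTM forget bias 1) under the given
#' seed.
#'
#' @param spec a [model_spec].
#' @param input_dim feature dimension per frame, default 193.
#' @param seed RNG seed fixing the initialization.
#' @return an object of class `lung_model`.
#' @export
build_model <- function(spec, input_dim = 193L, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  layers <- list()
  d <- input_dim
  if (spec$cnn_front) {
    layers$conv <- list(type = "conv", params = init_conv_front(d))
    d <- ((d + 1L) %/% 2L) * 64L
  }
  dirs <- if (spec$bidirectional) 2L else 1L
  layers$rnn1 <- init_rnn_layer(spec$cell, d, spec$units, spec$bidirectional)
  layers$rnn2 <- init_rnn_layer(spec$cell, spec$units * dirs, spec$units,
                                spec$bidirectional)
  layers$head <- list(type = "head", params = init_head(spec$units * dirs))
  structure(list(spec = spec, input_dim = input_dim, layers = layers),
            class = "lung_model")
}

#' Count trainable parameters of a detector
#'
#' Batch-normalization running statistics are not trainable and are
#' excluded.
#'
#' @param model a `lung_model`.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "lung_model"))
  total <- 0L
  for (layer in model$layers) {
    p <- layer$params
    flat <- unlist(p, recursive = TRUE, use.names = TRUE)
    nms <- names(p)
    # exclude running stats from the conv front end
    if (identical(layer$type, "conv")) {
      p <- p[setdiff(names(p), c("run_mean", "run_var"))]
      flat <- unlist(p, recursive = TRUE)
    }
    total <- total + length(flat)
  }
  as.integer(total)
}

#' @export
print.lung_model <- function(x, ...) {
  cat("<lung_model>", x$spec$name, "-", format(count_parameters(x), big.mark = ","),
      "trainable parameters; output length", if (x$spec$cnn_front) "T/2" else "T", "\n")
  invisible(x)
}

# Forward pass on a stacked batch; returns scores plus caches when training.
model_forward <- function(model, X_list, training = FALSE, keep_cache = FALSE) {
  B <- length(X_list); T <- nrow(X_list[[1]])
  caches <- list()
  if (!is.null(model$layers$conv)) {
    conv_outs <- vector("list", B)
    conv_caches <- if (keep_cache) vector("list", B)
    for (b in seq_len(B)) {
      r <- conv_front_forward(model$layers$conv$params, X_list[[b]],
                              training = training, keep_cache = keep_cache)
      conv_outs[[b]] <- r$out
      if (keep_cache) conv_caches[[b]] <- r$cache
    }
    caches$conv <- conv_caches
    X <- stack_batch(conv_outs)
    T <- nrow(conv_outs[[1]])
  } else {
    X <- stack_batch(X_list)
  }
  r1 <- rnn_layer_forward(model$layers$rnn1, X, B, T, keep_cache)
  r2 <- rnn_layer_forward(model$layers$rnn2, r1$out, B, T, keep_cache)
  hd <- head_forward(model$layers$head$params, r2$out, keep_cache)
  if (keep_cache) {
    caches$X <- X; caches$r1 <- r1; caches$r2 <- r2; caches$head <- hd$cache
  }
  list(scores = hd$scores, B = B, T = T, caches = caches)
}

model_backward <- function(model, fw, dlogit) {
  B <- fw$B; T <- fw$T
  ca <- fw$caches
  hb <- head_backward(model$layers$head$params, ca$r2$out, ca$head, dlogit)
  b2 <- rnn_layer_backward(model$layers$rnn2, ca$r1$out, ca$r2$cache, hb$dX, B, T)
  b1 <- rnn_layer_backward(model$layers$rnn1, ca$X, ca$r1$cache, b2$dX, B, T)
  grads <- list(rnn1 = b1$grads, rnn2 = b2$grads, head = hb$grads)
  if (!is.null(model$layers$conv)) {
    dX <- b1$dX
    g <- NULL
    for (b in seq_len(B)) {
      dOut_b <- dX[seq(b, B * T, by = B), , drop = FALSE]
      gb <- conv_front_backward(model$layers$conv$params, NULL,
                                ca$conv[[b]], dOut_b)$grads
      g <- if (is.null(g)) gb else mapply(`+`, g, gb, SIMPLIFY = FALSE)
    }
    grads <- c(list(conv = g), grads)
  }
  grads
}

model_params <- function(model) {
  out <- lapply(model$layers, `[[`, "params")
  if (!is.null(out$conv)) {
    out$conv <- out$conv[setdiff(names(out$conv), c("run_mean", "run_var"))]
  }
  out
}

set_model_params <- function(model, params) {
  for (nm in names(params)) {
    keep <- model$layers[[nm]]$params
    for (pn in names(params[[nm]])) keep[[pn]] <- params[[nm]][[pn]]
    model$layers[[nm]]$params <- keep
  }
  model
}

#' Run a detector on one recording's features
#'
#' @param object a `lung_model`.
#' @param features a `lung_features` object or a plain T x input_dim matrix.
#' @param ... unused.
#' @return numeric vector of per-frame scores in `[0, 1]`, length T for
#'   plain recurrent models and T/2 for CNN-fronted models.
#' @export
predict.lung_model <- function(object, features, ...) {
  X <- if (inherits(features, "lung_features")) features$values else features
  if (!is.matrix(X) || ncol(X) != object$input_dim) {
    stop("feature matrix with ", object$input_dim, " columns required, got ",
         paste(dim(X), collapse = " x "))
  }
  fw <- model_forward(object, list(X), training = FALSE, keep_cache = FALSE)
  fw$scores
}

# -- training ----------------------------------------------------------------

#' Training configuration
#'
#' Defaults are the benchmark schedule: Adam with initial learning rate
#' 1e-4, step decay by 0.2 when the validation loss has not decreased for
#' 10 epochs, and stopping when no improvement occurs over 50 consecutive
#' epochs. `max_epochs` caps the run for scaled-down workflows.
#'
#' @param initial_lr initial learning rate.
#' @param lr_decay_factor multiplicative decay on plateau.
#' @param lr_patience_epochs epochs without improvement before decay.
#' @param early_stop_epochs epochs without improvement before stopping.
#' @param max_epochs hard cap on epochs.
#' @param batch_size minibatch size.
#' @param seed RNG seed fixing data order (and any dropout-free noise).
#' @return a `train_config` list.
#' @export
train_config <- function(initial_lr = 1e-4, lr_decay_factor = 0.2,
                         lr_patience_epochs = 10, early_stop_epochs = 50,
                         max_epochs = 1000, batch_size = 32, seed = 1L) {
  stopifnot(initial_lr > 0, lr_decay_factor > 0, lr_patience_epochs > 0,
            early_stop_epochs > 0, max_epochs > 0, batch_size > 0)
  structure(list(initial_lr = initial_lr, lr_decay_factor = lr_decay_factor,
                 lr_patience_epochs = lr_patience_epochs,
                 early_stop_epochs = early_stop_epochs,
                 max_epochs = max_epochs, batch_size = batch_size,
                 seed = as.integer(seed)),
            class = "train_config")
}

bce_loss <- function(scores, y, eps = 1e-7) {
  p <- pmin(pmax(scores, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train a detector with per-frame binary cross-entropy
#'
#' Minibatch Adam with the plateau learning-rate schedule and early
#' stopping measured on validation loss (strict improvement); the weights
#' from the best validation epoch are restored. With a fixed seed the run
#' is bit-reproducible on CPU.
#'
#' @param model a `lung_model` from [build_model()].
#' @param X list of T x input_dim feature matrices (training set).
#' @param y list of binary target vectors (length T, or T/2 for
#'   CNN-fronted models).
#' @param X_val,y_val validation set in the same format.
#' @param config a [train_config].
#' @param verbose print per-epoch progress.
#' @return the trained `lung_model`, with a `history` data frame
#'   (epoch, train_loss, val_loss, lr) attached as an attribute.
#' @export
train_model <- function(model, X, y, X_val, y_val, config = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "lung_model"), length(X) == length(y))
  if (length(X) == 0) stop("empty training set")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  params <- model_params(model)
  m <- adam_init(params); v <- adam_init(params)
  step <- 0L
  lr <- config$initial_lr
  best_val <- Inf; best_params <- params
  lr_wait <- 0L; stop_wait <- 0L
  hist <- list()
  n <- length(X)

  val_loss <- function(mod) {
    tot <- 0; cnt <- 0
    bs <- config$batch_size
    for (i0 in seq(1, length(X_val), by = bs)) {
      i1 <- min(length(X_val), i0 + bs - 1)
      fw <- model_forward(mod, X_val[i0:i1], training = FALSE, keep_cache = FALSE)
      yb <- stack_targets(y_val[i0:i1])
      tot <- tot + bce_loss(fw$scores, yb) * length(yb)
      cnt <- cnt + length(yb)
    }
    tot / cnt
  }

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    tr_tot <- 0; tr_cnt <- 0
    for (i0 in seq(1, n, by = config$batch_size)) {
      i1 <- min(n, i0 + config$batch_size - 1)
      idx <- ord[i0:i1]
      fw <- model_forward(model, X[idx], training = TRUE, keep_cache = TRUE)
      yb <- stack_targets(y[idx])
      loss <- bce_loss(fw$scores, yb)
      tr_tot <- tr_tot + loss * length(yb); tr_cnt <- tr_cnt + length(yb)
      dlogit <- (fw$scores - yb) / length(yb)
      grads <- model_backward(model, fw, dlogit)
      step <- step + 1L
      upd <- adam_step(params, grads, m, v, lr, step)
      params <- upd$p; m <- upd$m; v <- upd$v
      model <- set_model_params(model, params)
      # update BN running stats from the batch statistics
      if (!is.null(model$layers$conv) && !is.null(fw$caches$conv)) {
        cc <- fw$caches$conv[[1]]
        cp <- model$layers$conv$params
        cp$run_mean <- BN_MOMENTUM * cp$run_mean + (1 - BN_MOMENTUM) * cc$mu
        cp$run_var <- BN_MOMENTUM * cp$run_var + (1 - BN_MOMENTUM) * cc$v
        model$layers$conv$params <- cp
      }
    }
    vl <- val_loss(model)
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = tr_tot / tr_cnt,
                                val_loss = vl, lr = lr)
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f  lr %g",
                      epoch, tr_tot / tr_cnt, vl, lr))
    }
    if (vl < best_val) {
      best_val <- vl; best_params <- params
      lr_wait <- 0L; stop_wait <- 0L
    } else {
      lr_wait <- lr_wait + 1L; stop_wait <- stop_wait + 1L
      if (lr_wait >= config$lr_patience_epochs) {
        lr <- lr * config$lr_decay_factor
        lr_wait <- 0L
      }
      if (stop_wait >= config$early_stop_epochs) break
    }
  }
  model <- set_model_params(model, best_params)
  attr(model, "history") <- do.call(rbind, hist)
  model
}

# -- grouped cross-validation ------------------------------------------------

#' Assign manifest groups to cross-validation folds
#'
#' Recordings collected on the same subject-day are acoustically similar,
#' so a group must never span two folds. Groups are shuffled under the
#' seed, then assigned largest-first to the currently smallest fold, which
#' balances fold sizes as far as the grouping permits.
#'
#' @param manifest a manifest data frame with a `group` column.
#' @param k number of folds, default 5.
#' @param seed RNG seed for the shuffle.
#' @return integer vector of fold ids (1..k), one per manifest row.
#' @export
make_folds <- function(manifest, k = 5, seed = 1L) {
  groups <- unique(manifest$group)
  if (length(groups) < k) {
    stop("insufficient groups: ", length(groups), " groups for ", k, " folds")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  sizes <- table(manifest$group)[groups]
  ord <- sample.int(length(groups))           # seeded tie-break
  groups <- groups[ord]; sizes <- sizes[ord]
  ord2 <- order(-as.integer(sizes))
  groups <- groups[ord2]; sizes <- sizes[ord2]
  fold_of_group <- integer(length(groups))
  fold_sizes <- numeric(k)
  for (i in seq_along(groups)) {
    f <- which.min(fold_sizes)
    fold_of_group[i] <- f
    fold_sizes[f] <- fold_sizes[f] + sizes[i]
  }
  names(fold_of_group) <- groups
  unname(fold_of_group[manifest$group])
}
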