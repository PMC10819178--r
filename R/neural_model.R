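# Multi-label feed-forward classifier over the 86 interaction types.
# Dense layers with optional batch normalization and ReLU activations feed a
# sigmoid output head; training minimizes binary cross-entropy with Adam.
# Written in plain R matrix code; gradients are verified against finite
# differences in the test suite.

#' Classifier configuration
#'
#' Defaults follow the reference architecture: pair features of length 100
#' into nine hidden layers of 2048 rectified-linear units with batch
#' normalization, 86 sigmoid outputs, binary cross-entropy loss, Adam with
#' learning rate 0.001, batch size 1024 and 20 epochs.
#'
#' @param input_dim Feature length (`2 k`). Default 100.
#' @param hidden_layers Number of hidden layers. Default 9.
#' @param hidden_units Units per hidden layer. Default 2048.
#' @param output_dim Number of interaction types. Default 86.
#' @param batch_norm Use batch normalization after each hidden linear
#'   transform, before the activation. Default `TRUE`.
#' @param learning_rate Adam step size. Default 0.001.
#' @param batch_size Minibatch size. Default 1024.
#' @param epochs Training epochs (no early stopping). Default 20.
#' @param seed Integer seed controlling initialization and batching.
#' @return A list of class `ddi_model_config`.
#' @export
model_config <- function(input_dim = 100L, hidden_layers = 9L,
                         hidden_units = 2048L, output_dim = 86L,
                         batch_norm = TRUE, learning_rate = 0.001,
                         batch_size = 1024L, epochs = 20L, seed = 0L) {
  stopifnot(input_dim > 0, hidden_layers >= 1, hidden_units > 0,
            output_dim > 0, learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_layers = as.integer(hidden_layers),
                 hidden_units = as.integer(hidden_units),
                 output_dim = as.integer(output_dim),
                 batch_norm = isTRUE(batch_norm),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "ddi_model_config")
}

#' Count trainable parameters
#'
#' Sum of weights and biases of all dense layers, plus (with batch
#' normalization) one scale and one shift parameter per unit of each hidden
#' layer. The default configuration has 33,990,742 trainable parameters
#' (33,953,878 without the batch-norm parameters); both round to 34 million.
#'
#' @param cfg A `ddi_model_config`.
#' @return Integer parameter count.
#' @export
#' @examples
#' round(count_parameters(model_config()) / 1e6)  # 34
count_parameters <- function(cfg) {
  stopifnot(inherits(cfg, "ddi_model_config"))
  dims <- c(cfg$input_dim, rep(cfg$hidden_units, cfg$hidden_layers),
            cfg$output_dim)
  dense <- sum(dims[-length(dims)] * dims[-1] + dims[-1])
  bn <- if (cfg$batch_norm) 2 * cfg$hidden_units * cfg$hidden_layers else 0
  as.integer(dense + bn)
}

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.9
.P_CLAMP <- 1e-7

.init_network <- function(cfg) {
  dims <- c(cfg$input_dim, rep(cfg$hidden_units, cfg$hidden_layers))
  hidden <- lapply(seq_len(cfg$hidden_layers), function(i) {
    fan_in <- dims[i]
    l <- list(W = matrix(stats::rnorm(fan_in * cfg$hidden_units,
                                      sd = sqrt(2 / fan_in)),
                         fan_in, cfg$hidden_units),
              b = numeric(cfg$hidden_units))
    if (cfg$batch_norm) {
      l$gamma <- rep(1, cfg$hidden_units)
      l$beta <- numeric(cfg$hidden_units)
      l$run_mean <- numeric(cfg$hidden_units)
      l$run_var <- rep(1, cfg$hidden_units)
    }
    l
  })
  out <- list(W = matrix(stats::rnorm(cfg$hidden_units * cfg$output_dim,
                                      sd = sqrt(1 / cfg$hidden_units)),
                         cfg$hidden_units, cfg$output_dim),
              b = numeric(cfg$output_dim))
  structure(list(cfg = cfg, hidden = hidden, out = out, trained_epochs = 0L),
            class = "ddi_model")
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# forward pass; train = TRUE uses batch statistics and returns caches,
# and (as a side effect value) the updated running statistics
.forward <- function(model, X, train = FALSE) {
  cfg <- model$cfg
  caches <- vector("list", cfg$hidden_layers)
  A <- X
  for (i in seq_len(cfg$hidden_layers)) {
    l <- model$hidden[[i]]
    Z <- A %*% l$W
    Z <- sweep(Z, 2, l$b, `+`)
    if (cfg$batch_norm) {
      if (train) {
        mu <- colMeans(Z)
        v <- colMeans(sweep(Z, 2, mu)^2)
        model$hidden[[i]]$run_mean <- .BN_MOMENTUM * l$run_mean + (1 - .BN_MOMENTUM) * mu
        model$hidden[[i]]$run_var <- .BN_MOMENTUM * l$run_var + (1 - .BN_MOMENTUM) * v
      } else {
        mu <- l$run_mean
        v <- l$run_var
      }
      istd <- 1 / sqrt(v + .BN_EPS)
      Zhat <- sweep(sweep(Z, 2, mu), 2, istd, `*`)
      H <- sweep(sweep(Zhat, 2, l$gamma, `*`), 2, l$beta, `+`)
    } else {
      Zhat <- NULL
      istd <- NULL
      H <- Z
    }
    A_new <- pmax(H, 0)
    if (train) caches[[i]] <- list(A_in = A, Zhat = Zhat, istd = istd, H = H)
    A <- A_new
  }
  logits <- sweep(A %*% model$out$W, 2, model$out$b, `+`)
  P <- .sigmoid(logits)
  list(P = P, A_last = A, caches = caches, model = model)
}

.bce <- function(P, Y) {
  P <- pmin(pmax(P, .P_CLAMP), 1 - .P_CLAMP)
  -mean(Y * log(P) + (1 - Y) * log(1 - P))
}

# gradients for all trainable parameters; fw is a train-mode forward result
.backward <- function(model, X, Y, fw) {
  cfg <- model$cfg
  n <- nrow(X)
  grads <- list(hidden = vector("list", cfg$hidden_layers), out = NULL)
  dLogits <- (fw$P - Y) / (n * cfg$output_dim)
  grads$out <- list(W = crossprod(fw$A_last, dLogits), b = colSums(dLogits))
  dA <- tcrossprod(dLogits, model$out$W)
  for (i in rev(seq_len(cfg$hidden_layers))) {
    l <- model$hidden[[i]]
    cache <- fw$caches[[i]]
    dH <- dA * (cache$H > 0)
    if (cfg$batch_norm) {
      g <- list(gamma = colSums(dH * cache$Zhat), beta = colSums(dH))
      dZhat <- sweep(dH, 2, l$gamma, `*`)
      m1 <- colMeans(dZhat)
      m2 <- colMeans(dZhat * cache$Zhat)
      dZ <- sweep(sweep(dZhat, 2, m1) - sweep(cache$Zhat, 2, m2, `*`),
                  2, cache$istd, `*`)
    } else {
      g <- list()
      dZ <- dH
    }
    g$W <- crossprod(cache$A_in, dZ)
    g$b <- colSums(dZ)
    grads$hidden[[i]] <- g
    dA <- tcrossprod(dZ, l$W)
  }
  grads
}

.PARAM_NAMES <- c("W", "b", "gamma", "beta")

.adam_init <- function(model) {
  zero_like <- function(l) lapply(l[intersect(.PARAM_NAMES, names(l))],
                                  function(p) p * 0)
  list(m = list(hidden = lapply(model$hidden, zero_like),
                out = zero_like(model$out)),
       v = list(hidden = lapply(model$hidden, zero_like),
                out = zero_like(model$out)),
       t = 0L)
}

.adam_step <- function(model, grads, state, lr, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  upd <- function(param, grad, m, v) {
    m <- b1 * m + (1 - b1) * grad
    v <- b2 * v + (1 - b2) * grad^2
    param <- param - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(param = param, m = m, v = v)
  }
  for (i in seq_along(model$hidden)) {
    for (p in intersect(.PARAM_NAMES, names(grads$hidden[[i]]))) {
      r <- upd(model$hidden[[i]][[p]], grads$hidden[[i]][[p]],
               state$m$hidden[[i]][[p]], state$v$hidden[[i]][[p]])
      model$hidden[[i]][[p]] <- r$param
      state$m$hidden[[i]][[p]] <- r$m
      state$v$hidden[[i]][[p]] <- r$v
    }
  }
  for (p in c("W", "b")) {
    r <- upd(model$out[[p]], grads$out[[p]], state$m$out[[p]], state$v$out[[p]])
    model$out[[p]] <- r$param
    state$m$out[[p]] <- r$m
    state$v$out[[p]] <- r$v
  }
  list(model = model, state = state)
}

.one_hot <- function(labels, output_dim) {
  stopifnot(all(labels >= 1), all(labels <= output_dim))
  Y <- matrix(0, length(labels), output_dim)
  Y[cbind(seq_along(labels), labels)] <- 1
  Y
}

#' Train the interaction-type classifier
#'
#' Minimizes per-output binary cross-entropy with Adam over minibatches for a
#' fixed number of epochs (no early stopping). Gold labels are single types
#' per pair, consumed as one-hot multi-label targets. Training is
#' deterministic for a fixed `cfg$seed`.
#'
#' @param x_train Feature matrix (`n x input_dim`).
#' @param y_train Integer gold type per row (`1..output_dim`), or a one-hot
#'   matrix.
#' @param cfg A `ddi_model_config`.
#' @param x_val,y_val Optional validation set, evaluated each epoch.
#' @return List with `model` (class `ddi_model`) and `history` (tibble with
#'   per-epoch `train_loss`, `train_acc`, `val_loss`, `val_acc`).
#' @export
train_model <- function(x_train, y_train, cfg = model_config(),
                        x_val = NULL, y_val = NULL) {
  stopifnot(is.matrix(x_train), nrow(x_train) >= 1)
  if (ncol(x_train) != cfg$input_dim) {
    stop("feature dimension ", ncol(x_train), " does not match input_dim ",
         cfg$input_dim, call. = FALSE)
  }
  Y <- if (is.matrix(y_train)) y_train else .one_hot(y_train, cfg$output_dim)
  lab <- max.col(Y, ties.method = "first")
  n <- nrow(x_train)
  hist <- vector("list", cfg$epochs)
  model <- NULL
  withr::with_seed(cfg$seed, {
    model <- .init_network(cfg)
    adam <- .adam_init(model)
    for (epoch in seq_len(cfg$epochs)) {
      idx <- sample.int(n)
      starts <- seq(1, n, by = cfg$batch_size)
      for (s in starts) {
        b <- idx[s:min(s + cfg$batch_size - 1, n)]
        if (length(b) < 2 && cfg$batch_norm) next  # batch stats undefined
        fw <- .forward(model, x_train[b, , drop = FALSE], train = TRUE)
        model <- fw$model  # running BN statistics were updated
        grads <- .backward(model, x_train[b, , drop = FALSE],
                           Y[b, , drop = FALSE], fw)
        stepped <- .adam_step(model, grads, adam, cfg$learning_rate)
        model <- stepped$model
        adam <- stepped$state
      }
      model$trained_epochs <- epoch
      P_tr <- .forward(model, x_train)$P
      row <- tibble::tibble(
        epoch = epoch,
        train_loss = .bce(P_tr, Y),
        train_acc = mean(max.col(P_tr, ties.method = "first") == lab))
      if (!is.null(x_val)) {
        Yv <- if (is.matrix(y_val)) y_val else .one_hot(y_val, cfg$output_dim)
        P_v <- .forward(model, x_val)$P
        row$val_loss <- .bce(P_v, Yv)
        row$val_acc <- mean(max.col(P_v, ties.method = "first") ==
                              max.col(Yv, ties.method = "first"))
      } else {
        row$val_loss <- NA_real_
        row$val_acc <- NA_real_
      }
      hist[[epoch]] <- row
    }
  })
  list(model = model, history = dplyr::bind_rows(hist))
}

#' Output-neuron activations for a feature matrix
#'
#' @param model A trained `ddi_model`.
#' @param X Feature matrix (`n x input_dim`) or a single feature vector.
#' @return Matrix (`n x output_dim`) of sigmoid activations in `[0, 1]`.
#' @export
predict_activations <- function(model, X) {
  stopifnot(inherits(model, "ddi_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  stopifnot(ncol(X) == model$cfg$input_dim)
  .forward(model, X)$P
}

#' Categorical accuracy
#'
#' Fraction of samples whose highest-activation output equals the gold type;
#' ties are broken by the lowest type identifier.
#'
#' @param model A trained `ddi_model`.
#' @param X Feature matrix.
#' @param labels Integer gold types (`1..output_dim`).
#' @return A number in `[0, 1]`.
#' @export
categorical_accuracy <- function(model, X, labels) {
  stopifnot(length(labels) == nrow(X), nrow(X) > 0)
  P <- predict_activations(model, X)
  mean(max.col(P, ties.method = "first") == labels)
}

#' Types fired by an activation vector
#'
#' @param activations Numeric activation vector (length `output_dim`) or a
#'   single-row matrix.
#' @param threshold Activation cutoff in `(0, 1)`; the screening default is
#'   0.94 (twice the base threshold 0.47).
#' @return Tibble with `type_id` and `score`, sorted by descending score.
#' @export
predict_types <- function(activations, threshold = 0.94) {
  stopifnot(threshold > 0, threshold < 1)
  a <- as.numeric(activations)
  hit <- which(a >= threshold)
  out <- tibble::tibble(type_id = as.integer(hit), score = a[hit])
  dplyr::arrange(out, dplyr::desc(.data$score), .data$type_id)
}

# ---- persistence ------------------------------------------------------------

#' Save a trained model as JSON
#'
#' Weights are written at full double precision together with the
#' configuration, so a reloaded model reproduces activations exactly.
#'
#' @param model A `ddi_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_ddi_model <- function(model, path) {
  stopifnot(inherits(model, "ddi_model"))
  ser_layer <- function(l) {
    lapply(l, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
      else list(dim = length(p), data = as.vector(p))
    })
  }
  obj <- list(config = unclass(model$cfg),
              trained_epochs = model$trained_epochs,
              hidden = lapply(model$hidden, ser_layer),
              out = ser_layer(model$out))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved by [save_ddi_model()]
#'
#' @param path File path.
#' @return A `ddi_model`.
#' @export
load_ddi_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cfg <- do.call(model_config, lapply(obj$config, unlist))
  de_layer <- function(l) {
    lapply(l, function(p) {
      d <- unlist(p$dim)
      x <- as.numeric(unlist(p$data))
      if (length(d) == 2) matrix(x, d[1], d[2]) else x
    })
  }
  hidden <- lapply(obj$hidden, de_layer)
  structure(list(cfg = cfg, hidden = hidden, out = de_layer(obj$out),
                 trained_epochs = as.integer(obj$trained_epochs)),
            class = "ddi_model")
}
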