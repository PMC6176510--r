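#' Cross-layer fully connected network configuration
#'
#' Topology and training hyper-parameters of the window classifier.  Defaults
#' give the 529 -> 80 -> 20 -> 1 network with every earlier layer wired to
#' every later layer (55,252 trainable parameters), input dropout 0.1 and no
#' hidden dropout, mean-squared-error objective, mini-batch (50) momentum
#' (0.9) gradient descent with learning rate 0.01 and weight decay 2e-4, and
#' early stopping on training accuracy.
#'
#' @param input_dim Number of input features (flattened sync matrix; 23
#'   channels -> 529).
#' @param hidden_widths Widths of the hidden layers.
#' @param dropout_input Input-layer dropout fraction.
#' @param learning_rate,momentum,weight_decay,batch_size,max_epochs Training
#'   hyper-parameters.
#' @param patience Epochs of non-increasing training accuracy before stopping.
#' @param threshold Decision cutoff on the network output.
#' @param init_gain Multiplier on the `sqrt(6 / (fan_in + fan_out))`
#'   initialization limit (default 1).
#' @param standardize Standardize features to zero mean / unit variance
#'   inside [clfcnn_fit()] (statistics from the training data, stored with
#'   the model and reapplied at prediction).  Raw mutual-information features
#'   are all positive with mean well above the 0/1 label scale; without
#'   centering, the first mean-squared-error momentum steps routinely drive
#'   every rectifier dead.  Default `TRUE`.
#' @param cross_layer `TRUE` for the full cross-layer wiring; `FALSE`
#'   restricts edges to adjacent layers (the plain feed-forward comparison
#'   network).
#' @param seed Integer seed for initialization, dropout and shuffling.
#' @return An object of class `clfcnn_config`.
#' @export
clfcnn_config <- function(input_dim = 529L, hidden_widths = c(80L, 20L),
                          dropout_input = 0.1, learning_rate = 0.01,
                          momentum = 0.9, weight_decay = 2e-4,
                          batch_size = 50L, max_epochs = 300L,
                          patience = 1L, threshold = 0.5, init_gain = 1,
                          standardize = TRUE, cross_layer = TRUE, seed = 7L) {
  widths <- c(as.integer(input_dim), as.integer(hidden_widths), 1L)
  if (any(widths <= 0L)) stop("layer widths must be positive")
  stopifnot(dropout_input >= 0, dropout_input < 1,
            learning_rate > 0, momentum >= 0, momentum < 1,
            weight_decay >= 0, batch_size >= 1L, max_epochs >= 1L,
            patience >= 1L, init_gain > 0)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_widths = as.integer(hidden_widths),
                 widths = widths,
                 dropout_input = dropout_input,
                 learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 threshold = threshold, init_gain = init_gain,
                 standardize = isTRUE(standardize),
                 cross_layer = isTRUE(cross_layer),
                 seed = as.integer(seed)),
            class = "clfcnn_config")
}

# edge list (j -> i, j < i) over layers 1..L (1 = input)
clfcnn_edges <- function(config) {
  L <- length(config$widths)
  edges <- list()
  for (i in 2:L) {
    js <- if (config$cross_layer) seq_len(i - 1L) else i - 1L
    for (j in js) edges[[length(edges) + 1L]] <- c(j, i)
  }
  edges
}

#' Build and initialize the classifier parameters
#'
#' One weight matrix and bias vector per forward edge `j -> i` (every earlier
#' layer to every later layer).  Weights are uniform in
#' `+/- init_gain * sqrt(6 / (fan_in + fan_out))`, biases zero; seeded and
#' deterministic.
#'
#' @param config A [clfcnn_config()].
#' @param seed Optional override of `config$seed`.
#' @return A `clfcnn_params` object: list of edges, each with `from`, `to`,
#'   `w` (width_from x width_to) and `b` (length width_to); attribute
#'   `n_parameters`.
#' @export
build_model <- function(config = clfcnn_config(), seed = config$seed) {
  set.seed(as.integer(seed))
  widths <- config$widths
  edges <- lapply(clfcnn_edges(config), function(e) {
    j <- e[1L]; i <- e[2L]
    lim <- config$init_gain * sqrt(6 / (widths[j] + widths[i]))
    list(from = j, to = i,
         w = matrix(stats::runif(widths[j] * widths[i], -lim, lim),
                    widths[j], widths[i]),
         b = numeric(widths[i]))
  })
  n_par <- sum(vapply(edges, function(e) length(e$w) + length(e$b),
                      numeric(1)))
  structure(list(edges = edges, config = config),
            class = "clfcnn_params", n_parameters = n_par)
}

#' Number of trainable parameters
#'
#' @param params A `clfcnn_params`.
#' @return Integer parameter count (weights + biases over all edges).
#' @export
n_parameters <- function(params) {
  as.integer(attr(params, "n_parameters"))
}

#' Per-edge parameter counts
#'
#' @param params A `clfcnn_params`.
#' @return Data frame with `from`, `to` and `n` (parameters on that edge),
#'   in edge order.
#' @export
edge_parameter_counts <- function(params) {
  data.frame(from = vapply(params$edges, `[[`, numeric(1), "from"),
             to = vapply(params$edges, `[[`, numeric(1), "to"),
             n = vapply(params$edges, function(e) length(e$w) + length(e$b),
                        numeric(1)))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# forward pass keeping per-edge pre-activations for backprop.
# X: n x input_dim.  Layer activation i = sum over incoming edges of
# relu(A_j W + b); the outer rectifier is the identity on this non-negative
# sum, so it is not applied again.
clfcnn_forward_pass <- function(params, X, training = FALSE,
                                dropout_mask = NULL) {
  cfg <- params$config
  widths <- cfg$widths
  L <- length(widths)
  n <- nrow(X)
  A <- vector("list", L)
  A[[1L]] <- X
  if (training && cfg$dropout_input > 0) {
    if (is.null(dropout_mask))
      dropout_mask <- matrix(stats::rbinom(n * widths[1L], 1L,
                                           1 - cfg$dropout_input),
                             n, widths[1L])
    A[[1L]] <- X * dropout_mask / (1 - cfg$dropout_input)  # inverted scaling
  }
  Z <- vector("list", length(params$edges))
  for (i in 2:L) A[[i]] <- matrix(0, n, widths[i])
  for (e in seq_along(params$edges)) {
    ed <- params$edges[[e]]
    z <- A[[ed$from]] %*% ed$w
    z <- sweep(z, 2L, ed$b, "+")
    Z[[e]] <- z
    A[[ed$to]] <- A[[ed$to]] + relu(z)
  }
  list(activations = A, preact = Z, output = A[[L]][, 1L],
       dropout_mask = dropout_mask)
}

#' Forward pass of the classifier
#'
#' Each later layer receives a rectified linear contribution from every
#' earlier layer through that edge's own weights and bias; contributions are
#' summed.  The output is a non-negative scalar per sample.  With
#' `training = TRUE`, input dropout (inverted scaling) is applied.
#'
#' @param params A `clfcnn_params`.
#' @param features Numeric matrix (samples x input_dim) or a single feature
#'   vector.
#' @param training Apply input dropout?
#' @param seed Optional seed for the dropout mask.
#' @return Numeric vector of outputs, one per sample.
#' @export
clfcnn_forward <- function(params, features, training = FALSE, seed = NULL) {
  if (!is.matrix(features)) features <- matrix(features, nrow = 1L)
  if (ncol(features) != params$config$input_dim)
    stop("feature dimension mismatch")
  if (!is.null(params$scaling))
    features <- sweep(sweep(features, 2L, params$scaling$mean), 2L,
                      params$scaling$sd, "/")
  if (!is.null(seed)) set.seed(as.integer(seed))
  clfcnn_forward_pass(params, features, training = training)$output
}

#' Mean-squared-error loss and gradients
#'
#' Loss is the batch mean of `(output - label)^2`; gradients flow by
#' reverse-mode chain rule along every cross-layer path.  The returned
#' gradients exclude the weight-decay term, which the optimizer applies
#' (see [sgd_momentum_step()]).
#'
#' @param params A `clfcnn_params`.
#' @param features Samples x input_dim matrix.
#' @param labels 0/1 vector, one per sample.
#' @param training Apply input dropout during the forward pass?
#' @param seed Optional seed for the dropout mask.
#' @return List with `loss`, `gradients` (per edge: `w`, `b`) and `output`.
#' @export
loss_and_gradients <- function(params, features, labels, training = FALSE,
                               seed = NULL) {
  if (!is.matrix(features)) features <- matrix(features, nrow = 1L)
  n <- nrow(features)
  if (n == 0L) stop("empty batch")
  stopifnot(length(labels) == n, all(labels %in% c(0, 1)))
  if (!is.null(seed)) set.seed(as.integer(seed))
  fw <- clfcnn_forward_pass(params, features, training = training)
  out <- fw$output
  loss <- mean((out - labels)^2)
  L <- length(params$config$widths)
  dA <- vector("list", L)
  dA[[L]] <- matrix(2 * (out - labels) / n, ncol = 1L)
  grads <- vector("list", length(params$edges))
  # walk edges in reverse destination order so dA is complete when used
  ord <- order(vapply(params$edges, `[[`, numeric(1), "to"),
               decreasing = TRUE)
  for (e in ord) {
    ed <- params$edges[[e]]
    dZ <- dA[[ed$to]] * (fw$preact[[e]] > 0)
    grads[[e]] <- list(w = crossprod(fw$activations[[ed$from]], dZ),
                       b = colSums(dZ))
    if (ed$from > 1L) {
      contrib <- dZ %*% t(ed$w)
      dA[[ed$from]] <- if (is.null(dA[[ed$from]])) contrib
                       else dA[[ed$from]] + contrib
    }
  }
  list(loss = loss, gradients = grads, output = out)
}

#' Momentum / weight-decay parameter update
#'
#' Element-wise, in the classic momentum / weight-decay form:
#' `v <- momentum * v - weight_decay * lr * w - lr * grad; w <- w + v`,
#' applied to every trainable parameter (weights and biases alike).
#'
#' @param params A `clfcnn_params`.
#' @param state Optimizer state from a previous call, or `NULL` to start
#'   with zero velocity.
#' @param gradients Gradients from [loss_and_gradients()].
#' @param config A [clfcnn_config()] (for the rates).
#' @return List with updated `params` and `state`.
#' @export
sgd_momentum_step <- function(params, state, gradients,
                              config = params$config) {
  eps <- config$learning_rate
  mom <- config$momentum
  wd <- config$weight_decay
  if (is.null(state)) {
    state <- list(v = lapply(params$edges, function(e)
      list(w = matrix(0, nrow(e$w), ncol(e$w)), b = numeric(length(e$b)))),
      iteration = 0L)
  }
  for (e in seq_along(params$edges)) {
    vw <- mom * state$v[[e]]$w - wd * eps * params$edges[[e]]$w -
      eps * gradients[[e]]$w
    vb <- mom * state$v[[e]]$b - wd * eps * params$edges[[e]]$b -
      eps * gradients[[e]]$b
    params$edges[[e]]$w <- params$edges[[e]]$w + vw
    params$edges[[e]]$b <- params$edges[[e]]$b + vb
    state$v[[e]]$w <- vw
    state$v[[e]]$b <- vb
  }
  state$iteration <- state$iteration + 1L
  list(params = params, state = state)
}

#' Train the classifier
#'
#' Mini-batch momentum gradient descent on the mean-squared error with input
#' dropout, weight decay and early stopping: training stops at the end of the
#' first epoch after training accuracy has failed to increase for `patience`
#' consecutive epochs, or at `max_epochs`, and the parameters from the
#' best-training-accuracy epoch are restored (so a transient rectifier
#' collapse late in training cannot corrupt the returned model).
#'
#' @param features Samples x input_dim matrix.
#' @param labels 0/1 vector.
#' @param config A [clfcnn_config()].
#' @param val_features,val_labels Optional validation split for the history.
#' @param params Optional warm-start parameters; defaults to a fresh
#'   [build_model()].
#' @return List with `params` (trained) and `history` (data frame: per-epoch
#'   `epoch`, `acc`, `loss`, `val_acc`, `val_loss`).
#' @export
clfcnn_fit <- function(features, labels, config = clfcnn_config(),
                       val_features = NULL, val_labels = NULL,
                       params = NULL) {
  if (!is.matrix(features)) features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(n >= 1L, length(labels) == n)
  if (is.null(params)) params <- build_model(config)
  if (config$standardize && is.null(params$scaling)) {
    mu <- colMeans(features)
    s <- apply(features, 2L, stats::sd)
    s[!is.finite(s) | s == 0] <- 1
    params$scaling <- list(mean = mu, sd = s)
  }
  if (!is.null(params$scaling)) {
    features <- sweep(sweep(features, 2L, params$scaling$mean), 2L,
                      params$scaling$sd, "/")
    if (!is.null(val_features))
      val_features <- sweep(sweep(as.matrix(val_features), 2L,
                                  params$scaling$mean), 2L,
                            params$scaling$sd, "/")
  }
  set.seed(config$seed + 1L)
  state <- NULL
  hist <- list()
  best_acc <- -Inf
  best_params <- params
  stall <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    idx <- sample.int(n)
    for (b in split(idx, ceiling(seq_along(idx) / config$batch_size))) {
      lg <- loss_and_gradients(params, features[b, , drop = FALSE],
                               labels[b], training = TRUE)
      st <- sgd_momentum_step(params, state, lg$gradients, config)
      params <- st$params
      state <- st$state
    }
    # features already carry the scaling here, so bypass clfcnn_forward
    out <- clfcnn_forward_pass(params, features)$output
    acc <- mean((out >= config$threshold) == (labels == 1))
    loss <- mean((out - labels)^2)
    if (!is.null(val_features)) {
      vout <- clfcnn_forward_pass(params, val_features)$output
      val_acc <- mean((vout >= config$threshold) == (val_labels == 1))
      val_loss <- mean((vout - val_labels)^2)
    } else {
      val_acc <- NA_real_; val_loss <- NA_real_
    }
    hist[[epoch]] <- data.frame(epoch = epoch, acc = acc, loss = loss,
                                val_acc = val_acc, val_loss = val_loss)
    if (acc > best_acc) {
      best_acc <- acc
      best_params <- params
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  list(params = best_params, history = do.call(rbind, hist))
}

#' Predict window labels
#'
#' @param params Trained `clfcnn_params`.
#' @param features Samples x input_dim matrix (or one feature vector).
#' @param threshold Decision cutoff; defaults to the config's.
#' @return Integer labels (1 = seizure when the output reaches the
#'   threshold, else 0), in input order.
#' @export
clfcnn_predict <- function(params, features,
                           threshold = params$config$threshold) {
  as.integer(clfcnn_forward(params, features) >= threshold)
}

#' Shuffle, split, cross-validate and test
#'
#' Shuffles the dataset with `split_seed`, splits it 64/16/20 into
#' train/validation/test, runs an `n_folds`-fold rotation over the pooled
#' train+validation samples (each fold trained independently from a fresh
#' initialization), then retrains on the full pool and reports held-out test
#' metrics.
#'
#' @param features Samples x input_dim matrix.
#' @param labels 0/1 vector.
#' @param config A [clfcnn_config()].
#' @param n_folds Number of cross-validation folds.
#' @param split_seed Seed for the initial shuffle.
#' @return List with `fold_metrics` (one `metrics_report` per fold),
#'   `test_metrics`, `test_auc`, `params` (the final model) and `splits`
#'   (index vectors).
#' @export
split_and_crossvalidate <- function(features, labels,
                                    config = clfcnn_config(),
                                    n_folds = 5L, split_seed = 7L) {
  n <- nrow(features)
  stopifnot(n >= n_folds)
  set.seed(as.integer(split_seed))
  perm <- sample.int(n)
  n_train <- floor(0.64 * n)
  n_val <- floor(0.16 * n)
  train_idx <- perm[seq_len(n_train)]
  val_idx <- perm[n_train + seq_len(n_val)]
  test_idx <- perm[(n_train + n_val + 1L):n]
  pool <- c(train_idx, val_idx)
  folds <- split(pool, rep_len(seq_len(n_folds), length(pool)))
  fold_metrics <- lapply(folds, function(hold) {
    tr <- setdiff(pool, hold)
    if (length(unique(labels[hold])) < 2L)
      warning("a class is absent from a fold; metrics partially undefined")
    fit <- clfcnn_fit(features[tr, , drop = FALSE], labels[tr], config,
                      features[hold, , drop = FALSE], labels[hold])
    pred <- clfcnn_predict(fit$params, features[hold, , drop = FALSE])
    classification_metrics(confusion(labels[hold], pred))
  })
  final <- clfcnn_fit(features[pool, , drop = FALSE], labels[pool], config,
                      features[val_idx, , drop = FALSE], labels[val_idx])
  test_scores <- clfcnn_forward(final$params,
                                features[test_idx, , drop = FALSE])
  test_pred <- as.integer(test_scores >= config$threshold)
  test_metrics <- classification_metrics(confusion(labels[test_idx],
                                                   test_pred))
  test_auc <- if (length(unique(labels[test_idx])) == 2L)
    roc_auc(test_scores, labels[test_idx]) else NA_real_
  list(fold_metrics = fold_metrics, test_metrics = test_metrics,
       test_auc = test_auc, params = final$params,
       splits = list(train = train_idx, val = val_idx, test = test_idx))
}
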