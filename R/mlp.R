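logistic <- function(u) 1 / (1 + exp(-u))

#' Train a feedforward regression network on depth features
#'
#' A multilayer perceptron mapping flattened CIP-like feature stacks
#' (fixed channel order, see [flatten_stack()]) to shape parameters —
#' canonical superquadric parameters or Isomap coordinates. Hidden layers
#' use logistic activations; the output layer is linear, modeling the
#' drive to downstream cosine-tuned neurons. Weights are trained by
#' backpropagation (mini-batch gradient descent with adaptive moments) on
#' mean squared error, with early stopping on a held-out tenth of the
#' training data. Training is deterministic given `seed`.
#'
#' @param train_features numeric matrix, one shape per row.
#' @param train_targets numeric matrix (or vector), one shape per row.
#' @param layer_sizes full layer spec including input and output sizes;
#'   default `c(ncol(features), 600, 300, ncol(targets))`.
#' @param seed RNG seed (weight init, batch shuffling, holdout split).
#' @param schedule list of optimizer settings: `batch` (64), `epochs`
#'   (maximum, 200), `patience` (early-stopping, 10), `lr` (1e-3),
#'   `lr_decay` (per-epoch multiplier, 1 = constant), `holdout` (0.1).
#' @param standardize z-score inputs with training statistics (default
#'   TRUE; improves conditioning — raw mode available).
#' @param standardize_targets z-score targets internally during training
#'   and undo the scaling at prediction time (default TRUE; mirrors the
#'   input/output normalization common in neural-network toolboxes).
#' @return A `regression_net` with weights, biases, input scaling, and a
#'   `history` data frame (epoch, train and holdout loss, checkpoint
#'   flag).
#' @export
train_mlp <- function(train_features, train_targets, layer_sizes = NULL,
                      seed = 1L, schedule = list(), standardize = TRUE,
                      standardize_targets = TRUE) {
  X <- as.matrix(train_features)
  Y <- as.matrix(train_targets)
  if (any(!is.finite(X)) || any(!is.finite(Y)))
    stop("non-finite features or targets")
  stopifnot(nrow(X) == nrow(Y))
  sc <- utils::modifyList(list(batch = 64L, epochs = 200L, patience = 10L,
                               lr = 1e-3, lr_decay = 1, holdout = 0.1),
                          schedule)
  if (is.null(layer_sizes)) layer_sizes <- c(ncol(X), 600L, 300L, ncol(Y))
  stopifnot(layer_sizes[1] == ncol(X),
            layer_sizes[length(layer_sizes)] == ncol(Y))
  L <- length(layer_sizes) - 1L

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  mu <- colMeans(X); sg <- rep(1, ncol(X))
  if (standardize) {
    sg <- apply(X, 2L, stats::sd); sg[sg < 1e-12] <- 1
    X <- sweep(sweep(X, 2L, mu), 2L, sg, "/")
  } else {
    mu <- rep(0, ncol(X))
  }
  tmu <- rep(0, ncol(Y)); tsg <- rep(1, ncol(Y))
  if (standardize_targets) {
    tmu <- colMeans(Y)
    tsg <- apply(Y, 2L, stats::sd); tsg[tsg < 1e-12] <- 1
    Y <- sweep(sweep(Y, 2L, tmu), 2L, tsg, "/")
  }

  n <- nrow(X)
  n_hold <- max(1L, round(sc$holdout * n))
  hold <- sample.int(n, n_hold)
  tr <- setdiff(seq_len(n), hold)
  Xtr <- X[tr, , drop = FALSE]; Ytr <- Y[tr, , drop = FALSE]
  Xho <- X[hold, , drop = FALSE]; Yho <- Y[hold, , drop = FALSE]

  ## Glorot-uniform init; output bias at the target mean so training
  ## starts from the mean predictor
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    lim <- sqrt(6 / (layer_sizes[l] + layer_sizes[l + 1L]))
    W[[l]] <- matrix(stats::runif(layer_sizes[l] * layer_sizes[l + 1L],
                                  -lim, lim),
                     layer_sizes[l], layer_sizes[l + 1L])
    b[[l]] <- if (l == L) colMeans(Y) else numeric(layer_sizes[l + 1L])
  }

  forward <- function(Xb, W, b) {
    A <- vector("list", L + 1L); A[[1L]] <- Xb
    for (l in seq_len(L)) {
      Z <- sweep(A[[l]] %*% W[[l]], 2L, b[[l]], "+")
      A[[l + 1L]] <- if (l < L) logistic(Z) else Z
    }
    A
  }
  loss_of <- function(Xb, Yb, W, b) {
    P <- forward(Xb, W, b)[[L + 1L]]
    mean((P - Yb)^2)
  }

  ## Adam state
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L

  best <- list(W = W, b = b,
               loss = loss_of(Xho, Yho, W, b), epoch = 0L)
  history <- data.frame(epoch = 0L, train_loss = loss_of(Xtr, Ytr, W, b),
                        holdout_loss = best$loss, checkpoint = TRUE)
  wait <- 0L
  ntr <- nrow(Xtr)
  lr <- sc$lr
  for (ep in seq_len(sc$epochs)) {
    ord <- sample.int(ntr)
    for (start in seq(1L, ntr, by = sc$batch)) {
      idx <- ord[start:min(start + sc$batch - 1L, ntr)]
      A <- forward(Xtr[idx, , drop = FALSE], W, b)
      m <- length(idx)
      delta <- 2 * (A[[L + 1L]] - Ytr[idx, , drop = FALSE]) / (m * ncol(Y))
      step <- step + 1L
      cor1 <- 1 - beta1^step; cor2 <- 1 - beta2^step
      for (l in L:1) {
        gW <- crossprod(A[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L) {
          delta <- (delta %*% t(W[[l]])) * A[[l]] * (1 - A[[l]])
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        W[[l]] <- W[[l]] - lr * (mW[[l]] / cor1) /
          (sqrt(vW[[l]] / cor2) + eps)
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        b[[l]] <- b[[l]] - lr * (mb[[l]] / cor1) /
          (sqrt(vb[[l]] / cor2) + eps)
      }
    }
    ho_loss <- loss_of(Xho, Yho, W, b)
    improved <- ho_loss < best$loss - 1e-12
    if (improved) {
      best <- list(W = W, b = b, loss = ho_loss, epoch = ep)
      wait <- 0L
    } else wait <- wait + 1L
    lr <- lr * sc$lr_decay
    history <- rbind(history,
                     data.frame(epoch = ep,
                                train_loss = loss_of(Xtr, Ytr, W, b),
                                holdout_loss = ho_loss,
                                checkpoint = improved))
    if (wait >= sc$patience) break
  }
  structure(list(weights = best$W, biases = best$b,
                 layer_sizes = layer_sizes,
                 input_center = mu, input_scale = sg,
                 target_center = tmu, target_scale = tsg,
                 standardize = standardize,
                 history = history, seed = as.integer(seed),
                 schedule = sc, best_epoch = best$epoch),
            class = "regression_net")
}

#' Predict with a trained regression network
#'
#' @param object a `regression_net`.
#' @param newdata feature matrix (one shape per row).
#' @param ... unused.
#' @return matrix of predicted targets.
#' @export
predict.regression_net <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (object$standardize)
    X <- sweep(sweep(X, 2L, object$input_center), 2L,
               object$input_scale, "/")
  L <- length(object$weights)
  A <- X
  for (l in seq_len(L)) {
    Z <- sweep(A %*% object$weights[[l]], 2L, object$biases[[l]], "+")
    A <- if (l < L) logistic(Z) else Z
  }
  if (!is.null(object$target_scale))
    A <- sweep(sweep(A, 2L, object$target_scale, "*"), 2L,
               object$target_center, "+")
  A
}

#' Evaluate a network on held-out shapes
#'
#' Computes per-dimension scatter statistics (Pearson correlation and
#' regression slope of prediction on target), per-shape Euclidean error
#' in target space, the mean Euclidean error (the headline scalar), and
#' the normalized error (mean Euclidean error divided by the RMS norm of
#' the centered targets), which makes errors comparable across target
#' spaces of different scale and dimension.
#'
#' @param net a `regression_net`, any object with a `predict` method
#'   returning a target matrix, or a plain function of the feature
#'   matrix.
#' @param val_features validation features (disjoint from training).
#' @param val_targets validation targets.
#' @param target_space tag recorded in the report (e.g.
#'   `"superquadric-9"`, `"isomap-8"`).
#' @return An `eval_report`: `per_dimension` (correlation, slope),
#'   `per_shape_error`, `mean_error`, `median_error`,
#'   `normalized_error`, `target_space`.
#' @export
evaluate_net <- function(net, val_features, val_targets,
                         target_space = "unknown") {
  Y <- as.matrix(val_targets)
  P <- if (is.function(net)) net(val_features)
       else stats::predict(net, val_features)
  stopifnot(all(dim(P) == dim(Y)))
  per_dim <- data.frame(
    dimension = seq_len(ncol(Y)),
    correlation = vapply(seq_len(ncol(Y)), function(j) {
      if (stats::sd(Y[, j]) < 1e-14 || stats::sd(P[, j]) < 1e-14) 0
      else stats::cor(P[, j], Y[, j])
    }, numeric(1)),
    slope = vapply(seq_len(ncol(Y)), function(j) {
      vy <- stats::var(Y[, j])
      if (vy < 1e-20) 0 else stats::cov(P[, j], Y[, j]) / vy
    }, numeric(1)))
  per_shape <- sqrt(rowSums((P - Y)^2))
  Yc <- sweep(Y, 2L, colMeans(Y))
  rms_norm <- sqrt(mean(rowSums(Yc^2)))
  structure(list(per_dimension = per_dim,
                 per_shape_error = per_shape,
                 mean_error = mean(per_shape),
                 median_error = stats::median(per_shape),
                 normalized_error = mean(per_shape) / rms_norm,
                 target_space = target_space,
                 predictions = P),
            class = "eval_report")
}

#' LIF population alternative to the backprop network
#'
#' A hidden layer of cosine-tuned LIF neurons with random preferred
#' directions over local receptive-field patches of the feature grid,
#' decoded by regularized least squares ([fit_decoders()]). More neurons
#' give better decodes; fully optimized multilayer perceptrons reach
#' similar accuracy with fewer units.
#'
#' @param features training feature matrix (flattened stacks, channel
#'   blocks of `n_grid^2` values).
#' @param targets training target matrix.
#' @param n_neurons hidden-layer size.
#' @param kernel_spec list: `patch` (patch side in grid cells, default
#'   3), `n_grid` (default 16), `n_channels` (default
#'   `ncol(features) / n_grid^2`).
#' @param seed RNG seed.
#' @param reg decoder regularization fraction (default 0.1).
#' @return An `nef_population`: encoder matrix, gains, biases, LIF
#'   constants, decoders. Predict with [predict.nef_population()].
#' @export
train_nef_population <- function(features, targets, n_neurons = 1000L,
                                 kernel_spec = list(), seed = 1L,
                                 reg = 0.1) {
  X <- as.matrix(features); Y <- as.matrix(targets)
  ks <- utils::modifyList(list(patch = 3L, n_grid = 16L,
                               n_channels = NULL), kernel_spec)
  if (is.null(ks$n_channels)) ks$n_channels <- ncol(X) %/% (ks$n_grid^2)
  stopifnot(ks$n_channels * ks$n_grid^2 == ncol(X))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  ng <- ks$n_grid; p <- ks$patch
  E <- matrix(0, n_neurons, ncol(X))
  for (i in seq_len(n_neurons)) {
    chan <- sample.int(ks$n_channels, 1L)
    r0 <- sample.int(ng - p + 1L, 1L); c0 <- sample.int(ng - p + 1L, 1L)
    dir <- stats::rnorm(p * p)
    dir <- dir / sqrt(sum(dir^2))
    idx <- as.vector(outer((r0:(r0 + p - 1L)),
                           (c0:(c0 + p - 1L) - 1L) * ng, "+")) +
      (chan - 1L) * ng * ng
    E[i, idx] <- dir
  }
  drive <- X %*% t(E)                      # n_samples x n_neurons
  radius <- apply(abs(drive), 2L, stats::quantile, 0.95)
  radius[radius < 1e-12] <- 1
  a <- sweep(drive, 2L, radius, "/")       # normalized projections
  tau_rc <- 0.02; tau_ref <- 0.005
  max_rate <- stats::runif(n_neurons, 100, 200)
  intercept <- stats::runif(n_neurons, -0.9, 0.9)
  I_max <- 1 / (1 - exp((tau_ref - 1 / max_rate) / tau_rc))
  alpha <- (I_max - 1) / (1 - intercept)
  bias <- 1 - alpha * intercept
  rates <- lif_rate(sweep(sweep(a, 2L, alpha, "*"), 2L, bias, "+"),
                    tau_ref, tau_rc)
  rates <- matrix(rates, nrow(X), n_neurons)
  dec <- fit_decoders(rates, Y, reg = reg)
  structure(list(encoders = E, radius = radius, alpha = alpha,
                 bias = bias, tau_rc = tau_rc, tau_ref = tau_ref,
                 decoders = dec, kernel_spec = ks,
                 seed = as.integer(seed)),
            class = "nef_population")
}

#' @rdname train_nef_population
#' @param object an `nef_population`.
#' @param newdata feature matrix.
#' @param ... unused.
#' @export
predict.nef_population <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  a <- sweep(X %*% t(object$encoders), 2L, object$radius, "/")
  I <- sweep(sweep(a, 2L, object$alpha, "*"), 2L, object$bias, "+")
  rates <- matrix(lif_rate(I, object$tau_ref, object$tau_rc),
                  nrow(X), length(object$alpha))
  decode(object$decoders, rates)
}
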