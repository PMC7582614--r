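#' Configuration for the fully connected SBP/DBP regressor
#'
#' Defaults mirror the full-scale architecture: 32 standardized
#' morphological features feeding four ReLU hidden layers of width
#' 2048/4096/8192/2048 and a linear 2-unit output (SBP, DBP in mmHg),
#' trained with the Nadam optimizer on mini-batches of 512 under a
#' 70/20/10 train/test/validation split. Hidden widths are configurable so
#' desk-scale experiments can use small networks; training hyperparameters
#' that the architecture leaves open (learning rate, epoch budget, early
#' stopping) are explicit here so runs are reproducible.
#'
#' @param input_dim Number of input features.
#' @param hidden_widths Integer vector of hidden-layer widths.
#' @param activation Hidden activation; only `"relu"` is implemented.
#' @param batch_size Mini-batch size (default 512).
#' @param optimizer Only `"nadam"` is implemented.
#' @param learning_rate Nadam step size (default 1e-3).
#' @param beta1,beta2,epsilon Nadam moment decay rates and stabilizer.
#' @param max_epochs Epoch budget (default 500); 0 returns initial weights.
#' @param patience Early-stopping patience on validation RMSE (default 10).
#' @param split_fractions Train/test/validation fractions summing to 1.
#' @param seed Integer seed for initialization and batch shuffling.
#' @return List of class `regressor_config`.
#' @export
regressor_config <- function(input_dim = 32,
                             hidden_widths = c(2048, 4096, 8192, 2048),
                             activation = "relu",
                             batch_size = 512,
                             optimizer = "nadam",
                             learning_rate = 1e-3,
                             beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7,
                             max_epochs = 500,
                             patience = 10,
                             split_fractions = c(train = 0.7, test = 0.2,
                                                 validation = 0.1),
                             seed = 1L) {
  if (any(hidden_widths <= 0)) stop("hidden widths must be positive")
  if (abs(sum(split_fractions) - 1) > 1e-8)
    stop("split fractions must sum to 1")
  if (!identical(tolower(activation), "relu"))
    stop("only the ReLU activation is implemented")
  if (!identical(tolower(optimizer), "nadam"))
    stop("only the Nadam optimizer is implemented")
  structure(list(
    input_dim = as.integer(input_dim),
    hidden_widths = as.integer(hidden_widths),
    activation = "relu", batch_size = as.integer(batch_size),
    optimizer = "nadam", learning_rate = learning_rate,
    beta1 = beta1, beta2 = beta2, epsilon = epsilon,
    max_epochs = as.integer(max_epochs), patience = as.integer(patience),
    split_fractions = split_fractions, seed = as.integer(seed)
  ), class = "regressor_config")
}

#' Shuffle and split a dataset into train/test/validation parts
#'
#' Rows are shuffled by the seed and split into disjoint, exhaustive parts
#' whose sizes are within one row of `fractions * n`.
#'
#' @param features Feature matrix (n rows).
#' @param labels Label matrix/vector with matching rows.
#' @param fractions Length-3 fractions (train, test, validation) summing
#'   to 1.
#' @param seed Integer seed.
#' @return List of three lists (`train`, `test`, `validation`), each with
#'   `features`, `labels` and the original row `indices`.
#' @export
split_dataset <- function(features, labels,
                          fractions = c(0.7, 0.2, 0.1), seed = 1L) {
  features <- as.matrix(features)
  labels <- as.matrix(labels)
  n <- nrow(features)
  if (n < 10) stop("need at least 10 rows to split")
  if (nrow(labels) != n) stop("features and labels disagree on row count")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  n1 <- round(fractions[1] * n)
  n2 <- round(fractions[2] * n)
  if (n1 + n2 > n) n2 <- n - n1
  idx <- list(train = perm[seq_len(n1)],
              test = if (n2 > 0) perm[n1 + seq_len(n2)] else integer(0),
              validation = if (n1 + n2 < n) perm[(n1 + n2 + 1):n] else integer(0))
  lapply(idx, function(i)
    list(features = features[i, , drop = FALSE],
         labels = labels[i, , drop = FALSE], indices = i))
}

# He-initialized network; output bias optionally preset to label means
.init_network <- function(config, output_bias = c(0, 0)) {
  widths <- c(config$input_dim, config$hidden_widths, 2L)
  L <- length(widths) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- widths[l]
    sdev <- if (l < L) sqrt(2 / fan_in) else sqrt(1 / fan_in)
    W[[l]] <- matrix(rnorm(fan_in * widths[l + 1L], 0, sdev),
                     fan_in, widths[l + 1L])
    b[[l]] <- if (l < L) rep(0, widths[l + 1L]) else as.numeric(output_bias)
  }
  structure(list(W = W, b = b, widths = widths), class = "mlp_network")
}

#' Forward pass of the fully connected network
#'
#' Each layer computes `act(X W + b)`: ReLU on hidden layers, identity on
#' the 2-unit output layer.
#'
#' @param network An `mlp_network` (e.g. `fit$network` from
#'   [train_regressor()]).
#' @param x Numeric matrix (rows = observations) or a single row vector,
#'   already on the scale the network was trained on.
#' @return Numeric matrix with one row per observation and columns
#'   `SBP`, `DBP`.
#' @export
mlp_forward <- function(network, x) {
  stopifnot(inherits(network, "mlp_network"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != network$widths[1])
    stop("input has ", ncol(x), " columns; network expects ",
         network$widths[1])
  A <- x
  L <- length(network$W)
  for (l in seq_len(L)) {
    Z <- A %*% network$W[[l]] +
      matrix(network$b[[l]], nrow(A), ncol(network$W[[l]]), byrow = TRUE)
    A <- if (l < L) pmax(Z, 0) else Z
  }
  colnames(A) <- c("SBP", "DBP")
  A
}

# forward with cached pre-activations for backprop
.forward_cache <- function(network, x) {
  L <- length(network$W)
  As <- vector("list", L + 1L); As[[1]] <- x
  Zs <- vector("list", L)
  for (l in seq_len(L)) {
    Zs[[l]] <- As[[l]] %*% network$W[[l]] +
      matrix(network$b[[l]], nrow(x), ncol(network$W[[l]]), byrow = TRUE)
    As[[l + 1L]] <- if (l < L) pmax(Zs[[l]], 0) else Zs[[l]]
  }
  list(As = As, Zs = Zs)
}

.rmse_mat <- function(truth, est) sqrt(mean((est - truth)^2))
.mae_mat <- function(truth, est) mean(abs(est - truth))

#' Train the regressor with Nadam
#'
#' Standardizes the training features (parameters stored for prediction
#' time), initializes the network (He initialization, output bias at the
#' training-label means) and minimizes the mean squared error over the
#' 2-dimensional output by mini-batch gradient descent with the Nadam
#' update (Adam with Nesterov momentum). RMSE is monitored and MAE
#' reported per epoch on the training and validation sets; the weights
#' from the best validation epoch are retained, with early stopping after
#' `patience` epochs without improvement. MSE is used as the training
#' objective because it shares its optimum with RMSE while giving stabler
#' gradients.
#'
#' @param config A [regressor_config()].
#' @param train,validation Lists with `features` and `labels` (as produced
#'   by [split_dataset()]); labels in mmHg, columns SBP/DBP.
#' @param verbose Print per-epoch losses.
#' @return Object of class `trained_regressor`: list with `network`,
#'   `config`, `center`/`scale` (fit-time standardization), `history`
#'   (per-epoch data frame) and `best_epoch`.
#' @export
train_regressor <- function(config, train, validation = NULL,
                            verbose = FALSE) {
  stopifnot(inherits(config, "regressor_config"))
  X <- as.matrix(train$features); Y <- as.matrix(train$labels)
  if (ncol(X) != config$input_dim)
    stop("training features have ", ncol(X), " columns; config expects ",
         config$input_dim)
  if (anyNA(X) || anyNA(Y)) stop("training data contain NAs; drop ",
                                 "incomplete cycles first")
  std <- standardize_features(X)
  Xs <- std$x
  has_val <- !is.null(validation) && nrow(as.matrix(validation$features)) > 0
  if (has_val) {
    Xv <- standardize_features(as.matrix(validation$features),
                               center = std$center, scale = std$scale)$x
    Yv <- as.matrix(validation$labels)
  }

  set.seed(config$seed)
  net <- .init_network(config, output_bias = colMeans(Y))
  if (config$max_epochs == 0) {
    return(structure(list(network = net, config = config,
                          center = std$center, scale = std$scale,
                          history = data.frame(), best_epoch = 0L),
                     class = "trained_regressor"))
  }

  L <- length(net$W)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(b) b * 0); vb <- mb
  b1 <- config$beta1; b2 <- config$beta2; eps <- config$epsilon
  lr <- config$learning_rate
  step <- 0L
  n <- nrow(Xs)
  best_val <- Inf; best_net <- net; best_epoch <- 0L; wait <- 0L
  hist <- vector("list", config$max_epochs)

  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(n)
    nb <- ceiling(n / config$batch_size)
    for (bi in seq_len(nb)) {
      rows <- perm[((bi - 1L) * config$batch_size + 1L):
                     min(bi * config$batch_size, n)]
      xb <- Xs[rows, , drop = FALSE]; yb <- Y[rows, , drop = FALSE]
      fc <- .forward_cache(net, xb)
      P <- fc$As[[L + 1L]]
      if (anyNA(P) || any(!is.finite(P)))
        stop("NaN/Inf loss at epoch ", epoch,
             "; try a smaller learning rate")
      delta <- 2 * (P - yb) / length(yb)
      step <- step + 1L
      for (l in rev(seq_len(L))) {
        gW <- crossprod(fc$As[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L)
          delta <- (delta %*% t(net$W[[l]])) * (fc$Zs[[l - 1L]] > 0)
        # Nadam: Adam moments with a Nesterov-style lookahead on the mean
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
        mhat <- mW[[l]] / (1 - b1^(step + 1L))
        vhat <- vW[[l]] / (1 - b2^step)
        net$W[[l]] <- net$W[[l]] - lr *
          (b1 * mhat + (1 - b1) * gW / (1 - b1^step)) / (sqrt(vhat) + eps)
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
        mbh <- mb[[l]] / (1 - b1^(step + 1L))
        vbh <- vb[[l]] / (1 - b2^step)
        net$b[[l]] <- net$b[[l]] - lr *
          (b1 * mbh + (1 - b1) * gb / (1 - b1^step)) / (sqrt(vbh) + eps)
      }
    }
    Pt <- mlp_forward(net, Xs)
    row <- data.frame(epoch = epoch,
                      train_rmse = .rmse_mat(Y, Pt),
                      train_mae = .mae_mat(Y, Pt),
                      val_rmse = NA_real_, val_mae = NA_real_)
    if (has_val) {
      Pv <- mlp_forward(net, Xv)
      row$val_rmse <- .rmse_mat(Yv, Pv)
      row$val_mae <- .mae_mat(Yv, Pv)
      if (row$val_rmse < best_val - 1e-9) {
        best_val <- row$val_rmse; best_net <- net
        best_epoch <- epoch; wait <- 0L
      } else wait <- wait + 1L
    } else {
      best_net <- net; best_epoch <- epoch
    }
    hist[[epoch]] <- row
    if (verbose)
      message(sprintf("epoch %3d  train RMSE %.3f  val RMSE %s", epoch,
                      row$train_rmse,
                      if (has_val) sprintf("%.3f", row$val_rmse) else "-"))
    if (has_val && wait >= config$patience) break
  }
  structure(list(network = best_net, config = config,
                 center = std$center, scale = std$scale,
                 history = do.call(rbind, hist[!vapply(hist, is.null, TRUE)]),
                 best_epoch = best_epoch),
            class = "trained_regressor")
}

#' Predict SBP/DBP for new feature rows
#'
#' Applies the standardization stored at fit time, then the forward pass.
#'
#' @param object A `trained_regressor`.
#' @param newdata Feature matrix (raw scale) or single row.
#' @param ... Unused.
#' @return Matrix with columns `SBP` and `DBP` in mmHg.
#' @export
predict.trained_regressor <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$config$input_dim)
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         object$config$input_dim)
  xs <- sweep(sweep(newdata, 2, object$center, "-"), 2, object$scale, "/")
  mlp_forward(object$network, xs)
}

#' @export
print.trained_regressor <- function(x, ...) {
  cat(sprintf("<trained_regressor> widths %s, best epoch %d\n",
              paste(x$network$widths, collapse = "-"), x$best_epoch))
  if (nrow(x$history) > 0) {
    last <- x$history[which.min(x$history$val_rmse), ]
    cat(sprintf("  best val RMSE %.3f mmHg (epoch %d)\n",
                last$val_rmse, last$epoch))
  }
  invisible(x)
}
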