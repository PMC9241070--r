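# The convolutional-recurrent site classifier: configuration, parameter
# initialisation, training via the compiled backpropagation loop, and the S3
# modelling interface.

.CLASSES <- c("physiological", "adventitious")

#' Network architecture configuration
#'
#' The exact architecture hyperparameters are configurable defaults of this
#' package, not fixed constants of the method: a width-`filter_width` 1-D
#' convolution over the residue axis, a unidirectional gated recurrent (GRU)
#' layer read out at the final hidden state, and a linear layer with two
#' output neurons.
#'
#' @param filter_width Odd convolution width w (default 7).
#' @param conv_channels Convolution output channels (default 64).
#' @param hidden GRU hidden size (default 128).
#' @return Object of class `mbs_net_config`.
#' @export
mbs_net_config <- function(filter_width = 7, conv_channels = 64,
                           hidden = 128) {
  stopifnot(filter_width >= 1, filter_width %% 2 == 1,
            conv_channels >= 1, hidden >= 1)
  structure(list(filter_width = as.integer(filter_width),
                 conv_channels = as.integer(conv_channels),
                 hidden = as.integer(hidden),
                 output_classes = 2L), class = "mbs_net_config")
}

#' Training configuration
#'
#' @param class_weight Weight multiplying the physiological-class
#'   contribution to the cross-entropy (default 1.7, compensating the
#'   physiological/adventitious imbalance).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param max_epochs Maximum training epochs (default 50).
#' @param patience Early-stopping patience on validation loss (default 8).
#' @param batch_size Sites per gradient step (default 32).
#' @param weight_decay Decoupled L2 weight decay applied to the weight
#'   matrices (default 1e-3).
#' @param l1_input Proximal L1 penalty on the input (convolution) layer
#'   (default 0.4).  Inputs without a persistent gradient signal get exactly
#'   zero first-layer weights, making the network provably blind to
#'   uninformative features.
#' @param input_noise Denoising-augmentation level: at every training
#'   presentation each input column receives Gaussian noise with standard
#'   deviation `input_noise` times that column's empirical domain magnitude
#'   (max - min over the training data; default 0.15).  This acts as an
#'   adaptive ridge, proportional to each feature's domain, that drives the
#'   first-layer weights of uninformative input columns toward zero, so
#'   the network does not latch onto noise idiosyncrasies of individual
#'   features.
#' @param threshold Classification threshold beta on the physiological
#'   probability (default 0.5; a site is called physiological iff
#'   p > threshold, strictly).
#' @param validation_fraction Stratified fraction held out for early
#'   stopping when no explicit validation set is given (default 0.1).
#' @return Object of class `mbs_train_control`.
#' @export
mbs_train_control <- function(class_weight = 1.7, learning_rate = 1e-3,
                              max_epochs = 50, patience = 8,
                              batch_size = 32, threshold = 0.5,
                              validation_fraction = 0.1,
                              weight_decay = 1e-3, l1_input = 0.4,
                              input_noise = 0.15) {
  stopifnot(class_weight > 0, learning_rate > 0, max_epochs >= 1,
            patience >= 1, patience <= max_epochs,
            threshold >= 0, threshold <= 1,
            validation_fraction > 0, validation_fraction < 1,
            weight_decay >= 0, l1_input >= 0, input_noise >= 0)
  structure(list(class_weight = class_weight, learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 threshold = threshold,
                 validation_fraction = validation_fraction,
                 weight_decay = weight_decay, l1_input = l1_input,
                 input_noise = input_noise),
            class = "mbs_train_control")
}

# Glorot-uniform initialisation drawn from the R RNG (reproducible under
# set.seed)
.init_params <- function(n_in, config) {
  gl <- function(nr, nc) {
    s <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -s, s), nr, nc)
  }
  ch <- config$conv_channels
  hid <- config$hidden
  w <- config$filter_width
  list(Wc = gl(ch, w * n_in), bc = numeric(ch),
       Wz = gl(hid, ch), Uz = gl(hid, hid), bz = numeric(hid),
       Wr = gl(hid, ch), Ur = gl(hid, hid), br = numeric(hid),
       Wn = gl(hid, ch), Un = gl(hid, hid), bn = numeric(hid),
       Wo = gl(2, hid), bo = numeric(2),
       filter_width = w)
}

.encode_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), .CLASSES)
  if (length(bad) > 0)
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  ifelse(labels == "physiological", 0L, 1L)   # 0 = positive class
}

#' Fit the convolutional-recurrent site classifier
#'
#' Trains the conv -> GRU -> linear network on labelled L x 29 feature
#' matrices with class-weighted cross-entropy, per-site processing of
#' variable-length inputs, and early stopping on a validation set (restoring
#' the best-validation-loss parameters).
#'
#' @param x A labelled `site_dataset`, or a list of L x 29 matrices (then
#'   `y` is required).
#' @param y Labels (`"physiological"`/`"adventitious"`); `NULL` when `x` is
#'   a labelled dataset.
#' @param validation Optional validation set (same forms as `x`); when
#'   `NULL`, a stratified `validation_fraction` of `x` is held out.
#' @param validation_y Labels for `validation` when it is not a dataset.
#' @param config Architecture, see [mbs_net_config()].
#' @param control Training settings, see [mbs_train_control()].
#' @param seed Optional integer; when given, `set.seed(seed)` is called
#'   before initialisation so the whole trajectory is reproducible.
#' @return Object of class `mbsnet` with `params`, loss histories,
#'   `best_epoch`, and the configurations used.
#' @export
mbsnet <- function(x, y = NULL, validation = NULL, validation_y = NULL,
                   config = mbs_net_config(), control = mbs_train_control(),
                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- .as_matrix_list(x)
  lab <- .labels_of(x, y)
  stopifnot(length(X) == length(lab))
  yy <- .encode_labels(lab)
  n_in <- ncol(X[[1]])
  if (any(vapply(X, ncol, 1L) != n_in))
    stop("all feature matrices must have the same number of columns")

  if (is.null(validation)) {
    idx_val <- .stratified_holdout(yy, control$validation_fraction)
    Xval <- X[idx_val]; yval <- yy[idx_val]
    X <- X[-idx_val]; yy <- yy[-idx_val]
  } else {
    Xval <- .as_matrix_list(validation)
    yval <- .encode_labels(.labels_of(validation, validation_y))
  }
  if (length(unique(yy)) < 2)
    stop("training data must contain both classes")

  # fixed feature-type scaling: the accessibility columns (Angstrom^2 and
  # percent) are divided by 100 so all inputs share the order-one scale of
  # the frequency and one-hot columns.  The divisors are stored in the
  # model and re-applied at prediction time, so the public interface stays
  # in the raw feature domain.
  center <- numeric(n_in)
  scale <- rep(1, n_in)
  nm <- colnames(X[[1]])
  if (!is.null(nm)) scale[nm %in% c("abs_sasa", "rel_sasa")] <- 100
  X <- lapply(X, .standardise, center, scale)
  Xval <- lapply(Xval, .standardise, center, scale)

  params <- .init_params(n_in, config)
  ord <- t(vapply(seq_len(control$max_epochs),
                  function(e) sample.int(length(X)),
                  integer(length(X))))
  # per-column augmentation scale: fraction of the empirical domain
  rng_lo <- Reduce(pmin, lapply(X, function(m) apply(m, 2, min)))
  rng_hi <- Reduce(pmax, lapply(X, function(m) apply(m, 2, max)))
  col_noise <- control$input_noise * (rng_hi - rng_lo)
  fit <- .nn_train(params, X, yy, Xval, yval, ord,
                   control$class_weight, control$learning_rate,
                   control$max_epochs, control$patience,
                   control$batch_size, control$weight_decay,
                   control$l1_input, col_noise,
                   sample.int(.Machine$integer.max, 1))
  structure(list(params = fit$params, config = config, control = control,
                 classes = .CLASSES,
                 center = center, scale = scale,
                 n_features = n_in,
                 feature_names = colnames(X[[1]]),
                 train_loss = fit$train_loss, val_loss = fit$val_loss,
                 best_epoch = fit$best_epoch, epochs_run = fit$epochs_run,
                 n_train = length(X), n_validation = length(Xval),
                 call = match.call()), class = "mbsnet")
}

.standardise <- function(m, center, scale) {
  sweep(sweep(m, 2, center), 2, scale, "/")
}

.stratified_holdout <- function(y, fraction) {
  idx <- unlist(lapply(unique(y), function(cl) {
    members <- which(y == cl)
    n <- max(1L, round(length(members) * fraction))
    sample(members, n)
  }))
  sort(idx)
}

#' Predict method for mbsnet models
#'
#' @param object A fitted `mbsnet`.
#' @param newdata A `site_dataset`, list of matrices, or single matrix.
#' @param threshold Classification threshold beta (default: the model's
#'   training threshold).  Physiological iff `p_physiological > threshold`.
#' @param ... Unused.
#' @return Data frame with `site_id`, `p_physiological`, `p_adventitious`,
#'   `confidence` (absolute difference of the two probabilities), and
#'   `class`.
#' @export
predict.mbsnet <- function(object, newdata, threshold = NULL, ...) {
  if (is.null(threshold)) threshold <- object$control$threshold
  X <- .as_matrix_list(newdata)
  if (any(vapply(X, ncol, 1L) != object$n_features))
    stop("feature count mismatch: model expects ", object$n_features,
         " columns")
  X <- lapply(X, .standardise, object$center, object$scale)
  pr <- .nn_predict(object$params, X)
  data.frame(site_id = .site_ids_of(newdata, length(X)),
             p_physiological = pr[, 1],
             p_adventitious = pr[, 2],
             confidence = abs(pr[, 1] - pr[, 2]),
             class = ifelse(pr[, 1] > threshold, "physiological",
                            "adventitious"),
             stringsAsFactors = FALSE)
}

#' Convolutional encoding of a site
#'
#' Runs only the convolutional stage: each output row is a nonlinear
#' function of the width-w window centred on the residue (zero-padded at
#' the ends, so sequence length is preserved).
#'
#' @param object A fitted `mbsnet` (or a raw parameter list).
#' @param s L x n feature matrix.
#' @return L x conv_channels matrix S'.
#' @export
conv_encode <- function(object, s) {
  p <- if (inherits(object, "mbsnet")) object$params else object
  s <- as.matrix(s)
  if (nrow(s) < 1) stop("cannot encode a zero-length site")
  if (inherits(object, "mbsnet"))
    s <- .standardise(s, object$center, object$scale)
  .nn_conv_forward(p, s)
}

#' Recurrent encoding of a convolved sequence
#'
#' Single forward GRU pass over S', returning only the final hidden state
#' h_L, the fixed-size global representation of the site.
#'
#' @param object A fitted `mbsnet` (or a raw parameter list).
#' @param sprime L x conv_channels matrix from [conv_encode()].
#' @return Numeric vector h_L.
#' @export
recurrent_encode <- function(object, sprime) {
  p <- if (inherits(object, "mbsnet")) object$params else object
  sprime <- as.matrix(sprime)
  if (nrow(sprime) < 1) stop("cannot encode a zero-length sequence")
  as.numeric(.nn_gru_encoded(p, sprime))
}

#' Class probabilities from a hidden state
#'
#' Applies the linear output layer and softmax to h_L, yielding the
#' two-class probability vector, the confidence, and the assigned class at
#' threshold beta.
#'
#' @param object A fitted `mbsnet` (or a raw parameter list).
#' @param h Hidden-state vector h_L.
#' @param threshold Classification threshold beta (default 0.4).
#' @return List with `p_physiological`, `p_adventitious`, `confidence`,
#'   `class`.
#' @export
classify_hidden <- function(object, h, threshold = 0.5) {
  p <- if (inherits(object, "mbsnet")) object$params else object
  logits <- as.numeric(p$Wo %*% h + p$bo)
  e <- exp(logits - max(logits))
  pr <- e / sum(e)
  list(p_physiological = pr[1], p_adventitious = pr[2],
       confidence = abs(pr[1] - pr[2]),
       class = if (pr[1] > threshold) "physiological" else "adventitious")
}

#' @export
print.mbsnet <- function(x, ...) {
  cat("Conv-GRU metal-binding-site classifier\n")
  cat(sprintf("  conv: width %d, %d channels | GRU hidden: %d | classes: 2\n",
              x$config$filter_width, x$config$conv_channels,
              x$config$hidden))
  cat(sprintf("  trained on %d sites (%d validation), best epoch %d/%d\n",
              x$n_train, x$n_validation, x$best_epoch, x$epochs_run))
  cat(sprintf("  best validation loss: %.4f\n", min(x$val_loss)))
  invisible(x)
}

#' @export
summary.mbsnet <- function(object, ...) {
  print(object)
  np <- sum(vapply(object$params[names(object$params) != "filter_width"],
                   length, 1L))
  cat(sprintf("  parameters: %d | class weight: %.2f | lr: %g | beta: %.2f\n",
              np, object$control$class_weight,
              object$control$learning_rate, object$control$threshold))
  cat(sprintf("  loss trajectory (val): %s\n",
              paste(sprintf("%.3f", object$val_loss), collapse = " ")))
  invisible(object)
}

#' @export
coef.mbsnet <- function(object, ...) object$params

#' @export
plot.mbsnet <- function(x, ...) {
  ep <- seq_along(x$train_loss)
  graphics::plot(ep, x$train_loss, type = "l", col = "steelblue",
                 xlab = "epoch", ylab = "weighted cross-entropy",
                 ylim = range(c(x$train_loss, x$val_loss)), ...)
  graphics::lines(ep, x$val_loss, col = "firebrick")
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("training", "validation"),
                   col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}
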