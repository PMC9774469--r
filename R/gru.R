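# From-scratch gated-recurrent-unit regressor for DOE tables.
#
# Gate equations (no bias terms):
#   r_t = sigmoid(Wr h_{t-1} + Ur x_t)
#   h~  = tanh(W (r_t * h_{t-1}) + U x_t)
#   z_t = sigmoid(Wz h_{t-1} + Uz x_t)
#   h_t = (1 - z_t) * h_{t-1} + z_t * h~
# Each design run is a length-1 sequence whose input is the coded factor
# triple; prediction is a linear readout of h_1 from h_0 = 0.

sigmoid <- function(x) 1 / (1 + exp(-x))

# evaluate expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' GRU training hyperparameters
#'
#' Defaults are the published settings for the conversion surrogate: 50
#' hidden units, gradient-norm threshold 0.1, initial learning rate 0.01
#' dropped by a factor of 0.2 every 100 epochs, 150 training epochs.
#'
#' @param n_hidden Hidden-state width (positive integer).
#' @param gradient_threshold Global gradient-norm clip, in (0, 1].
#' @param initial_lr Initial learning rate, in (0, 1].
#' @param lr_drop_factor Multiplicative learning-rate drop, in (0, 1].
#' @param lr_drop_period Epochs between drops (positive integer).
#' @param epochs Number of full-batch epochs (positive integer).
#' @param seed Integer seed for weight initialization.
#' @return A list of class `gru_hyperparams`.
#' @export
gru_hyperparams <- function(n_hidden = 50, gradient_threshold = 0.1,
                            initial_lr = 0.01, lr_drop_factor = 0.2,
                            lr_drop_period = 100, epochs = 150, seed = 1) {
  stopifnot(n_hidden >= 1, n_hidden == round(n_hidden),
            gradient_threshold > 0, gradient_threshold <= 1,
            initial_lr > 0, initial_lr <= 1,
            lr_drop_factor > 0, lr_drop_factor <= 1,
            lr_drop_period >= 1, lr_drop_period == round(lr_drop_period),
            epochs >= 1, epochs == round(epochs))
  structure(list(n_hidden = as.integer(n_hidden),
                 gradient_threshold = gradient_threshold,
                 initial_lr = initial_lr, lr_drop_factor = lr_drop_factor,
                 lr_drop_period = as.integer(lr_drop_period),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "gru_hyperparams")
}

#' Learning-rate step schedule
#'
#' `initial_lr * lr_drop_factor^floor(epoch / lr_drop_period)` with `epoch`
#' counted from 0, so the default schedule is 0.01 for epochs 0--99 and
#' 0.002 for epochs 100--149.
#'
#' @param hp A [gru_hyperparams()].
#' @param epoch Zero-based epoch index (vectorized).
#' @return Learning rate(s).
#' @export
lr_schedule <- function(hp, epoch) {
  hp$initial_lr * hp$lr_drop_factor^floor(epoch / hp$lr_drop_period)
}

#' Initialize GRU weights
#'
#' Gate and candidate matrices are drawn uniformly from
#' `(-1/sqrt(n_hidden), +1/sqrt(n_hidden))` with a private seeded RNG stream
#' (draw order Wr, Ur, Wz, Uz, W, U); the readout vector starts at zero with
#' offset `offset_init`. `y_center`/`y_scale` hold the response
#' standardization applied during training (identity until trained), so
#' predictions are always in raw % units.
#'
#' @param n_hidden Hidden width.
#' @param n_input Input width (3 coded factors).
#' @param seed Integer seed.
#' @param offset_init Initial readout offset on the standardized scale.
#' @return A list of class `gru_weights` with elements `Wr`, `Ur`, `Wz`,
#'   `Uz`, `W`, `U` (matrices), `v` (readout vector), `offset`, `y_center`,
#'   `y_scale`, `n_hidden`, `n_input`.
#' @export
gru_init <- function(n_hidden = 50, n_input = 3, seed = 1, offset_init = 0) {
  s <- 1 / sqrt(n_hidden)
  with_seed(seed, {
    rmat <- function(r, c) matrix(stats::runif(r * c, -s, s), r, c)
    w <- list(Wr = rmat(n_hidden, n_hidden), Ur = rmat(n_hidden, n_input),
              Wz = rmat(n_hidden, n_hidden), Uz = rmat(n_hidden, n_input),
              W = rmat(n_hidden, n_hidden), U = rmat(n_hidden, n_input),
              v = rep(0, n_hidden), offset = offset_init,
              y_center = 0, y_scale = 1,
              n_hidden = as.integer(n_hidden), n_input = as.integer(n_input))
    class(w) <- "gru_weights"
    w
  })
}

check_gru_shapes <- function(x, h_prev, w) {
  if (length(x) != w$n_input) {
    stop("input width ", length(x), " does not match n_input ", w$n_input,
         call. = FALSE)
  }
  if (length(h_prev) != w$n_hidden) {
    stop("hidden width ", length(h_prev), " does not match n_hidden ",
         w$n_hidden, call. = FALSE)
  }
}

#' One GRU cell step
#'
#' Applies the bias-free gate equations to a single input vector and the
#' previous hidden state, returning every intermediate gate activation.
#'
#' @param x Input vector (length `n_input`).
#' @param h_prev Previous hidden state (length `n_hidden`).
#' @param w A `gru_weights` object.
#' @return A list of class `gate_trace`: `rt`, `zt` (each elementwise in
#'   (0,1)), `h_tilde` (in (-1,1)), `ht = (1-zt)*h_prev + zt*h_tilde`.
#' @export
gru_cell_step <- function(x, h_prev, w) {
  check_gru_shapes(x, h_prev, w)
  rt <- sigmoid(as.vector(w$Wr %*% h_prev + w$Ur %*% x))
  h_tilde <- tanh(as.vector(w$W %*% (rt * h_prev) + w$U %*% x))
  zt <- sigmoid(as.vector(w$Wz %*% h_prev + w$Uz %*% x))
  ht <- (1 - zt) * h_prev + zt * h_tilde
  structure(list(rt = rt, zt = zt, h_tilde = h_tilde, ht = ht),
            class = "gate_trace")
}

# batch forward on the standardized scale; X is n x n_input, h0 = 0
gru_forward_batch <- function(X, w) {
  h0 <- matrix(0, nrow(X), w$n_hidden)
  R <- sigmoid(h0 %*% t(w$Wr) + X %*% t(w$Ur))
  Htil <- tanh((R * h0) %*% t(w$W) + X %*% t(w$U))
  Z <- sigmoid(h0 %*% t(w$Wz) + X %*% t(w$Uz))
  H <- (1 - Z) * h0 + Z * Htil
  list(pred = as.vector(H %*% w$v) + w$offset,
       H = H, Htil = Htil, Z = Z, R = R, h0 = h0)
}

#' Predict conversion for coded factor settings
#'
#' One cell step from a zero hidden state on the length-1 sequence formed by
#' the coded triple, followed by the linear readout; the stored response
#' standardization is undone so the result is in raw %.
#'
#' @param run A coded triple, or an n x 3 matrix of coded triples.
#' @param w A `gru_weights` object.
#' @return Predicted conversion(s), %.
#' @export
gru_forward <- function(run, w) {
  X <- rbind(run)
  if (ncol(X) != w$n_input) stop("input width mismatch", call. = FALSE)
  gru_forward_batch(X, w)$pred * w$y_scale + w$y_center
}

# mean-squared-error loss and full analytic gradient on the standardized
# scale; exposed for gradient verification
gru_loss_grad <- function(w, X, y_std) {
  n <- nrow(X)
  h0 <- matrix(0, n, w$n_hidden)
  Ar <- h0 %*% t(w$Wr) + X %*% t(w$Ur); R <- sigmoid(Ar)
  Rh <- R * h0
  Ah <- Rh %*% t(w$W) + X %*% t(w$U); Htil <- tanh(Ah)
  Az <- h0 %*% t(w$Wz) + X %*% t(w$Uz); Z <- sigmoid(Az)
  H <- (1 - Z) * h0 + Z * Htil
  pred <- as.vector(H %*% w$v) + w$offset
  e <- pred - y_std
  loss <- mean(e^2)
  gpred <- 2 * e / n
  gH <- outer(gpred, w$v)
  gZ <- gH * (Htil - h0)
  gHtil <- gH * Z
  gAz <- gZ * Z * (1 - Z)
  gAh <- gHtil * (1 - Htil^2)
  gRh <- gAh %*% w$W
  gR <- gRh * h0
  gAr <- gR * R * (1 - R)
  grad <- list(
    Wr = t(gAr) %*% h0, Ur = t(gAr) %*% X,
    Wz = t(gAz) %*% h0, Uz = t(gAz) %*% X,
    W = t(gAh) %*% Rh, U = t(gAh) %*% X,
    v = as.vector(t(H) %*% gpred), offset = sum(gpred)
  )
  list(loss = loss, grad = grad, pred = pred)
}

GRU_PARAM_NAMES <- c("Wr", "Ur", "Wz", "Uz", "W", "U", "v", "offset")

# global L2 norm over all parameter gradients
grad_global_norm <- function(g) sqrt(sum(vapply(g[GRU_PARAM_NAMES],
                                                function(x) sum(x^2), 0)))

clip_gradient <- function(g, threshold) {
  gn <- grad_global_norm(g)
  if (gn > threshold) {
    g[GRU_PARAM_NAMES] <- lapply(g[GRU_PARAM_NAMES],
                                 function(x) x * threshold / gn)
  }
  g
}

#' Train the GRU surrogate on a design table
#'
#' Full-batch Adam on the mean-squared error of the standardized response,
#' with the gradient vector globally norm-clipped at
#' `hp$gradient_threshold` before the Adam update and the step-decay
#' learning-rate schedule of [lr_schedule()]. Responses are standardized to
#' zero mean and unit variance for optimization (the printed clip threshold
#' and learning rates are on that scale); the standardization is stored in
#' the weights and undone at prediction time. Training is deterministic
#' given `(seed, hyperparameters, table)`.
#'
#' @param table A `design_table` with responses (>= 2 runs).
#' @param hp A [gru_hyperparams()].
#' @return A list of class `gru_fit`: `weights` (`gru_weights`), `trace`
#'   (`data.frame` with `epoch` (1-based), `lr`, `loss` — the standardized
#'   MSE before that epoch's update).
#' @export
gru_train <- function(table, hp = gru_hyperparams()) {
  y <- table$conversion_pct
  if (any(is.na(y))) stop("design table has missing responses", call. = FALSE)
  if (length(y) < 2L) stop("need at least 2 runs to train", call. = FALSE)
  X <- coded_matrix(table)
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  y_std <- (y - y_center) / y_scale
  w <- gru_init(hp$n_hidden, ncol(X), hp$seed, offset_init = mean(y_std))
  w$y_center <- y_center
  w$y_scale <- y_scale
  # Adam state
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  m <- lapply(w[GRU_PARAM_NAMES], function(x) x * 0)
  v2 <- m
  trace <- data.frame(epoch = seq_len(hp$epochs), lr = NA_real_,
                      loss = NA_real_)
  for (ep in seq_len(hp$epochs)) {
    lr <- lr_schedule(hp, ep - 1)
    lg <- gru_loss_grad(w, X, y_std)
    if (!is.finite(lg$loss)) {
      stop("training diverged (non-finite loss) at epoch ", ep, call. = FALSE)
    }
    trace$lr[ep] <- lr
    trace$loss[ep] <- lg$loss
    g <- clip_gradient(lg$grad, hp$gradient_threshold)
    for (nm in GRU_PARAM_NAMES) {
      m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g[[nm]]
      v2[[nm]] <- b2 * v2[[nm]] + (1 - b2) * g[[nm]]^2
      mhat <- m[[nm]] / (1 - b1^ep)
      vhat <- v2[[nm]] / (1 - b2^ep)
      w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  structure(list(weights = w, trace = trace, hyperparams = hp),
            class = "gru_fit")
}

#' @export
print.gru_fit <- function(x, ...) {
  cat(sprintf("<gru_fit> %d hidden units, %d epochs, final loss %.4g (standardized MSE)\n",
              x$weights$n_hidden, nrow(x$trace), x$trace$loss[nrow(x$trace)]))
  invisible(x)
}

#' Score GRU predictions on a design table
#'
#' @param table A `design_table` with responses.
#' @param w `gru_weights` (or a `gru_fit`).
#' @return A list: `predictions` (`data.frame` with `run_id`, `actual`,
#'   `predicted`) and `metrics` (a [score_metrics()] report).
#' @export
gru_score <- function(table, w) {
  if (inherits(w, "gru_fit")) w <- w$weights
  pred <- gru_forward(coded_matrix(table), w)
  list(predictions = data.frame(run_id = table$run_id,
                                actual = table$conversion_pct,
                                predicted = pred),
       metrics = score_metrics(table$conversion_pct, pred))
}

#' Serialize / restore GRU weights as JSON
#'
#' Matrices are stored row-major with shape metadata alongside the response
#' standardization, so a restored model predicts identically.
#'
#' @param w A `gru_weights` object.
#' @param file Path to a JSON file.
#' @export
write_gru_json <- function(w, file) {
  obj <- list(n_hidden = w$n_hidden, n_input = w$n_input,
              y_center = w$y_center, y_scale = w$y_scale,
              offset = w$offset, v = w$v)
  for (nm in c("Wr", "Ur", "Wz", "Uz", "W", "U")) {
    obj[[nm]] <- list(dim = dim(w[[nm]]), data = as.vector(t(w[[nm]])))
  }
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_gru_json
#' @export
read_gru_json <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  w <- list(n_hidden = as.integer(obj$n_hidden),
            n_input = as.integer(obj$n_input),
            y_center = obj$y_center, y_scale = obj$y_scale,
            offset = obj$offset, v = obj$v)
  for (nm in c("Wr", "Ur", "Wz", "Uz", "W", "U")) {
    d <- obj[[nm]]$dim
    w[[nm]] <- matrix(obj[[nm]]$data, d[1], d[2], byrow = TRUE)
  }
  class(w) <- "gru_weights"
  w
}
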