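#' Ensemble of feed-forward regression networks
#'
#' Trains `n_members` independent networks that differ only in their random
#' seed (weight initialisation, internal validation split and batch order),
#' the deep-ensemble recipe used for uncertainty quantification: the
#' ensemble mean is the prediction and the member spread its uncertainty.
#' Each member has ReLU hidden layers, a linear output, and is trained with
#' the Adam optimiser on mean-squared error with early stopping on an
#' internal validation split. Inputs and the target are z-scored with
#' training-set statistics stored in the object.
#'
#' A member whose loss goes non-finite is retrained with a fresh derived
#' seed (up to 3 retries).
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y numeric target vector.
#' @param n_members number of ensemble members (default 20).
#' @param hidden integer vector of hidden-layer widths (default `c(128, 128)`).
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size minibatch size (default 32).
#' @param max_epochs epoch cap (default 2000).
#' @param patience early-stopping patience in epochs (default 50).
#' @param val_frac internal validation fraction (default 0.1).
#' @param seed master seed; member seeds are derived deterministically.
#' @return object of class `ff_ensemble`.
#' @export
ff_ensemble <- function(X, y, n_members = 20L, hidden = c(128L, 128L),
                        lr = 1e-3, batch_size = 32L, max_epochs = 2000L,
                        patience = 50L, val_frac = 0.1, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), nrow(X) >= 5L, all(is.finite(X)), all(is.finite(y)))
  x_mean <- colMeans(X)
  x_sd <- apply(X, 2L, stats::sd)
  x_sd[x_sd < 1e-12] <- 1
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd < 1e-12) y_sd <- 1
  Xs <- sweep(sweep(X, 2L, x_mean), 2L, x_sd, "/")
  ys <- (y - y_mean) / y_sd

  members <- vector("list", n_members)
  for (i in seq_len(n_members)) {
    fit <- NULL
    for (try in 0:3) {
      member_seed <- (seed + 7919L * i + 104729L * try) %% 2147483647L
      fit <- .mlp_fit(Xs, ys, as.integer(hidden), lr, as.integer(batch_size),
                      as.integer(max_epochs), as.integer(patience),
                      val_frac, as.integer(member_seed))
      if (isTRUE(fit$ok)) break
    }
    if (!isTRUE(fit$ok)) {
      stop(sprintf("ensemble member %d failed to train after 3 retries (%s)",
                   i, fit$reason))
    }
    members[[i]] <- fit
  }
  structure(list(members = members, n_members = as.integer(n_members),
                 hidden = as.integer(hidden),
                 x_mean = x_mean, x_sd = x_sd, y_mean = y_mean, y_sd = y_sd,
                 seed = as.integer(seed), n_train = nrow(X)),
            class = "ff_ensemble")
}

#' @export
print.ff_ensemble <- function(x, ...) {
  val <- vapply(x$members, `[[`, numeric(1), "best_val_loss")
  cat(sprintf("<ff_ensemble> %d members, hidden [%s], trained on %d samples; median val MSE %.3e\n",
              x$n_members, paste(x$hidden, collapse = ", "), x$n_train,
              stats::median(val) * x$y_sd^2))
  invisible(x)
}

#' Predict from a network ensemble
#'
#' @param object a [ff_ensemble()].
#' @param newdata numeric matrix of features (rows = samples).
#' @param ... unused.
#' @return list with `mean`, `std` (unbiased member standard deviation;
#'   identically 0 for a single member), `members` (samples x members
#'   matrix) and `extrapolation` (logical per sample: any feature more than
#'   3 training standard deviations from the training mean).
#' @export
predict.ff_ensemble <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  Xs <- sweep(sweep(X, 2L, object$x_mean), 2L, object$x_sd, "/")
  M <- vapply(object$members,
              function(m) as.numeric(.mlp_predict(m$W, m$b, Xs)),
              numeric(nrow(Xs)))
  M <- matrix(M, nrow = nrow(Xs)) * object$y_sd + object$y_mean
  extrap <- apply(abs(Xs) > 3, 1L, any)
  list(mean = rowMeans(M),
       std = if (ncol(M) > 1L) apply(M, 1L, stats::sd) else rep(0, nrow(M)),
       members = M,
       extrapolation = extrap)
}

#' Training diagnostics of an ensemble
#'
#' @param object a [ff_ensemble()].
#' @return data.frame with per-member best epoch, epochs run and best
#'   validation loss (target scale).
#' @export
ensemble_history <- function(object) {
  stopifnot(inherits(object, "ff_ensemble"))
  data.frame(
    member = seq_len(object$n_members),
    best_epoch = vapply(object$members, `[[`, numeric(1), "best_epoch"),
    epochs_run = vapply(object$members, `[[`, numeric(1), "epochs_run"),
    val_mse = vapply(object$members, `[[`, numeric(1), "best_val_loss") * object$y_sd^2)
}
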