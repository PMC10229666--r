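# Linear autoencoder: a single linear map to a low-dimensional latent space
# and a linear map back (through a sigmoid under the cross-entropy loss),
# trained by full-batch gradient descent. The latent coordinates are the
# substrate for Gaussian-mixture consensus clustering.

#' Configure the autoencoder
#'
#' @param latent_dim Latent dimension (default 16).
#' @param epochs Training epochs (default 500).
#' @param learning_rate Initial gradient-descent step (default 0.5; the step
#'   is halved whenever an epoch would increase the loss, so the recorded
#'   loss trace is non-increasing).
#' @param loss `"bernoulli_cross_entropy"` (sigmoid decoder, default) or
#'   `"squared_error"` (linear decoder).
#' @param seed Seed for the parameter initialization stream.
#' @return A list of class `mds_embed_config`.
#' @export
embedding_config <- function(latent_dim = 16L, epochs = 500L,
                             learning_rate = 0.5,
                             loss = c("bernoulli_cross_entropy",
                                      "squared_error"),
                             seed = 1L) {
  loss <- match.arg(loss)
  check_scalar_number(latent_dim, "latent_dim", 1)
  check_scalar_number(epochs, "epochs", 1)
  check_scalar_number(learning_rate, "learning_rate", 1e-12)
  structure(list(latent_dim = as.integer(latent_dim),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, loss = loss,
                 seed = as.integer(seed)),
            class = "mds_embed_config")
}

ae_loss <- function(X, params, loss) {
  Z <- sweep(X %*% params$W1, 2L, params$b1, "+")
  A <- sweep(Z %*% params$W2, 2L, params$b2, "+")
  if (loss == "bernoulli_cross_entropy") {
    Y <- stats::plogis(A)
    eps <- 1e-12
    -mean(X * log(Y + eps) + (1 - X) * log(1 - Y + eps))
  } else {
    mean((A - X)^2)
  }
}

ae_gradients <- function(X, params, loss) {
  n <- nrow(X); p <- ncol(X)
  Z <- sweep(X %*% params$W1, 2L, params$b1, "+")
  A <- sweep(Z %*% params$W2, 2L, params$b2, "+")
  delta <- if (loss == "bernoulli_cross_entropy") {
    (stats::plogis(A) - X) / (n * p)
  } else {
    2 * (A - X) / (n * p)
  }
  dZ <- delta %*% t(params$W2)
  list(W2 = crossprod(Z, delta), b2 = colSums(delta),
       W1 = crossprod(X, dZ), b1 = colSums(dZ))
}

#' Fit the linear autoencoder embedding
#'
#' Learns a `latent_dim`-dimensional linear embedding of a binary feature
#' matrix: encoder `Z = X W1 + b1`, decoder `sigmoid(Z W2 + b2)` under
#' Bernoulli cross-entropy (or a linear decoder under squared error).
#' Training is full-batch gradient descent from a seeded scaled-uniform
#' initialization; whenever a step would increase the loss it is retried
#' with a halved step, so the loss trace is monotone non-increasing and the
#' fit is deterministic given the seed.
#'
#' @param features A `mds_features` tibble (from [encode_features()]) or a
#'   numeric 0/1 matrix with row names.
#' @param config An [embedding_config()].
#' @return An object of class `mds_embedding` with elements `coordinates`
#'   (n x latent_dim matrix), `patient_ids`, `loss_trace`, `params`,
#'   `feature_names`, `config`.
#' @examples
#' coh <- simulate_cohort(preset_mds_like(), n_patients = 60, seed = 1)
#' X <- encode_features(coh)
#' emb <- fit_autoencoder(X, embedding_config(latent_dim = 4, epochs = 50))
#' dim(emb$coordinates)
#' @export
fit_autoencoder <- function(features, config = embedding_config()) {
  X <- if (is.matrix(features)) features else as_feature_matrix(features)
  n <- nrow(X); p <- ncol(X)
  if (config$latent_dim > p) {
    abort("`latent_dim` must not exceed the number of features.")
  }
  if (nrow(unique(X)) < 2L) {
    abort("feature matrix is degenerate: fewer than 2 distinct rows.")
  }
  d <- config$latent_dim

  params <- with_seed(substream_seed(config$seed, "ae-init"), {
    a1 <- sqrt(6 / (p + d)); a2 <- sqrt(6 / (d + p))
    list(W1 = matrix(runif(p * d, -a1, a1), p, d),
         b1 = rep(0, d),
         W2 = matrix(runif(d * p, -a2, a2), d, p),
         b2 = rep(0, p))
  })

  lr <- config$learning_rate
  trace <- numeric(config$epochs)
  current <- ae_loss(X, params, config$loss)
  for (epoch in seq_len(config$epochs)) {
    g <- ae_gradients(X, params, config$loss)
    repeat {
      cand <- list(W1 = params$W1 - lr * g$W1, b1 = params$b1 - lr * g$b1,
                   W2 = params$W2 - lr * g$W2, b2 = params$b2 - lr * g$b2)
      cand_loss <- ae_loss(X, cand, config$loss)
      if (!is.finite(cand_loss)) {
        if (lr < 1e-12) {
          abort(sprintf(
            "autoencoder training diverged (non-finite loss at epoch %d, learning rate %g).",
            epoch, lr))
        }
        lr <- lr / 2
        next
      }
      if (cand_loss <= current || lr < 1e-12) break
      lr <- lr / 2
    }
    params <- cand
    current <- cand_loss
    trace[epoch] <- current
    lr <- min(lr * 1.05, 100 * config$learning_rate)  # regrow after success
  }
  if (!all(is.finite(trace))) {
    abort("autoencoder training produced a non-finite loss trace.")
  }

  coords <- sweep(X %*% params$W1, 2L, params$b1, "+")
  rownames(coords) <- rownames(X)
  colnames(coords) <- paste0("Z", seq_len(d))
  structure(list(coordinates = coords, patient_ids = rownames(X),
                 loss_trace = trace, params = params,
                 feature_names = colnames(X), config = config),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat("<mds_embedding> ", nrow(x$coordinates), " patients x ",
      ncol(x$coordinates), " latent dims; final loss ",
      signif(x$loss_trace[length(x$loss_trace)], 5), "\n", sep = "")
  invisible(x)
}

#' Encode new patients with a fitted embedding
#'
#' Applies the stored linear encoder to a new binary feature matrix whose
#' columns must match the training features exactly (no refitting).
#'
#' @param object A `mds_embedding`.
#' @param newdata A `mds_features` tibble or 0/1 matrix with the training
#'   feature columns.
#' @param ... Unused.
#' @return n x latent_dim coordinate matrix.
#' @export
predict.mds_embedding <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else as_feature_matrix(newdata)
  if (!identical(colnames(X), object$feature_names)) {
    abort("`newdata` columns do not match the training feature names.")
  }
  coords <- sweep(X %*% object$params$W1, 2L, object$params$b1, "+")
  colnames(coords) <- colnames(object$coordinates)
  coords
}

#' @method tidy mds_embedding
#' @export
tidy.mds_embedding <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$coordinates))
  dplyr::bind_cols(tibble::tibble(patient_id = x$patient_ids), out)
}

#' @method glance mds_embedding
#' @export
glance.mds_embedding <- function(x, ...) {
  tibble::tibble(n = nrow(x$coordinates),
                 latent_dim = ncol(x$coordinates),
                 epochs = length(x$loss_trace),
                 initial_loss = x$loss_trace[1],
                 final_loss = x$loss_trace[length(x$loss_trace)])
}

#' Plot the autoencoder training loss trace
#'
#' @param object A `mds_embedding`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mds_embedding
#' @export
autoplot.mds_embedding <- function(object, ...) {
  df <- tibble::tibble(epoch = seq_along(object$loss_trace),
                       loss = object$loss_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "reconstruction loss",
                  title = "Autoencoder training loss") +
    ggplot2::theme_minimal()
}
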