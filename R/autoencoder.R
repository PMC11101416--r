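#' Derive a stacked-encoder architecture from input and latent size
#'
#' Hidden widths start at the largest power of two below the input dimension
#' (capped at `max_width`) and halve until the next halving would reach the
#' bottleneck, with at most three hidden layers. Hidden layers use ReLU, the
#' bottleneck is linear, and the decoder mirrors the encoder with a sigmoid
#' output layer (matching data scaled to `[0, 1]`).
#'
#' @param input_dim number of input features.
#' @param latent_dim bottleneck width.
#' @param max_width cap on the first hidden layer (default 1024).
#' @return an `encoder_spec` with fields `input_dim`, `hidden_widths`,
#'   `latent_dim`, `hidden_activation`, `final_activation`.
#' @examples
#' build_encoder_spec(335854, 256)$hidden_widths  # 1024, 512
#' build_encoder_spec(512, 256)$hidden_widths     # none: single-layer encoder
#' @export
build_encoder_spec <- function(input_dim, latent_dim, max_width = 1024) {
  if (latent_dim >= input_dim) {
    abort(sprintf(paste0("latent_dim (%d) must be below input_dim (%d); ",
                         "pad the assay with pad_features() first"),
                  latent_dim, input_dim),
          class = "tensoromics_must_pad")
  }
  w <- min(max_width, 2^floor(log2(max(input_dim - 1, 1))))
  widths <- integer(0)
  while (w > latent_dim && length(widths) < 3) {
    widths <- c(widths, w)
    w <- w %/% 2
  }
  structure(list(input_dim = as.integer(input_dim),
                 hidden_widths = as.integer(widths),
                 latent_dim = as.integer(latent_dim),
                 hidden_activation = "relu",
                 final_activation = "sigmoid"),
            class = "encoder_spec")
}

#' Autoencoder training hyperparameters
#'
#' Defaults follow the pipeline's standard regime: Adam, learning rate 0.001,
#' 10 epochs, minibatches of 128.
#'
#' @param learning_rate Adam step size.
#' @param epochs full passes over the training data.
#' @param batch_size minibatch size.
#' @param seed integer seed controlling initialization and shuffling.
#' @return a `train_hyper` list.
#' @export
train_hyper <- function(learning_rate = 0.001, epochs = 10, batch_size = 128,
                        seed = 1L) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1)
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_hyper")
}

activate <- function(x, act) {
  switch(act,
         relu = pmax(x, 0),
         sigmoid = 1 / (1 + exp(-x)),
         linear = x,
         abort(paste0("unknown activation: ", act)))
}

activate_grad <- function(pre, post, act) {
  switch(act,
         relu = (pre > 0) * 1,
         sigmoid = post * (1 - post),
         linear = array(1, dim(pre)),
         abort(paste0("unknown activation: ", act)))
}

ae_layer_dims <- function(spec) {
  enc <- c(spec$input_dim, spec$hidden_widths, spec$latent_dim)
  dec <- c(spec$latent_dim, rev(spec$hidden_widths), spec$input_dim)
  n_enc <- length(enc) - 1
  acts <- c(rep("relu", length(spec$hidden_widths)), "linear",
            rep("relu", length(spec$hidden_widths)), "sigmoid")
  list(dims_in = c(enc[-length(enc)], dec[-length(dec)]),
       dims_out = c(enc[-1], dec[-1]),
       acts = acts, n_encoder = n_enc)
}

ae_init_layers <- function(spec) {
  ld <- ae_layer_dims(spec)
  map(seq_along(ld$acts), function(i) {
    fan_in <- ld$dims_in[i]
    lim <- 1 / sqrt(fan_in)
    list(W = matrix(runif(fan_in * ld$dims_out[i], -lim, lim), fan_in),
         b = rep(0, ld$dims_out[i]),
         act = ld$acts[i])
  })
}

ae_forward <- function(layers, X, upto = length(layers)) {
  H <- X
  pre <- post <- vector("list", upto)
  for (i in seq_len(upto)) {
    Z <- H %*% layers[[i]]$W
    Z <- sweep(Z, 2, layers[[i]]$b, "+")
    H <- activate(Z, layers[[i]]$act)
    pre[[i]] <- Z
    post[[i]] <- H
  }
  list(out = H, pre = pre, post = post)
}

adam_state <- function(layers) {
  map(layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                               mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(par, grad, st, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), st = st)
}

#' Train a stacked autoencoder on one assay
#'
#' Minimizes the mean squared error between input and reconstruction with
#' Adam, recording the mean training loss per epoch. Weight initialization is
#' uniform fan-in; given the same data, spec and seed the fitted weights are
#' bit-identical across runs.
#'
#' @param m omics tibble, already imputed and min-max scaled to `[0, 1]`.
#' @param spec an [build_encoder_spec()] result.
#' @param hyper a [train_hyper()].
#' @return a `trained_autoencoder` holding the layer weights, the training
#'   history (tibble `epoch`, `train_loss`; epoch 0 is the pre-training loss),
#'   the feature names and the spec.
#' @export
train_autoencoder <- function(m, spec, hyper = train_hyper()) {
  check_omics(m)
  X <- omics_values(m)
  if (anyNA(X)) abort("training data contains missing values; impute first",
                      class = "tensoromics_schema_error")
  if (ncol(X) != spec$input_dim) {
    abort(sprintf("matrix has %d features but spec expects %d", ncol(X), spec$input_dim),
          class = "tensoromics_schema_error")
  }
  n <- nrow(X)
  withr::with_seed(hyper$seed, {
    layers <- ae_init_layers(spec)
    states <- map(layers, function(l) list(
      W = list(m = l$W * 0, v = l$W * 0),
      b = list(m = l$b * 0, v = l$b * 0)))
    loss0 <- mean((ae_forward(layers, X)$out - X)^2)
    history <- tibble(epoch = 0L, train_loss = loss0)
    t_step <- 0
    for (epoch in seq_len(hyper$epochs)) {
      ord <- sample.int(n)
      batch_losses <- c()
      for (start in seq(1, n, by = hyper$batch_size)) {
        idx <- ord[start:min(start + hyper$batch_size - 1, n)]
        Xb <- X[idx, , drop = FALSE]
        fw <- ae_forward(layers, Xb)
        loss <- mean((fw$out - Xb)^2)
        if (!is.finite(loss)) {
          abort(sprintf("training diverged at epoch %d (non-finite loss)", epoch),
                class = "tensoromics_training_diverged")
        }
        batch_losses <- c(batch_losses, loss)
        t_step <- t_step + 1
        # backprop
        delta <- 2 * (fw$out - Xb) / length(Xb)
        for (i in rev(seq_along(layers))) {
          dz <- delta * activate_grad(fw$pre[[i]], fw$post[[i]], layers[[i]]$act)
          input_i <- if (i == 1) Xb else fw$post[[i - 1]]
          gW <- crossprod(input_i, dz)
          gb <- colSums(dz)
          delta <- dz %*% t(layers[[i]]$W)
          upW <- adam_step(layers[[i]]$W, gW, states[[i]]$W, hyper$learning_rate, t_step)
          layers[[i]]$W <- upW$par; states[[i]]$W <- upW$st
          upb <- adam_step(layers[[i]]$b, gb, states[[i]]$b, hyper$learning_rate, t_step)
          layers[[i]]$b <- upb$par; states[[i]]$b <- upb$st
        }
      }
      history <- bind_rows(history, tibble(epoch = epoch,
                                           train_loss = mean(batch_losses)))
    }
    structure(list(spec = spec, hyper = hyper, layers = layers,
                   feature_names = colnames(X),
                   n_encoder = ae_layer_dims(spec)$n_encoder,
                   assay = assay_name(m), history = history),
              class = "trained_autoencoder")
  })
}

#' @export
print.trained_autoencoder <- function(x, ...) {
  cat(sprintf("<trained_autoencoder> assay=%s  %d -> [%s] -> %d\n",
              x$assay %||% "?", x$spec$input_dim,
              paste(x$spec$hidden_widths, collapse = ", "), x$spec$latent_dim))
  cat(sprintf("  final train MSE: %.5f (epoch %d)\n",
              tail(x$history$train_loss, 1), tail(x$history$epoch, 1)))
  invisible(x)
}

# encoder forward pass on a bare matrix (rows = samples)
encode_matrix <- function(model, X) {
  ae_forward(model$layers, X, upto = model$n_encoder)$out
}

#' Encode an assay into its latent block
#'
#' @param model a [train_autoencoder()] result.
#' @param m omics tibble with the same features (names and order) as the
#'   training matrix.
#' @return a latent tibble: `sample_id` plus `latent_1 .. latent_d'`, with the
#'   assay name preserved in the `"assay"` attribute.
#' @export
encode <- function(model, m) {
  check_omics(m)
  if (!identical(omics_features(m), model$feature_names)) {
    abort("feature names/order differ from the training matrix",
          class = "tensoromics_schema_error")
  }
  X <- omics_values(m)
  H <- if (nrow(X) == 0) matrix(0, 0, model$spec$latent_dim) else encode_matrix(model, X)
  out <- new_omics_tbl(H, m$sample_id, paste0("latent_", seq_len(ncol(H))),
                       model$assay %||% assay_name(m))
  out
}

#' Select the bottleneck width by k-fold cross-validation
#'
#' Trains one autoencoder per candidate latent size on each fold and returns
#' the candidate with the lowest mean validation MSE; ties break toward the
#' smaller latent. Candidates at or above the input dimension are skipped
#' with a warning.
#'
#' @param m training omics tibble (scaled).
#' @param candidates integer vector of latent sizes, e.g. `c(64, 128, 256, 512)`.
#' @param folds number of CV folds (>= 2).
#' @param hyper a [train_hyper()].
#' @param max_width first-hidden-layer cap passed to [build_encoder_spec()].
#' @return the selected latent size, with the CV table (candidate, mean
#'   validation MSE) in attribute `"cv_table"`.
#' @export
select_latent_size <- function(m, candidates, folds = 10, hyper = train_hyper(),
                               max_width = 1024) {
  if (length(candidates) == 0) abort("candidates must be nonempty",
                                     class = "tensoromics_invalid_spec")
  if (folds < 2) abort("folds must be >= 2", class = "tensoromics_invalid_spec")
  d <- length(omics_features(m))
  valid <- candidates[candidates < d]
  if (length(valid) < length(candidates)) {
    warn(sprintf("skipping %d candidate(s) >= input dimension %d",
                 length(candidates) - length(valid), d))
  }
  if (length(valid) == 0) abort("no valid latent-size candidate below input dim",
                                class = "tensoromics_no_valid_candidate")
  X <- omics_values(m)
  n <- nrow(X)
  fold_id <- withr::with_seed(derive_seed(hyper$seed, "cvfolds"),
                              sample(rep(seq_len(folds), length.out = n)))
  cv <- map_dbl(valid, function(cand) {
    spec <- build_encoder_spec(d, cand, max_width)
    mean(map_dbl(seq_len(folds), function(f) {
      tr <- new_omics_tbl(X[fold_id != f, , drop = FALSE],
                          m$sample_id[fold_id != f], colnames(X), assay_name(m))
      model <- train_autoencoder(tr, spec, hyper)
      Xv <- X[fold_id == f, , drop = FALSE]
      mean((ae_forward(model$layers, Xv)$out - Xv)^2)
    }))
  })
  best <- valid[order(cv, valid)][1]
  attr(best, "cv_table") <- tibble(latent_dim = valid, cv_mse = cv)
  best
}

# gradient of one latent coordinate with respect to the input, evaluated at
# each row of X; returns a matrix of the same shape as X
encoder_input_gradient <- function(model, X, latent_index) {
  upto <- model$n_encoder
  fw <- ae_forward(model$layers, X, upto = upto)
  delta <- matrix(0, nrow(X), model$spec$latent_dim)
  delta[, latent_index] <- 1
  for (i in rev(seq_len(upto))) {
    dz <- delta * activate_grad(fw$pre[[i]], fw$post[[i]], model$layers[[i]]$act)
    delta <- dz %*% t(model$layers[[i]]$W)
  }
  delta
}

#' Export an autoencoder training history as CSV
#'
#' @param model a `trained_autoencoder`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_training_history <- function(model, path) {
  readr::write_csv(model$history, path)
  invisible(path)
}
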