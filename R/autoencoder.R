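# Multilayer perceptron machinery and the stacked autoencoder used to
# initialize the embedding.  Written directly on BLAS matrix products:
# the networks here are small (a few dense layers) and the whole
# clustering phase needs gradients injected at the bottleneck, so a
# self-contained implementation keeps the training loop transparent and
# deterministic.

act_fun <- function(a, type) {
  switch(type,
         relu = pmax(a, 0),
         tanh = tanh(a),
         linear = a,
         stop("unknown activation: ", type, call. = FALSE))
}

# derivative wrt pre-activation, expressed with the post-activation value
act_deriv <- function(post, type) {
  switch(type,
         relu = (post > 0) * 1,
         tanh = 1 - post^2,
         linear = array(1, dim(post)),
         stop("unknown activation: ", type, call. = FALSE))
}

# Glorot-uniform initialized dense layer
new_layer <- function(n_in, n_out, activation) {
  lim <- sqrt(6 / (n_in + n_out))
  list(W = matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out),
       b = numeric(n_out), activation = activation)
}

# forward pass keeping per-layer outputs for backprop
mlp_forward <- function(layers, x) {
  outs <- vector("list", length(layers) + 1L)
  outs[[1L]] <- x
  for (l in seq_along(layers)) {
    a <- sweep(outs[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
    outs[[l + 1L]] <- act_fun(a, layers[[l]]$activation)
  }
  outs
}

# backward pass from d(loss)/d(output); returns per-layer W and b grads
mlp_backward <- function(layers, outs, dout) {
  grads <- vector("list", length(layers))
  delta <- dout
  for (l in rev(seq_along(layers))) {
    delta <- delta * act_deriv(outs[[l + 1L]], layers[[l]]$activation)
    grads[[l]] <- list(W = crossprod(outs[[l]], delta),
                       b = colSums(delta))
    if (l > 1L) delta <- delta %*% t(layers[[l]]$W)
  }
  grads
}

# in-place SGD-with-momentum step; velocity list mutated by the caller
sgd_step <- function(layers, grads, vel, lr, momentum) {
  for (l in seq_along(layers)) {
    vel[[l]]$W <- momentum * vel[[l]]$W - lr * grads[[l]]$W
    vel[[l]]$b <- momentum * vel[[l]]$b - lr * grads[[l]]$b
    layers[[l]]$W <- layers[[l]]$W + vel[[l]]$W
    layers[[l]]$b <- layers[[l]]$b + vel[[l]]$b
  }
  list(layers = layers, vel = vel)
}

zero_velocity <- function(layers) {
  lapply(layers, function(l) list(W = array(0, dim(l$W)),
                                  b = numeric(length(l$b))))
}

mse <- function(a, b) mean((a - b)^2)

# minibatch training of an MLP against a fixed target matrix (MSE loss),
# with an early plateau stop on the epoch-level training loss
train_mlp <- function(layers, x, y, epochs, lr = 0.01, momentum = 0.9,
                      batch_size = 256, noise_sd = 0,
                      plateau_rel = 1e-4, patience = 10, what = "layer") {
  n <- nrow(x)
  vel <- zero_velocity(layers)
  losses <- numeric(0)
  stale <- 0L
  if (epochs > 0) for (e in seq_len(epochs)) {
    perm <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      if (noise_sd > 0) {
        xb <- xb + matrix(stats::rnorm(length(xb), 0, noise_sd),
                          nrow(xb), ncol(xb))
      }
      outs <- mlp_forward(layers, xb)
      out <- outs[[length(outs)]]
      dout <- 2 * (out - y[idx, , drop = FALSE]) / length(out)
      grads <- mlp_backward(layers, outs, dout)
      st <- sgd_step(layers, grads, vel, lr, momentum)
      layers <- st$layers; vel <- st$vel
    }
    fit <- mlp_forward(layers, x)
    loss <- mse(fit[[length(fit)]], y)
    if (!is.finite(loss)) {
      stop("training loss became non-finite in ", what,
           " at epoch ", e, call. = FALSE)
    }
    losses <- c(losses, loss)
    if (e > 1L) {
      rel <- (losses[e - 1L] - loss) / max(losses[e - 1L], 1e-12)
      stale <- if (rel < plateau_rel) stale + 1L else 0L
      if (stale >= patience) break
    }
  }
  list(layers = layers, losses = losses)
}

#' Layer-wise pretraining of a stacked autoencoder
#'
#' Initializes a stacked autoencoder greedily: each encoder layer is
#' trained (with its mirrored decoder layer) to reconstruct the previous
#' layer's output, then the trained layers are concatenated into a full
#' encoder followed by the decoder layers in reverse order.  Hidden
#' layers use ReLU activations; the bottleneck layer and the last decoder
#' layer use tanh, so both the embedding and the reconstruction span
#' negative and positive values.
#'
#' @param x numeric matrix (cells x genes), typically the standardized
#'   output of [preprocess_counts()], or an `expr_matrix`.
#' @param layer_dims integer vector of strictly decreasing layer widths
#'   from the input dimension to the bottleneck, e.g. `c(200, 64, 32)`.
#' @param epochs_per_layer training-epoch cap per greedy layer (an early
#'   plateau stop may end a layer sooner).
#' @param lr,momentum,batch_size stochastic-gradient-descent settings.
#' @param noise_sd standard deviation of Gaussian input noise during
#'   layer-wise training (0 = plain, not denoising, autoencoder).
#' @param seed RNG seed; the same seed, input and thread count give
#'   bit-identical weights.
#' @return an object of class `autoencoder` holding the full layer stack,
#'   the encoder depth, and the training log.
#' @seealso [finetune()], [encode()]
#' @export
pretrain_layerwise <- function(x, layer_dims, epochs_per_layer = 100,
                               lr = 0.01, momentum = 0.9, batch_size = 256,
                               noise_sd = 0, seed = 1L) {
  if (inherits(x, "expr_matrix")) x <- x$values
  x <- as.matrix(x)
  check_that(length(layer_dims) >= 2, "`layer_dims` needs input and bottleneck")
  check_that(layer_dims[1L] == ncol(x),
             "layer_dims[1] (", layer_dims[1L], ") must equal ncol(x) (",
             ncol(x), ")")
  check_that(all(diff(layer_dims) < 0),
             "`layer_dims` must be strictly decreasing (got ",
             paste(layer_dims, collapse = ", "), ")")
  n_enc <- length(layer_dims) - 1L
  with_seed(derive_seed(seed, "pretrain"), {
    enc <- vector("list", n_enc)
    dec <- vector("list", n_enc)
    losses <- vector("list", n_enc)
    h <- x
    for (l in seq_len(n_enc)) {
      enc_act <- if (l == n_enc) "tanh" else "relu"
      dec_act <- if (l == 1L) "tanh" else "relu"
      pair <- list(new_layer(layer_dims[l], layer_dims[l + 1L], enc_act),
                   new_layer(layer_dims[l + 1L], layer_dims[l], dec_act))
      fit <- train_mlp(pair, h, h, epochs_per_layer, lr, momentum,
                       batch_size, noise_sd,
                       what = sprintf("pretraining layer %d", l))
      enc[[l]] <- fit$layers[[1L]]
      dec[[l]] <- fit$layers[[2L]]
      losses[[l]] <- fit$losses
      h <- act_fun(sweep(h %*% enc[[l]]$W, 2, enc[[l]]$b, "+"),
                   enc[[l]]$activation)
    }
    structure(list(layers = c(enc, rev(dec)), n_encoder = n_enc,
                   layer_dims = layer_dims, seed = seed,
                   pretrain_losses = losses, finetune_losses = numeric(0)),
              class = "autoencoder")
  })
}

#' Fine-tune a pretrained autoencoder end to end
#'
#' Trains the concatenated encoder-decoder stack to minimize the
#' reconstruction mean squared error on `x`.  With `epochs = 0` the model
#' is returned unchanged.  The logged loss curve is stored in
#' `$finetune_losses` (element 1 is the loss before any update).
#'
#' @param model an `autoencoder` from [pretrain_layerwise()].
#' @param x the training matrix (or `expr_matrix`) used for pretraining.
#' @param epochs fine-tuning epoch cap.
#' @inheritParams pretrain_layerwise
#' @return the fine-tuned `autoencoder`.
#' @export
finetune <- function(model, x, epochs = 100, lr = 0.01, momentum = 0.9,
                     batch_size = 256, seed = 1L) {
  check_that(inherits(model, "autoencoder"), "`model` must be an autoencoder")
  if (inherits(x, "expr_matrix")) x <- x$values
  x <- as.matrix(x)
  if (epochs == 0) return(model)
  with_seed(derive_seed(seed, "finetune"), {
    out0 <- mlp_forward(model$layers, x)
    loss0 <- mse(out0[[length(out0)]], x)
    fit <- train_mlp(model$layers, x, x, epochs, lr, momentum, batch_size,
                     what = "fine-tuning")
    model$layers <- fit$layers
    model$finetune_losses <- c(loss0, fit$losses)
    model
  })
}

#' Extract the encoder half of an autoencoder
#'
#' The decoder is only needed for reconstruction during initialization;
#' clustering uses the encoder alone.
#'
#' @param model an `autoencoder`.
#' @return an object of class `encoder_model`.
#' @export
encoder <- function(model) {
  check_that(inherits(model, "autoencoder"), "`model` must be an autoencoder")
  structure(list(layers = model$layers[seq_len(model$n_encoder)],
                 layer_dims = model$layer_dims, seed = model$seed),
            class = "encoder_model")
}

#' Map expression profiles to the bottleneck embedding
#'
#' Deterministic forward pass through the encoder layers; every embedding
#' coordinate lies in (-1, 1) because of the tanh bottleneck.
#'
#' @param model an `encoder_model` or `autoencoder`.
#' @param x matrix (or `expr_matrix`) with as many columns as the encoder
#'   input dimension; may have zero rows.
#' @return an `n x d` embedding matrix.
#' @export
encode <- function(model, x) {
  if (inherits(model, "autoencoder")) model <- encoder(model)
  check_that(inherits(model, "encoder_model"),
             "`model` must be an encoder_model or autoencoder")
  if (inherits(x, "expr_matrix")) x <- x$values
  x <- as.matrix(x)
  check_that(ncol(x) == model$layer_dims[1L],
             "x has ", ncol(x), " columns but the encoder expects ",
             model$layer_dims[1L])
  h <- x
  for (l in model$layers) {
    h <- act_fun(sweep(h %*% l$W, 2, l$b, "+"), l$activation)
  }
  h
}

#' Reconstruct inputs through the full autoencoder
#'
#' @param model an `autoencoder`.
#' @param x input matrix (or `expr_matrix`).
#' @return the reconstruction (same shape as `x`, entries in (-1, 1)).
#' @export
reconstruct <- function(model, x) {
  check_that(inherits(model, "autoencoder"), "`model` must be an autoencoder")
  if (inherits(x, "expr_matrix")) x <- x$values
  outs <- mlp_forward(model$layers, as.matrix(x))
  outs[[length(outs)]]
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single JSON file holding layer dimensions, weights,
#' activation tags, encoder depth and seed; it restores a model usable for
#' encoding (and reconstruction, for full autoencoders).
#'
#' @param model an `autoencoder` or `encoder_model`.
#' @param path JSON file path.
#' @return `save_model()`: `path`, invisibly; `load_model()`: the model.
#' @export
save_model <- function(model, path) {
  check_that(inherits(model, c("autoencoder", "encoder_model")),
             "`model` must be an autoencoder or encoder_model")
  payload <- list(
    class = class(model)[1L],
    layer_dims = model$layer_dims,
    n_encoder = if (inherits(model, "autoencoder")) model$n_encoder
                else length(model$layers),
    seed = model$seed,
    layers = lapply(model$layers, function(l) {
      list(W = as.vector(l$W), dim = dim(l$W), b = l$b,
           activation = l$activation)
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  layers <- lapply(seq_len(nrow(p$layers)), function(i) {
    l <- p$layers[i, ]
    list(W = matrix(l$W[[1L]], l$dim[[1L]][1L], l$dim[[1L]][2L]),
         b = as.numeric(l$b[[1L]]), activation = l$activation)
  })
  if (identical(p$class, "autoencoder")) {
    structure(list(layers = layers, n_encoder = p$n_encoder,
                   layer_dims = p$layer_dims, seed = p$seed,
                   pretrain_losses = list(), finetune_losses = numeric(0)),
              class = "autoencoder")
  } else {
    structure(list(layers = layers, layer_dims = p$layer_dims,
                   seed = p$seed),
              class = "encoder_model")
  }
}
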