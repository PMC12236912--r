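#' Training configuration for the brain-age CNN
#'
#' Mirrors the published regime: mean absolute error as the optimization
#' target (mean squared error tracked but unused), Adam at learning rate
#' 1e-4, and global gradient-norm clipping at 1. Epoch budget, batch size,
#' early stopping and initialization are configurable because they are not
#' part of the published regime.
#'
#' @param learning_rate Adam step size.
#' @param grad_clip_max_norm global L2 gradient-norm ceiling.
#' @param batch_size subjects per optimization step.
#' @param max_epochs maximum training epochs.
#' @param early_stop_patience epochs without validation-MAE improvement
#'   before stopping; \code{Inf} disables early stopping.
#' @param loss loss label; only \code{"MAE"} is supported.
#' @param seed integer seed driving batch shuffling and dropout masks.
#' @param init_output_bias if TRUE (default), the output-layer bias is set to
#'   the median training age before the first step. With a terminal ReLU and
#'   a small learning rate this warm start avoids a dead output unit and
#'   removes the long plateau in which the network learns only the age scale.
#' @return an object of class \code{train_config}.
#' @export
train_config <- function(learning_rate = 1e-4,
                         grad_clip_max_norm = 1,
                         batch_size = 16L,
                         max_epochs = 20L,
                         early_stop_patience = Inf,
                         loss = "MAE",
                         seed = 1L,
                         init_output_bias = TRUE) {
  if (learning_rate < 0) stop_config("learning_rate", "must be >= 0")
  if (grad_clip_max_norm <= 0) stop_config("grad_clip_max_norm", "must be > 0")
  if (batch_size < 1) stop_config("batch_size", "must be >= 1")
  if (!identical(loss, "MAE"))
    stop_config("loss", "must be 'MAE' (the optimization target)")
  structure(list(learning_rate = learning_rate,
                 grad_clip_max_norm = grad_clip_max_norm,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = early_stop_patience,
                 loss = loss,
                 seed = as.integer(seed),
                 init_output_bias = isTRUE(init_output_bias)),
            class = "train_config")
}

#' Instantiate a CNN with seeded random weights
#'
#' Builds the layer stack described by an \code{\link{arch_config}}:
#' per block \code{[conv -> batch-norm -> ReLU] x convs_per_block} followed
#' by a stride-2 max pool, then flatten and a dropout / fully-connected head
#' ending in a single ReLU output. Weights use fan-in-scaled uniform
#' initialization, batch-norm scale/shift start at 1/0, and all draws come
#' from \code{seed}, so two builds with the same seed are identical.
#'
#' @param arch an \code{arch_config}.
#' @param seed integer seed for weight initialization.
#' @return an object of class \code{cnn_model}.
#' @export
build_model <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "arch_config"))
  shapes <- forward_shapes(arch)
  params <- list()
  buffers <- list()
  with_seed(mix_seed(seed, 0L), {
    c_in <- arch$in_channels
    k3 <- arch$kernel^3
    for (b in seq_along(arch$block_filters)) {
      f <- arch$block_filters[b]
      for (j in seq_len(arch$convs_per_block)) {
        bound <- 1 / sqrt(k3 * c_in)
        params[[sprintf("b%d_conv%d_W", b, j)]] <-
          matrix(runif(k3 * c_in * f, -bound, bound), k3 * c_in, f)
        params[[sprintf("b%d_conv%d_b", b, j)]] <- runif(f, -bound, bound)
        params[[sprintf("b%d_bn%d_gamma", b, j)]] <- rep(1, f)
        params[[sprintf("b%d_bn%d_beta", b, j)]] <- rep(0, f)
        buffers[[sprintf("b%d_bn%d_rm", b, j)]] <- rep(0, f)
        buffers[[sprintf("b%d_bn%d_rv", b, j)]] <- rep(1, f)
        c_in <- f
      }
    }
    widths <- c(shapes$flatten_length, arch$fc_widths, arch$output_width)
    for (i in seq_len(length(widths) - 1)) {
      bound <- 1 / sqrt(widths[i])
      params[[sprintf("fc%d_W", i)]] <-
        matrix(runif(widths[i] * widths[i + 1], -bound, bound),
               widths[i], widths[i + 1])
      params[[sprintf("fc%d_b", i)]] <- runif(widths[i + 1], -bound, bound)
    }
  })
  structure(list(arch = arch, shapes = shapes, params = params,
                 buffers = buffers, seed = as.integer(seed)),
            class = "cnn_model")
}

#' Count realized parameters of a built model by enumeration
#'
#' Brute-force sum of the lengths of every learnable tensor; the independent
#' counterpart of the closed-form \code{\link{count_parameters}}.
#'
#' @param model a \code{cnn_model}.
#' @return integer parameter count.
#' @export
count_realized_parameters <- function(model) {
  stopifnot(inherits(model, "cnn_model"))
  as.integer(sum(vapply(model$params, length, 1L)))
}

# convert a batch_tensor (N, C, X, Y, Z) into the stacked internal layout:
# a (N*nvox x C) matrix whose rows are sample-major blocks of nvox voxels in
# R's column-major (X, Y, Z) order
batch_to_big <- function(batch) {
  stopifnot(inherits(batch, "batch_tensor"))
  d <- dim(batch$data)
  n <- d[1]; nc <- d[2]; nvox <- prod(d[3:5])
  X <- matrix(0, n * nvox, nc)
  for (c in seq_len(nc)) {
    arr <- array(batch$data[, c, , , ], c(n, d[3:5]))
    X[, c] <- as.vector(aperm(arr, c(2, 3, 4, 1)))
  }
  list(X = X, n = n)
}

# rows of the stacked layout belonging to the given sample indices
big_rows <- function(sel, nvox) {
  as.vector(vapply(sel, function(i) ((i - 1L) * nvox + 1L):(i * nvox),
                   integer(nvox)))
}

bn_eps <- 1e-5
bn_momentum <- 0.1

# forward pass over the stacked (n*nvox x C) layout.
# train = TRUE uses batch statistics + dropout (consuming the current RNG
# stream) and returns caches for backward; train = FALSE uses running
# statistics, no dropout, no caches.
cnn_forward <- function(model, X, n, train = FALSE, update_running = train) {
  arch <- model$arch
  p <- model$params
  buf <- model$buffers
  dims <- arch$input_dims
  cache <- if (train) list(blocks = list()) else NULL
  a <- X
  for (b in seq_along(arch$block_filters)) {
    blk_cache <- list(convs = list())
    for (j in seq_len(arch$convs_per_block)) {
      W <- p[[sprintf("b%d_conv%d_W", b, j)]]
      bb <- p[[sprintf("b%d_conv%d_b", b, j)]]
      conv_in <- a
      a <- .conv3d_fwd_batch(a, as.integer(dims), n, W, bb)
      g <- p[[sprintf("b%d_bn%d_gamma", b, j)]]
      be <- p[[sprintf("b%d_bn%d_beta", b, j)]]
      if (train) {
        r <- .bn_relu_fwd_train(a, g, be, bn_eps)
        if (update_running) {
          nr <- nrow(a)
          vu <- r$var_biased * nr / max(1, nr - 1)
          buf[[sprintf("b%d_bn%d_rm", b, j)]] <-
            (1 - bn_momentum) * buf[[sprintf("b%d_bn%d_rm", b, j)]] +
            bn_momentum * drop(r$mu)
          buf[[sprintf("b%d_bn%d_rv", b, j)]] <-
            (1 - bn_momentum) * buf[[sprintf("b%d_bn%d_rv", b, j)]] +
            bn_momentum * drop(vu)
        }
        a <- r$out
        blk_cache$convs[[j]] <- list(conv_in = conv_in, dims = dims,
                                     out = r$out, xhat = r$xhat,
                                     invstd = drop(r$invstd))
      } else {
        a <- .bn_relu_fwd_eval(a, g, be,
                               buf[[sprintf("b%d_bn%d_rm", b, j)]],
                               buf[[sprintf("b%d_bn%d_rv", b, j)]], bn_eps)
      }
    }
    pl <- .maxpool3d_fwd_batch(a, as.integer(dims), n)
    if (train) {
      blk_cache$pool_idx <- pl$idx
      blk_cache$pool_nrow_in <- nrow(a)
      cache$blocks[[b]] <- blk_cache
    }
    dims <- pl$out_dims
    a <- pl$out
  }
  # flatten: per sample, voxels within a channel vary fastest, then channels
  nvox <- prod(dims)
  nc <- ncol(a)
  Xf <- matrix(aperm(array(a, c(nvox, n, nc)), c(2, 1, 3)), n, nvox * nc)
  if (train) cache$flat_dims <- dims
  widths <- c(model$shapes$flatten_length, arch$fc_widths, arch$output_width)
  n_fc <- length(widths) - 1
  if (train) cache$fc <- list()
  for (i in seq_len(n_fc)) {
    if (train && arch$dropout_rate > 0) {
      keep <- 1 - arch$dropout_rate
      mask <- matrix(rbinom(length(Xf), 1, keep), nrow(Xf), ncol(Xf)) / keep
      Xf <- Xf * mask
    } else mask <- NULL
    W <- p[[sprintf("fc%d_W", i)]]
    bb <- p[[sprintf("fc%d_b", i)]]
    H <- Xf %*% W
    H <- sweep(H, 2, bb, `+`)
    if (train) cache$fc[[i]] <- list(input = Xf, mask = mask)
    Xf <- H
  }
  preact <- drop(Xf)
  pred <- pmax(preact, 0)
  if (train) {
    cache$preact <- preact
    list(pred = pred, cache = cache, buffers = buf)
  } else {
    list(pred = pred)
  }
}

# backward pass; gpred is dLoss/dprediction (length n). Returns grads named
# like model$params.
cnn_backward <- function(model, cache, gpred) {
  arch <- model$arch
  p <- model$params
  grads <- list()
  n <- length(gpred)
  g <- matrix(gpred * (cache$preact > 0), n, 1)
  widths <- c(model$shapes$flatten_length, arch$fc_widths, arch$output_width)
  n_fc <- length(widths) - 1
  for (i in rev(seq_len(n_fc))) {
    fc <- cache$fc[[i]]
    W <- p[[sprintf("fc%d_W", i)]]
    grads[[sprintf("fc%d_W", i)]] <- crossprod(fc$input, g)
    grads[[sprintf("fc%d_b", i)]] <- colSums(g)
    g <- g %*% t(W)
    if (!is.null(fc$mask)) g <- g * fc$mask
  }
  # unflatten into the stacked (n*nvox x C) layout
  dims <- cache$flat_dims
  nvox <- prod(dims)
  nc <- utils::tail(arch$block_filters, 1)
  ga <- matrix(aperm(array(g, c(n, nvox, nc)), c(2, 1, 3)), nvox * n, nc)
  for (b in rev(seq_along(arch$block_filters))) {
    blk <- cache$blocks[[b]]
    ga <- .maxpool3d_bwd_batch(ga, blk$pool_idx, blk$pool_nrow_in)
    for (j in rev(seq_len(arch$convs_per_block))) {
      cv <- blk$convs[[j]]
      r <- .bn_relu_bwd(ga, cv$out, cv$xhat, cv$invstd,
                        p[[sprintf("b%d_bn%d_gamma", b, j)]])
      grads[[sprintf("b%d_bn%d_gamma", b, j)]] <- drop(r$ggamma)
      grads[[sprintf("b%d_bn%d_beta", b, j)]] <- drop(r$gbeta)
      W <- p[[sprintf("b%d_conv%d_W", b, j)]]
      bw <- .conv3d_bwd_batch(cv$conv_in, as.integer(cv$dims), n, W, r$gx)
      grads[[sprintf("b%d_conv%d_W", b, j)]] <- bw$gW
      grads[[sprintf("b%d_conv%d_b", b, j)]] <- drop(bw$gb)
      ga <- bw$gx
    }
  }
  grads
}

global_grad_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train a CNN with Adam on the mean-absolute-error objective
#'
#' Optimizes batch-mean absolute error with Adam, clipping the global
#' gradient norm at \code{cfg$grad_clip_max_norm} each step, and logs
#' training and validation MAE and MSE per epoch. The returned model carries
#' the weights of the best-validation-MAE epoch. The run is deterministic
#' given \code{cfg$seed}: epoch shuffling and dropout masks are drawn from a
#' dedicated RNG stream.
#'
#' @param model a \code{cnn_model} from \code{\link{build_model}}.
#' @param train list with \code{x} (a \code{batch_tensor}) and \code{ages}.
#' @param val like \code{train}, or NULL to monitor on the training set.
#' @param cfg a \code{train_config}.
#' @return list with \code{model} (best weights), \code{log} (per-epoch
#'   data frame) and \code{best_epoch}.
#' @export
train_model <- function(model, train, val = NULL, cfg = train_config()) {
  stopifnot(inherits(model, "cnn_model"), inherits(cfg, "train_config"))
  big <- batch_to_big(train$x)
  nvox <- prod(model$arch$input_dims)
  ages <- train$ages
  if (big$n == 0) stop("empty training set", call. = FALSE)
  if (length(ages) != big$n)
    stop("ages do not align with training batch", call. = FALSE)
  if (!is.null(val)) {
    val_big <- batch_to_big(val$x)
    if (any(val$x$subject_ids %in% train$x$subject_ids))
      stop("train and validation subject ids overlap", call. = FALSE)
  }
  if (cfg$init_output_bias && model$arch$output_width == 1L) {
    n_fc <- length(model$arch$fc_widths) + 1L
    model$params[[sprintf("fc%d_b", n_fc)]] <- stats::median(ages)
  }
  opt <- adam_init(model$params)
  n <- big$n
  bs <- min(cfg$batch_size, n)
  log <- data.frame(epoch = integer(), train_mae = numeric(),
                    train_mse = numeric(), val_mae = numeric(),
                    val_mse = numeric())
  best <- list(mae = Inf, params = model$params, buffers = model$buffers,
               epoch = 0L)
  wait <- 0L
  with_seed(mix_seed(cfg$seed, 777L), {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      abs_err <- sq_err <- 0
      for (start in seq(1, n, by = bs)) {
        sel <- ord[start:min(start + bs - 1, n)]
        fw <- cnn_forward(model, big$X[big_rows(sel, nvox), , drop = FALSE],
                          length(sel), train = TRUE)
        model$buffers <- fw$buffers
        err <- fw$pred - ages[sel]
        if (any(!is.finite(err)))
          stop(sprintf("non-finite loss at epoch %d, batch starting %d",
                       epoch, start), call. = FALSE)
        abs_err <- abs_err + sum(abs(err))
        sq_err <- sq_err + sum(err^2)
        gpred <- sign(err) / length(sel)
        grads <- cnn_backward(model, fw$cache, gpred)
        gn <- global_grad_norm(grads)
        if (gn > cfg$grad_clip_max_norm)
          grads <- lapply(grads, function(g) g * (cfg$grad_clip_max_norm / gn))
        upd <- adam_step(model$params, grads, opt, cfg$learning_rate)
        model$params <- upd$params
        opt <- upd$state
      }
      train_mae <- abs_err / n
      train_mse <- sq_err / n
      if (!is.null(val)) {
        vp <- predict_with_big(model, val_big)
        val_mae <- mean(abs(vp - val$ages))
        val_mse <- mean((vp - val$ages)^2)
      } else {
        val_mae <- train_mae
        val_mse <- train_mse
      }
      log[nrow(log) + 1L, ] <- list(epoch, train_mae, train_mse, val_mae, val_mse)
      if (val_mae < best$mae) {
        best <- list(mae = val_mae, params = model$params,
                     buffers = model$buffers, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$early_stop_patience) break
      }
    }
  })
  model$params <- best$params
  model$buffers <- best$buffers
  list(model = model, log = log, best_epoch = best$epoch)
}

predict_with_big <- function(model, big, chunk = 32L) {
  nvox <- prod(model$arch$input_dims)
  out <- numeric(big$n)
  for (start in seq(1, big$n, by = chunk)) {
    sel <- start:min(start + chunk - 1, big$n)
    out[sel] <- cnn_forward(model, big$X[big_rows(sel, nvox), , drop = FALSE],
                            length(sel), train = FALSE)$pred
  }
  out
}

#' Predict ages for a batch of subjects
#'
#' Evaluation mode: dropout disabled and batch normalization using running
#' statistics, so predictions are independent of how subjects are split into
#' batches. The terminal ReLU guarantees non-negative predictions.
#'
#' @param model a trained (or freshly built) \code{cnn_model}.
#' @param batch a \code{batch_tensor} from \code{\link{stack_batch}}.
#' @return named numeric vector of predicted ages (names = subject ids).
#' @export
predict_ages <- function(model, batch) {
  stopifnot(inherits(model, "cnn_model"), inherits(batch, "batch_tensor"))
  if (!all(dim(batch$data)[3:5] == model$arch$input_dims))
    stop(sprintf("batch dims %s do not match model input dims %s",
                 paste(dim(batch$data)[3:5], collapse = "x"),
                 paste(model$arch$input_dims, collapse = "x")), call. = FALSE)
  stats::setNames(predict_with_big(model, batch_to_big(batch)),
                  batch$subject_ids)
}

#' Spatial activation shapes of a realized model on a probe batch
#'
#' Runs one subject of zeros through the built network and records the
#' spatial dimensions entering each block and the realized flatten length.
#' Used to audit \code{\link{forward_shapes}} against the actual layer stack.
#'
#' @param model a \code{cnn_model}.
#' @return list with \code{stage_dims} and \code{flatten_length} as realized.
#' @export
probe_shapes <- function(model) {
  arch <- model$arch
  dims <- arch$input_dims
  x <- matrix(0, prod(dims), arch$in_channels)
  stages <- matrix(dims, nrow = 1)
  a <- x
  for (b in seq_along(arch$block_filters)) {
    for (j in seq_len(arch$convs_per_block)) {
      W <- model$params[[sprintf("b%d_conv%d_W", b, j)]]
      bb <- model$params[[sprintf("b%d_conv%d_b", b, j)]]
      a <- .conv3d_fwd(a, as.integer(dims), W, bb)
    }
    pl <- .maxpool3d_fwd(a, as.integer(dims))
    dims <- pl$out_dims
    a <- pl$out
    stages <- rbind(stages, dims)
  }
  dimnames(stages) <- list(
    c("input", paste0("block", seq_along(arch$block_filters))),
    c("X", "Y", "Z"))
  list(stage_dims = stages, flatten_length = length(as.vector(a)))
}
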