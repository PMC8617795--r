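#' Model configuration for the segmentation networks
#'
#' Collects the architectural and training hyperparameters shared by the
#' three builders. Filter counts double at every pooling stage starting from
#' `base_filters`; convolutions are 3x3 with 2x2 max pooling and 2x2
#' stride-2 transposed-convolution upsampling. When `use_rff` is on, a
#' random-Fourier-features layer approximating a Gaussian kernel is inserted
#' after the last pooling (FCN) or at the bottleneck end (U-net/ResUnet),
#' producing `Q_factor` channels per spatial position; the admissible
#' `Q_factor` grid is \{8, 16, 32, 64, 128\}.
#'
#' @param architecture one of `"fcn"`, `"unet"`, `"resunet"`.
#' @param input_size length-2 integer vector (rows, cols); must be divisible
#'   by `2^depth`.
#' @param depth number of 2x pooling stages (4 stages on 128x128 input give
#'   the 8x8 bottleneck).
#' @param base_filters filters in the first stage.
#' @param use_rff insert the RFF kernel layer?
#' @param Q_factor RFF feature count per position, in \{8, 16, 32, 64, 128\}.
#' @param rff_sigma Gaussian kernel bandwidth; `NULL` (default) applies the
#'   median heuristic to bottleneck features of a warm-up batch at fit time.
#' @param rff_trainable update the RFF frequencies/phases during training?
#' @param rff_seed seed for the RFF parameter draw.
#' @param learning_rate Adam learning rate (1e-3 default).
#' @param batch_size mini-batch size (32 default).
#' @param epochs training epochs.
#' @param optimizer_seed seed governing weight initialization and batch
#'   shuffling.
#' @param fcn_skips use the skip-refined FCN variant (FCN-8s style) instead
#'   of a single upsampling head.
#' @return An object of class `"model_config"`.
#' @export
model_config <- function(architecture = c("unet", "resunet", "fcn"),
                         input_size = c(128L, 128L),
                         depth = 4L, base_filters = 16L,
                         use_rff = TRUE, Q_factor = 16L,
                         rff_sigma = NULL, rff_trainable = FALSE, rff_seed = 1L,
                         learning_rate = 1e-3, batch_size = 32L, epochs = 10L,
                         optimizer_seed = 1L, fcn_skips = FALSE) {
  architecture <- match.arg(architecture)
  if (length(input_size) != 2L || any(input_size <= 0))
    stop("'input_size' must be two positive integers", call. = FALSE)
  stopifnot_scalar(depth, "depth", positive = TRUE, integerish = TRUE)
  if (any(input_size %% 2^depth != 0))
    stop(sprintf("input_size must be divisible by 2^depth = %d", 2^depth),
         call. = FALSE)
  stopifnot_scalar(base_filters, "base_filters", positive = TRUE, integerish = TRUE)
  if (use_rff && !(Q_factor %in% c(8L, 16L, 32L, 64L, 128L)))
    stop("'Q_factor' must be one of 8, 16, 32, 64, 128", call. = FALSE)
  stopifnot_scalar(learning_rate, "learning_rate", positive = TRUE)
  stopifnot_scalar(batch_size, "batch_size", positive = TRUE, integerish = TRUE)
  stopifnot_scalar(epochs, "epochs", positive = TRUE, integerish = TRUE)
  structure(list(architecture = architecture,
                 input_size = as.integer(input_size),
                 depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 use_rff = isTRUE(use_rff), Q_factor = as.integer(Q_factor),
                 rff_sigma = rff_sigma, rff_trainable = isTRUE(rff_trainable),
                 rff_seed = as.integer(rff_seed),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 optimizer_seed = as.integer(optimizer_seed),
                 fcn_skips = isTRUE(fcn_skips)),
            class = "model_config")
}

# -- builder helpers ---------------------------------------------------------

gb_conv <- function(st, cout, k = 3L, relu = TRUE) {
  r <- add_node(st$g, "conv", st$cur, k = k, cin = st$ch, cout = cout)
  st$g <- r$g; st$cur <- r$id
  if (relu) {
    r <- add_node(st$g, "relu", st$cur)
    st$g <- r$g; st$cur <- r$id
  }
  st$ch <- cout
  st
}

gb_op <- function(st, op, inputs, ch, ...) {
  r <- add_node(st$g, op, inputs, ...)
  st$g <- r$g; st$cur <- r$id; st$ch <- ch
  st
}

# Residual block as used by ResUnet: out = conv(relu(conv(x))) + proj(x),
# with a 1x1 projection when channel counts differ.
gb_residual_block <- function(st, cout) {
  x_id <- st$cur; x_ch <- st$ch
  st <- gb_conv(st, cout)                      # conv + relu
  st <- gb_conv(st, cout, relu = FALSE)        # conv
  t_id <- st$cur
  if (x_ch != cout) {
    r <- add_node(st$g, "conv", x_id, k = 1L, cin = x_ch, cout = cout)
    st$g <- r$g; p_id <- r$id
  } else p_id <- x_id
  gb_op(st, "add", c(t_id, p_id), cout)
}

insert_rff_node <- function(st, config) {
  r <- add_node(st$g, "rff", st$cur, P = st$ch, Q = config$Q_factor)
  st$g <- r$g; st$cur <- r$id; st$ch <- config$Q_factor
  st
}

finish_net <- function(st, config, cam_node, rff_node, arch) {
  logits <- st$cur
  st <- gb_op(st, "sigmoid", st$cur, st$ch)
  structure(list(nodes = st$g$nodes, config = config,
                 input_node = 1L, logits_node = logits, output_node = st$cur,
                 cam_node = cam_node, rff_node = rff_node, arch = arch),
            class = "seg_network")
}

#' Build a segmentation network
#'
#' `build_fcn()` builds a VGG-style encoder whose last pooling output feeds
#' (optionally through the RFF layer) a 1x1 score convolution and a chain of
#' learnable 2x upsampling layers back to input resolution.
#' `build_unet()` builds the symmetric encoder--decoder with skip
#' connections; `build_resunet()` replaces each two-convolution block with a
#' residual block. With `use_rff = TRUE` the RFF layer sits after the last
#' pooling (FCN) or at the bottleneck end (U-net/ResUnet) and its
#' `Q_factor`-channel output enters the decoder.
#'
#' The returned network is untrained; [seg_fit()] initializes and trains it.
#'
#' @param config a [model_config()] whose `architecture` matches the builder.
#' @return An object of class `"seg_network"`.
#' @export
build_unet <- function(config) {
  if (config$architecture != "unet") stop("config$architecture must be 'unet'")
  build_ushape(config, residual = FALSE, arch = "unet")
}

#' @rdname build_unet
#' @export
build_resunet <- function(config) {
  if (config$architecture != "resunet") stop("config$architecture must be 'resunet'")
  build_ushape(config, residual = TRUE, arch = "resunet")
}

build_ushape <- function(config, residual, arch) {
  st <- list(g = new_graph(), cur = 0L, ch = 1L)
  r <- add_node(st$g, "input")
  st$g <- r$g; st$cur <- r$id
  block <- if (residual) gb_residual_block else
    function(s, f) gb_conv(gb_conv(s, f), f)
  skips <- integer(config$depth); skip_ch <- integer(config$depth)
  for (s in seq_len(config$depth)) {
    f <- config$base_filters * 2L^(s - 1L)
    st <- block(st, f)
    skips[s] <- st$cur; skip_ch[s] <- st$ch
    st <- gb_op(st, "pool", st$cur, st$ch)
  }
  st <- block(st, config$base_filters * 2L^config$depth)
  cam_node <- st$cur
  rff_node <- NA_integer_
  if (config$use_rff) {
    st <- insert_rff_node(st, config)
    rff_node <- st$cur
  }
  for (s in rev(seq_len(config$depth))) {
    f <- config$base_filters * 2L^(s - 1L)
    r <- add_node(st$g, "convt", st$cur, cin = st$ch, cout = f)
    st$g <- r$g; st$cur <- r$id; st$ch <- f
    st <- gb_op(st, "concat", c(st$cur, skips[s]), f + skip_ch[s])
    st <- block(st, f)
  }
  st <- gb_conv(st, 1L, k = 1L, relu = FALSE)   # score head -> logits
  finish_net(st, config, cam_node, rff_node, arch)
}

#' @rdname build_unet
#' @export
build_fcn <- function(config) {
  if (config$architecture != "fcn") stop("config$architecture must be 'fcn'")
  st <- list(g = new_graph(), cur = 0L, ch = 1L)
  r <- add_node(st$g, "input")
  st$g <- r$g; st$cur <- r$id
  pool_scores <- integer(0)
  cam_node <- NA_integer_
  for (s in seq_len(config$depth)) {
    f <- config$base_filters * 2L^(s - 1L)
    st <- gb_conv(st, f)
    st <- gb_conv(st, f)
    cam_node <- st$cur                       # last conv before the insertion
    st <- gb_op(st, "pool", st$cur, st$ch)
    if (config$fcn_skips && s < config$depth) {
      # 1x1 score of intermediate pools for the skip-refined variant
      r <- add_node(st$g, "conv", st$cur, k = 1L, cin = st$ch, cout = 1L)
      st$g <- r$g
      pool_scores[s] <- r$id
    }
  }
  rff_node <- NA_integer_
  if (config$use_rff) {
    st <- insert_rff_node(st, config)
    rff_node <- st$cur
  }
  st <- gb_conv(st, 1L, k = 1L, relu = FALSE)  # 1x1 score on the coarse grid
  for (s in rev(seq_len(config$depth))) {
    r <- add_node(st$g, "convt", st$cur, cin = 1L, cout = 1L)
    st$g <- r$g; st$cur <- r$id
    if (config$fcn_skips && s > 1L)
      st <- gb_op(st, "add", c(st$cur, pool_scores[s - 1L]), 1L)
  }
  st$ch <- 1L
  finish_net(st, config, cam_node, rff_node, arch = "fcn")
}

build_model <- function(config) {
  switch(config$architecture,
         unet = build_unet(config),
         resunet = build_resunet(config),
         fcn = build_fcn(config))
}

#' Apply a residual block to a feature grid
#'
#' Functional form of the ResUnet building block
#' \eqn{F \mapsto \phi(F) + F} with
#' \eqn{\phi(F) = W_2 \otimes \mathrm{ReLU}(W_1 \otimes F + b_1) + b_2}; a
#' 1x1 projection is applied to the identity branch when the channel counts
#' differ.
#'
#' @param x feature grid, `H x W x Cin` array.
#' @param w1,b1,w2,b2 convolution weights/biases; `w2` decides the output
#'   channels.
#' @param wp,bp optional 1x1 projection weights for the identity branch
#'   (required iff input and output channel counts differ).
#' @return `H x W x Cout` array.
#' @export
residual_block <- function(x, w1, b1, w2, b2, wp = NULL, bp = NULL) {
  x4 <- as_batch(x)
  h <- pmax(conv2d_fw(x4, w1, b1), 0)
  t <- conv2d_fw(h, w2, b2)
  cin <- dim(x4)[3L]; cout <- dim(t)[3L]
  idp <- if (cin == cout && is.null(wp)) x4 else {
    if (is.null(wp)) stop("channel mismatch requires a projection (wp, bp)")
    conv2d_fw(x4, wp, if (is.null(bp)) numeric(dim(wp)[4L]) else bp)
  }
  out <- t + idp
  if (length(dim(x)) <= 3L) array(out, dim(out)[1:3]) else out
}

#' Per-node structural summary of a network
#'
#' @param net a `"seg_network"` or fitted `"kernseg_fit"`.
#' @return Data frame with node id, operation, inputs and parameter counts.
#' @export
layer_summary <- function(net) {
  if (inherits(net, "kernseg_fit")) net <- net$network
  rows <- lapply(seq_along(net$nodes), function(id) {
    nd <- net$nodes[[id]]
    np <- if (!is.null(nd$param)) sum(vapply(nd$param, length, numeric(1)))
          else if (nd$op == "rff") length(nd$rff$omega) + length(nd$rff$b)
          else 0
    data.frame(id = id, op = nd$op,
               inputs = paste(nd$inputs, collapse = ","),
               n_param = np, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Total trainable parameter count
#' @param net a `"seg_network"` or `"kernseg_fit"`.
#' @return Number of trainable scalars (fixed RFF draws excluded).
#' @export
n_parameters <- function(net) {
  if (inherits(net, "kernseg_fit")) net <- net$network
  count_params(net)
}

# Create the RFF parameters of a built network, optionally using the median
# heuristic on warm-up bottleneck features.
attach_rff <- function(net, config, warmup_x = NULL) {
  if (!config$use_rff) return(net)
  id <- net$rff_node
  P <- net$nodes[[id]]$attrs$P
  sigma <- config$rff_sigma
  if (is.null(sigma)) {
    if (is.null(warmup_x)) sigma <- 1
    else {
      fw <- forward_net(net, warmup_x, upto = net$nodes[[id]]$inputs)
      f <- fw$outs[[net$nodes[[id]]$inputs]]
      d <- dim(f)
      X <- t(matrix(aperm(f, c(3L, 1L, 2L, 4L)), nrow = d[3L]))
      sigma <- rff_median_sigma(X, seed = config$rff_seed)
    }
  }
  net$nodes[[id]]$rff <- sample_rff_params(P, config$Q_factor, sigma,
                                           seed = config$rff_seed,
                                           trainable = config$rff_trainable)
  net
}

# -- fitting -----------------------------------------------------------------

#' Fit a kernel-enhanced segmentation network
#'
#' Builds the configured architecture, initializes it deterministically,
#' and minimizes the Dice-based loss \eqn{1 - s(M, \hat M)} (see
#' [dice_loss()]) by mini-batch Adam. The validation split is scored after
#' every epoch and the best-validation weights are retained.
#'
#' @param dataset a `"seg_dataset"` (from [generate_dataset()] or
#'   [read_dataset()]) with nonempty `"train"` and `"val"` splits, or a list
#'   with elements `train` and `val`, each a list of `image_pair`s.
#' @param config a [model_config()].
#' @param verbose print per-epoch losses?
#' @return An object of class `"kernseg_fit"` with components `network`
#'   (best-validation weights), `config`, `history` (data frame of per-epoch
#'   train/validation loss) and `best_epoch`.
#' @seealso [predict.kernseg_fit()], [seg_evaluate()], [cam_for_image()]
#' @export
seg_fit <- function(dataset, config, verbose = FALSE) {
  splits <- dataset_splits(dataset)
  if (length(splits$train) == 0L || length(splits$val) == 0L)
    stop("training and validation splits must be nonempty", call. = FALSE)
  xtr <- as_batch(lapply(splits$train, `[[`, "image"))
  ytr <- as_batch(lapply(splits$train, `[[`, "mask"))
  xva <- as_batch(lapply(splits$val, `[[`, "image"))
  yva <- as_batch(lapply(splits$val, `[[`, "mask"))
  if (!all(dim(xtr)[1:2] == config$input_size))
    stop("image size does not match config$input_size", call. = FALSE)

  net <- build_model(config)
  net <- init_network(net, child_seed(config$optimizer_seed, 1L))
  warm <- xtr[, , , seq_len(min(8L, dim(xtr)[4L])), drop = FALSE]
  net <- attach_rff(net, config, warmup_x = warm)

  params <- collect_params(net)
  state <- adam_init(params)
  ntr <- dim(xtr)[4L]
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), steps = integer(0))
  best <- list(val = Inf, params = params, epoch = 0L)

  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(child_seed(config$optimizer_seed, 100L + ep), sample.int(ntr))
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, ntr, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, ntr)]
      xb <- xtr[, , , idx, drop = FALSE]
      yb <- ytr[, , , idx, drop = FALSE]
      fw <- forward_net(net, xb)
      pb <- fw$outs[[net$output_node]]
      dl <- dice_loss_batch(yb, pb)
      if (!is.finite(dl$loss))
        stop(sprintf("non-finite loss at epoch %d (batch starting %d); ",
                     ep, start),
             "check learning rate and input scaling", call. = FALSE)
      ep_loss <- ep_loss + dl$loss; nb <- nb + 1L
      seeds <- list(); seeds[[as.character(net$output_node)]] <- dl$grad
      bw <- backward_net(net, fw, seeds)
      g <- flatten_pgrads(net, bw$param_grads)
      upd <- adam_step(params, g, state, lr = config$learning_rate)
      params <- upd$params; state <- upd$state
      net <- set_params(net, params)
    }
    vl <- eval_loss(net, xva, yva, config$batch_size)
    history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                         val_loss = vl, steps = state$t))
    if (vl < best$val) best <- list(val = vl, params = params, epoch = ep)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", ep, ep_loss / nb, vl))
  }
  net <- set_params(net, best$params)
  structure(list(network = net, config = config, history = history,
                 best_epoch = best$epoch),
            class = "kernseg_fit")
}

dataset_splits <- function(dataset) {
  if (inherits(dataset, "seg_dataset")) {
    list(train = dataset$pairs[dataset$split == "train"],
         val = dataset$pairs[dataset$split == "val"],
         test = dataset$pairs[dataset$split == "test"])
  } else if (is.list(dataset) && !is.null(dataset$train)) {
    dataset
  } else stop("'dataset' must be a seg_dataset or a list with $train/$val")
}

eval_loss <- function(net, x, y, batch_size) {
  n <- dim(x)[4L]
  tot <- 0
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fw <- forward_net(net, x[, , , idx, drop = FALSE])
    p <- fw$outs[[net$output_node]]
    for (i in seq_along(idx))
      tot <- tot + dice_loss(y[, , 1L, idx[i]], p[, , 1L, i])
  }
  tot / n
}

# -- methods -----------------------------------------------------------------

#' Predict segmentation masks from a fitted network
#'
#' @param object a `"kernseg_fit"`.
#' @param newdata an image matrix, a list of image matrices or
#'   `image_pair`s, or a `"seg_dataset"`.
#' @param type `"prob"` for probability grids, `"mask"` for 0/1 masks
#'   thresholded at `threshold`, `"logits"` for the pre-activation grid G.
#' @param threshold binarization threshold for `type = "mask"`.
#' @param ... unused.
#' @return A matrix for single-image input, else a list of matrices.
#' @export
predict.kernseg_fit <- function(object, newdata, type = c("prob", "mask", "logits"),
                                threshold = 0.5, ...) {
  type <- match.arg(type)
  single <- is.matrix(newdata)
  imgs <- if (single) list(newdata)
    else if (inherits(newdata, "seg_dataset")) lapply(newdata$pairs, `[[`, "image")
    else lapply(newdata, function(e) if (inherits(e, "image_pair")) e$image else e)
  net <- object$network
  node <- if (type == "logits") net$logits_node else net$output_node
  out <- vector("list", length(imgs))
  bs <- object$config$batch_size
  for (start in seq(1L, length(imgs), by = bs)) {
    idx <- start:min(start + bs - 1L, length(imgs))
    xb <- as_batch(imgs[idx])
    fw <- forward_net(net, xb, upto = node)
    v <- fw$outs[[node]]
    for (i in seq_along(idx)) out[[idx[i]]] <- v[, , 1L, i]
  }
  if (type == "mask") out <- lapply(out, function(m) (m >= threshold) * 1)
  if (single) out[[1L]] else out
}

#' @export
print.kernseg_fit <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Kernel-enhanced segmentation network (%s%s)\n",
              if (cfg$use_rff) "RFF-" else "", cfg$architecture))
  cat(sprintf("  input %dx%d, depth %d, base filters %d%s\n",
              cfg$input_size[1L], cfg$input_size[2L], cfg$depth, cfg$base_filters,
              if (cfg$use_rff) sprintf(", Q factor %d", cfg$Q_factor) else ""))
  cat(sprintf("  %d trainable parameters; trained %d epochs (best val loss %.4f at epoch %d)\n",
              n_parameters(x), nrow(x$history),
              min(x$history$val_loss), x$best_epoch))
  invisible(x)
}

#' @export
summary.kernseg_fit <- function(object, ...) {
  print(object)
  cat("\nLayer stack:\n")
  print(layer_summary(object))
  invisible(object)
}

#' @export
coef.kernseg_fit <- function(object, ...) collect_params(object$network)

#' @export
plot.kernseg_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red"),
                    xlab = "epoch", ylab = "Dice loss", ...)
  graphics::legend("topright", c("train", "validation"),
                   lty = 1, col = c("black", "red"), bty = "n")
  invisible(x)
}

#' @export
print.seg_network <- function(x, ...) {
  cat(sprintf("Untrained %s network (%d nodes)\n", x$arch, length(x$nodes)))
  invisible(x)
}
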