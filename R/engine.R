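# Minimal computational-graph engine for the segmentation networks.
#
# A network is a list of nodes in topological order (inputs always precede
# consumers). Node ops: input, conv (kxk, stride 1, same padding), relu,
# pool (2x2 max), convt (2x2 stride-2 transposed conv), concat (channels),
# add, rff, sigmoid. Activations are H x W x C x N arrays. The heavy kernels
# (conv/pool/deconv) live in src/conv_ops.cpp.

new_graph <- function() {
  list(nodes = list())
}

add_node <- function(g, op, inputs = integer(0), ...) {
  id <- length(g$nodes) + 1L
  g$nodes[[id]] <- list(op = op, inputs = as.integer(inputs), attrs = list(...))
  list(g = g, id = id)
}

concat4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (!all(da[c(1L, 2L, 4L)] == db[c(1L, 2L, 4L)]))
    stop("concat: spatial/batch dimensions disagree", call. = FALSE)
  out <- array(0, c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  out[, , seq_len(da[3L]), ] <- a
  out[, , da[3L] + seq_len(db[3L]), ] <- b
  out
}

# Initialize weights (He-style) for every parametric node; deterministic
# given `seed`. RFF nodes are populated separately (they may need a
# data-driven bandwidth).
init_network <- function(net, seed) {
  with_seed(seed, {
    for (id in seq_along(net$nodes)) {
      nd <- net$nodes[[id]]
      if (nd$op == "conv") {
        k <- nd$attrs$k; cin <- nd$attrs$cin; cout <- nd$attrs$cout
        if (isTRUE(nd$attrs$zero_init)) {
          W <- array(0, c(k, k, cin, cout))
        } else {
          W <- array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
                     c(k, k, cin, cout))
        }
        net$nodes[[id]]$param <- list(W = W, b = numeric(cout))
      } else if (nd$op == "convt") {
        cin <- nd$attrs$cin; cout <- nd$attrs$cout
        W <- array(rnorm(4 * cin * cout, sd = sqrt(2 / (4 * cin))),
                   c(2L, 2L, cin, cout))
        net$nodes[[id]]$param <- list(W = W, b = numeric(cout))
      }
    }
  })
  net
}

# Forward pass. Returns all node outputs plus per-node caches.
# `upto` stops evaluation after that node id (used for warm-up features).
forward_net <- function(net, x, upto = NULL) {
  n <- length(net$nodes)
  outs <- vector("list", n)
  caches <- vector("list", n)
  last <- if (is.null(upto)) n else upto
  for (id in seq_len(last)) {
    nd <- net$nodes[[id]]
    outs[[id]] <- switch(nd$op,
      input = x,
      conv = conv2d_fw(outs[[nd$inputs]], nd$param$W, nd$param$b),
      relu = pmax(outs[[nd$inputs]], 0),
      pool = {
        r <- maxpool2_fw(outs[[nd$inputs]])
        caches[[id]] <- list(idx = r$idx, xdim = dim(outs[[nd$inputs]]))
        r$y
      },
      convt = convt2_fw(outs[[nd$inputs]], nd$param$W, nd$param$b),
      concat = concat4(outs[[nd$inputs[1L]]], outs[[nd$inputs[2L]]]),
      add = outs[[nd$inputs[1L]]] + outs[[nd$inputs[2L]]],
      rff = {
        r <- rff_fw(outs[[nd$inputs]], nd$rff)
        caches[[id]] <- r[c("A", "X", "scale")]
        r$y
      },
      sigmoid = 1 / (1 + exp(-outs[[nd$inputs]])),
      stop("unknown op: ", nd$op)
    )
  }
  list(outs = outs, caches = caches)
}

accum_grad <- function(grads, id, g) {
  grads[[id]] <- if (is.null(grads[[id]])) g else grads[[id]] + g
  grads
}

# Reverse pass from gradients seeded at arbitrary nodes. Returns gradients at
# every reached node and, when `param_grads`, the parameter gradients.
backward_net <- function(net, fw, seeds, param_grads = TRUE) {
  n <- length(net$nodes)
  grads <- vector("list", n)
  pgrads <- vector("list", n)
  for (nm in names(seeds)) grads <- accum_grad(grads, as.integer(nm), seeds[[nm]])
  for (id in rev(seq_len(n))) {
    g <- grads[[id]]
    if (is.null(g)) next
    nd <- net$nodes[[id]]
    switch(nd$op,
      input = NULL,
      conv = {
        r <- conv2d_bw(fw$outs[[nd$inputs]], nd$param$W, g)
        grads <- accum_grad(grads, nd$inputs, r$gx)
        if (param_grads) pgrads[[id]] <- list(W = r$gw, b = r$gb)
      },
      relu = grads <- accum_grad(grads, nd$inputs, g * (fw$outs[[id]] > 0)),
      pool = {
        ca <- fw$caches[[id]]
        grads <- accum_grad(grads, nd$inputs, maxpool2_bw(ca$idx, g, ca$xdim))
      },
      convt = {
        r <- convt2_bw(fw$outs[[nd$inputs]], nd$param$W, g)
        grads <- accum_grad(grads, nd$inputs, r$gx)
        if (param_grads) pgrads[[id]] <- list(W = r$gw, b = r$gb)
      },
      concat = {
        c1 <- dim(fw$outs[[nd$inputs[1L]]])[3L]
        grads <- accum_grad(grads, nd$inputs[1L], g[, , seq_len(c1), , drop = FALSE])
        grads <- accum_grad(grads, nd$inputs[2L],
                            g[, , (c1 + 1L):dim(g)[3L], , drop = FALSE])
      },
      add = {
        grads <- accum_grad(grads, nd$inputs[1L], g)
        grads <- accum_grad(grads, nd$inputs[2L], g)
      },
      rff = {
        r <- rff_bw(g, fw$caches[[id]], nd$rff)
        grads <- accum_grad(grads, nd$inputs, r$gx)
        if (param_grads && nd$rff$trainable)
          pgrads[[id]] <- list(omega = r$gomega, b = r$gb)
      },
      sigmoid = {
        s <- fw$outs[[id]]
        grads <- accum_grad(grads, nd$inputs, g * s * (1 - s))
      }
    )
  }
  list(node_grads = grads, param_grads = pgrads)
}

# Named list of trainable parameter tensors, keyed "<node>.<name>".
collect_params <- function(net) {
  out <- list()
  for (id in seq_along(net$nodes)) {
    nd <- net$nodes[[id]]
    if (!is.null(nd$param))
      for (nm in names(nd$param)) out[[sprintf("%d.%s", id, nm)]] <- nd$param[[nm]]
    if (nd$op == "rff" && nd$rff$trainable) {
      out[[sprintf("%d.omega", id)]] <- nd$rff$omega
      out[[sprintf("%d.b", id)]] <- nd$rff$b
    }
  }
  out
}

set_params <- function(net, params) {
  for (key in names(params)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    id <- as.integer(parts[1L]); nm <- parts[2L]
    nd <- net$nodes[[id]]
    if (nd$op == "rff") net$nodes[[id]]$rff[[nm]] <- params[[key]]
    else net$nodes[[id]]$param[[nm]] <- params[[key]]
  }
  net
}

count_params <- function(net) {
  sum(vapply(collect_params(net), length, numeric(1)))
}

# One Adam update over the collected parameter gradients.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (key in names(grads)) {
    g <- grads[[key]]
    state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
    mhat <- state$m[[key]] / (1 - beta1^state$t)
    vhat <- state$v[[key]] / (1 - beta2^state$t)
    params[[key]] <- params[[key]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Map backward_net parameter gradients to the collect_params keying.
flatten_pgrads <- function(net, pgrads) {
  out <- list()
  for (id in seq_along(pgrads)) {
    pg <- pgrads[[id]]
    if (is.null(pg)) next
    for (nm in names(pg)) out[[sprintf("%d.%s", id, nm)]] <- pg[[nm]]
  }
  out
}
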