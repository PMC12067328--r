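# Minimal 3D convolutional network stack with reverse-mode gradients.
#
# Feature maps are stored as (n_voxels x channels) matrices, voxels in
# column-major order of the (z, y, x) array.  Convolutions use an
# im2col formulation: a sparse 0/1 gather matrix S maps the padded
# input volume onto the (output-voxel x kernel-tap) column matrix, so
# the convolution itself is a dense BLAS matmul and the gradient with
# respect to the input is the adjoint crossprod(S, .).  Transposed
# convolutions are the exact adjoint of the corresponding stride-s
# convolution, sharing the same gather matrix.
#
# Padding is "same" with the TensorFlow convention: out = ceil(in/s),
# total padding (out-1)*s + k - in, split floor/ceil between the two
# sides.  This reproduces the shape bookkeeping of the pix2pix
# architecture (a 256-edge cube halves through every stride-2 block
# down to a 1-cube bottleneck).

conv_out_shape <- function(in_shape, stride) as.integer(ceiling(in_shape / stride))

make_conv_plan <- function(in_shape, k, stride) {
  in_shape <- as.integer(in_shape)
  out_shape <- conv_out_shape(in_shape, stride)
  pad_total <- pmax((out_shape - 1L) * stride + k - in_shape, 0L)
  pad_beg <- pad_total %/% 2L
  n_out <- prod(out_shape)
  k3 <- k^3
  rows <- vector("list", k3)
  cols <- vector("list", k3)
  o1 <- 0:(out_shape[1] - 1L); o2 <- 0:(out_shape[2] - 1L); o3 <- 0:(out_shape[3] - 1L)
  tap <- 0L
  for (t3 in 0:(k - 1L)) for (t2 in 0:(k - 1L)) for (t1 in 0:(k - 1L)) {
    tap <- tap + 1L
    i1 <- o1 * stride - pad_beg[1] + t1
    i2 <- o2 * stride - pad_beg[2] + t2
    i3 <- o3 * stride - pad_beg[3] + t3
    v1 <- which(i1 >= 0L & i1 < in_shape[1])
    v2 <- which(i2 >= 0L & i2 < in_shape[2])
    v3 <- which(i3 >= 0L & i3 < in_shape[3])
    if (!length(v1) || !length(v2) || !length(v3)) next
    g <- expand.grid(a = v1, b = v2, c = v3)
    o_lin <- (g$a - 1L) + out_shape[1] * (g$b - 1L) +
      out_shape[1] * out_shape[2] * (g$c - 1L) + 1L
    i_lin <- i1[g$a] + in_shape[1] * i2[g$b] +
      in_shape[1] * in_shape[2] * i3[g$c] + 1L
    rows[[tap]] <- (tap - 1L) * n_out + o_lin
    cols[[tap]] <- i_lin
  }
  S <- Matrix::sparseMatrix(i = unlist(rows), j = unlist(cols), x = 1,
                            dims = c(n_out * k3, prod(in_shape)))
  list(S = S, in_shape = in_shape, out_shape = out_shape,
       n_in = prod(in_shape), n_out = n_out, k = k, k3 = k3)
}

plan_cache_get <- function(cache, in_shape, k, stride) {
  key <- paste(c(in_shape, k, stride), collapse = "_")
  p <- cache[[key]]
  if (is.null(p)) {
    p <- make_conv_plan(in_shape, k, stride)
    cache[[key]] <- p
  }
  p
}

# ---- layers -----------------------------------------------------------

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  for (nm in names(list(...))) assign(nm, list(...)[[nm]], envir = e)
  e
}

init_conv <- function(c_in, c_out, k, stride, init_sd = 0.02) {
  new_layer("conv", c_in = c_in, c_out = c_out, k = k, stride = stride,
            W = matrix(rnorm(k^3 * c_in * c_out, 0, init_sd), k^3 * c_in, c_out),
            b = numeric(c_out))
}

init_convt <- function(c_in, c_out, k, stride, init_sd = 0.02) {
  new_layer("convt", c_in = c_in, c_out = c_out, k = k, stride = stride,
            W = matrix(rnorm(k^3 * c_out * c_in, 0, init_sd), k^3 * c_out, c_in),
            b = numeric(c_out))
}

init_bn <- function(c, eps = 1e-3, momentum = 0.99) {
  new_layer("bn", c = c, eps = eps, momentum = momentum,
            gamma = rep(1, c), beta = numeric(c),
            run_mean = numeric(c), run_var = rep(1, c))
}

conv_forward <- function(ly, x, in_shape, plans) {
  p <- plan_cache_get(plans, in_shape, ly$k, ly$stride)
  col <- as.matrix(p$S %*% x)
  dim(col) <- c(p$n_out, p$k3 * ly$c_in)
  ly$cache_col <- col
  ly$cache_plan <- p
  out <- col %*% ly$W
  out <- sweep(out, 2, ly$b, "+")
  list(out = out, shape = p$out_shape)
}

conv_backward <- function(ly, dout, accumulate = TRUE) {
  p <- ly$cache_plan
  if (accumulate) {
    ly$gW <- ly$gW + crossprod(ly$cache_col, dout)
    ly$gb <- ly$gb + colSums(dout)
  }
  dcol <- dout %*% t(ly$W)
  dim(dcol) <- c(p$n_out * p$k3, ly$c_in)
  as.matrix(Matrix::crossprod(p$S, dcol))
}

convt_forward <- function(ly, x, in_shape, plans) {
  out_shape <- as.integer(in_shape * ly$stride)
  p <- plan_cache_get(plans, out_shape, ly$k, ly$stride)
  stopifnot(p$n_out == nrow(x))
  g <- x %*% t(ly$W)                      # (n_in, k3*c_out)
  dim(g) <- c(p$n_out * p$k3, ly$c_out)
  out <- as.matrix(Matrix::crossprod(p$S, g))
  out <- sweep(out, 2, ly$b, "+")
  ly$cache_x <- x
  ly$cache_plan <- p
  list(out = out, shape = out_shape)
}

convt_backward <- function(ly, dout, accumulate = TRUE) {
  p <- ly$cache_plan
  dg <- as.matrix(p$S %*% dout)
  dim(dg) <- c(p$n_out, p$k3 * ly$c_out)
  if (accumulate) {
    ly$gW <- ly$gW + crossprod(dg, ly$cache_x)
    ly$gb <- ly$gb + colSums(dout)
  }
  dg %*% ly$W
}

bn_forward <- function(ly, x, training) {
  ly$cache_training <- training
  if (training) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    va <- colMeans(xc^2)
    ly$run_mean <- ly$momentum * ly$run_mean + (1 - ly$momentum) * mu
    ly$run_var <- ly$momentum * ly$run_var + (1 - ly$momentum) * va
    inv <- 1 / sqrt(va + ly$eps)
    xhat <- sweep(xc, 2, inv, "*")
    ly$cache_xhat <- xhat
    ly$cache_inv <- inv
  } else {
    inv <- 1 / sqrt(ly$run_var + ly$eps)
    xhat <- sweep(sweep(x, 2, ly$run_mean), 2, inv, "*")
  }
  sweep(sweep(xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
}

bn_backward <- function(ly, dout, accumulate = TRUE) {
  if (!isTRUE(ly$cache_training)) {
    # inference mode is a fixed per-channel affine map; parameter
    # gradients are not accumulated on this path (probing only)
    return(sweep(dout, 2, ly$gamma / sqrt(ly$run_var + ly$eps), "*"))
  }
  xhat <- ly$cache_xhat
  n <- nrow(dout)
  if (accumulate) {
    ly$ggamma <- ly$ggamma + colSums(dout * xhat)
    ly$gbeta <- ly$gbeta + colSums(dout)
  }
  dxhat <- sweep(dout, 2, ly$gamma, "*")
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), "*")
  sweep(t1 - t2, 2, ly$cache_inv, "*")
}

lrelu <- function(x, slope) ifelse(x >= 0, x, slope * x)
lrelu_grad <- function(x, slope) ifelse(x >= 0, 1, slope)

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, mask = NULL))
  mask <- matrix(runif(length(x)) >= rate, nrow(x), ncol(x)) / (1 - rate)
  list(out = x * mask, mask = mask)
}

# ---- parameter bookkeeping -------------------------------------------

layer_param_names <- function(ly) {
  switch(ly$type, conv = c("W", "b"), convt = c("W", "b"),
         bn = c("gamma", "beta"), character(0))
}

zero_grads <- function(layers) {
  for (ly in layers) for (nm in layer_param_names(ly)) {
    assign(paste0("g", nm), get(nm, envir = ly) * 0, envir = ly)
  }
  invisible(NULL)
}

count_params <- function(layers) {
  sum(vapply(layers, function(ly)
    sum(vapply(layer_param_names(ly),
               function(nm) length(get(nm, envir = ly)), 0)), 0))
}

layers_state <- function(layers) {
  lapply(layers, function(ly) {
    st <- list(type = ly$type)
    for (nm in c(layer_param_names(ly), "run_mean", "run_var")) {
      if (exists(nm, envir = ly, inherits = FALSE)) st[[nm]] <- get(nm, envir = ly)
    }
    st
  })
}

layers_restore <- function(layers, state) {
  stopifnot(length(layers) == length(state))
  for (i in seq_along(layers)) {
    for (nm in setdiff(names(state[[i]]), "type")) {
      assign(nm, state[[i]][[nm]], envir = layers[[i]])
    }
  }
  invisible(layers)
}

adam_init <- function(layers) {
  for (ly in layers) for (nm in layer_param_names(ly)) {
    assign(paste0("m_", nm), get(nm, envir = ly) * 0, envir = ly)
    assign(paste0("v_", nm), get(nm, envir = ly) * 0, envir = ly)
  }
  zero_grads(layers)
}

adam_step <- function(layers, lr, beta1, beta2, t, eps = 1e-8) {
  for (ly in layers) for (nm in layer_param_names(ly)) {
    g <- get(paste0("g", nm), envir = ly)
    m <- beta1 * get(paste0("m_", nm), envir = ly) + (1 - beta1) * g
    v <- beta2 * get(paste0("v_", nm), envir = ly) + (1 - beta2) * g^2
    assign(paste0("m_", nm), m, envir = ly)
    assign(paste0("v_", nm), v, envir = ly)
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    assign(nm, get(nm, envir = ly) - lr * mhat / (sqrt(vhat) + eps), envir = ly)
    assign(paste0("g", nm), g * 0, envir = ly)
  }
  invisible(NULL)
}

# intensity <-> network scale: 8-bit [0,255] maps onto the tanh range
normalize_intensity <- function(x) x / 127.5 - 1
denormalize_intensity <- function(y) pmin(pmax(round_half_away((y + 1) * 127.5), 0), 255)
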