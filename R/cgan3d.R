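# 3D pix2pix conditional GAN: a 3D U-Net generator translating
# artifact-bearing cubes into artifact-free ones, and a 3D PatchGAN
# discriminator scoring (source, candidate) pairs patch-wise.  Trained
# alternately with binary cross-entropy adversarial losses plus an L1
# reconstruction term weighted by lambda.

default_encoder_filters <- c(64, 128, 256, 512, 512, 512, 512, 512)

#' Generator (3D U-Net) architecture specification
#'
#' The encoder halves the cube edge per block down to a 1-cube
#' bottleneck, so the number of encoder blocks is `log2(cube_edge)`;
#' the decoder mirrors the encoder minus the bottleneck and ends in a
#' transposed convolution with a tanh head.  The default filter
#' progression is 64-128-256-512-512-... truncated to the depth.  All
#' convolutions use 4-cube kernels with stride 2 and same padding.
#'
#' @param cube_edge input/output cube edge; a power of two >= 8.
#' @param encoder_filters integer vector, one entry per encoder block.
#' @param decoder_filters integer vector of `length(encoder_filters)-1`
#'   entries (default: mirror of the encoder minus the bottleneck).
#' @param kernel kernel edge (default 4).
#' @param stride stride (default 2).
#' @param dropout_rate dropout on the first `n_dropout` decoder blocks.
#' @param n_dropout number of decoder blocks with dropout (default 3).
#' @param leaky_slope negative slope of the encoder leaky ReLUs.
#' @return a `generator_spec` list.
#' @export
generator_spec <- function(cube_edge = 256L,
                           encoder_filters = NULL,
                           decoder_filters = NULL,
                           kernel = 4L, stride = 2L,
                           dropout_rate = 0.5, n_dropout = 3L,
                           leaky_slope = 0.2) {
  n <- log2(cube_edge)
  if (cube_edge < 8 || n != round(n))
    abort_param("cube_edge must be a power of two >= 8")
  n <- as.integer(n)
  if (is.null(encoder_filters))
    encoder_filters <- rep_len(default_encoder_filters, max(n, 8L))[1:n]
  if (length(encoder_filters) != n)
    abort_param(sprintf("need log2(cube_edge) = %d encoder filter entries", n))
  if (is.null(decoder_filters)) decoder_filters <- rev(encoder_filters)[-1]
  if (length(decoder_filters) != n - 1L)
    abort_param("decoder_filters must mirror the encoder minus the bottleneck")
  structure(list(cube_edge = as.integer(cube_edge),
                 encoder_filters = as.integer(encoder_filters),
                 decoder_filters = as.integer(decoder_filters),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 dropout_rate = dropout_rate, n_dropout = as.integer(n_dropout),
                 leaky_slope = leaky_slope),
            class = "generator_spec")
}

#' Discriminator (3D PatchGAN) architecture specification
#'
#' Four convolution blocks (filters 64-128-256-512 by default) with
#' strides 2,2,2,1, followed by a stride-1 scoring convolution with a
#' sigmoid head; the final two convolutions therefore run at stride 1.
#' With 4-cube kernels this stack sees a 70-voxel patch per output
#' score.
#'
#' @param filters integer vector of block filter counts.
#' @param strides integer vector of per-block strides (last entries 1).
#' @param kernel kernel edge (default 4).
#' @param leaky_slope negative slope of the leaky ReLUs.
#' @return a `discriminator_spec` list.
#' @export
discriminator_spec <- function(filters = c(64, 128, 256, 512),
                               strides = c(2, 2, 2, 1),
                               kernel = 4L, leaky_slope = 0.2) {
  if (length(strides) != length(filters))
    abort_param("filters and strides must have equal length")
  if (utils::tail(strides, 1) != 1)
    abort_param("the final block must have stride 1 (the scoring conv is stride 1 too)")
  structure(list(filters = as.integer(filters), strides = as.integer(strides),
                 kernel = as.integer(kernel), leaky_slope = leaky_slope),
            class = "discriminator_spec")
}

#' Analytic receptive field of the discriminator
#'
#' Voxels per axis of input seen by one output patch score, from the
#' standard recurrence `RF <- RF + (k - 1) * jump; jump <- jump * s`
#' over the layer stack (blocks plus the stride-1 scoring conv).  The
#' default spec yields 70.
#'
#' @param spec a [discriminator_spec()].
#' @return integer receptive-field edge in voxels.
#' @export
receptive_field <- function(spec = discriminator_spec()) {
  stopifnot(inherits(spec, "discriminator_spec"))
  strides <- c(spec$strides, 1L)  # blocks + scoring conv
  rf <- 1
  jump <- 1
  for (s in strides) {
    rf <- rf + (spec$kernel - 1) * jump
    jump <- jump * s
  }
  as.integer(rf)
}

#' Build the 3D U-Net generator
#'
#' Encoder blocks: convolution, batch normalization (absent in the
#' first block and the bottleneck) and leaky ReLU; the bottleneck uses
#' a plain ReLU.  Decoder blocks: transposed convolution, batch norm,
#' dropout on the first `n_dropout` blocks, concatenation with the
#' same-resolution encoder output (skip connection), ReLU.  The output
#' layer is a transposed convolution with a tanh head mapping back to
#' one channel.  Weights are initialized from N(0, 0.02^2).
#'
#' @param spec a [generator_spec()].
#' @param init_seed seed for weight initialization.
#' @return a `generator_model`.
#' @export
build_generator <- function(spec = generator_spec(), init_seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- length(spec$encoder_filters)
  with_seed(init_seed, {
    enc <- vector("list", n)
    c_prev <- 1L
    for (i in seq_len(n)) {
      enc[[i]] <- list(conv = init_conv(c_prev, spec$encoder_filters[i],
                                        spec$kernel, spec$stride),
                       bn = if (i > 1L && i < n)
                         init_bn(spec$encoder_filters[i]) else NULL,
                       act = if (i < n) "lrelu" else "relu")
      c_prev <- spec$encoder_filters[i]
    }
    dec <- vector("list", n - 1L)
    for (j in seq_len(n - 1L)) {
      c_in <- if (j == 1L) spec$encoder_filters[n] else
        spec$decoder_filters[j - 1L] + spec$encoder_filters[n - j + 1L]
      dec[[j]] <- list(convt = init_convt(c_in, spec$decoder_filters[j],
                                          spec$kernel, spec$stride),
                       bn = init_bn(spec$decoder_filters[j]),
                       dropout = j <= spec$n_dropout,
                       skip = n - j)
    }
    out_cin <- spec$decoder_filters[n - 1L] + spec$encoder_filters[1L]
    out_layer <- init_convt(out_cin, 1L, spec$kernel, spec$stride)
    model <- structure(list(spec = spec, enc = enc, dec = dec,
                            out = out_layer, plans = new.env(parent = emptyenv()),
                            meta = new.env(parent = emptyenv())),
                       class = "generator_model")
    model$meta$epoch <- 0L
    model$meta$init_seed <- as.integer(init_seed)
    model
  })
}

gen_layers <- function(model) {
  ls <- list()
  for (b in model$enc) { ls <- c(ls, list(b$conv)); if (!is.null(b$bn)) ls <- c(ls, list(b$bn)) }
  for (b in model$dec) ls <- c(ls, list(b$convt), list(b$bn))
  c(ls, list(model$out))
}

#' Number of learnable parameters of a model
#'
#' Counts convolution weights and biases and batch-norm scale/shift
#' parameters (running statistics excluded).
#'
#' @param model a `generator_model` or `discriminator_model`.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  layers <- if (inherits(model, "generator_model")) gen_layers(model)
            else disc_layers(model)
  count_params(layers)
}

generator_forward <- function(model, x, training = FALSE) {
  spec <- model$spec
  n <- length(model$enc)
  shape <- rep(spec$cube_edge, 3L)
  e_out <- vector("list", n)
  e_shape <- vector("list", n)
  e_pre <- vector("list", n)
  h <- x
  for (i in seq_len(n)) {
    blk <- model$enc[[i]]
    cf <- conv_forward(blk$conv, h, shape, model$plans)
    h <- cf$out; shape <- cf$shape
    if (!is.null(blk$bn)) h <- bn_forward(blk$bn, h, training)
    e_pre[[i]] <- h
    h <- if (blk$act == "lrelu") lrelu(h, spec$leaky_slope) else pmax(h, 0)
    e_out[[i]] <- h
    e_shape[[i]] <- shape
  }
  d_pre <- vector("list", n - 1L)
  d_drop <- vector("list", n - 1L)
  for (j in seq_len(n - 1L)) {
    blk <- model$dec[[j]]
    tf <- convt_forward(blk$convt, h, shape, model$plans)
    h <- tf$out; shape <- tf$shape
    h <- bn_forward(blk$bn, h, training)
    if (blk$dropout) {
      dr <- dropout_forward(h, spec$dropout_rate, training)
      h <- dr$out
      d_drop[[j]] <- dr$mask
    }
    h <- cbind(h, e_out[[blk$skip]])
    d_pre[[j]] <- h
    h <- pmax(h, 0)
  }
  of <- convt_forward(model$out, h, shape, model$plans)
  y <- tanh(of$out)
  model$meta$cache <- list(e_pre = e_pre, e_out = e_out, d_pre = d_pre,
                           d_drop = d_drop, y = y)
  y
}

generator_backward <- function(model, dy) {
  spec <- model$spec
  n <- length(model$enc)
  cache <- model$meta$cache
  dh <- dy * (1 - cache$y^2)                       # tanh'
  dh <- convt_backward(model$out, dh)
  skip_grads <- vector("list", n)
  for (j in rev(seq_len(n - 1L))) {
    blk <- model$dec[[j]]
    dh <- dh * (cache$d_pre[[j]] >= 0)             # relu'
    cs <- ncol(dh) - spec$encoder_filters[blk$skip]
    dskip <- dh[, (cs + 1L):ncol(dh), drop = FALSE]
    sg <- skip_grads[[blk$skip]]
    skip_grads[[blk$skip]] <- if (is.null(sg)) dskip else sg + dskip
    dh <- dh[, seq_len(cs), drop = FALSE]
    if (blk$dropout && !is.null(cache$d_drop[[j]])) dh <- dh * cache$d_drop[[j]]
    dh <- bn_backward(blk$bn, dh)
    dh <- convt_backward(blk$convt, dh)
  }
  for (i in rev(seq_len(n))) {
    blk <- model$enc[[i]]
    if (!is.null(skip_grads[[i]])) dh <- dh + skip_grads[[i]]
    dh <- if (blk$act == "lrelu") dh * lrelu_grad(cache$e_pre[[i]], spec$leaky_slope)
          else dh * (cache$e_pre[[i]] >= 0)
    if (!is.null(blk$bn)) dh <- bn_backward(blk$bn, dh)
    dh <- conv_backward(blk$conv, dh)
  }
  dh
}

#' Build the 3D PatchGAN discriminator
#'
#' The input is the channel-wise concatenation of the source cube and
#' a candidate cube (real target or generator output).  Each block is
#' convolution, batch normalization (absent in the first block) and
#' leaky ReLU; a final stride-1 convolution with a sigmoid head emits
#' the 3D patch score map, every score in (0, 1).
#'
#' @param spec a [discriminator_spec()].
#' @param init_seed seed for weight initialization.
#' @return a `discriminator_model`.
#' @export
build_discriminator <- function(spec = discriminator_spec(), init_seed = 1L) {
  stopifnot(inherits(spec, "discriminator_spec"))
  with_seed(init_seed, {
    nb <- length(spec$filters)
    blocks <- vector("list", nb)
    c_prev <- 2L
    for (i in seq_len(nb)) {
      blocks[[i]] <- list(conv = init_conv(c_prev, spec$filters[i],
                                           spec$kernel, spec$strides[i]),
                          bn = if (i > 1L) init_bn(spec$filters[i]) else NULL)
      c_prev <- spec$filters[i]
    }
    score <- init_conv(c_prev, 1L, spec$kernel, 1L)
    structure(list(spec = spec, blocks = blocks, score = score,
                   plans = new.env(parent = emptyenv()),
                   meta = new.env(parent = emptyenv())),
              class = "discriminator_model")
  })
}

disc_layers <- function(model) {
  ls <- list()
  for (b in model$blocks) { ls <- c(ls, list(b$conv)); if (!is.null(b$bn)) ls <- c(ls, list(b$bn)) }
  c(ls, list(model$score))
}

sigmoid <- function(x) 1 / (1 + exp(-pmin(pmax(x, -30), 30)))

discriminator_forward <- function(model, source, candidate, in_shape,
                                  training = FALSE) {
  spec <- model$spec
  h <- cbind(source, candidate)
  shape <- as.integer(in_shape)
  pre <- vector("list", length(model$blocks))
  for (i in seq_along(model$blocks)) {
    blk <- model$blocks[[i]]
    cf <- conv_forward(blk$conv, h, shape, model$plans)
    h <- cf$out; shape <- cf$shape
    if (!is.null(blk$bn)) h <- bn_forward(blk$bn, h, training)
    pre[[i]] <- h
    h <- lrelu(h, spec$leaky_slope)
  }
  sf <- conv_forward(model$score, h, shape, model$plans)
  model$meta$cache <- list(pre = pre)
  list(scores = sigmoid(sf$out), logits = sf$out, shape = sf$shape)
}

# dlogits: gradient w.r.t. the pre-sigmoid scoring logits (the fused
# sigmoid+BCE form (p - y)/N is used by the training loop for
# numerical stability).  Returns the gradient w.r.t. the 2-channel
# input; set accumulate = FALSE to probe input gradients without
# touching parameter gradients.
discriminator_backward <- function(model, dlogits, accumulate = TRUE) {
  spec <- model$spec
  cache <- model$meta$cache
  dh <- conv_backward(model$score, dlogits, accumulate)
  for (i in rev(seq_along(model$blocks))) {
    blk <- model$blocks[[i]]
    dh <- dh * lrelu_grad(cache$pre[[i]], spec$leaky_slope)
    if (!is.null(blk$bn)) dh <- bn_backward(blk$bn, dh, accumulate)
    dh <- conv_backward(blk$conv, dh, accumulate)
  }
  dh
}

#' Empirically probe the discriminator receptive field
#'
#' Cross-check of [receptive_field()]: builds a discriminator with the
#' given kernel/stride stack (filter counts may be overridden — the
#' footprint does not depend on them), runs a forward pass in
#' inference mode on a random volume, back-propagates from a single
#' central patch score and measures the per-axis extent of the nonzero
#' input-gradient footprint.
#'
#' @param spec a [discriminator_spec()].
#' @param input_edge probe volume edge (must exceed the receptive
#'   field for an interior score; default 80).
#' @param filters optional reduced filter counts for speed.
#' @param seed RNG seed for weights and probe volume.
#' @return integer: maximal footprint extent over the three axes.
#' @export
probe_receptive_field <- function(spec = discriminator_spec(),
                                  input_edge = 80L, filters = NULL,
                                  seed = 1L) {
  if (!is.null(filters)) {
    spec <- discriminator_spec(filters = filters, strides = spec$strides,
                               kernel = spec$kernel,
                               leaky_slope = spec$leaky_slope)
  }
  model <- build_discriminator(spec, init_seed = seed)
  shape <- rep(as.integer(input_edge), 3L)
  x <- with_seed(seed + 1L, matrix(rnorm(prod(shape) * 2), prod(shape), 2))
  fw <- discriminator_forward(model, x[, 1, drop = FALSE],
                              x[, 2, drop = FALSE], shape, training = FALSE)
  # scores near the map center can still have their support clipped by
  # the asymmetric trailing padding, so probe a few diagonal candidates
  # and keep the widest (interior) footprint
  ctrs <- unique(pmax(0L, pmin(fw$shape[1] - 1L,
                               floor(fw$shape[1] / 2) + (-3:1))))
  best <- 0L
  for (ci in ctrs) {
    dl <- matrix(0, nrow(fw$logits), 1)
    dl[1 + ci + fw$shape[1] * ci + fw$shape[1] * fw$shape[2] * ci, 1] <- 1
    din <- discriminator_backward(model, dl, accumulate = FALSE)
    foot <- array(rowSums(abs(din)) > 0, shape)
    ext <- vapply(1:3, function(ax) {
      any_ax <- apply(foot, ax, any)
      if (!any(any_ax)) return(0L)
      diff(range(which(any_ax))) + 1L
    }, 0L)
    best <- max(best, ext)
  }
  best
}

# ---- losses -----------------------------------------------------------

clamp_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

bce_mean <- function(p, y) {
  p <- clamp_prob(p)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Generator loss: adversarial BCE plus weighted L1
#'
#' `BCE(d_scores_fake, 1) + lambda_l1 * mean(|generated - target|)`:
#' the generator is rewarded for patch scores the discriminator takes
#' for real, plus an L1 reconstruction term that anchors the output to
#' the ground truth.
#'
#' @param d_scores_fake patch score map of the fake pair, values in (0, 1).
#' @param generated,target cubes (arrays or matrices) of equal shape,
#'   on a common intensity scale.
#' @param lambda_l1 L1 weight (default 100).
#' @return scalar loss.
#' @export
generator_loss <- function(d_scores_fake, generated, target, lambda_l1 = 100) {
  if (!all(dim(generated) == dim(target)) || length(generated) != length(target))
    abort_param("generated and target must share one shape")
  bce_mean(d_scores_fake, 1) + lambda_l1 * mean(abs(generated - target))
}

#' Discriminator loss: averaged real/fake BCE
#'
#' `0.5 * (BCE(d_scores_real, 1) + BCE(d_scores_fake, 0))`; the
#' halving follows the original pix2pix convention of slowing the
#' discriminator relative to the generator.
#'
#' @param d_scores_real,d_scores_fake patch score maps in (0, 1).
#' @return scalar loss.
#' @export
discriminator_loss <- function(d_scores_real, d_scores_fake) {
  0.5 * (bce_mean(d_scores_real, 1) + bce_mean(d_scores_fake, 0))
}

# ---- training ---------------------------------------------------------

#' Training configuration
#'
#' Defaults are the published pix2pix settings for this task: Adam
#' with learning rate 0.0002, beta1 = 0, beta2 = 0.999, batch size 1,
#' lambda = 100 on the L1 term, and a generator checkpoint every 10
#' epochs.  Note beta1 = 0 (not the 0.5 of the original pix2pix
#' implementation) is used deliberately.
#'
#' @param epochs number of training epochs.
#' @param lambda_l1 L1 weight in the generator objective.
#' @param learning_rate,beta1,beta2 Adam settings.
#' @param batch_size training batch size (only 1 is supported, as in
#'   the published setup).
#' @param checkpoint_interval_epochs checkpoint cadence.
#' @param seed global training seed (shuffling, dropout, init).
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 100L, lambda_l1 = 100,
                         learning_rate = 2e-4, beta1 = 0, beta2 = 0.999,
                         batch_size = 1L, checkpoint_interval_epochs = 10L,
                         seed = 1L) {
  if (lambda_l1 <= 0) abort_param("lambda_l1 must be positive")
  if (batch_size != 1L) abort_param("only batch_size = 1 is supported")
  if (epochs < 1L) abort_param("epochs must be >= 1")
  structure(list(epochs = as.integer(epochs), lambda_l1 = lambda_l1,
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 batch_size = 1L,
                 checkpoint_interval_epochs = as.integer(checkpoint_interval_epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

generator_state <- function(model) {
  list(spec = model$spec, epoch = model$meta$epoch,
       enc = layers_state(gen_layers(model)))
}

generator_from_state <- function(state) {
  model <- build_generator(state$spec, init_seed = 0L)
  layers_restore(gen_layers(model), state$enc)
  model$meta$epoch <- state$epoch
  model
}

save_generator_checkpoint <- function(model, dir, epoch) {
  path <- file.path(dir, sprintf("generator_epoch%d.rds", epoch))
  st <- generator_state(model)
  st$epoch <- as.integer(epoch)
  saveRDS(st, path)
  list(epoch = as.integer(epoch), path = path)
}

#' Load a generator checkpoint
#'
#' @param path path to a `generator_epoch<N>.rds` checkpoint file.
#' @return a `generator_model`.
#' @export
load_generator <- function(path) {
  if (!file.exists(path)) abort_io(paste0("no such checkpoint: ", path))
  generator_from_state(readRDS(path))
}

#' Train the 3D pix2pix conditional GAN
#'
#' Alternating updates with batch size 1: per training pair, one
#' discriminator step on the real pair (source, target) and the fake
#' pair (source, generated), then one generator step against the
#' adversarial plus L1 objective.  Intensities are normalized to
#' `[-1, 1]` before the network and denormalized after.  A generator
#' checkpoint is written at epoch 0 (the untrained baseline) and every
#' `checkpoint_interval_epochs`; per-iteration losses are logged to
#' `losses.csv` and a JSON manifest records specs, config and seed.
#' Fully deterministic given `cfg$seed`.
#'
#' @param pairs list of `training_pair` objects with one common cube
#'   edge.
#' @param gen_spec,disc_spec architecture specifications; the
#'   generator's `cube_edge` must equal the pairs' edge.
#' @param cfg a [train_config()].
#' @param checkpoint_dir directory for checkpoints and logs.
#' @return a `checkpoint_series`: list with `checkpoints` (epoch,
#'   path), `losses` (data frame), `gen_spec`, `cfg`, `dir`.
#' @export
train_cgan <- function(pairs, gen_spec, disc_spec = NULL,
                       cfg = train_config(), checkpoint_dir = tempfile("run")) {
  if (!length(pairs)) abort_param("`pairs` must be non-empty")
  edges <- unique(vapply(pairs, function(p) dim(p$source$data)[1], 0))
  shapes_ok <- all(vapply(pairs, function(p)
    length(unique(dim(p$source$data))) == 1L &&
      all(dim(p$source$data) == dim(p$target$data)), TRUE))
  if (length(edges) != 1L || !shapes_ok)
    abort_param("all pairs must be cubes of one common edge length")
  if (edges != gen_spec$cube_edge)
    abort_param(sprintf("pair edge (%d) != generator cube_edge (%d)",
                        edges, gen_spec$cube_edge))
  if (is.null(disc_spec)) disc_spec <- discriminator_spec()
  dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
  shape <- rep(gen_spec$cube_edge, 3L)
  n_vox <- prod(shape)
  a_list <- lapply(pairs, function(p)
    matrix(normalize_intensity(as.numeric(p$source$data)), n_vox, 1))
  b_list <- lapply(pairs, function(p)
    matrix(normalize_intensity(as.numeric(p$target$data)), n_vox, 1))

  losses <- vector("list", cfg$epochs * length(pairs))
  series <- list()
  with_seed(cfg$seed, {
    G <- build_generator(gen_spec, init_seed = derive_seed(cfg$seed, "gen_init"))
    D <- build_discriminator(disc_spec,
                             init_seed = derive_seed(cfg$seed, "disc_init"))
    gl <- gen_layers(G); dl <- disc_layers(D)
    adam_init(gl); adam_init(dl)
    series[[1]] <- save_generator_checkpoint(G, checkpoint_dir, 0L)
    it <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(length(pairs))
      for (idx in ord) {
        it <- it + 1L
        a <- a_list[[idx]]; b <- b_list[[idx]]
        fake <- generator_forward(G, a, training = TRUE)
        # --- discriminator update ---
        fr <- discriminator_forward(D, a, b, shape, training = TRUE)
        np <- length(fr$logits)
        discriminator_backward(D, (fr$scores - 1) * (0.5 / np))
        ff <- discriminator_forward(D, a, fake, shape, training = TRUE)
        discriminator_backward(D, ff$scores * (0.5 / np))
        adam_step(dl, cfg$learning_rate, cfg$beta1, cfg$beta2, it)
        # --- generator update ---
        fg <- discriminator_forward(D, a, fake, shape, training = TRUE)
        dinput <- discriminator_backward(D, (fg$scores - 1) / np,
                                         accumulate = FALSE)
        zero_grads(dl)
        dfake <- dinput[, 2, drop = FALSE] +
          cfg$lambda_l1 * sign(fake - b) / n_vox
        generator_backward(G, dfake)
        adam_step(gl, cfg$learning_rate, cfg$beta1, cfg$beta2, it)
        losses[[it]] <- c(iteration = it, epoch = epoch,
                          d_loss = discriminator_loss(fr$scores, ff$scores),
                          g_adv = bce_mean(fg$scores, 1),
                          g_l1 = mean(abs(fake - b)))
      }
      G$meta$epoch <- epoch
      if (epoch %% cfg$checkpoint_interval_epochs == 0L) {
        series[[length(series) + 1L]] <-
          save_generator_checkpoint(G, checkpoint_dir, epoch)
      }
    }
  })
  loss_df <- as.data.frame(do.call(rbind, losses))
  utils::write.csv(loss_df, file.path(checkpoint_dir, "losses.csv"),
                   row.names = FALSE)
  manifest <- list(gen_spec = unclass(gen_spec), disc_spec = unclass(disc_spec),
                   cfg = unclass(cfg), n_pairs = length(pairs),
                   checkpoints = vapply(series, function(s) basename(s$path), ""),
                   loss_trace = "losses.csv")
  jsonlite::write_json(manifest, file.path(checkpoint_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(list(checkpoints = series, gen_spec = gen_spec,
                 disc_spec = disc_spec, cfg = cfg, losses = loss_df,
                 dir = checkpoint_dir),
            class = "checkpoint_series")
}

#' Run the generator on a cube
#'
#' Deterministic inference: dropout off, batch normalization on
#' running statistics.  The cube is normalized to `[-1, 1]`, passed
#' through the network and mapped back to 8-bit.
#'
#' @param model a `generator_model` (or a checkpoint entry/path).
#' @param cube an 8-bit `volume3d` with edge equal to the model's
#'   `cube_edge`.
#' @return a `volume3d` of the same shape, voxel size and origin.
#' @export
generate <- function(model, cube) {
  if (is.character(model)) model <- load_generator(model)
  if (is.list(model) && !inherits(model, "generator_model") &&
      !is.null(model$path)) model <- load_generator(model$path)
  stopifnot(inherits(model, "generator_model"))
  cube <- as_volume3d(cube)
  d <- dim(cube$data)
  e <- model$spec$cube_edge
  if (length(unique(d)) != 1L || d[1] != e)
    abort_param(sprintf("cube must be %d^3 voxels for this model, got %s",
                        e, paste(d, collapse = "x")))
  x <- matrix(normalize_intensity(as.numeric(cube$data)), prod(d), 1)
  y <- generator_forward(model, x, training = FALSE)
  volume3d(array(denormalize_intensity(y), d), cube$voxel_size_um, cube$origin)
}
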