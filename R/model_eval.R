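# Checkpoint-selection metrics: relative error, PSNR and a
# whole-volume SSIM, plus the rank-sum selection over a checkpoint
# series evaluated on held-out pairs.

#' Metric configuration
#'
#' @param max_v maximum possible voxel value (255 for 8-bit volumes).
#' @param c1,c2 SSIM stabilizers; defaults are the standard constants
#'   `(0.01 max_v)^2` and `(0.03 max_v)^2`.
#' @param psnr_cap_db value reported when MSE = 0 (identical pair);
#'   default `Inf`, serialized as `"inf"`.
#' @return a `metric_config` list.
#' @export
metric_config <- function(max_v = 255, c1 = (0.01 * max_v)^2,
                          c2 = (0.03 * max_v)^2, psnr_cap_db = Inf) {
  if (c1 <= 0 || c2 <= 0) abort_param("c1 and c2 must be positive")
  structure(list(max_v = max_v, c1 = c1, c2 = c2, psnr_cap_db = psnr_cap_db),
            class = "metric_config")
}

metric_data <- function(x) if (inherits(x, "volume3d")) x$data else x

check_same_shape <- function(gen, real) {
  g <- metric_data(gen); r <- metric_data(real)
  if (!all(dim(g) == dim(r)))
    abort_param("volumes must share one shape")
  list(g = as.numeric(g), r = as.numeric(r))
}

#' Relative error between a generated and a ground-truth volume
#'
#' Sum of absolute voxel differences normalized by the summed
#' ground-truth intensity:
#' `RE = sum |I_gen - I_real| / sum I_real`.  Absolute differences are
#' summed first and normalized once per pair (not voxel-wise), making
#' the measure insensitive to overall intensity scale.
#'
#' @param gen,real volumes (`volume3d` or arrays) of one shape.
#' @return non-negative scalar.
#' @export
relative_error <- function(gen, real) {
  d <- check_same_shape(gen, real)
  denom <- sum(d$r)
  if (denom == 0)
    abort("relative error undefined: ground truth sums to zero",
          "airgap3d_undefined_normalization")
  sum(abs(d$g - d$r)) / denom
}

#' Peak signal-to-noise ratio in decibels
#'
#' `PSNR = 10 log10(max_v^2 / MSE)`; identical pairs (MSE = 0) report
#' `cfg$psnr_cap_db` (infinity by convention).
#'
#' @param gen,real volumes of one shape.
#' @param cfg a [metric_config()].
#' @return PSNR in dB.
#' @export
psnr <- function(gen, real, cfg = metric_config()) {
  d <- check_same_shape(gen, real)
  mse <- mean((d$g - d$r)^2)
  if (mse == 0) return(cfg$psnr_cap_db)
  10 * log10(cfg$max_v^2 / mse)
}

#' Structural similarity index of a volume pair
#'
#' Whole-volume (single-window) SSIM: one mean, variance and
#' covariance per volume,
#' `[(2 mu_g mu_r + c1)(2 cov + c2)] / [(mu_g^2 + mu_r^2 + c1)(var_g + var_r + c2)]`.
#' Symmetric in its arguments, 1 iff the volumes are identical.  An
#' optional sliding-window mean (`window` voxels per axis) is offered
#' for local structure weighting.
#'
#' @param gen,real volumes of one shape.
#' @param cfg a [metric_config()].
#' @param window `NULL` for the single-window form (default), or an
#'   odd cubic window edge for a sliding-window mean SSIM.
#' @return scalar in `[-1, 1]`.
#' @export
ssim <- function(gen, real, cfg = metric_config(), window = NULL) {
  d <- check_same_shape(gen, real)
  if (is.null(window)) {
    return(ssim_terms(d$g, d$r, cfg))
  }
  if (window %% 2 != 1) abort_param("window must be odd")
  g <- metric_data(gen); r <- metric_data(real)
  dm <- dim(g)
  half <- (window - 1) / 2
  centers <- lapply(dm, function(n) seq(1 + half, n - half, by = window))
  vals <- c()
  for (cz in centers[[1]]) for (cy in centers[[2]]) for (cx in centers[[3]]) {
    iz <- (cz - half):(cz + half); iy <- (cy - half):(cy + half)
    ix <- (cx - half):(cx + half)
    vals <- c(vals, ssim_terms(as.numeric(g[iz, iy, ix]),
                               as.numeric(r[iz, iy, ix]), cfg))
  }
  mean(vals)
}

ssim_terms <- function(g, r, cfg) {
  n <- length(g)
  mu_g <- mean(g); mu_r <- mean(r)
  var_g <- sum((g - mu_g)^2) / n
  var_r <- sum((r - mu_r)^2) / n
  cov_gr <- sum((g - mu_g) * (r - mu_r)) / n
  ((2 * mu_g * mu_r + cfg$c1) * (2 * cov_gr + cfg$c2)) /
    ((mu_g^2 + mu_r^2 + cfg$c1) * (var_g + var_r + cfg$c2))
}

#' Evaluate a checkpoint series and select the best generator
#'
#' For every checkpoint, the generator is run on each held-out pair's
#' source and compared with its target; RE, PSNR and SSIM are averaged
#' over pairs.  Selection is by best average rank across the three
#' metrics (RE ascending, PSNR and SSIM descending) — the three
#' measures are combined rather than trusting any single one — with
#' ties broken toward the later epoch.  An `"re"` rule (lowest mean RE
#' only) is selectable.
#'
#' @param series a `checkpoint_series` from [train_cgan()], or a list
#'   of checkpoint entries `(epoch, path)`.
#' @param test_pairs list of held-out `training_pair` objects.
#' @param cfg a [metric_config()].
#' @param rule `"rank_sum"` (default) or `"re"`.
#' @return list with `table` (one row per checkpoint: means, rank sum,
#'   selection flag) and `selected` (epoch of the chosen checkpoint).
#' @export
evaluate_checkpoints <- function(series, test_pairs, cfg = metric_config(),
                                 rule = c("rank_sum", "re")) {
  rule <- match.arg(rule)
  cks <- if (inherits(series, "checkpoint_series")) series$checkpoints else series
  if (!length(cks)) abort_param("need at least one checkpoint")
  if (!length(test_pairs)) abort_param("need at least one test pair")
  rows <- lapply(cks, function(ck) {
    model <- if (inherits(ck, "generator_model")) ck else load_generator(ck$path)
    ms <- vapply(test_pairs, function(p) {
      gen <- generate(model, p$source)
      c(re = relative_error(gen, p$target),
        psnr = psnr(gen, p$target, cfg),
        ssim = ssim(gen, p$target, cfg))
    }, c(re = 0, psnr = 0, ssim = 0))
    data.frame(epoch = if (!is.null(ck$epoch)) ck$epoch else model$meta$epoch,
               re_mean = mean(ms["re", ]),
               psnr_mean_db = mean(ms["psnr", ]),
               ssim_mean = mean(ms["ssim", ]),
               n_pairs = length(test_pairs))
  })
  tab <- do.call(rbind, rows)
  rank_re <- rank(tab$re_mean, ties.method = "average")
  rank_psnr <- rank(-tab$psnr_mean_db, ties.method = "average")
  rank_ssim <- rank(-tab$ssim_mean, ties.method = "average")
  tab$rank_sum <- rank_re + rank_psnr + rank_ssim
  key <- if (rule == "rank_sum") tab$rank_sum else rank_re
  best <- which(key == min(key))
  sel <- best[which.max(tab$epoch[best])]   # ties -> later epoch
  tab$selected <- seq_len(nrow(tab)) == sel
  list(table = tab, selected = tab$epoch[sel])
}
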