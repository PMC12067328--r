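abort <- function(msg, class) {
  stop(structure(class = c(class, "airgap3d_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

abort_param <- function(msg) abort(msg, "airgap3d_parameter_error")
abort_io <- function(msg) abort(msg, "airgap3d_io_error")
abort_format <- function(msg) abort(msg, "airgap3d_format_error")

#' Derive a reproducible sub-seed from a global seed and a label
#'
#' Every stochastic stage of the pipeline draws its own seed
#' deterministically from one global seed plus the stage name, so that
#' e.g. the phantom tissue and its artifact realization can be varied
#' independently while a whole run stays reproducible from a single
#' integer.
#'
#' @param global_seed integer global seed.
#' @param label character scalar naming the stage.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(global_seed, label) {
  stopifnot(is.numeric(global_seed), length(global_seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(paste0(label, ":", as.integer(global_seed)))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

log_msg <- function(level, ...) {
  lev <- getOption("airgap3d.log_level", "info")
  ord <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  if (ord[[level]] >= ord[[lev]]) {
    message(sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    toupper(level), paste0(...)))
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
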