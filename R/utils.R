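# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a base seed and a stream label
#'
#' All randomness in the package flows from one integer seed; independent
#' stages (cohort structure, per-array noise, replicate rendering, splits)
#' draw from sub-streams keyed by label so that regenerating a subset of an
#' experiment reproduces it exactly.
#'
#' @param seed integer base seed.
#' @param ... character or integer stream keys.
#' @return an integer in [0, 2^31 - 2].
#' @keywords internal
derive_seed <- function(seed, ...) {
  keys <- unlist(lapply(list(...), function(k) {
    if (is.character(k)) utf8ToInt(paste(k, collapse = "|")) else as.integer(k)
  }))
  x <- as.double(seed) %% 2147483647
  for (k in keys) {
    # 16807 = Lehmer multiplier; keeps everything exactly representable
    x <- (x * 16807 + as.double(k) %% 2147483647) %% 2147483647
  }
  as.integer(x)
}

stop_named <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Clamp a p-value into (0, 1] so degenerate statistics keep valid reports.
clamp_p <- function(p) min(max(p, .Machine$double.xmin), 1)
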