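#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a named substream seed from a master seed
#'
#' Every stochastic stage of the pipeline (simulation, survey draw,
#' cross-validation folds, bootstrap, imputation) consumes its own seed,
#' derived deterministically from one master seed. This keeps stages
#' independently re-runnable while a single `--seed` controls the whole run.
#'
#' @param seed master seed (integer).
#' @param stream substream name, e.g. `"bootstrap"`.
#' @param index optional replicate index folded into the stream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  val <- (abs(seed) %% 2147483647) * 48271 + h * 16807 + index * 69621
  as.integer(val %% 2147483646L + 1L)
}

clamp01 <- function(p, what = "prediction") {
  out <- p < 0 | p > 1
  if (any(out, na.rm = TRUE)) {
    warning(sprintf("%d %s value(s) outside [0,1] clamped", sum(out, na.rm = TRUE), what))
    p <- pmin(pmax(p, 0), 1)
  }
  p
}

is_binary <- function(y) all(y %in% c(0, 1))
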