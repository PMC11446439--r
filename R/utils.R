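#' Derive a reproducible child seed from a root seed and labels
#'
#' Hierarchical seeding: every stochastic stage of the pipeline draws its seed
#' deterministically from one root seed plus identifying labels (subject,
#' condition, channel, stage name). Adding subjects or stages therefore never
#' reshuffles the streams of existing ones.
#'
#' @param root Integer root seed.
#' @param ... Labels (coerced to character) identifying the substream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "S01", "cycling", "open")
derive_seed <- function(root, ...) {
  stopifnot(is.numeric(root), length(root) == 1, is.finite(root))
  h <- abs(as.double(root)) %% 2147483647
  for (tok in vapply(list(...), as.character, character(1))) {
    for (ch in utf8ToInt(tok)) h <- (h * 31 + ch) %% 2147483647
    h <- (h * 131 + 17) %% 2147483647
  }
  as.integer(h)
}

# affine per-index seeds for segment substreams (cheap, vectorised)
segment_seeds <- function(base, n) {
  as.integer((as.double(base) + (seq_len(n) - 1) * 1103515245 + 12345) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_config <- function(msg) stop(msg, call. = FALSE)

assert_signal <- function(x, what = "signal") {
  if (!is.numeric(x) || length(x) == 0) {
    abort_config(sprintf("%s must be a non-empty numeric vector", what))
  }
  if (any(!is.finite(x))) {
    abort_config(sprintf("%s contains non-finite values", what))
  }
  invisible(x)
}
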