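#' Derive a child seed from a root seed and a label
#'
#' All stochastic operations in the package draw their seed from a single
#' root seed plus a fixed text label (e.g. `"bootstrap:17"`). Labels are
#' hashed with FNV-1a so that adding a new stochastic stage never perturbs
#' the draws of an existing one, and runs are reproducible given the root
#' seed alone.
#'
#' @param root integer root seed.
#' @param label character label naming the consumer of the stream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(root, label) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(label))
  # FNV-1a over the label bytes, done in double precision to avoid
  # integer overflow; 2^31 - 1 keeps the result a valid R integer.
  h <- 2166136261
  for (b in utf8ToInt(label)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  s <- (abs(root) * 2654435761 + h) %% (2^31 - 1)
  as.integer(s + 1)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
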