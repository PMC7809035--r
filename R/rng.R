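#' Derive a named child seed from a root seed
#'
#' All randomness in the synthetic generators flows from one root seed via
#' named child streams, one per output, so adding a new output never
#' perturbs draws of existing outputs.
#'
#' @param root integer root seed.
#' @param name character stream name.
#' @return An integer seed in `[0, 2^31)`.
#' @export
child_seed <- function(root, name) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(name))
  m <- 2147480009 # large prime below 2^31
  h <- 0
  for (cc in utf8ToInt(name)) h <- (h * 31 + cc) %% m
  as.integer((abs(as.numeric(root)) * 48271 + h) %% m)
}

# Evaluate `code` under the RNG stream (root, name), restoring the caller's
# RNG state afterwards.
with_stream <- function(root, name, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(child_seed(root, name))
  force(code)
}
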