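#' Derive a child seed from a master seed
#'
#' All stochastic stages of the pipeline draw their seed deterministically
#' from one master seed, so a whole experiment is reproducible from a single
#' integer. The derivation is a small multiplicative hash of the master seed
#' and a stage label, folded into the positive 32-bit integer range.
#'
#' @param master_seed Integer master seed.
#' @param label Character label naming the consumer (e.g. `"climate"`,
#'   `"species:7"`).
#' @return A single integer in `[0, 2^31 - 1]`.
#' @export
#' @examples
#' derive_seed(42, "climate")
#' derive_seed(42, "species:3")
derive_seed <- function(master_seed, label) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  h <- as.double(master_seed) %% 2147483647
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# run code with a locally-set RNG state, restoring the caller's state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_invalid <- function(msg) abort(msg, class = "bioscen_invalid_input")
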