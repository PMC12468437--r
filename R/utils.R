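# Internal helpers shared across modules.

stop_pcg <- function(fmt, ..., class = "pcgnet_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_pcg("`%s` must be a single positive finite number (got %s)",
             name, paste(format(x), collapse = ","),
             class = "pcgnet_invalid_parameter")
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop_pcg("`%s` must be a single non-negative finite number", name,
             class = "pcgnet_invalid_parameter")
  invisible(x)
}

#' Derive a child seed from a master seed
#'
#' All stages of a run draw their randomness from seeds derived
#' deterministically from one master seed, so that a single `--seed`
#' reproduces every stage.  Derivation is a small multiplicative hash of
#' the master seed and a stage/record counter, folded into the 31-bit
#' range R accepts for [set.seed()].
#'
#' @param master integer master seed.
#' @param counter non-negative integer distinguishing the consumer
#'   (stage index, record index, fold index, ...).
#' @return a single integer seed in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(master, counter = 0L) {
  m <- as.double(master) %% 2147483647
  c <- as.double(counter) %% 2147483647
  # two rounds of a Lehmer-style mix keep nearby (master, counter) pairs apart
  x <- (m * 48271 + c * 69621 + 12345) %% 2147483647
  x <- (x * 48271 + 1) %% 2147483647
  as.integer(x)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
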