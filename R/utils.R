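#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporarily-seeded RNG, restoring prior state on exit.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Derive a per-stage seed from one root seed.
#'
#' Keeps every derived seed a valid 32-bit integer so one `--seed` reproduces
#' the whole pipeline while stages stay statistically decoupled.
#'
#' @param seed integer root seed.
#' @param stage integer stage index (>= 1) or stage name.
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage) {
  if (is.character(stage)) stage <- sum(utf8ToInt(stage))
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stage)) %% 2147483647L)
}

#' @noRd
assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

#' @noRd
is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == floor(x) && x >= 0

#' @noRd
dna_alphabet_ok <- function(s) all(grepl("^[ACGT]+$", s))
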