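#' @keywords internal
"_PACKAGE"

# Run code under a private RNG stream, restoring the caller's .Random.seed.
# All exported stochastic entry points funnel through this so that a given
# (args, seed) pair is reproducible regardless of surrounding RNG use.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_stimchoice <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "stimchoice_error")))
}

# Nearly-even split of n into k integer parts (sum preserved).
split_even <- function(n, k) {
  base <- n %/% k
  out <- rep(base, k)
  extra <- n - base * k
  if (extra > 0) out[seq_len(extra)] <- out[seq_len(extra)] + 1L
  out
}
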