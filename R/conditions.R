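# Classed error conditions so callers (and tests) can distinguish contract
# violations: embentropy_<class>_error, all inheriting embentropy_error.

stop_emb <- function(class, msg, call = sys.call(-1)) {
  cond <- structure(
    class = c(paste0("embentropy_", class), "embentropy_error",
              "error", "condition"),
    list(message = msg, call = call)
  )
  stop(cond)
}

# evaluate code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# round-half-up (round() rounds halves to even, which would bias split sizes)
round_half_up <- function(x) floor(x + 0.5)
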