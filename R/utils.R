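# Internal helpers shared across modules.

# Run `expr` under a locally seeded RNG without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Deterministic sub-seed derivation: one master seed, one label per stage.
# Kept below 2^31 - 1 so the result is always a valid integer seed.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h * 69621) %% 2147483647)
}

# round-half-up (round() in R rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bisfruit <- function(msg, class) {
  stop(structure(class = c(class, "bisfruit_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
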