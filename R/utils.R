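# Internal helpers: classed error conditions, seed derivation, frame checks.

stop_invalid <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("specvote_invalid_argument", "error"),
                      call = call))
}

stop_insufficient <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("specvote_insufficient_specimens",
                                     "specvote_invalid_argument", "error"),
                      call = call))
}

stop_no_blob <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("specvote_no_blob", "error"),
                      call = call))
}

# Stable 31-bit hash of a string combined with a master seed, so per-specimen
# randomness is reproducible independently of generation order.
derive_seed <- function(master, key) {
  stopifnot(length(master) == 1L, length(key) == 1L)
  h <- as.double(master %% 2147483647L)
  for (code in utf8ToInt(as.character(key))) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards (the RNG kind is part of the saved state).
with_seed <- function(seed, expr, normal_kind = NULL) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  old_kinds <- RNGkind()
  on.exit({
    if (is.null(old)) {
      # no saved state to restore: reset the session's current RNG kinds
      # (they are internal state, not part of .Random.seed's absence)
      RNGkind(old_kinds[1], old_kinds[2], old_kinds[3])
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  # always pin the generator kinds so the stream does not depend on
  # whatever kind the session happens to be using
  set.seed(seed, kind = "Mersenne-Twister",
           normal.kind = if (is.null(normal_kind)) "Inversion" else normal_kind,
           sample.kind = "Rejection")
  expr
}

check_frame <- function(frame, arg = "frame") {
  if (!is.matrix(frame) || !is.numeric(frame) || any(dim(frame) < 1L))
    stop_invalid(sprintf("`%s` must be a numeric matrix with positive dimensions", arg))
  invisible(frame)
}

# round-half-up, stated so split sizes are bit-exactly reproducible
round_half_up <- function(x) floor(x + 0.5)
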