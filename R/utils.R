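# internal helpers shared across modules

Z95 <- stats::qnorm(0.975)

#' @noRd
p_two_sided <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  # keep p in (0, 1] as required downstream
  pmax(p, .Machine$double.xmin)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic sub-seed derivation from one master seed; keeps every
# component stream reproducible regardless of evaluation order.
# Result always in [1, 2^31 - 2].
#' @noRd
derive_seed <- function(master, k) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(master) %% m)
  for (i in seq_len(k + 1L)) s <- (s * 48271 + 11) %% m
  as.integer(max(1, s %% (m - 1)))
}

#' @noRd
stop_mrm <- function(msg, class) {
  stop(structure(
    class = c(class, "mrmediate_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
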