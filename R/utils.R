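#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All exported stochastic functions route their
# randomness through this helper so a single seed makes a whole analysis
# replayable without clobbering the user's random stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive `n` independent child seeds from a master seed (stream splitting:
# every stochastic stage of a pipeline gets its own replayable seed).
split_seed <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# All permutations of 1..n as an n! x n matrix (used for exhaustive
# permutation tests on small panels).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (i in seq_len(n)) {
    idx <- c(seq_len(i - 1L), seq.int(i + 1L, length.out = n - i))
    out[row + seq_len(nrow(sub)), ] <- cbind(i, matrix(idx[sub], nrow(sub)))
    row <- row + nrow(sub)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
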