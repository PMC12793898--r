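# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs `expr` on the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All permutations of 1..n as an n! x n integer matrix (n <= 9 guard upstream).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_binary <- function(x) all(x %in% c(0, 1) | is.na(x))
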