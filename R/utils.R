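# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library calls never clobber user RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Shift a matrix by (dr, dc), padding with `fill`. shift_mat(m, 1, 0) moves
# content down: result[r, c] == m[r - 1, c].
shift_mat <- function(m, dr, dc, fill = NA) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(fill, n, p)
  rs <- seq_len(n) - dr
  cs <- seq_len(p) - dc
  rok <- rs >= 1 & rs <= n
  cok <- cs >= 1 & cs <= p
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# The 8-neighbourhood in counter-clockwise angular order starting at east.
# Row offsets are negated relative to angle because row index grows downward.
NEIGH8 <- cbind(
  dr = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
  dc = c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
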