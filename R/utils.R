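#' @keywords internal
"_PACKAGE"

# Deterministic 31-bit seed derived from a master seed and a string key.
# Polynomial rolling hash mod the Mersenne prime 2^31 - 1; keeps every
# derived seed a valid 32-bit R integer.
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Run `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Composite Gauss-Legendre rule on [lo, hi]: `panels` panels of `pts` nodes.
# Nodes/weights by Golub-Welsch on the Jacobi matrix (symmetric tridiagonal).
gauss_legendre <- function(lo, hi, panels, pts) {
  i <- seq_len(pts - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, pts, pts)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x0 <- rev(e$values)
  w0 <- rev(2 * e$vectors[1L, ]^2)
  edges <- seq(lo, hi, length.out = panels + 1L)
  half <- diff(edges) / 2
  mid <- (edges[-1L] + edges[-(panels + 1L)]) / 2
  list(
    nodes = as.vector(outer(x0, half) + rep(mid, each = pts)),
    weights = as.vector(outer(w0, half))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
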