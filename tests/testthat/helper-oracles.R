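## Naive reference implementations and small random-instance generators.
## These stay deliberately independent of the package's vectorized paths.

bruteRuzicka <- function(x, y) {
  num <- 0
  den <- 0
  for (i in seq_along(x)) {
    num <- num + min(x[i], y[i])
    den <- den + max(x[i], y[i])
  }
  num / den
}

## all within-group pairs, one explicit double loop
bruteCIndex <- function(m, mask) {
  m <- m / rowSums(m)
  idx <- which(mask)
  out <- numeric(0)
  for (a in seq_along(idx)) {
    for (b in seq_along(idx)) {
      if (a < b) out <- c(out, bruteRuzicka(m[idx[a], ], m[idx[b], ]))
    }
  }
  out
}

randomCountMatrix <- function(n, p, lambda = 5) {
  m <- matrix(rpois(n * p, lambda), n, p)
  m[m < 2] <- 0
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1
  rownames(m) <- sprintf("s%02d", seq_len(n))
  colnames(m) <- sprintf("t%02d", seq_len(p))
  m
}

randomDistanceMatrix <- function(n, k = 3) {
  y <- matrix(rnorm(n * k), n, k)
  d <- as.matrix(dist(y))
  dimnames(d) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
  d
}

## F1 of an estimated CoabundanceNetwork against a logical adjacency
edgeF1 <- function(g, truth) {
  nodes <- rownames(truth)
  est <- matrix(FALSE, nrow(truth), ncol(truth), dimnames = dimnames(truth))
  e <- networkEdges(g)
  for (r in seq_len(nrow(e))) {
    est[e$u[r], e$v[r]] <- est[e$v[r], e$u[r]] <- TRUE
  }
  tp <- sum(est & truth) / 2
  fp <- sum(est & !truth) / 2
  fn <- sum(!est & truth) / 2
  if (2 * tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

chainPrecision <- function(p, rho = -0.4) {
  om <- diag(1, p)
  for (i in seq_len(p - 1)) om[i, i + 1] <- om[i + 1, i] <- rho
  om
}
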