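# Independent brute-force oracles.  Each one recomputes a package formula by
# a different route (set arithmetic, exact integer factorisation, dense
# triple loops) so agreement is evidence, not tautology.

# --- exact binomials via prime factorisation -------------------------------
# C(n, k) is represented by the exact prime-power exponents of n!, k! and
# (n-k)! (Legendre's formula); the only floating-point step is the final
# sum of exponent * log(prime).  Completely independent of lchoose().

primes_upto <- function(n) {
  if (n < 2) return(integer(0))
  is_p <- rep(TRUE, n)
  is_p[1] <- FALSE
  p <- 2
  while (p * p <= n) {
    if (is_p[p]) is_p[seq(p * p, n, by = p)] <- FALSE
    p <- p + 1
  }
  which(is_p)
}

factorial_exponents <- function(n, primes) {
  vapply(primes, function(p) {
    e <- 0; q <- p
    while (q <= n) { e <- e + n %/% q; q <- q * p }
    e
  }, numeric(1))
}

# exponent vector of C(n, k) over `primes`
choose_exponents <- function(n, k, primes) {
  stopifnot(k >= 0, k <= n)
  factorial_exponents(n, primes) - factorial_exponents(k, primes) -
    factorial_exponents(n - k, primes)
}

# -log of the domain-content similarity ratio, from exact exponents
ds_oracle <- function(nc, ni, nj, nt) {
  primes <- primes_upto(max(2, nt))
  expo <- choose_exponents(nt, nc, primes) +
    choose_exponents(nt - nc, ni - nc, primes) +
    choose_exponents(nt - ni, nj - nc, primes) -
    choose_exponents(nt, ni, primes) -
    choose_exponents(nt, nj, primes)
  -sum(expo * log(primes))
}

# --- closed-neighborhood overlap (topology layer) --------------------------
eq1_oracle <- function(edges, n, i, j) {
  nbrs <- function(v) {
    e <- edges
    sort(unique(c(v, e[e[, 1] == v, 2], e[e[, 2] == v, 1])))
  }
  Ni <- nbrs(i); Nj <- nbrs(j)
  cmn <- length(intersect(Ni, Nj))
  if (cmn == 0) return(0)
  4 * cmn^2 / ((length(Ni) + cmn) * (length(Nj) + cmn))
}

# --- module density and co-module association ------------------------------
eq4_oracle <- function(module, edges) {
  e <- 0
  for (r in seq_len(nrow(edges))) {
    if (edges[r, 1] %in% module && edges[r, 2] %in% module) e <- e + 1
  }
  2 * e / (length(module) * (length(module) - 1))
}

eq5_oracle <- function(i, j, modules, scores) {
  shared <- 0; si <- 0; sj <- 0
  for (k in seq_along(modules)) {
    ini <- i %in% modules[[k]]; inj <- j %in% modules[[k]]
    if (ini) si <- si + scores[k]
    if (inj) sj <- sj + scores[k]
    if (ini && inj) shared <- shared + scores[k]
  }
  if (si == 0 || sj == 0 || shared == 0) return(0)
  shared^2 / (si * sj)
}

# --- dense normalisations and triple-loop contractions ---------------------
dense_protein_norm <- function(layers) {
  n <- nrow(layers[[1]])
  lapply(layers, function(L) {
    L <- as.matrix(L)
    for (j in seq_len(n)) {
      s <- sum(L[, j])
      L[, j] <- if (s > 0) L[, j] / s else rep(1 / n, n)
    }
    L
  })
}

dense_layer_norm <- function(layers) {
  n <- nrow(layers[[1]])
  m <- length(layers)
  dl <- lapply(layers, as.matrix)
  out <- lapply(seq_len(m), function(k) matrix(0, n, n))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- sum(vapply(dl, function(L) L[i, j], numeric(1)))
    for (k in seq_len(m)) {
      out[[k]][i, j] <- if (s > 0) dl[[k]][i, j] / s else 1 / m
    }
  }
  out
}

contract_x_oracle <- function(norm_layers, x, y) {
  n <- nrow(norm_layers[[1]])
  v <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    for (k in seq_along(norm_layers)) {
      v[i] <- v[i] + norm_layers[[k]][i, j] * x[j] * y[k]
    }
  }
  v
}

contract_y_oracle <- function(norm_layers, x, xn) {
  vapply(seq_along(norm_layers), function(k) {
    s <- 0
    n <- nrow(norm_layers[[k]])
    for (i in seq_len(n)) for (j in seq_len(n)) {
      s <- s + norm_layers[[k]][i, j] * x[i] * xn[j]
    }
    s
  }, numeric(1))
}

# random sparse symmetric zero-diagonal layers for property tests
random_tensor <- function(n, m = 3, p = 0.4) {
  layers <- lapply(seq_len(m), function(k) {
    A <- matrix(0, n, n)
    up <- which(upper.tri(A))
    on <- up[runif(length(up)) < p]
    A[on] <- runif(length(on))
    A + t(A)
  })
  similarity_tensor(lapply(layers, function(L) Matrix::Matrix(L, sparse = TRUE)))
}
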