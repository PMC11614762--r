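# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the partial-trace oracle is an explicit index
# summation, the kernel oracle a trigonometric closed form, the Grover
# oracle the textbook sin^2 formula.

# Partial trace by explicit double-loop bit summation (independent of the
# package implementation, which works block-wise).
oracle_partial_trace <- function(mat, n, keep) {
  keep <- sort(keep)
  traced <- setdiff(0:(n - 1L), keep)
  dK <- 2L^length(keep)
  out <- matrix(0+0i, dK, dK)
  embed_bits <- function(sub, positions) {
    full <- 0L
    for (t in seq_along(positions))
      full <- full + bitwShiftL(bitwAnd(bitwShiftR(sub, t - 1L), 1L),
                                positions[t])
    full
  }
  for (a in 0:(dK - 1L)) for (b in 0:(dK - 1L)) {
    acc <- 0+0i
    for (e in 0:(2L^length(traced) - 1L)) {
      r <- embed_bits(a, keep) + embed_bits(e, traced)
      c <- embed_bits(b, keep) + embed_bits(e, traced)
      acc <- acc + mat[r + 1L, c + 1L]
    }
    out[a + 1L, b + 1L] <- acc
  }
  out
}

# Haar-ish random pure state.
random_state <- function(n) {
  v <- complex(real = rnorm(2^n), imaginary = rnorm(2^n))
  quantum_state(v / sqrt(sum(Mod(v)^2)))
}

# Random full-rank density matrix (mixture of random pure states).
random_density <- function(n, n_terms = 4L) {
  d <- 2L^n
  m <- matrix(0+0i, d, d)
  w <- runif(n_terms); w <- w / sum(w)
  for (t in seq_len(n_terms)) {
    v <- complex(real = rnorm(d), imaginary = rnorm(d))
    v <- v / sqrt(sum(Mod(v)^2))
    m <- m + w[t] * outer(v, Conj(v))
  }
  density_matrix((m + Conj(t(m))) / 2 / Re(sum(diag(m))))
}

# Random single-qubit unitary via QR of a complex Gaussian matrix.
random_unitary <- function(d = 2L) {
  z <- matrix(complex(real = rnorm(d * d), imaginary = rnorm(d * d)), d, d)
  q <- qr.Q(qr(z))
  q %*% diag(exp(-1i * Arg(diag(qr.R(qr(z))))), d)
}

# Closed-form Grover marked mass.
oracle_grover_mass <- function(N, M, k) sin((2 * k + 1) * asin(sqrt(M / N)))^2

# Closed-form fidelity kernel of the tensored Y-rotation map.
oracle_ry_kernel <- function(x, y) prod(cos(pi * (x - y) / 2)^2)

# Small random binary feature table.
random_table <- function(n_patients, n_features, p = 0.5,
                         roles = NULL) {
  m <- matrix(rbinom(n_patients * n_features, 1L, p), n_patients,
              n_features)
  colnames(m) <- paste0("f", seq_len(n_features))
  rownames(m) <- sprintf("P%04d", seq_len(n_patients))
  if (is.null(roles))
    roles <- setNames(rep("gene", n_features), colnames(m))
  feature_table(m, roles)
}

# Exhaustive Ising minimum with a different loop order than the package
# (iterate spins as a grid via expand.grid, scan linearly).
oracle_ising_minimum <- function(model) {
  grid <- as.matrix(expand.grid(rep(list(c(1, -1)), model$m)))
  e <- apply(grid, 1, function(s) ising_energy(model, s))
  min(e)
}
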