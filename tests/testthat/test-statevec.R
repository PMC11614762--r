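test_that("amplitude encoding reproduces empirical joint frequencies", {
  # degenerate: one feature always 1
  t1 <- feature_table(matrix(1L, 5, 1, dimnames = list(NULL, "f")),
                      roles = c(f = "gene"))
  st <- encode_joint_distribution(t1, "f")
  expect_equal(unname(Mod(st$amplitudes)), c(0, 1))

  # uniform over 4 patterns
  t2 <- feature_table(matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2,
                             dimnames = list(NULL, c("a", "b"))),
                      roles = c(a = "gene", b = "symptom"))
  st2 <- encode_joint_distribution(t2, c("a", "b"))
  expect_equal(unname(Mod(st2$amplitudes)), rep(0.5, 4))

  # 7 patients with pattern 10, 3 with 01
  m <- rbind(matrix(c(1, 0), 7, 2, byrow = TRUE),
             matrix(c(0, 1), 3, 2, byrow = TRUE))
  colnames(m) <- c("a", "b")
  t3 <- feature_table(m, roles = c(a = "gene", b = "symptom"))
  st3 <- encode_joint_distribution(t3, c("a", "b"))
  p <- measure_probabilities(st3)
  expect_equal(unname(p[c("10", "01")]), c(0.7, 0.3))
  expect_equal(unname(p[c("00", "11")]), c(0, 0))
  expect_true(all(Im(st3$amplitudes) == 0) && all(Re(st3$amplitudes) >= 0))

  expect_error(encode_joint_distribution(t3, "missing"), "unknown feature")
  expect_error(encode_joint_distribution(t3, character(0)), "at least one")
})

test_that("encoding round-trips: measurement equals empirical frequency", {
  set.seed(41)
  for (rep in 1:25) {
    nf <- sample(1:4, 1)
    tab <- random_table(sample(3:60, 1), nf, p = runif(1, 0.2, 0.8))
    st <- encode_joint_distribution(tab, tab$feature_names)
    probs <- measure_probabilities(st)
    w <- 2^((nf - 1):0)
    emp <- tabulate(as.vector(tab$records %*% w) + 1L, nbins = 2^nf) /
      nrow(tab$records)
    expect_equal(unname(probs), emp, tolerance = 1e-12)
    expect_equal(sum(probs), 1, tolerance = 1e-10)
  }
})

test_that("measurement follows the Born rule", {
  bell <- quantum_state(c(1, 0, 0, 1) / sqrt(2))
  p <- measure_probabilities(bell)
  expect_equal(unname(p), c(0.5, 0, 0, 0.5))
  expect_named(p, c("00", "01", "10", "11"))
  p0 <- measure_probabilities(quantum_state(c(1, 0)))
  expect_equal(unname(p0), c(1, 0))
})

test_that("tensor product composes registers with a as the high block", {
  zero <- quantum_state(c(1, 0)); one <- quantum_state(c(0, 1))
  st01 <- tensor_states(zero, one)
  expect_equal(which(Mod(st01$amplitudes) > 0.5), 2L)  # |01>
  ab <- tensor_states(quantum_state(c(sqrt(0.8), sqrt(0.2))), zero)
  expect_equal(unname(Mod(ab$amplitudes)),
               c(sqrt(0.8), 0, sqrt(0.2), 0))  # |00> and |10>
  set.seed(5)
  t2 <- tensor_states(random_state(2), random_state(1))
  expect_equal(sum(Mod(t2$amplitudes)^2), 1, tolerance = 1e-10)
})

test_that("to_density builds the rank-1 projector", {
  expect_equal(to_density(quantum_state(c(1, 0)))$matrix,
               matrix(c(1, 0, 0, 0) + 0i, 2, 2))
  bell <- to_density(quantum_state(c(1, 0, 0, 1) / sqrt(2)))
  expect_equal(Re(bell$matrix[c(1, 4, 13, 16)]), rep(0.5, 4))
  set.seed(6)
  rho <- to_density(random_state(3))
  expect_equal(Re(sum(diag(rho$matrix))), 1, tolerance = 1e-12)
})

test_that("partial trace matches the brute-force summation oracle", {
  bellA <- partial_trace(to_density(quantum_state(c(1, 0, 0, 1) / sqrt(2))),
                         keep = 0)
  expect_equal(bellA$matrix, diag(2) * (0.5 + 0i), tolerance = 1e-12)
  # product state |01>: more-significant qubit reduces to |0><0|
  p01 <- partial_trace(to_density(quantum_state(c(0, 1, 0, 0))), keep = 1)
  expect_equal(Re(p01$matrix), matrix(c(1, 0, 0, 0), 2, 2), tolerance = 1e-12)

  set.seed(7)
  for (n in 2:4) for (rep in 1:5) {
    rho <- to_density(random_state(n))
    keeps <- list(0, n - 1L, if (n > 2) c(0, n - 1L) else 0)
    for (keep in keeps) {
      got <- partial_trace(rho, keep)$matrix
      want <- oracle_partial_trace(rho$matrix, n, keep)
      expect_lt(max(Mod(got - want)), 1e-12)
    }
  }
})

test_that("tracing out b from tensor(a, b) recovers a", {
  set.seed(8)
  for (rep in 1:5) {
    a <- random_state(2); b <- random_state(1)
    rho <- to_density(tensor_states(a, b))
    redA <- partial_trace(rho, keep = c(1, 2))  # a occupies the high bits
    expect_lt(max(Mod(redA$matrix - to_density(a)$matrix)), 1e-10)
  }
})

test_that("apply_unitary acts on targets and preserves the norm", {
  H <- matrix(c(1, 1, 1, -1) / sqrt(2), 2, 2)
  plus <- apply_unitary(quantum_state(c(1, 0)), H, targets = 0)
  expect_equal(Re(plus$amplitudes), c(1, 1) / sqrt(2), tolerance = 1e-12)
  X <- matrix(c(0, 1, 1, 0), 2, 2)
  st <- apply_unitary(quantum_state(c(1, 0, 0, 0)), X, targets = 0)
  expect_equal(which(Mod(st$amplitudes) > 0.5), 2L)  # |01>
  set.seed(9)
  psi <- random_state(3)
  U <- random_unitary(4)
  fwd <- apply_unitary(psi, U, targets = c(0, 2))
  back <- apply_unitary(fwd, Conj(t(U)), targets = c(0, 2))
  expect_lt(max(Mod(back$amplitudes - psi$amplitudes)), 1e-10)
  expect_equal(sum(Mod(fwd$amplitudes)^2), 1, tolerance = 1e-10)
  expect_error(apply_unitary(psi, matrix(c(1, 0, 0, 2), 2, 2), 0),
               "not unitary")
  expect_error(apply_unitary(psi, U, targets = c(1, 1)), "distinct")
})

test_that("invalid states and density matrices are rejected", {
  expect_error(quantum_state(c(1, 1)), "not normalized")
  expect_error(quantum_state(c(1, 0, 0)), "power of 2")
  expect_error(density_matrix(matrix(c(1, 1, 0, 0), 2, 2)), "Hermitian")
  expect_error(density_matrix(diag(c(0.9, 0.9)) / 1.2), "trace")
  expect_error(partial_trace(to_density(quantum_state(c(1, 0))), keep = 3),
               "invalid qubit")
})

test_that("state and density JSON serialization round-trips", {
  set.seed(10)
  st <- random_state(2)
  f <- tempfile(fileext = ".json")
  quantum_to_json(st, f)
  back <- quantum_from_json(f)
  expect_lt(max(Mod(back$amplitudes - st$amplitudes)), 1e-14)
  rho <- random_density(2)
  quantum_to_json(rho, f)
  back2 <- quantum_from_json(f)
  expect_lt(max(Mod(back2$matrix - rho$matrix)), 1e-14)
  unlink(f)
})
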