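test_that("energy honors the sign conventions of each interaction order", {
  zero <- ising_model(3)
  expect_equal(ising_energy(zero, c(1, -1, 1)), 0)
  mJ <- ising_model(2, J = data.frame(i = 1, j = 2, value = 1))
  expect_equal(ising_energy(mJ, c(1, 1)), -1)   # -J s_i s_j
  mK <- ising_model(3, K = data.frame(i = 1, j = 2, k = 3, value = 1))
  expect_equal(ising_energy(mK, c(1, 1, 1)), 1) # +K s_i s_j s_k
  mh <- ising_model(1, h = 1)
  expect_equal(ising_energy(mh, 1), -1)         # -h s_i
  expect_error(ising_energy(mJ, c(1, 1, 1)), "length")
  expect_error(ising_energy(mJ, c(1, 0)), "\\+1 or -1")
})

test_that("Z2 symmetry: global flip fixes J terms and negates K terms", {
  set.seed(31)
  for (rep in 1:10) {
    m <- 5
    mod <- ising_model(
      m, h = 0,
      J = data.frame(i = c(1, 2), j = c(3, 5), value = rnorm(2)),
      K = data.frame(i = 1, j = 2, k = 4, value = rnorm(1)))
    s <- sample(c(-1, 1), m, replace = TRUE)
    e <- ising_energy(mod, s)
    ef <- ising_energy(mod, -s)
    kterm <- mod$K$value * prod(s[c(1, 2, 4)])
    expect_equal(ef - e, -2 * kterm, tolerance = 1e-12)
    noK <- ising_model(m, h = 0, J = mod$J)
    expect_equal(ising_energy(noK, s), ising_energy(noK, -s),
                 tolerance = 1e-12)
  }
})

test_that("moment estimators recover planted pairwise structure", {
  # duplicated balanced feature pair: J = cov of identical +/-1 vars = 1
  v <- rep(c(0L, 1L), 50)
  tab <- feature_table(cbind(a = v, b = v, c = rep(c(0L, 1L, 1L, 0L), 25)),
                       roles = c(a = "gene", b = "gene", c = "gene"))
  mod <- estimate_ising(tab, c("a", "b"), max_order = 2)
  expect_equal(mod$J$value, 1, tolerance = 1e-12)
  # independent features: all couplings concentrate near zero
  set.seed(32)
  n <- 4000
  ind <- random_table(n, 4)
  mi <- estimate_ising(ind, ind$feature_names, max_order = 3)
  expect_true(all(abs(mi$J$value) < 3 / sqrt(n)))
  expect_true(all(abs(mi$K$value) < 3 / sqrt(n)))
})

test_that("parity data yields a dominant third-order coupling", {
  set.seed(33)
  n <- 3000
  a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
  k <- bitwXor(a, b)
  tab <- feature_table(cbind(a = a, b = b, k = k),
                       roles = c(a = "gene", b = "symptom", k = "disease"))
  mod <- estimate_ising(tab, c("a", "b", "k"), max_order = 3)
  expect_gt(abs(mod$K$value), 0.9)          # ~ -1 for exact parity
  expect_true(all(abs(mod$J$value) < abs(mod$K$value)))
  expect_true(all(abs(mod$J$value) < 0.06))
})

test_that("constant features are flagged and get zero couplings", {
  tab <- feature_table(cbind(a = rep(1L, 10), b = rep(c(0L, 1L), 5)),
                       roles = c(a = "gene", b = "gene"))
  expect_warning(mod <- estimate_ising(tab, c("a", "b"), max_order = 2),
                 "constant feature")
  expect_equal(mod$J$value, 0)
})

test_that("brute force matches an independent enumeration exactly", {
  m1 <- ising_model(1, h = 1)
  gs <- ground_state_bruteforce(m1)
  expect_equal(gs$configuration, 1)
  expect_equal(gs$energy, -1)
  # ferromagnetic m = 4: all aligned, six pairs
  pairs <- t(combn(4, 2))
  ferro <- ising_model(4, J = data.frame(i = pairs[, 1], j = pairs[, 2],
                                         value = 1))
  gf <- ground_state_bruteforce(ferro)
  expect_equal(gf$energy, -6)
  expect_equal(gf$configuration, rep(1, 4))  # tie broken toward +1
  set.seed(34)
  for (rep in 1:5) {
    m <- sample(4:8, 1)
    pr <- t(combn(m, 2)); tr <- t(combn(m, 3))
    mod <- ising_model(
      m, h = rnorm(m),
      J = data.frame(i = pr[, 1], j = pr[, 2], value = rnorm(nrow(pr))),
      K = data.frame(i = tr[, 1], j = tr[, 2], k = tr[, 3],
                     value = rnorm(nrow(tr), 0, 0.5)))
    gs <- ground_state_bruteforce(mod)
    expect_equal(gs$energy, oracle_ising_minimum(mod), tolerance = 1e-10)
    expect_equal(ising_energy(mod, gs$configuration), gs$energy,
                 tolerance = 1e-12)
    # minimality spot-check against random configurations
    rand_e <- replicate(200, ising_energy(
      mod, sample(c(-1, 1), m, replace = TRUE)))
    expect_true(all(gs$energy <= rand_e + 1e-12))
  }
})

test_that("annealers are seed-deterministic and reach small ground states", {
  set.seed(35)
  pr <- t(combn(8, 2))
  mod <- ising_model(8, h = rnorm(8, 0, 0.2),
                     J = data.frame(i = pr[, 1], j = pr[, 2],
                                    value = rnorm(nrow(pr))))
  sched <- anneal_schedule(n_sweeps = 500, n_restarts = 4, seed = 17)
  a1 <- simulated_annealing(mod, sched)
  a2 <- simulated_annealing(mod, sched)
  expect_identical(a1, a2)
  q1 <- simulated_quantum_annealing(mod, sched)
  q2 <- simulated_quantum_annealing(mod, sched)
  expect_identical(q1, q2)
  gt <- ground_state_bruteforce(mod)
  expect_equal(a1$energy, gt$energy, tolerance = 1e-10)
  expect_equal(q1$energy, gt$energy, tolerance = 1e-10)
  # best-seen trace is non-increasing; final <= any random configuration
  expect_true(all(diff(a1$trace) <= 1e-12))
  expect_true(all(diff(q1$trace) <= 1e-12))
  expect_gte(ising_energy(mod, sample(c(-1, 1), 8, replace = TRUE)),
             a1$energy)
  # zero-coefficient model: any configuration, energy 0
  z <- simulated_annealing(ising_model(4), sched)
  expect_equal(z$energy, 0)
})

test_that("annealer energies never undercut the exact ground energy", {
  set.seed(36)
  for (rep in 1:3) {
    pr <- t(combn(6, 2)); tr <- t(combn(6, 3))
    mod <- ising_model(6, h = rnorm(6),
                       J = data.frame(i = pr[, 1], j = pr[, 2],
                                      value = rnorm(nrow(pr))),
                       K = data.frame(i = tr[, 1], j = tr[, 2],
                                      k = tr[, 3],
                                      value = rnorm(nrow(tr), 0, 0.4)))
    gt <- ground_state_bruteforce(mod)
    sched <- anneal_schedule(n_sweeps = 300, n_restarts = 2, seed = rep)
    expect_gte(simulated_annealing(mod, sched)$energy, gt$energy - 1e-10)
    expect_gte(simulated_quantum_annealing(mod, sched)$energy,
               gt$energy - 1e-10)
  }
})

test_that("estimation ranks the true strongest coupling on Gibbs samples", {
  # exact Gibbs sampling at T = 1 by enumerating the m <= 6 configuration
  # space; the strongest planted J should rank first in most replicates
  gibbs_table <- function(mod, n, seed) {
    grid <- as.matrix(expand.grid(rep(list(c(1, -1)), mod$m)))
    e <- apply(grid, 1, function(s) ising_energy(mod, s))
    p <- exp(-e); p <- p / sum(p)
    set.seed(seed)
    rows <- sample(nrow(grid), n, replace = TRUE, prob = p)
    bits <- (grid[rows, , drop = FALSE] + 1) / 2
    colnames(bits) <- paste0("f", seq_len(mod$m))
    feature_table(bits, setNames(rep("gene", mod$m), colnames(bits)))
  }
  pr <- t(combn(5, 2))
  set.seed(37)
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    vals <- c(1.2, runif(nrow(pr) - 1, -0.15, 0.15))
    mod <- ising_model(5, J = data.frame(i = pr[, 1], j = pr[, 2],
                                         value = vals))
    tab <- gibbs_table(mod, 800, seed = 1000 + r)
    est <- estimate_ising(tab, tab$feature_names, max_order = 2)
    top <- model_to_associations(est)[1, ]
    hits <- hits + (top$indices == "1,2")
  }
  expect_gte(hits, 0.9 * n_rep)
})

test_that("association ranking orders by magnitude with stable ties", {
  mod <- ising_model(4,
                     J = data.frame(i = c(1, 1), j = c(2, 3),
                                    value = c(0.5, -0.5)),
                     K = data.frame(i = 1, j = 2, k = 3, value = 0.8))
  assoc <- model_to_associations(mod)
  expect_equal(assoc$order[1], 3L)
  expect_equal(assoc$features[1], "s1:s2:s3")
  # |0.5| tie: lower order first is moot (both order 2), lexicographic
  expect_equal(assoc$indices[2:3], c("1,2", "1,3"))
  expect_equal(assoc$sign, c("+", "+", "-"))
  top1 <- model_to_associations(mod, top_q = 1)
  expect_equal(nrow(top1), 1L)
  zero <- model_to_associations(ising_model(3,
    J = data.frame(i = 1, j = 2, value = 0),
    K = data.frame(i = 1, j = 2, k = 3, value = 0)))
  expect_equal(zero$coefficient, c(0, 0))
  expect_equal(zero$order, c(2L, 3L))  # lower order first on ties
})

test_that("Ising JSON serialization round-trips", {
  mod <- ising_model(3, h = c(0.1, -0.2, 0.3),
                     J = data.frame(i = 1, j = 3, value = 0.7),
                     K = data.frame(i = 1, j = 2, k = 3, value = -0.4),
                     feature_names = c("g", "s", "d"))
  f <- tempfile(fileext = ".json")
  ising_to_json(mod, f)
  back <- ising_from_json(f)
  expect_equal(back$h, mod$h)
  expect_equal(back$J$value, mod$J$value)
  expect_equal(back$K$value, mod$K$value)
  expect_equal(back$feature_names, mod$feature_names)
  unlink(f)
})
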