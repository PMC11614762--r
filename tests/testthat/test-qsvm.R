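test_that("feature map sends binary vectors to basis states", {
  spec <- kernel_spec(3)
  z <- feature_map_state(c(0, 0, 0), spec)
  expect_equal(Mod(z$amplitudes), c(1, rep(0, 7)), tolerance = 1e-12)
  o <- feature_map_state(c(1, 1, 1), spec)
  expect_equal(Mod(o$amplitudes), c(rep(0, 7), 1), tolerance = 1e-12)
  set.seed(51)
  r <- feature_map_state(runif(3), spec)
  expect_equal(sum(Mod(r$amplitudes)^2), 1, tolerance = 1e-10)
  expect_error(feature_map_state(c(0.5, 1.2, 0), spec), "\\[0, 1\\]")
  expect_error(feature_map_state(c(0.5, 0.5), spec), "expects")
})

test_that("fidelity kernel matches the trigonometric closed form", {
  spec <- kernel_spec(4)
  set.seed(52)
  for (rep in 1:10) {
    x <- runif(4); y <- runif(4)
    expect_equal(quantum_kernel(x, y, spec), oracle_ry_kernel(x, y),
                 tolerance = 1e-12)
    expect_equal(quantum_kernel(x, y, spec), quantum_kernel(y, x, spec),
                 tolerance = 1e-12)
    expect_equal(quantum_kernel(x, x, spec), 1, tolerance = 1e-12)
    k <- quantum_kernel(x, y, spec)
    expect_true(k >= 0 && k <= 1)
  }
  expect_lt(quantum_kernel(rep(0, 4), rep(1, 4), spec), 1e-60)
})

test_that("Gram matrices have unit diagonal and are PSD", {
  spec <- kernel_spec(3)
  g1 <- gram_matrix(matrix(c(0.2, 0.5, 0.8), 1, 3), spec)
  expect_equal(dim(g1), c(1L, 1L))
  expect_equal(g1[1, 1], 1, tolerance = 1e-12)
  dup <- gram_matrix(rbind(c(0.1, 0.4, 0.9), c(0.1, 0.4, 0.9)), spec)
  expect_equal(as.vector(dup), rep(1, 4), tolerance = 1e-12)
  expect_equal(sort(eigen(dup, symmetric = TRUE)$values), c(0, 2),
               tolerance = 1e-12)
  set.seed(53)
  for (rep in 1:5) {
    S <- matrix(runif(30), 10, 3)
    G <- gram_matrix(S, spec)
    expect_lt(max(abs(diag(G) - 1)), 1e-12)
    expect_lt(max(abs(G - t(G))), 1e-12)
    expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
    # entries agree with the pairwise kernel
    expect_equal(G[1, 2], quantum_kernel(S[1, ], S[2, ], spec),
                 tolerance = 1e-12)
  }
})

test_that("two orthogonal samples give the textbook 2-point solution", {
  fit <- train_qsvm(rbind(c(0, 0), c(1, 1)), c(1, -1), kernel_spec(2))
  # orthogonal images: dual has closed form alpha_1 = alpha_2 = 1, b = 0
  expect_equal(fit$alpha, c(1, 1), tolerance = 1e-6)
  expect_equal(fit$b, 0, tolerance = 1e-6)
  expect_equal(predict(fit, rbind(c(0, 0), c(1, 1))), c(1, -1))
})

test_that("training satisfies dual feasibility and separates clusters", {
  set.seed(54)
  X <- rbind(matrix(runif(20 * 3, 0, 0.25), ncol = 3),
             matrix(runif(20 * 3, 0.75, 1), ncol = 3))
  y <- rep(c(1, -1), each = 20)
  fit <- train_qsvm(X, y, kernel_spec(3))
  expect_true(fit$converged)
  expect_true(all(fit$alpha >= 0 & fit$alpha <= fit$C))
  expect_lt(abs(sum(fit$alpha * fit$labels)), 1e-10)
  expect_equal(mean(predict(fit, X) == y), 1)
  # held-out accuracy on fresh draws from the same clusters
  Xt <- rbind(matrix(runif(10 * 3, 0, 0.25), ncol = 3),
              matrix(runif(10 * 3, 0.75, 1), ncol = 3))
  yt <- rep(c(1, -1), each = 10)
  expect_gt(mean(predict(fit, Xt) == yt), 0.9)
  expect_error(train_qsvm(X, rep(1, 40)), "single-class")
})

test_that("duplicating the training set leaves the decision unchanged", {
  set.seed(55)
  X <- rbind(matrix(runif(10 * 2, 0, 0.3), ncol = 2),
             matrix(runif(10 * 2, 0.7, 1), ncol = 2))
  y <- rep(c(1, -1), each = 10)
  spec <- kernel_spec(2)
  f1 <- train_qsvm(X, y, spec, tolerance = 1e-8)
  f2 <- train_qsvm(rbind(X, X), c(y, y), spec, tolerance = 1e-8)
  probe <- matrix(runif(16), 8, 2)
  m1 <- apply(probe, 1, function(p) decide(f1, p)$margin)
  m2 <- apply(probe, 1, function(p) decide(f2, p)$margin)
  expect_lt(max(abs(m1 - m2)), 1e-6)
})

test_that("decision values equal the direct kernel summation", {
  set.seed(56)
  X <- matrix(runif(24), 8, 3)
  y <- rep(c(1, -1), 4)
  fit <- train_qsvm(X, y, kernel_spec(3))
  for (rep in 1:20) {
    p <- runif(3)
    d <- decide(fit, p)
    manual <- sum(fit$alpha * fit$labels *
                    apply(X, 1, function(r)
                      quantum_kernel(r, p, fit$spec))) + fit$b
    expect_equal(d$margin, manual, tolerance = 1e-12)
    expect_identical(d$label, if (manual >= 0) 1 else -1)
  }
  # constant fit: all alpha zero, positive bias labels everything +1
  cf <- fit; cf$alpha[] <- 0; cf$b <- 0.5
  expect_identical(decide(cf, c(0.3, 0.3, 0.3))$label, 1)
  # a free support vector reproduces its own label
  free <- which(fit$alpha > 1e-6 & fit$alpha < fit$C - 1e-6)
  if (length(free))
    expect_identical(decide(fit, X[free[1], ])$label, fit$labels[free[1]])
})

test_that("solver agrees with an independent dual QP solver", {
  skip_if_not_installed("kernlab")
  set.seed(57)
  X <- rbind(matrix(runif(15 * 3, 0, 0.35), ncol = 3),
             matrix(runif(15 * 3, 0.65, 1), ncol = 3))
  y <- rep(c(1, -1), each = 15)
  spec <- kernel_spec(3)
  fit <- train_qsvm(X, y, spec, C = 10, tolerance = 1e-8)
  G <- gram_matrix(X, spec)
  kf <- kernlab::ksvm(kernlab::as.kernelMatrix(G), factor(y),
                      type = "C-svc", C = 10, scaled = FALSE, tol = 1e-9)
  dual_obj <- function(a) {
    v <- a * y
    sum(a) - 0.5 * sum(v * (G %*% v))
  }
  a_k <- numeric(30)
  a_k[kernlab::SVindex(kf)] <- abs(unlist(kernlab::alpha(kf)))
  expect_equal(dual_obj(fit$alpha), dual_obj(a_k), tolerance = 1e-5)
  probe <- matrix(runif(24), 8, 3)
  cross <- t(apply(probe, 1, function(p)
    apply(X, 1, function(r) quantum_kernel(r, p, spec))))
  dk <- kernlab::predict(kf,
    kernlab::as.kernelMatrix(cross[, kernlab::SVindex(kf), drop = FALSE]),
    type = "decision")
  mine <- apply(probe, 1, function(p) decide(fit, p)$margin)
  expect_lt(max(abs(as.numeric(dk) - mine)), 1e-5)
})

test_that("inner-product kernel variant reduces to the state overlap", {
  spec <- kernel_spec(2, feature_map = "inner")
  x <- c(0.2, 0.6); y <- c(0.8, 0.1)
  ov <- prod(cos(pi * (x - y) / 2))
  expect_equal(quantum_kernel(x, y, spec), ov, tolerance = 1e-12)
})

test_that("fit JSON serialization captures the model", {
  set.seed(58)
  X <- matrix(runif(12), 6, 2)
  y <- rep(c(1, -1), 3)
  fit <- train_qsvm(X, y, kernel_spec(2))
  js <- jsonlite::fromJSON(qsvm_to_json(fit))
  expect_equal(js$alpha, fit$alpha, tolerance = 1e-12)
  expect_equal(js$b, fit$b, tolerance = 1e-12)
  expect_equal(js$feature_map, "ry")
})
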