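# Entanglement entropies as association scores between feature subsystems.
# All entropies are in bits (log base 2), so a Bell pair scores exactly 1.

.eig_clip <- 1e-12

#' Options for the relative-entropy-of-entanglement optimizer
#'
#' The separable set is approximated by convex combinations of product pure
#' states; these options size that ansatz and the multi-restart local search.
#'
#' @param n_product_terms number of product terms in the separable mixture
#'   (default 8).
#' @param n_restarts number of optimizer restarts (default 16); the first is
#'   initialized from the eigenstructure of the input, the rest randomly.
#' @param max_iter Nelder-Mead iteration cap per restart (default 300).
#' @param tolerance convergence tolerance on the objective (default 1e-6).
#' @param seed integer seed for the random restarts.
#' @return A list of class `entanglement_options`.
#' @export
entanglement_options <- function(n_product_terms = 8L, n_restarts = 16L,
                                 max_iter = 300L, tolerance = 1e-6,
                                 seed = 1L) {
  stopifnot(n_product_terms >= 1L, n_restarts >= 1L, tolerance > 0)
  structure(list(n_product_terms = as.integer(n_product_terms),
                 n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter),
                 tolerance = tolerance, seed = as.integer(seed)),
            class = "entanglement_options")
}

# Eigenvalues of a Hermitian matrix, clipped below at .eig_clip for logs.
.herm_eigen <- function(m) eigen(m, symmetric = TRUE)

#' Von Neumann entropy in bits
#'
#' \eqn{S(\rho) = -\sum_i \lambda_i \log_2 \lambda_i} over the eigenvalues of
#' the density matrix, with \eqn{0 \log 0 = 0}. Pure states score 0; the
#' maximally mixed n-qubit state scores n.
#'
#' @param rho a [density_matrix()].
#' @return Entropy in bits, in `[0, n_qubits]`.
#' @export
von_neumann_entropy <- function(rho) {
  stopifnot(inherits(rho, "density_matrix"))
  ev <- Re(eigen(rho$matrix, symmetric = TRUE, only.values = TRUE)$values)
  ev <- ev[ev > .eig_clip]
  max(0, -sum(ev * log2(ev)))
}

#' Quantum relative entropy in bits
#'
#' \eqn{S(\rho \| \sigma) = \mathrm{Tr}(\rho(\log_2\rho - \log_2\sigma))}.
#' Non-negative (Klein's inequality), zero iff the arguments coincide, and
#' infinite when the support of `rho` is not contained in the support of
#' `sigma` — that case is signaled as a condition of class
#' `quantmine_infinite_divergence` rather than returning a number.
#'
#' @param rho,sigma [density_matrix()] objects of equal dimension.
#' @return Relative entropy in bits.
#' @export
quantum_relative_entropy <- function(rho, sigma) {
  stopifnot(inherits(rho, "density_matrix"), inherits(sigma, "density_matrix"))
  if (rho$n_qubits != sigma$n_qubits)
    stop("dimension mismatch: ", rho$n_qubits, " vs ", sigma$n_qubits,
         " qubits")
  er <- .herm_eigen(rho$matrix)
  es <- .herm_eigen(sigma$matrix)
  lr <- Re(er$values); ls <- Re(es$values)
  # support check: mass of rho on the kernel of sigma
  ker <- es$vectors[, ls < 1e-9, drop = FALSE]
  if (ncol(ker) > 0) {
    leak <- Re(sum(diag(Conj(t(ker)) %*% rho$matrix %*% ker)))
    if (leak > 1e-9)
      stop(structure(class = c("quantmine_infinite_divergence",
                               "error", "condition"),
                     list(message = paste0(
                       "support of rho is not contained in support of sigma",
                       " (leaked mass ", format(leak), "): divergence is",
                       " infinite"), call = sys.call(-1))))
  }
  lr_c <- pmax(lr, .eig_clip); ls_c <- pmax(ls, .eig_clip)
  t1 <- sum(lr[lr > .eig_clip] * log2(lr[lr > .eig_clip]))
  log_sigma <- es$vectors %*% (log2(ls_c) * Conj(t(es$vectors)))
  t2 <- Re(sum(diag(rho$matrix %*% log_sigma)))
  max(0, t1 - t2)
}

#' Entanglement entropy of a pure state across a bipartition
#'
#' For a pure state the entanglement between a qubit subset and its
#' complement equals the von Neumann entropy of either reduced state; this
#' is also the relative entropy of entanglement for pure states, which makes
#' it the closed-form reference for the variational measure.
#'
#' @param state a [quantum_state()].
#' @param bipartition 0-based qubit indices of one side; must be a proper
#'   nonempty subset.
#' @return Entanglement in bits, in `[0, min(|A|, |B|)]`.
#' @export
entanglement_pure <- function(state, bipartition) {
  stopifnot(inherits(state, "quantum_state"))
  n <- state$n_qubits
  bipartition <- sort(unique(as.integer(bipartition)))
  if (length(bipartition) == 0L || length(bipartition) >= n)
    stop("bipartition must be a proper nonempty subset of the ", n, " qubits")
  if (any(bipartition < 0L | bipartition >= n))
    stop("invalid qubit index in bipartition")
  von_neumann_entropy(partial_trace(to_density(state), keep = bipartition))
}

# --- variational relative entropy of entanglement ---------------------------

# Hyperspherical parameterization of a d-dimensional pure state:
# 2(d-1) real parameters -> complex unit vector (global phase fixed).
.params_to_pure <- function(theta, phi) {
  d <- length(theta) + 1L
  amp <- complex(length.out = d)
  sin_prod <- 1
  for (i in seq_len(d - 1L)) {
    amp[i] <- sin_prod * cos(theta[i]) *
      (if (i == 1L) 1 + 0i else exp(1i * phi[i - 1L]))
    sin_prod <- sin_prod * sin(theta[i])
  }
  amp[d] <- sin_prod * exp(1i * phi[d - 1L])
  amp
}

.pure_to_params <- function(amp) {
  d <- length(amp)
  amp <- amp * exp(-1i * Arg(amp[1]))
  theta <- numeric(d - 1L); phi <- numeric(d - 1L)
  r <- Mod(amp)
  sin_prod <- 1
  for (i in seq_len(d - 1L)) {
    ct <- if (sin_prod > 1e-14) min(1, max(-1, r[i] / sin_prod)) else 1
    theta[i] <- acos(ct)
    sin_prod <- sin_prod * sin(theta[i])
    if (i > 1L) phi[i - 1L] <- Arg(amp[i])
  }
  phi[d - 1L] <- Arg(amp[d])
  list(theta = theta, phi = phi)
}

# Build the separable mixture sigma from a flat parameter vector.
# Layout per term: [theta_A, phi_A, theta_B, phi_B, logit weight].
.build_separable <- function(par, dA, dB, n_terms) {
  pA <- 2L * (dA - 1L); pB <- 2L * (dB - 1L)
  per <- pA + pB + 1L
  d <- dA * dB
  sigma <- matrix(0+0i, d, d)
  w <- numeric(n_terms)
  comps <- vector("list", n_terms)
  for (t in seq_len(n_terms)) {
    off <- (t - 1L) * per
    a <- .params_to_pure(par[off + seq_len(dA - 1L)],
                         par[off + (dA - 1L) + seq_len(dA - 1L)])
    b <- .params_to_pure(par[off + pA + seq_len(dB - 1L)],
                         par[off + pA + (dB - 1L) + seq_len(dB - 1L)])
    w[t] <- par[off + per]
    comps[[t]] <- kronecker(a, b)  # A = high bits, B = low bits
  }
  w <- exp(w - max(w)); w <- w / sum(w)
  for (t in seq_len(n_terms))
    sigma <- sigma + w[t] * outer(comps[[t]], Conj(comps[[t]]))
  sigma
}

# Permute the qubits of a density matrix: perm[q+1] gives the new position
# of qubit q.
.permute_qubits <- function(mat, perm) {
  n <- length(perm)
  d <- 2L^n
  idx <- 0:(d - 1L)
  newidx <- integer(d)
  for (q in 0:(n - 1L)) {
    bit <- bitwAnd(bitwShiftR(idx, q), 1L)
    newidx <- newidx + bitwShiftL(bit, perm[q + 1L])
  }
  ord <- order(newidx)
  mat[ord, ord, drop = FALSE]
}

#' Relative entropy of entanglement (variational)
#'
#' Approximates \eqn{E_R(\rho) = \min_{\sigma \in D} S(\rho \| \sigma)},
#' the minimum relative entropy from the state to the separable set, by
#' minimizing over mixtures of product pure states
#' \eqn{\sigma = \sum_k p_k\, \rho_A^k \otimes \rho_B^k} with multi-restart
#' Nelder-Mead. The first restart is seeded from the eigenstructure of the
#' input (for a pure state this is its Schmidt mixture, the known optimum),
#' so the returned value is a tight upper bound that matches the pure-state
#' closed form.
#'
#' @param rho a [density_matrix()] on at most 4 qubits, with at most 2 qubits
#'   per side of the bipartition.
#' @param bipartition 0-based qubit indices of side A.
#' @param opts an [entanglement_options()] object.
#' @return A list with `value` (bits), `converged` flag, and `n_restarts`.
#' @export
relative_entropy_of_entanglement <- function(rho, bipartition,
                                             opts = entanglement_options()) {
  stopifnot(inherits(rho, "density_matrix"),
            inherits(opts, "entanglement_options"))
  n <- rho$n_qubits
  A <- sort(unique(as.integer(bipartition)))
  B <- setdiff(0:(n - 1L), A)
  if (length(A) == 0L || length(B) == 0L)
    stop("bipartition must be a proper nonempty subset")
  if (length(A) > 2L || length(B) > 2L)
    stop("at most 2 qubits per side are supported (tractability cap)")
  dA <- 2L^length(A); dB <- 2L^length(B)
  # reorder qubits so B occupies the low bits and A the high bits
  perm <- integer(n)
  perm[B + 1L] <- seq_along(B) - 1L
  perm[A + 1L] <- length(B) + seq_along(A) - 1L
  m <- .permute_qubits(rho$matrix, perm)
  er <- .herm_eigen(m)
  lr <- Re(er$values)
  t1 <- sum(lr[lr > .eig_clip] * log2(lr[lr > .eig_clip]))
  n_terms <- opts$n_product_terms
  pA <- 2L * (dA - 1L); pB <- 2L * (dB - 1L)
  per <- pA + pB + 1L
  objective <- function(par) {
    sigma <- .build_separable(par, dA, dB, n_terms)
    es <- .herm_eigen(sigma)
    ls <- pmax(Re(es$values), .eig_clip)
    log_sigma <- es$vectors %*% (log2(ls) * Conj(t(es$vectors)))
    val <- t1 - Re(sum(diag(m %*% log_sigma)))
    if (!is.finite(val)) 1e6 else val
  }
  # restart 1: product terms from the Schmidt structure of the leading
  # eigenvectors of rho — exact for pure inputs, a strong guess for mixed.
  eigen_init <- function() {
    # candidate product terms: Schmidt components of every eigenvector of
    # rho, weighted by (eigenvalue mass) x (Schmidt weight), best first
    cands <- list()
    for (v_idx in seq_len(ncol(er$vectors))) {
      psi <- matrix(er$vectors[, v_idx], nrow = dB)  # rows B, cols A
      sv <- svd(psi)
      for (comp in seq_along(sv$d)) {
        if (sv$d[comp] < 1e-9 && length(cands)) next
        cands[[length(cands) + 1L]] <- list(
          a = Conj(sv$v[, comp]) + 0i, b = sv$u[, comp] + 0i,
          lam = max(lr[v_idx], .eig_clip) * sv$d[comp]^2)
      }
    }
    cands <- cands[order(-vapply(cands, `[[`, numeric(1), "lam"))]
    par <- numeric(n_terms * per)
    for (t in seq_len(n_terms)) {
      off <- (t - 1L) * per
      cand <- cands[[((t - 1L) %% length(cands)) + 1L]]
      aP <- .pure_to_params(cand$a)
      bP <- .pure_to_params(cand$b)
      par[off + seq_len(dA - 1L)] <- aP$theta
      par[off + (dA - 1L) + seq_len(dA - 1L)] <- aP$phi
      par[off + pA + seq_len(dB - 1L)] <- bP$theta
      par[off + pA + (dB - 1L) + seq_len(dB - 1L)] <- bP$phi
      # a candidate recycled beyond its first appearance must not add
      # weight, or the softmax mixture would double-count it
      par[off + per] <- if (t <= length(cands))
        log(max(cand$lam, 1e-8)) else log(1e-8)
    }
    par
  }
  best <- Inf; best_conv <- FALSE
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(opts$seed)
  for (r in seq_len(opts$n_restarts)) {
    par0 <- if (r == 1L) eigen_init()
            else runif(n_terms * per, -pi, pi)
    fit <- optim(par0, objective, method = "Nelder-Mead",
                 control = list(maxit = opts$max_iter,
                                reltol = opts$tolerance))
    v0 <- objective(par0)
    val <- min(fit$value, v0)
    if (val < best) {
      best <- val
      best_conv <- fit$convergence == 0L || abs(fit$value - v0) < opts$tolerance
    }
  }
  list(value = max(0, best), converged = best_conv,
       n_restarts = opts$n_restarts)
}

#' Pairwise entanglement scores between two feature groups
#'
#' For every (a, b) feature pair the empirical two-feature joint
#' distribution is amplitude-encoded and scored with the pure-state
#' entanglement entropy — the package's quantum association score. A score
#' of 0 means the empirical pair distribution factorizes; 1 bit means the
#' pair is perfectly (Bell-like) correlated.
#'
#' @param table a [feature_table()].
#' @param group_a,group_b disjoint character vectors of feature names.
#' @return Numeric matrix of scores, rows `group_a`, columns `group_b`.
#' @export
entanglement_matrix <- function(table, group_a, group_b) {
  stopifnot(inherits(table, "feature_table"))
  group_a <- as.character(group_a); group_b <- as.character(group_b)
  if (length(intersect(group_a, group_b)))
    stop("feature groups must be disjoint; overlap: ",
         paste(intersect(group_a, group_b), collapse = ", "))
  out <- matrix(NA_real_, length(group_a), length(group_b),
                dimnames = list(group_a, group_b))
  for (a in group_a) for (b in group_b) {
    st <- encode_joint_distribution(table, c(a, b))
    out[a, b] <- entanglement_pure(st, bipartition = 1L)  # qubit 1 = feature a
  }
  out
}

#' Write an entanglement matrix as TSV and edge list
#'
#' @param scores matrix from [entanglement_matrix()].
#' @param path TSV path for the matrix form.
#' @param edge_path optional TSV path for the long (feature_a, feature_b,
#'   score) edge-list form.
#' @return `path`, invisibly.
#' @export
write_entanglement_tsv <- function(scores, path, edge_path = NULL) {
  df <- data.frame(feature = rownames(scores), scores, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(edge_path)) {
    edges <- data.frame(
      feature_a = rep(rownames(scores), times = ncol(scores)),
      feature_b = rep(colnames(scores), each = nrow(scores)),
      score = as.vector(scores))
    utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
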