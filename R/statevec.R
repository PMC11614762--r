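#' @useDynLib quantmine, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rbinom optim setNames
#' @importFrom utils head read.csv read.delim adist
NULL

# Register cap: a 20-qubit statevector is ~16 MB of complex doubles; beyond
# that exact simulation stops being a desk-scale exercise.
QUANTMINE_N_MAX <- 20L

.norm_tol <- 1e-10

#' Pure quantum state on a small register
#'
#' Constructs an n-qubit pure state from its full amplitude vector over the
#' \eqn{2^n} computational basis states. Basis index `x` is read as the bit
#' string \eqn{x_{n-1} \ldots x_0}: qubit 0 is the least-significant bit, a
#' convention shared by every function in the package.
#'
#' @param amplitudes complex (or numeric) vector of length \eqn{2^n};
#'   must have unit norm within `1e-10`.
#' @param qubit_labels optional character vector of length n naming the
#'   qubits, ordered from qubit n-1 (most significant) down to qubit 0.
#' @return An object of class `quantum_state` with fields `n_qubits`,
#'   `amplitudes` and `qubit_labels`.
#' @examples
#' quantum_state(c(1, 0))                  # |0>
#' quantum_state(rep(0.5, 4))              # uniform 2-qubit state
#' @export
quantum_state <- function(amplitudes, qubit_labels = NULL) {
  amplitudes <- as.complex(amplitudes)
  len <- length(amplitudes)
  n <- as.integer(round(log2(len)))
  if (len < 2L || bitwAnd(len, len - 1L) != 0L)
    stop("amplitude vector length must be a power of 2 (>= 2), got ", len)
  if (n > QUANTMINE_N_MAX)
    stop("register of ", n, " qubits exceeds the cap of ", QUANTMINE_N_MAX,
         " qubits (statevector intractable)")
  nrm <- sum(Mod(amplitudes)^2)
  if (abs(nrm - 1) > .norm_tol)
    stop("state is not normalized: sum |alpha_x|^2 = ", format(nrm))
  if (!is.null(qubit_labels)) {
    qubit_labels <- as.character(qubit_labels)
    if (length(qubit_labels) != n)
      stop("qubit_labels must have length ", n)
  }
  structure(list(n_qubits = n, amplitudes = amplitudes,
                 qubit_labels = qubit_labels),
            class = "quantum_state")
}

#' @export
print.quantum_state <- function(x, ...) {
  cat("<quantum_state> ", x$n_qubits, " qubit(s)\n", sep = "")
  p <- Mod(x$amplitudes)^2
  show <- which(p > 1e-12)
  labs <- basis_strings(x$n_qubits)[show]
  for (i in seq_along(show)) {
    a <- x$amplitudes[show[i]]
    cat(sprintf("  |%s>  amp = %s  (p = %.6f)\n", labs[i],
                format(a, digits = 6), p[show[i]]))
  }
  invisible(x)
}

#' Basis-state labels for an n-qubit register
#'
#' @param n number of qubits.
#' @return Character vector of all \eqn{2^n} bit strings
#'   \eqn{x_{n-1}\ldots x_0} in increasing index order.
#' @export
basis_strings <- function(n) {
  n <- as.integer(n)
  idx <- 0:(2^n - 1)
  vapply(idx, function(i) {
    bits <- bitwAnd(bitwShiftR(i, (n - 1L):0L), 1L)
    paste(bits, collapse = "")
  }, character(1))
}

#' Amplitude-encode an empirical joint distribution
#'
#' Maps the empirical joint distribution of a set of binary features onto a
#' quantum register: \eqn{\alpha_x = \sqrt{\hat P(x)}} where \eqn{\hat P} is
#' the observed frequency of feature bit-pattern `x` in the table. All
#' amplitudes are real and non-negative (the distribution fixes only the
#' moduli, so the non-negative root is taken for reproducibility), and
#' measuring the state reproduces the empirical pattern frequencies exactly.
#'
#' The first feature in `features` becomes the most-significant qubit, so the
#' basis string reads left-to-right in the order the features were listed.
#' Patterns absent from the table get amplitude exactly 0 (no pseudocount)
#' unless `smoothing > 0`, in which case `smoothing` is added to every
#' pattern count before normalization.
#'
#' @param table a [feature_table()].
#' @param features character vector of feature names, 1 to 20 of them.
#' @param smoothing non-negative pseudocount added to each pattern (default 0).
#' @return A [quantum_state()] with `qubit_labels` set to `features`.
#' @examples
#' tab <- feature_table(matrix(c(1, 0, 1, 1), 2, 2,
#'                     dimnames = list(NULL, c("g", "s"))),
#'                     roles = c(g = "gene", s = "symptom"))
#' encode_joint_distribution(tab, c("g", "s"))
#' @export
encode_joint_distribution <- function(table, features, smoothing = 0) {
  stopifnot(inherits(table, "feature_table"))
  features <- as.character(features)
  n <- length(features)
  if (n < 1L) stop("at least one feature is required")
  if (n > QUANTMINE_N_MAX)
    stop(n, " features exceed the register cap of ", QUANTMINE_N_MAX,
         " qubits (statevector intractable)")
  missing <- setdiff(features, table$feature_names)
  if (length(missing))
    stop("unknown feature name(s): ", paste(missing, collapse = ", "))
  m <- table$records[, features, drop = FALSE]
  if (nrow(m) < 1L) stop("empty table: no patient records to encode")
  # index x: features[1] is the most-significant bit
  weights <- 2^((n - 1L):0L)
  idx <- as.vector(m %*% weights) + 1L
  counts <- tabulate(idx, nbins = 2L^n) + smoothing
  p <- counts / sum(counts)
  quantum_state(sqrt(p), qubit_labels = features)
}

#' Measurement probabilities of a state
#'
#' Born-rule outcome distribution \eqn{P(x) = |\alpha_x|^2} over the
#' computational basis.
#'
#' @param state a [quantum_state()].
#' @return Named numeric vector: names are the n-bit basis strings, values
#'   the outcome probabilities (summing to 1).
#' @export
measure_probabilities <- function(state) {
  stopifnot(inherits(state, "quantum_state"))
  setNames(Mod(state$amplitudes)^2, basis_strings(state$n_qubits))
}

#' Tensor product of two registers
#'
#' Composes two states into one register with `a`'s qubits as the
#' more-significant block, matching the \eqn{|x\rangle = |x_{n-1}\rangle
#' \otimes \cdots \otimes |x_0\rangle} decomposition.
#'
#' @param a,b [quantum_state()] objects.
#' @return A `quantum_state` on `a$n_qubits + b$n_qubits` qubits.
#' @export
tensor_states <- function(a, b) {
  stopifnot(inherits(a, "quantum_state"), inherits(b, "quantum_state"))
  n <- a$n_qubits + b$n_qubits
  if (n > QUANTMINE_N_MAX)
    stop("combined register of ", n, " qubits exceeds the cap of ",
         QUANTMINE_N_MAX)
  amps <- as.vector(outer(b$amplitudes, a$amplitudes))  # a = high bits
  labels <- NULL
  if (!is.null(a$qubit_labels) && !is.null(b$qubit_labels))
    labels <- c(a$qubit_labels, b$qubit_labels)
  quantum_state(amps, qubit_labels = labels)
}

#' Density matrix of a small register
#'
#' @param matrix square complex matrix of dimension \eqn{2^n}; must be
#'   Hermitian, unit-trace and positive semi-definite within `1e-10`.
#' @param qubit_labels optional qubit names (most significant first).
#' @return An object of class `density_matrix`.
#' @export
density_matrix <- function(matrix, qubit_labels = NULL) {
  m <- as.matrix(matrix)
  storage.mode(m) <- "complex"
  d <- nrow(m)
  if (ncol(m) != d) stop("density matrix must be square")
  n <- as.integer(round(log2(d)))
  if (2L^n != d) stop("dimension must be a power of 2, got ", d)
  if (max(Mod(m - Conj(t(m)))) > .norm_tol)
    stop("matrix is not Hermitian within 1e-10")
  tr <- Re(sum(diag(m)))
  if (abs(tr - 1) > .norm_tol)
    stop("trace must be 1, got ", format(tr))
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -.norm_tol)
    stop("matrix is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")")
  if (!is.null(qubit_labels) && length(qubit_labels) != n)
    stop("qubit_labels must have length ", n)
  structure(list(n_qubits = n, matrix = m, qubit_labels = qubit_labels),
            class = "density_matrix")
}

#' @export
print.density_matrix <- function(x, ...) {
  cat("<density_matrix> ", x$n_qubits, " qubit(s), dim ",
      nrow(x$matrix), "\n", sep = "")
  invisible(x)
}

#' Rank-1 density operator of a pure state
#'
#' @param state a [quantum_state()].
#' @return The projector \eqn{|\Psi\rangle\langle\Psi|} as a
#'   [density_matrix()].
#' @export
to_density <- function(state) {
  stopifnot(inherits(state, "quantum_state"))
  a <- state$amplitudes
  density_matrix(outer(a, Conj(a)), qubit_labels = state$qubit_labels)
}

#' Partial trace onto a subset of qubits
#'
#' Traces out the complement of `keep`, returning the reduced state of the
#' kept qubits. Kept qubits retain their relative order: the lowest kept
#' qubit index becomes qubit 0 of the output.
#'
#' @param rho a [density_matrix()].
#' @param keep integer vector of qubit indices to keep (0-based, qubit 0 is
#'   the least-significant bit). Must be nonempty.
#' @return A `density_matrix` on `length(keep)` qubits (the input itself if
#'   `keep` is the full set).
#' @export
partial_trace <- function(rho, keep) {
  stopifnot(inherits(rho, "density_matrix"))
  n <- rho$n_qubits
  keep <- sort(unique(as.integer(keep)))
  if (length(keep) == 0L) stop("keep must contain at least one qubit index")
  if (any(keep < 0L | keep >= n))
    stop("invalid qubit index; valid range is 0..", n - 1L)
  traced <- setdiff(0:(n - 1L), keep)
  if (length(traced) == 0L) return(rho)
  dK <- 2L^length(keep)
  dT <- 2L^length(traced)
  # full index of (kept-subindex a, traced-subindex e): place bits
  place <- function(sub, positions) {
    out <- integer(length(sub))
    for (t in seq_along(positions)) {
      bit <- bitwAnd(bitwShiftR(sub, t - 1L), 1L)
      out <- out + bitwShiftL(bit, positions[t])
    }
    out
  }
  keptFull <- place(0:(dK - 1L), keep)      # contribution of kept bits
  tracedFull <- place(0:(dT - 1L), traced)  # contribution of traced bits
  out <- matrix(0+0i, dK, dK)
  for (e in tracedFull) {
    rows <- keptFull + e + 1L
    out <- out + rho$matrix[rows, rows, drop = FALSE]
  }
  labels <- NULL
  if (!is.null(rho$qubit_labels))
    labels <- rho$qubit_labels[n - rev(keep)]  # labels stored high-first
  density_matrix(out, qubit_labels = labels)
}

#' Apply a unitary gate to selected qubits
#'
#' Lifts a gate on `length(targets)` qubits to the full register and applies
#' it. `targets[1]` is the least-significant qubit of the gate's own
#' subspace.
#'
#' @param state a [quantum_state()].
#' @param gate complex matrix of dimension \eqn{2^t}; must be unitary within
#'   `1e-10`.
#' @param targets distinct 0-based qubit indices, one per gate qubit.
#' @return The transformed `quantum_state`.
#' @examples
#' H <- matrix(1 / sqrt(2) * c(1, 1, 1, -1), 2, 2)
#' apply_unitary(quantum_state(c(1, 0)), H, targets = 0)
#' @export
apply_unitary <- function(state, gate, targets) {
  stopifnot(inherits(state, "quantum_state"))
  gate <- as.matrix(gate)
  storage.mode(gate) <- "complex"
  t <- length(targets)
  targets <- as.integer(targets)
  if (anyDuplicated(targets)) stop("target qubits must be distinct")
  n <- state$n_qubits
  if (any(targets < 0L | targets >= n))
    stop("invalid target qubit index; valid range is 0..", n - 1L)
  dG <- 2L^t
  if (nrow(gate) != dG || ncol(gate) != dG)
    stop("gate must be ", dG, "x", dG, " for ", t, " target qubit(s)")
  dev <- max(Mod(gate %*% Conj(t(gate)) - diag(dG)))
  if (dev > .norm_tol)
    stop("gate is not unitary within 1e-10 (deviation ", format(dev), ")")
  rest <- setdiff(0:(n - 1L), targets)
  dR <- 2L^length(rest)
  place <- function(sub, positions) {
    out <- integer(length(sub))
    for (k in seq_along(positions)) {
      bit <- bitwAnd(bitwShiftR(sub, k - 1L), 1L)
      out <- out + bitwShiftL(bit, positions[k])
    }
    out
  }
  gFull <- place(0:(dG - 1L), targets)
  rFull <- place(0:(dR - 1L), rest)
  # A[r, g] = amplitude at full index rFull[r] + gFull[g]
  idx <- outer(rFull, gFull, `+`) + 1L
  A <- matrix(state$amplitudes[idx], dR, dG)
  Anew <- A %*% t(gate)
  amps <- state$amplitudes
  amps[as.vector(idx)] <- as.vector(Anew)
  quantum_state(amps, qubit_labels = state$qubit_labels)
}

#' Serialize a state or density matrix to JSON
#'
#' @param x a `quantum_state` or `density_matrix`.
#' @param path file to write; if `NULL`, the JSON string is returned.
#' @return The path (invisibly) or a JSON string.
#' @export
quantum_to_json <- function(x, path = NULL) {
  if (inherits(x, "quantum_state")) {
    obj <- list(type = "quantum_state", n_qubits = x$n_qubits,
                amplitudes_re = Re(x$amplitudes),
                amplitudes_im = Im(x$amplitudes),
                qubit_labels = x$qubit_labels)
  } else if (inherits(x, "density_matrix")) {
    obj <- list(type = "density_matrix", n_qubits = x$n_qubits,
                entries_re = as.vector(Re(x$matrix)),
                entries_im = as.vector(Im(x$matrix)),
                qubit_labels = x$qubit_labels)
  } else stop("unsupported type for quantum serialization")
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a state or density matrix from JSON
#'
#' @param path file written by [quantum_to_json()].
#' @return The deserialized object.
#' @export
quantum_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  labels <- obj$qubit_labels
  if (length(labels) == 0) labels <- NULL
  if (obj$type == "quantum_state") {
    quantum_state(complex(real = obj$amplitudes_re,
                          imaginary = obj$amplitudes_im),
                  qubit_labels = labels)
  } else if (obj$type == "density_matrix") {
    d <- 2L^obj$n_qubits
    density_matrix(matrix(complex(real = obj$entries_re,
                                  imaginary = obj$entries_im), d, d),
                   qubit_labels = labels)
  } else stop("unrecognized quantum JSON type: ", obj$type)
}
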