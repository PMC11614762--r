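# Quantum fidelity-kernel SVM. Each sample is mapped to a product state by
# per-feature Y-rotations (angle pi * value), similarity is the fidelity
# |<phi(x)|phi(y)>|^2, and classification uses the standard dual soft-margin
# machine f(x) = sign(sum_i alpha_i y_i K(x_i, x) + b) over that kernel.

#' Quantum kernel specification
#'
#' @param n_features number of input features (one qubit each).
#' @param feature_map `"ry"` (default): per-feature Y-rotation by angle
#'   \eqn{\pi x_j}, tensored across features, giving the fidelity kernel
#'   \eqn{K(x,y) = \prod_j \cos^2(\pi(x_j - y_j)/2)}. `"inner"`: the literal
#'   state inner product \eqn{\langle\phi(x)|\phi(y)\rangle} (real part),
#'   kept as a documented alternative; with a shared unitary it reduces to
#'   the plain overlap of the encoded states.
#' @return A list of class `kernel_spec`.
#' @export
kernel_spec <- function(n_features, feature_map = c("ry", "inner")) {
  n_features <- as.integer(n_features)
  feature_map <- match.arg(feature_map)
  stopifnot(n_features >= 1L, n_features <= QUANTMINE_N_MAX)
  structure(list(n_features = n_features, feature_map = feature_map),
            class = "kernel_spec")
}

.check_sample <- function(x, spec) {
  x <- as.numeric(x)
  if (length(x) != spec$n_features)
    stop("sample has ", length(x), " features; kernel expects ",
         spec$n_features)
  if (any(x < 0 | x > 1))
    stop("feature values must lie in [0, 1]; rescale inputs first")
  x
}

#' Quantum feature-map state of a sample
#'
#' \eqn{|\phi(x)\rangle = U(x)|0\cdots0\rangle} where `U(x)` applies a
#' Y-rotation by angle \eqn{\pi x_j} on the qubit of feature j. Feature 1 is
#' the most-significant qubit. A 0 maps to \eqn{|0\rangle}, a 1 to
#' \eqn{|1\rangle}, intermediate values interpolate on the Bloch sphere.
#'
#' @param x numeric vector with values in `[0, 1]`.
#' @param spec a [kernel_spec()].
#' @return A [quantum_state()].
#' @export
feature_map_state <- function(x, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  x <- .check_sample(x, spec)
  amp <- 1
  for (j in seq_along(x)) {
    half <- pi * x[j] / 2
    amp <- as.vector(outer(c(cos(half), sin(half)), amp))
  }
  # outer(qubit_j, acc): acc varies slowest -> feature 1 ends most significant
  quantum_state(as.complex(amp))
}

.state_matrix <- function(samples, spec) {
  t(apply(samples, 1, function(x) Re(feature_map_state(x, spec)$amplitudes)))
}

#' Quantum kernel between two samples
#'
#' Fidelity form \eqn{K(x,y) = |\langle\phi(x)|\phi(y)\rangle|^2} (default),
#' computed from the simulated feature-map states. Symmetric, bounded in
#' `[0, 1]`, with `K(x, x) = 1`.
#'
#' @param x,y numeric vectors of equal length with values in `[0, 1]`.
#' @param spec a [kernel_spec()].
#' @return Scalar similarity.
#' @export
quantum_kernel <- function(x, y, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  ax <- feature_map_state(x, spec)$amplitudes
  ay <- feature_map_state(y, spec)$amplitudes
  ov <- sum(Conj(ax) * ay)
  if (spec$feature_map == "inner") Re(ov) else Mod(ov)^2
}

#' Gram matrix of quantum kernel values
#'
#' Builds all feature-map states once and forms every pairwise overlap.
#' The result has a unit diagonal and is positive semi-definite (within
#' numerical tolerance 1e-8), as any fidelity kernel must be.
#'
#' @param samples numeric matrix, one sample per row, values in `[0, 1]`.
#' @param spec a [kernel_spec()].
#' @return Symmetric `n x n` kernel matrix.
#' @export
gram_matrix <- function(samples, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  samples <- as.matrix(samples)
  if (nrow(samples) < 1L) stop("no samples")
  Phi <- .state_matrix(samples, spec)
  G <- Phi %*% t(Phi)  # real amplitudes: overlap matrix
  if (spec$feature_map == "inner") G else G^2
}

#' Train a quantum-kernel SVM
#'
#' Solves the dual soft-margin problem over the quantum Gram matrix with
#' pairwise (SMO-style) coordinate optimization: the most KKT-violating
#' multiplier is paired with the partner of largest error gap, both updated
#' analytically with box clipping, until no violation exceeds `tolerance`.
#' Pair selection is deterministic, so training is reproducible. The bias
#' `b` is the average over unbounded support vectors.
#'
#' @param samples numeric matrix (rows = samples, values in `[0, 1]`).
#' @param labels vector of class labels in `{-1, +1}`; both classes must be
#'   present.
#' @param spec a [kernel_spec()]; defaults to an `"ry"` map sized to the
#'   samples.
#' @param C box constraint (default 10).
#' @param tolerance KKT tolerance (default 1e-3).
#' @param max_passes cap on full passes without progress safeguards.
#' @return An object of class `qsvm_fit` with fields `alpha`, `b`,
#'   `samples`, `labels`, `spec`, `C`, `tolerance`, `converged`,
#'   `n_iterations`.
#' @export
train_qsvm <- function(samples, labels, spec = NULL, C = 10,
                       tolerance = 1e-3, max_passes = 200L) {
  samples <- as.matrix(samples)
  labels <- as.numeric(labels)
  n <- nrow(samples)
  if (n < 2L) stop("at least 2 samples are required")
  if (!all(labels %in% c(-1, 1)))
    stop("labels must be -1 or +1")
  if (length(unique(labels)) < 2L)
    stop("single-class input: both labels must be present")
  if (is.null(spec)) spec <- kernel_spec(ncol(samples))
  stopifnot(C > 0, tolerance > 0)
  G <- gram_matrix(samples, spec)
  y <- labels
  alpha <- numeric(n)
  b <- 0
  f <- numeric(n)  # sum_j alpha_j y_j K_ij, maintained incrementally
  iter <- 0L
  stale_passes <- 0L
  while (stale_passes < 3L && iter < max_passes * n) {
    changed <- 0L
    for (i in seq_len(n)) {
      Ei <- f[i] + b - y[i]
      if (!((y[i] * Ei < -tolerance && alpha[i] < C) ||
            (y[i] * Ei > tolerance && alpha[i] > 0))) next
      E <- f + b - y
      gap <- abs(Ei - E)
      gap[i] <- -Inf
      # partners in decreasing error-gap order (deterministic fallback:
      # if the best partner makes no progress, try the next)
      for (j in order(-gap, seq_len(n))) {
        if (j == i) next
        Ej <- E[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (L >= H) next
        eta <- 2 * G[i, j] - G[i, i] - G[j, j]
        if (eta >= -1e-12) next
        aj_new <- min(H, max(L, aj_old - y[j] * (Ei - Ej) / eta))
        if (abs(aj_new - aj_old) < 1e-10 * (aj_new + aj_old + 1e-10)) next
        ai_new <- ai_old + y[i] * y[j] * (aj_old - aj_new)
        b1 <- b - Ei - y[i] * (ai_new - ai_old) * G[i, i] -
          y[j] * (aj_new - aj_old) * G[i, j]
        b2 <- b - Ej - y[i] * (ai_new - ai_old) * G[i, j] -
          y[j] * (aj_new - aj_old) * G[j, j]
        alpha[i] <- ai_new; alpha[j] <- aj_new
        f <- f + (ai_new - ai_old) * y[i] * G[, i] +
          (aj_new - aj_old) * y[j] * G[, j]
        b <- if (ai_new > 0 && ai_new < C) b1
             else if (aj_new > 0 && aj_new < C) b2
             else (b1 + b2) / 2
        changed <- changed + 1L
        iter <- iter + 1L
        break
      }
    }
    stale_passes <- if (changed == 0L) stale_passes + 1L else 0L
  }
  f <- as.vector(G %*% (alpha * y))
  free <- alpha > 1e-9 & alpha < C - 1e-9
  b <- if (any(free)) mean(y[free] - f[free]) else b
  E <- f + b - y
  kkt <- pmax(ifelse(alpha < C, pmax(0, -y * E), 0),
              ifelse(alpha > 0, pmax(0, y * E), 0))
  converged <- max(kkt) < 10 * tolerance
  structure(list(alpha = alpha, b = b, samples = samples, labels = y,
                 spec = spec, C = C, tolerance = tolerance,
                 converged = converged, n_iterations = iter),
            class = "qsvm_fit")
}

#' @export
print.qsvm_fit <- function(x, ...) {
  cat("<qsvm_fit> ", length(x$alpha), " training samples, ",
      sum(x$alpha > 1e-9), " support vectors, C = ", x$C,
      if (x$converged) ", converged" else ", NOT converged", "\n", sep = "")
  invisible(x)
}

#' Classify a sample with a trained quantum SVM
#'
#' Evaluates \eqn{f(x) = \mathrm{sign}(\sum_i \alpha_i y_i K(x_i, x) + b)};
#' the raw margin is returned alongside the label, and `sign(0)` is defined
#' as `+1`.
#'
#' @param fit a `qsvm_fit` from [train_qsvm()].
#' @param x numeric vector matching the fit's feature dimension.
#' @return List with `label` (+1 or -1) and `margin`.
#' @export
decide <- function(fit, x) {
  stopifnot(inherits(fit, "qsvm_fit"))
  x <- .check_sample(x, fit$spec)
  phi <- Re(feature_map_state(x, fit$spec)$amplitudes)
  Phi <- .state_matrix(fit$samples, fit$spec)
  kv <- as.vector(Phi %*% phi)
  if (fit$spec$feature_map != "inner") kv <- kv^2
  margin <- sum(fit$alpha * fit$labels * kv) + fit$b
  list(label = if (margin >= 0) 1 else -1, margin = margin)
}

#' @export
predict.qsvm_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  # batch evaluation: build the feature-map states once per set
  Phi_new <- .state_matrix(newdata, object$spec)
  Phi_tr <- .state_matrix(object$samples, object$spec)
  Kc <- Phi_new %*% t(Phi_tr)
  if (object$spec$feature_map != "inner") Kc <- Kc^2
  margins <- as.vector(Kc %*% (object$alpha * object$labels)) + object$b
  ifelse(margins >= 0, 1, -1)
}

#' Serialize a quantum SVM fit to JSON
#'
#' @param fit a `qsvm_fit`.
#' @param path file to write; if `NULL` the JSON string is returned.
#' @return The path (invisibly) or a JSON string.
#' @export
qsvm_to_json <- function(fit, path = NULL) {
  obj <- list(alpha = fit$alpha, b = fit$b,
              samples = as.data.frame(fit$samples), labels = fit$labels,
              n_features = fit$spec$n_features,
              feature_map = fit$spec$feature_map,
              C = fit$C, tolerance = fit$tolerance,
              converged = fit$converged)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
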