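# Higher-order Ising energy model over spins s_i = +/-1:
#   E(s) = - sum_{i<j} J_ij s_i s_j - sum_i h_i s_i + sum_{i<j<k} K_ijk s_i s_j s_k
# Note the sign asymmetry: pairwise couplings and fields enter with a minus
# sign while the third-order couplings enter with a plus sign, so a POSITIVE
# K penalizes aligned triples. The estimators below are centered-moment
# based, so a strictly third-order dependence (parity) produces a large |K|
# with vanishing pairwise J — the signature second-order statistics miss.

.check_tuples <- function(df, cols, m) {
  if (is.null(df) || nrow(df) == 0L)
    return(stats::setNames(as.data.frame(matrix(numeric(0), 0, length(cols) + 1L)),
                           c(cols, "value")))
  df <- as.data.frame(df)
  stopifnot(all(c(cols, "value") %in% names(df)))
  df <- df[, c(cols, "value")]
  idx <- as.matrix(df[, cols, drop = FALSE])
  storage.mode(idx) <- "integer"
  if (any(idx < 1L | idx > m)) stop("coupling index out of range 1..", m)
  if (length(cols) > 1L && any(t(apply(idx, 1, diff)) <= 0L))
    stop("coupling indices must be strictly increasing (i < j < k)")
  if (any(!is.finite(df$value))) stop("all coefficients must be finite")
  key <- apply(idx, 1, paste, collapse = ",")
  if (anyDuplicated(key)) stop("duplicate coupling tuple")
  df[, cols] <- idx
  df
}

#' Higher-order Ising model
#'
#' @param m number of spins.
#' @param h numeric vector of per-spin bias fields (length `m`; recycled
#'   scalar 0 allowed).
#' @param J data.frame with columns `i`, `j`, `value`: pairwise couplings,
#'   stored only for `i < j`.
#' @param K data.frame with columns `i`, `j`, `k`, `value`: third-order
#'   couplings, `i < j < k`.
#' @param L4 optional data.frame with columns `i`, `j`, `k`, `l`, `value`:
#'   fourth-order couplings accepted for forward energy evaluation only.
#' @param feature_names optional character vector naming the spins.
#' @return An object of class `ising_model`.
#' @export
ising_model <- function(m, h = 0, J = NULL, K = NULL, L4 = NULL,
                        feature_names = NULL) {
  m <- as.integer(m)
  stopifnot(m >= 1L)
  h <- rep_len(as.numeric(h), m)
  if (any(!is.finite(h))) stop("all bias terms must be finite")
  J <- .check_tuples(J, c("i", "j"), m)
  K <- .check_tuples(K, c("i", "j", "k"), m)
  L4 <- if (is.null(L4)) NULL else .check_tuples(L4, c("i", "j", "k", "l"), m)
  if (!is.null(feature_names)) {
    feature_names <- as.character(feature_names)
    if (length(feature_names) != m) stop("feature_names must have length m")
  }
  structure(list(m = m, h = h, J = J, K = K, L4 = L4,
                 feature_names = feature_names),
            class = "ising_model")
}

#' @export
print.ising_model <- function(x, ...) {
  cat("<ising_model> ", x$m, " spins, ", nrow(x$J), " pairwise, ",
      nrow(x$K), " third-order coupling(s)\n", sep = "")
  invisible(x)
}

#' Ising energy of a spin configuration
#'
#' @param model an [ising_model()].
#' @param s numeric vector of spins in `{+1, -1}`, length `m`.
#' @return The scalar energy
#'   \eqn{E = -\sum_{i<j} J_{ij}s_is_j - \sum_i h_is_i +
#'        \sum_{i<j<k} K_{ijk}s_is_js_k} (plus any fourth-order terms, which
#'   also enter with a plus sign).
#' @export
ising_energy <- function(model, s) {
  stopifnot(inherits(model, "ising_model"))
  s <- as.numeric(s)
  if (length(s) != model$m)
    stop("configuration length ", length(s), " != m = ", model$m)
  if (!all(s %in% c(-1, 1))) stop("spins must be exactly +1 or -1")
  e <- -sum(model$h * s)
  if (nrow(model$J))
    e <- e - sum(model$J$value * s[model$J$i] * s[model$J$j])
  if (nrow(model$K))
    e <- e + sum(model$K$value * s[model$K$i] * s[model$K$j] * s[model$K$k])
  if (!is.null(model$L4) && nrow(model$L4))
    e <- e + sum(model$L4$value * s[model$L4$i] * s[model$L4$j] *
                   s[model$L4$k] * s[model$L4$l])
  e
}

#' Estimate a higher-order Ising model from binary data
#'
#' Maps bits to spins \eqn{\sigma = 2b - 1} and sets the coefficients from
#' empirical moments: \eqn{h_i = \bar\sigma_i}, \eqn{J_{ij} =
#' \widehat{\mathrm{cov}}(\sigma_i, \sigma_j)} (population form, denominator
#' n), and for `max_order = 3` the third central cross-moment
#' \eqn{K_{ijk} = \widehat E[(\sigma_i-\mu_i)(\sigma_j-\mu_j)
#' (\sigma_k-\mu_k)]}. Central moments vanish for strictly pairwise data and
#' isolate genuinely third-order structure; they rank interactions by
#' strength rather than recovering generative couplings exactly.
#'
#' @param table a [feature_table()].
#' @param features character vector of feature names to model.
#' @param max_order 2 or 3.
#' @return An [ising_model()] over the selected features; constant features
#'   trigger a warning (their centered moments, and hence couplings, are 0).
#' @export
estimate_ising <- function(table, features, max_order = 3L) {
  stopifnot(inherits(table, "feature_table"))
  features <- as.character(features)
  max_order <- as.integer(max_order)
  if (!max_order %in% c(2L, 3L)) stop("max_order must be 2 or 3")
  missing <- setdiff(features, table$feature_names)
  if (length(missing))
    stop("unknown feature name(s): ", paste(missing, collapse = ", "))
  bits <- table$records[, features, drop = FALSE]
  nrec <- nrow(bits)
  if (nrec < 2L) stop("at least 2 records are required")
  sig <- 2 * bits - 1
  mu <- colMeans(sig)
  const <- which(apply(sig, 2, function(v) all(v == v[1])))
  if (length(const))
    warning("constant feature(s) with zero variance: ",
            paste(features[const], collapse = ", "),
            " (their couplings are 0 by the defining moments)")
  C <- sweep(sig, 2, mu)
  m <- length(features)
  Jrows <- list(); Krows <- list()
  if (m >= 2L) {
    cm <- crossprod(C) / nrec
    pairs <- which(upper.tri(cm), arr.ind = TRUE)
    Jrows <- data.frame(i = pairs[, 1], j = pairs[, 2],
                        value = cm[pairs])
  }
  if (max_order == 3L && m >= 3L) {
    combs <- utils::combn(m, 3L)
    vals <- apply(combs, 2, function(t3)
      mean(C[, t3[1]] * C[, t3[2]] * C[, t3[3]]))
    Krows <- data.frame(i = combs[1, ], j = combs[2, ], k = combs[3, ],
                        value = vals)
  }
  ising_model(m, h = mu,
              J = if (length(Jrows)) Jrows else NULL,
              K = if (length(Krows)) Krows else NULL,
              feature_names = features)
}

# Spin configurations in tie-break order: enumeration index maps bit 0 to
# spin +1 and bit 1 to spin -1, spin 1 most significant, so ascending index
# is lexicographic order with +1 < -1.
.config_from_index <- function(idx, m) {
  bits <- bitwAnd(bitwShiftR(idx, (m - 1L):0L), 1L)
  1 - 2 * bits
}

#' Exact ground state by exhaustive enumeration
#'
#' Enumerates all \eqn{2^m} configurations and returns the first energy
#' minimum in lexicographic order (with +1 ordered before -1). Serves as the
#' exact oracle the annealers are validated against.
#'
#' @param model an [ising_model()] with `m <= 20`.
#' @return List with `configuration` (spin vector) and `energy`.
#' @export
ground_state_bruteforce <- function(model) {
  stopifnot(inherits(model, "ising_model"))
  m <- model$m
  if (m > 20L) stop("m = ", m, " too large for exhaustive enumeration")
  best_e <- Inf; best_idx <- NA_integer_
  chunk <- 2L^min(m, 14L)
  total <- 2L^m
  J <- model$J; K <- model$K; h <- model$h
  for (start in seq(0L, total - 1L, by = chunk)) {
    idx <- start:(min(start + chunk, total) - 1L)
    S <- matrix(vapply(idx, .config_from_index, numeric(m), m = m),
                ncol = m, byrow = TRUE)
    e <- -as.vector(S %*% h)
    if (nrow(J)) e <- e - as.vector((S[, J$i, drop = FALSE] *
                                     S[, J$j, drop = FALSE]) %*% J$value)
    if (nrow(K)) e <- e + as.vector((S[, K$i, drop = FALSE] *
                                     S[, K$j, drop = FALSE] *
                                     S[, K$k, drop = FALSE]) %*% K$value)
    if (!is.null(model$L4) && nrow(model$L4)) {
      L4 <- model$L4
      e <- e + as.vector((S[, L4$i, drop = FALSE] * S[, L4$j, drop = FALSE] *
                          S[, L4$k, drop = FALSE] * S[, L4$l, drop = FALSE]) %*%
                           L4$value)
    }
    w <- which.min(e)
    if (e[w] < best_e) { best_e <- e[w]; best_idx <- idx[w] }
  }
  list(configuration = .config_from_index(best_idx, m), energy = best_e)
}

#' Annealing schedule for the Monte-Carlo ground-state searchers
#'
#' Defaults: 2000 sweeps, thermal schedule T from 2.0 down to 0.05,
#' transverse field from 2.5 down to 0.01 over 8 Trotter slices, 8 restarts.
#'
#' @param n_sweeps sweeps per restart.
#' @param temperature_start,temperature_end geometric thermal schedule
#'   endpoints (start >= end > 0).
#' @param transverse_field_start,transverse_field_end geometric transverse
#'   field endpoints for the quantum annealer (start >= end > 0).
#' @param n_trotter number of Trotter replicas (>= 2) for the quantum mode.
#' @param n_restarts independent restarts; the best result is kept.
#' @param seed integer seed; identical seeds give identical results.
#' @return A list of class `anneal_schedule`.
#' @export
anneal_schedule <- function(n_sweeps = 2000L, temperature_start = 2.0,
                            temperature_end = 0.05,
                            transverse_field_start = 2.5,
                            transverse_field_end = 0.01,
                            n_trotter = 8L, n_restarts = 8L, seed = 1L) {
  stopifnot(n_sweeps >= 1L,
            temperature_start >= temperature_end, temperature_end > 0,
            transverse_field_start >= transverse_field_end,
            transverse_field_end > 0,
            n_trotter >= 2L, n_restarts >= 1L)
  structure(list(n_sweeps = as.integer(n_sweeps),
                 temperature_start = temperature_start,
                 temperature_end = temperature_end,
                 transverse_field_start = transverse_field_start,
                 transverse_field_end = transverse_field_end,
                 n_trotter = as.integer(n_trotter),
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "anneal_schedule")
}

.model_dense <- function(model) {
  m <- model$m
  Jm <- matrix(0, m, m)
  if (nrow(model$J)) {
    Jm[cbind(model$J$i, model$J$j)] <- model$J$value
    Jm <- Jm + t(Jm)
  }
  Kt <- if (nrow(model$K))
    cbind(model$K$i, model$K$j, model$K$k, model$K$value)
  else matrix(0, 0, 4)
  list(Jm = Jm, Kt = Kt)
}

#' Simulated (thermal) annealing ground-state search
#'
#' Metropolis single-spin-flip dynamics with a geometric temperature decay,
#' restarted `n_restarts` times from random configurations; the best-seen
#' configuration across all restarts is returned. Deterministic for a fixed
#' schedule seed.
#'
#' @param model an [ising_model()].
#' @param schedule an [anneal_schedule()].
#' @return List with `configuration`, `energy` and `trace` (best-seen
#'   energy after each sweep of the best restart; non-increasing).
#' @export
simulated_annealing <- function(model, schedule = anneal_schedule()) {
  stopifnot(inherits(model, "ising_model"),
            inherits(schedule, "anneal_schedule"))
  d <- .model_dense(model)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(schedule$seed)
  res <- anneal_sa_cpp(model$h, d$Jm, d$Kt, schedule$n_sweeps,
                       schedule$temperature_start, schedule$temperature_end,
                       schedule$n_restarts)
  list(configuration = as.numeric(res$configuration), energy = res$energy,
       trace = as.numeric(res$trace))
}

#' Simulated quantum annealing (path-integral Monte Carlo)
#'
#' Trotterizes the transverse-field Ising dynamics into `n_trotter` coupled
#' replicas. The inter-replica ferromagnetic coupling is
#' \eqn{J_\perp = -\tfrac{1}{2}\log\tanh(\Gamma/(P\,T))} with the transverse
#' field \eqn{\Gamma} decayed geometrically over the schedule; Metropolis
#' updates run at fixed temperature `temperature_end`. The best
#' single-replica configuration (by problem energy) across all restarts is
#' returned.
#'
#' @inheritParams simulated_annealing
#' @return List with `configuration`, `energy` and `trace`.
#' @export
simulated_quantum_annealing <- function(model, schedule = anneal_schedule()) {
  stopifnot(inherits(model, "ising_model"),
            inherits(schedule, "anneal_schedule"))
  if (schedule$transverse_field_end <= 0 ||
      schedule$transverse_field_start <= 0)
    stop("transverse field must be positive")
  d <- .model_dense(model)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(schedule$seed)
  res <- anneal_sqa_cpp(model$h, d$Jm, d$Kt, schedule$n_sweeps,
                        schedule$temperature_end,
                        schedule$transverse_field_start,
                        schedule$transverse_field_end,
                        schedule$n_trotter, schedule$n_restarts)
  list(configuration = as.numeric(res$configuration), energy = res$energy,
       trace = as.numeric(res$trace))
}

#' Rank model couplings as an association list
#'
#' Orders every pairwise and third-order coupling by absolute coefficient
#' (descending); ties favor the lower order, then lexicographic index
#' tuples. This ranked list is the package's decoded "association model":
#' a large |K| with small |J| on the same features flags a strictly
#' higher-order dependence.
#'
#' @param model an [ising_model()].
#' @param top_q number of top interactions to return (default: all).
#' @return data.frame with columns `order`, `features`, `indices`,
#'   `coefficient`, `sign`, `rank`.
#' @export
model_to_associations <- function(model, top_q = NULL) {
  stopifnot(inherits(model, "ising_model"))
  nm <- model$feature_names
  if (is.null(nm)) nm <- paste0("s", seq_len(model$m))
  rows <- list()
  if (nrow(model$J)) {
    rows[[1]] <- data.frame(
      order = 2L,
      features = paste(nm[model$J$i], nm[model$J$j], sep = ":"),
      indices = paste(model$J$i, model$J$j, sep = ","),
      coefficient = model$J$value)
  }
  if (nrow(model$K)) {
    rows[[2]] <- data.frame(
      order = 3L,
      features = paste(nm[model$K$i], nm[model$K$j], nm[model$K$k], sep = ":"),
      indices = paste(model$K$i, model$K$j, model$K$k, sep = ","),
      coefficient = model$K$value)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(order = integer(0), features = character(0),
                      indices = character(0), coefficient = numeric(0))
  ord <- order(-abs(out$coefficient), out$order, out$indices)
  out <- out[ord, , drop = FALSE]
  out$sign <- ifelse(out$coefficient >= 0, "+", "-")
  out$rank <- seq_len(nrow(out))
  if (!is.null(top_q)) {
    stopifnot(top_q >= 1L)
    out <- head(out, top_q)
  }
  rownames(out) <- NULL
  out
}

#' Serialize an Ising model to JSON
#'
#' @param model an [ising_model()].
#' @param path file to write; if `NULL` the JSON string is returned.
#' @return The path (invisibly) or a JSON string.
#' @export
ising_to_json <- function(model, path = NULL) {
  obj <- list(m = model$m, h = model$h,
              J = model$J, K = model$K,
              feature_names = model$feature_names)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "columns")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read an Ising model from JSON
#'
#' @param path file written by [ising_to_json()].
#' @return An [ising_model()].
#' @export
ising_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  tolist <- function(x) if (length(x) == 0 || length(x$value) == 0) NULL
                        else as.data.frame(x)
  nms <- obj$feature_names
  if (length(nms) == 0) nms <- NULL
  ising_model(obj$m, h = obj$h, J = tolist(obj$J), K = tolist(obj$K),
              feature_names = nms)
}
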