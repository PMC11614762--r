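# Grover amplitude amplification over the combination space of feature
# patterns, simulated exactly on the statevector. The oracle is a diagonal
# phase flip on the marked basis strings and the diffusion operator is the
# reflection 2|s><s| - I about the uniform superposition.

#' Grover iteration count for a multi-target search
#'
#' \eqn{k = \lfloor (\pi/4)\sqrt{N/M} \rfloor} for a search space of size
#' `N` containing `M` target states. The floor is taken as printed — not
#' rounded — even where rounding would give a slightly higher success
#' probability.
#'
#' @param N search-space size, a power of 2.
#' @param M number of target states, `1 <= M <= N`.
#' @return Integer iteration count.
#' @examples
#' grover_iterations(4, 1)   # 1
#' grover_iterations(16, 1)  # 3
#' @export
grover_iterations <- function(N, M) {
  N <- as.numeric(N); M <- as.numeric(M)
  if (N < 1 || bitwAnd(as.integer(N), as.integer(N) - 1L) != 0L)
    stop("N must be a power of 2")
  if (M < 1) stop("M = 0: no target states to search for")
  if (M > N) stop("M cannot exceed N")
  as.integer(floor(pi / 4 * sqrt(N / M)))
}

#' Closed-form success probability of Grover search
#'
#' After `k` Grover rounds the probability mass on the `M` marked states is
#' \eqn{\sin^2((2k+1)\arcsin\sqrt{M/N})}. This closed form is the exact
#' reference the simulated search is checked against.
#'
#' @inheritParams grover_iterations
#' @param k number of Grover rounds, `>= 0`.
#' @return Probability in `[0, 1]`.
#' @export
grover_success_probability <- function(N, M, k) {
  N <- as.numeric(N); M <- as.numeric(M)
  if (N < 1 || bitwAnd(as.integer(N), as.integer(N) - 1L) != 0L)
    stop("N must be a power of 2")
  if (M < 1) stop("M = 0: no target states")
  if (M > N) stop("M cannot exceed N")
  if (k < 0) stop("k must be non-negative")
  sin((2 * k + 1) * asin(sqrt(M / N)))^2
}

#' Specification of a Grover search problem
#'
#' @param n_qubits register size; the search space has \eqn{N = 2^n} strings.
#' @param predicate function taking an n-bit basis string (character) and
#'   returning `TRUE` for target states; must be total.
#' @param k_override optional iteration count overriding the closed-form
#'   choice.
#' @return A list of class `search_spec`.
#' @export
search_spec <- function(n_qubits, predicate, k_override = NULL) {
  n_qubits <- as.integer(n_qubits)
  stopifnot(n_qubits >= 1L, n_qubits <= QUANTMINE_N_MAX,
            is.function(predicate))
  if (!is.null(k_override)) k_override <- as.integer(k_override)
  structure(list(n_qubits = n_qubits, predicate = predicate,
                 k_override = k_override),
            class = "search_spec")
}

#' Simulated Grover search
#'
#' Initializes the uniform superposition and applies `k` rounds of phase
#' oracle plus diffusion, with `k` from [grover_iterations()] unless
#' overridden. The final measurement distribution is reported exactly (no
#' sampling); the marked strings share the amplified mass equally.
#'
#' @param spec a [search_spec()].
#' @return A list with `state` (final [quantum_state()]), `distribution`
#'   (named probabilities), `k`, `marked` (character vector of marked
#'   strings) and `marked_mass`.
#' @export
grover_search <- function(spec) {
  stopifnot(inherits(spec, "search_spec"))
  n <- spec$n_qubits
  N <- 2L^n
  strings <- basis_strings(n)
  marked <- which(vapply(strings, spec$predicate, logical(1)))
  M <- length(marked)
  if (M == 0L)
    stop(structure(class = c("quantmine_no_targets", "error", "condition"),
                   list(message = "predicate marks no basis string",
                        call = sys.call(-1))))
  k <- if (!is.null(spec$k_override)) spec$k_override
       else grover_iterations(N, M)
  amp <- rep(1 / sqrt(N), N)
  for (round in seq_len(k)) {
    amp[marked] <- -amp[marked]          # phase oracle
    amp <- 2 * mean(amp) - amp           # diffusion: 2|s><s| - I
  }
  st <- quantum_state(amp)
  dist <- measure_probabilities(st)
  list(state = st, distribution = dist, k = k,
       marked = strings[marked], marked_mass = sum(dist[marked]))
}

#' Sample measurement outcomes from a Grover result
#'
#' Seeded multinomial sampling from the exact final distribution, for
#' demonstration; analyses should use the exact distribution.
#'
#' @param result list from [grover_search()].
#' @param n_shots number of measurement shots.
#' @param seed integer seed.
#' @return Named integer vector of outcome counts.
#' @export
grover_sample <- function(result, n_shots = 1024L, seed = 1L) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  draws <- sample(names(result$distribution), n_shots, replace = TRUE,
                  prob = result$distribution)
  table(factor(draws, levels = names(result$distribution)))
}

#' Mine amplified feature combinations from a table
#'
#' Builds a Grover oracle from a pattern rule evaluated on the empirical
#' statistics of the selected gene, symptom and disease features, runs the
#' simulated search, and decodes the marked basis strings back into named
#' feature patterns. The marked set is identical to a classical exhaustive
#' scan — amplification changes the measurement probabilities, never the
#' membership.
#'
#' @param table a [feature_table()].
#' @param genes,symptoms,diseases character vectors of feature names; their
#'   concatenation (genes first, most significant) defines the register.
#' @param min_support minimum empirical frequency for a full pattern to be
#'   marked (default 0.1). Ignored when `pattern_rule` is given.
#' @param pattern_rule optional predicate `function(pattern_bits, frequency)`
#'   returning `TRUE` for patterns to mark; `pattern_bits` is a named 0/1
#'   vector over the selected features.
#' @return A data.frame of class `mining_result`: one row per marked
#'   pattern with the decoded feature values, final probability and
#'   empirical support count, sorted by probability (descending) then basis
#'   string. Attributes `k` and `marked_mass` carry the search summary. If
#'   nothing is marked, a zero-row result is returned (no error).
#' @export
mine_combinations <- function(table, genes, symptoms, diseases,
                              min_support = 0.1, pattern_rule = NULL) {
  stopifnot(inherits(table, "feature_table"))
  features <- c(as.character(genes), as.character(symptoms),
                as.character(diseases))
  n <- length(features)
  if (n < 1L) stop("no features selected")
  if (n > QUANTMINE_N_MAX)
    stop(n, " features exceed the register cap of ", QUANTMINE_N_MAX)
  missing <- setdiff(features, table$feature_names)
  if (length(missing))
    stop("unknown feature name(s): ", paste(missing, collapse = ", "))
  m <- table$records[, features, drop = FALSE]
  weights <- 2^((n - 1L):0L)
  idx <- as.vector(m %*% weights) + 1L
  counts <- tabulate(idx, nbins = 2L^n)
  freqs <- counts / nrow(m)
  strings <- basis_strings(n)
  bits_of <- function(s) {
    b <- as.integer(strsplit(s, "")[[1]])
    names(b) <- features
    b
  }
  if (is.null(pattern_rule))
    pattern_rule <- function(pattern_bits, frequency) frequency >= min_support
  mask <- vapply(seq_along(strings), function(i)
    isTRUE(pattern_rule(bits_of(strings[i]), freqs[i])), logical(1))
  empty <- structure(
    data.frame(pattern = character(0), probability = numeric(0),
               support = integer(0)),
    class = c("mining_result", "data.frame"), k = 0L, marked_mass = 0)
  if (!any(mask)) return(empty)
  pred <- function(s) mask[match(s, strings)]
  res <- grover_search(search_spec(n, pred))
  rows <- which(mask)
  out <- data.frame(pattern = strings[rows],
                    probability = unname(res$distribution[rows]),
                    support = counts[rows],
                    stringsAsFactors = FALSE)
  bits <- t(vapply(out$pattern, bits_of, integer(n)))
  colnames(bits) <- features
  out <- cbind(out, as.data.frame(bits))
  ord <- order(-out$probability, out$pattern)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("mining_result", "data.frame"),
            k = res$k, marked_mass = res$marked_mass, features = features)
}

#' Write mined combinations as TSV
#'
#' @param result a `mining_result` from [mine_combinations()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_mining_tsv <- function(result, path) {
  df <- as.data.frame(result)
  df$marked <- TRUE
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
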