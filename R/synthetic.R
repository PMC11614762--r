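# Seeded generator of binary patient-record tables with planted pairwise and
# strictly third-order dependencies. Parity (XOR) is the canonical planted
# triple: with balanced marginals every pair inside a parity triple is
# uncorrelated, so the dependence is invisible to all second-order
# statistics and only a third-order estimator can recover it.

#' Specification for the synthetic patient-table generator
#'
#' @param n_patients number of records to draw.
#' @param features data.frame with columns `name`, `role` (one of `gene`,
#'   `symptom`, `disease`, `environment`) and `marginal` (Bernoulli
#'   probability in (0, 1)).
#' @param pairwise_effects optional data.frame with columns `i`, `j`
#'   (feature names) and `strength` in `[-1, 1]`: feature `j` copies `i`
#'   (or its complement for negative strength) with probability
#'   `|strength|`, otherwise it is drawn from its own marginal.
#' @param triple_effects optional data.frame with columns `i`, `j`, `k`,
#'   `mechanism` (`"parity"` or `"and_gate"`) and `strength` in `[0, 1]`:
#'   feature `k` is set to `i XOR j` (or `i AND j`) with probability
#'   `strength`, otherwise drawn from its marginal.
#' @param noise independent bit-flip probability applied to every cell after
#'   the dependencies are imposed (default 0).
#' @param seed master integer seed. Each feature consumes its own
#'   pseudorandom substream derived from the master seed, so appending
#'   features never perturbs previously generated columns.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(n_patients, features, pairwise_effects = NULL,
                           triple_effects = NULL, noise = 0, seed = 1L) {
  features <- as.data.frame(features)
  stopifnot(all(c("name", "role", "marginal") %in% names(features)),
            n_patients >= 1L, noise >= 0, noise <= 1)
  features$name <- as.character(features$name)
  features$role <- as.character(features$role)
  if (anyDuplicated(features$name)) stop("feature names must be unique")
  if (!all(features$role %in% c("gene", "symptom", "disease", "environment")))
    stop("roles must be gene, symptom, disease or environment")
  if (any(features$marginal <= 0 | features$marginal >= 1))
    stop("marginals must lie strictly inside (0, 1)")
  check_names <- function(x) {
    bad <- setdiff(x, features$name)
    if (length(bad)) stop("effect references unknown feature(s): ",
                          paste(bad, collapse = ", "))
  }
  targets <- character(0)
  if (!is.null(pairwise_effects)) {
    pairwise_effects <- as.data.frame(pairwise_effects)
    stopifnot(all(c("i", "j", "strength") %in% names(pairwise_effects)))
    check_names(c(pairwise_effects$i, pairwise_effects$j))
    if (any(abs(pairwise_effects$strength) > 1))
      stop("pairwise strengths must lie in [-1, 1]")
    targets <- c(targets, as.character(pairwise_effects$j))
  }
  if (!is.null(triple_effects)) {
    triple_effects <- as.data.frame(triple_effects)
    stopifnot(all(c("i", "j", "k", "mechanism", "strength") %in%
                    names(triple_effects)))
    check_names(c(triple_effects$i, triple_effects$j, triple_effects$k))
    if (!all(triple_effects$mechanism %in% c("parity", "and_gate")))
      stop("mechanism must be 'parity' or 'and_gate'")
    if (any(triple_effects$strength < 0 | triple_effects$strength > 1))
      stop("triple strengths must lie in [0, 1]")
    targets <- c(targets, as.character(triple_effects$k))
  }
  if (anyDuplicated(targets))
    stop("contradictory effects: feature(s) ",
         paste(unique(targets[duplicated(targets)]), collapse = ", "),
         " targeted by more than one effect")
  structure(list(n_patients = as.integer(n_patients), features = features,
                 pairwise_effects = pairwise_effects,
                 triple_effects = triple_effects,
                 noise = noise, seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate a synthetic patient table
#'
#' Draws each base feature from its marginal, overwrites pairwise-effect
#' targets by the correlated-bit construction, overwrites triple-effect
#' targets from the configured mechanism, and finally applies independent
#' bit-flip noise. Fully reproducible from the spec's seed.
#'
#' @param spec a [generator_spec()].
#' @return A [feature_table()] with roles taken from the spec.
#' @export
generate_table <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  feats <- spec$features
  nf <- nrow(feats)
  np <- spec$n_patients
  # one substream per feature (plus one for its noise mask), derived once
  # from the master seed in feature order
  set.seed(spec$seed)
  streams <- matrix(sample.int(2147483646L, 2L * nf), nrow = nf,
                    byrow = TRUE)  # row f = feature f's (base, noise) seeds
  cols <- matrix(0L, np, nf, dimnames = list(NULL, feats$name))
  for (f in seq_len(nf)) {
    set.seed(streams[f, 1L])
    cols[, f] <- rbinom(np, 1L, feats$marginal[f])
  }
  pe <- spec$pairwise_effects
  if (!is.null(pe)) for (r in seq_len(nrow(pe))) {
    src <- cols[, pe$i[r]]
    tgt_idx <- match(pe$j[r], feats$name)
    set.seed(streams[tgt_idx, 1L] + 1L)
    copy <- runif(np) < abs(pe$strength[r])
    base <- rbinom(np, 1L, feats$marginal[tgt_idx])
    val <- if (pe$strength[r] >= 0) src else 1L - src
    cols[, tgt_idx] <- ifelse(copy, val, base)
  }
  te <- spec$triple_effects
  if (!is.null(te)) for (r in seq_len(nrow(te))) {
    a <- cols[, te$i[r]]; b <- cols[, te$j[r]]
    tgt_idx <- match(te$k[r], feats$name)
    set.seed(streams[tgt_idx, 1L] + 1L)
    fire <- runif(np) < te$strength[r]
    base <- rbinom(np, 1L, feats$marginal[tgt_idx])
    mech <- if (te$mechanism[r] == "parity") bitwXor(a, b) else a * b
    cols[, tgt_idx] <- ifelse(fire, mech, base)
  }
  if (spec$noise > 0) for (f in seq_len(nf)) {
    set.seed(streams[f, 2L])
    flip <- runif(np) < spec$noise
    cols[, f] <- ifelse(flip, 1L - cols[, f], cols[, f])
  }
  rownames(cols) <- sprintf("P%04d", seq_len(np))
  feature_table(cols, roles = setNames(feats$role, feats$name))
}

#' Ground truth of the planted dependencies
#'
#' @param spec a [generator_spec()].
#' @return data.frame with one row per planted effect: `order` (2 or 3),
#'   `features` (colon-joined names), `mechanism` and `strength`. Invariant
#'   to `n_patients` and `seed`.
#' @export
planted_truth <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  rows <- list()
  pe <- spec$pairwise_effects
  if (!is.null(pe) && nrow(pe))
    rows[[1]] <- data.frame(order = 2L,
                            features = paste(pe$i, pe$j, sep = ":"),
                            mechanism = "copy",
                            strength = pe$strength)
  te <- spec$triple_effects
  if (!is.null(te) && nrow(te))
    rows[[2]] <- data.frame(order = 3L,
                            features = paste(te$i, te$j, te$k, sep = ":"),
                            mechanism = te$mechanism,
                            strength = te$strength)
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(order = integer(0), features = character(0),
                      mechanism = character(0), strength = numeric(0))
  rownames(out) <- NULL
  out
}

#' Default demonstration scenario
#'
#' A seven-feature gene/symptom/disease panel with one planted parity triple
#' (g1, s1 -> d1, strength 0.9) and one planted pairwise link (g2 -> s2,
#' strength 0.5), balanced marginals, and 5% measurement noise. These are
#' the study conditions used throughout the package's examples and checks:
#' the parity strength models a near-deterministic logical interaction seen
#' through imperfect measurements.
#'
#' @param n_patients number of records (default 2000).
#' @param seed master seed.
#' @param noise bit-flip probability (default 0.05).
#' @return A [generator_spec()].
#' @export
demo_scenario <- function(n_patients = 2000L, seed = 1L, noise = 0.05) {
  generator_spec(
    n_patients = n_patients,
    features = data.frame(
      name = c("g1", "g2", "g3", "s1", "s2", "s3", "d1"),
      role = c("gene", "gene", "gene", "symptom", "symptom", "symptom",
               "disease"),
      marginal = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5)),
    pairwise_effects = data.frame(i = "g2", j = "s2", strength = 0.5),
    triple_effects = data.frame(i = "g1", j = "s1", k = "d1",
                                mechanism = "parity", strength = 0.9),
    noise = noise, seed = seed)
}
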