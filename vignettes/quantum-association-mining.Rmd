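---
title: "Quantum-inspired mining of higher-order associations in binary health data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum-inspired mining of higher-order associations in binary health data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantmine)
```

## The problem

Clinical and genomic cohorts are often summarized as binary
patient-by-feature tables: a gene variant present or absent, a symptom
reported or not, a diagnosis made or not. Pairwise statistics (correlations,
odds ratios, mutual information) dominate routine analysis of such tables,
but some dependencies are *strictly higher-order*: three features can be
jointly constrained while every pair among them is statistically
independent. The canonical example is a parity (XOR) relation, `d = g XOR s`
— knowing the gene alone, or the symptom alone, tells you nothing about the
disease, yet the triple is (near-)deterministic. Any screening method built
from second-order statistics is blind to such structure.

`quantmine` attacks this with a pipeline of quantum-information primitives,
simulated exactly on classical hardware for small registers:

1. **Amplitude encoding.** The empirical joint distribution of a feature
   subset is loaded into a quantum register as
   \(\alpha_x = \sqrt{\hat P(x)}\), so that Born-rule measurement
   reproduces the data distribution exactly.
2. **Entanglement discovery.** The entanglement entropy of the encoded
   two-feature state scores each gene–symptom pair; product (independent)
   distributions score 0 bits and perfectly coupled pairs score 1 bit.
3. **Grover mining.** Frequent gene–symptom–disease patterns are marked by
   an oracle and their measurement probability amplified with
   \(k = \lfloor (\pi/4)\sqrt{N/M} \rfloor\) Grover rounds.
4. **Higher-order Ising optimization.** Empirical moments are mapped to a
   third-order Ising energy
   \(E(s) = -\sum_{i<j} J_{ij}s_is_j - \sum_i h_is_i +
   \sum_{i<j<k} K_{ijk}s_is_js_k\),
   whose couplings are ranked and whose ground state is found by
   simulated (thermal) annealing or path-integral simulated quantum
   annealing.
5. **Quantum-kernel classification.** A fidelity kernel
   \(K(x,y) = |\langle\phi(x)|\phi(y)\rangle|^2\) over tensored
   single-qubit feature maps feeds a dual soft-margin SVM
   \(f(x) = \mathrm{sign}(\sum_i \alpha_i y_i K(x_i,x) + b)\)
   evaluated on a seeded 7:3 train/test split.

Everything is exact statevector simulation: there is no hardware backend,
no sampling noise unless explicitly requested, and registers are capped at
20 qubits (a 16 MB statevector), which is ample for the feature panels the
package targets.

## Conventions and numerical choices

**Bit order.** Basis index \(x\) is read as the bit string
\(x_{n-1}\ldots x_0\) with qubit 0 the least-significant bit. In
`encode_joint_distribution()` the *first* listed feature becomes the
most-significant qubit, so basis strings read left-to-right in listing
order. `tensor_states(a, b)` places `a`'s qubits in the more-significant
block. All modules share these conventions.

**Amplitude phases.** An empirical distribution fixes only \(|\alpha_x|\);
the package always takes the real non-negative root
\(\alpha_x = +\sqrt{\hat P(x)}\). This makes encoding unique and
reproducible and leaves measurement probabilities untouched. Zero-frequency
patterns get amplitude exactly 0 — no pseudocount — unless a `smoothing`
pseudocount is requested, because the encoded state is meant to *be* the
empirical distribution, not a regularized estimate of it.

**Entropies** are in bits (base-2 logs) throughout, the natural unit for
qubit systems: a Bell pair scores exactly 1. Eigenvalues are clipped at
1e-12 before logarithms; matrix logarithms go through eigendecomposition
(all inputs are Hermitian by construction). Invariant checks (norms,
Hermiticity, trace, unitarity) use a 1e-10 tolerance; oracle-equivalence
tests on tiny instances use 1e-12.

## The relative entropy of entanglement

For density-matrix inputs the association score is the relative entropy of
entanglement,
\(E_R(\rho) = \min_{\sigma \in D} S(\rho\|\sigma)\) with
\(S(\rho\|\sigma) = \mathrm{Tr}\,\rho(\log_2\rho - \log_2\sigma)\)
and \(D\) the separable set. Minimizing over all separable states is
intractable, so the package restricts \(\sigma\) to convex combinations of
product pure states,
\(\sigma = \sum_k p_k\, |a_k\rangle\langle a_k| \otimes
|b_k\rangle\langle b_k|\)
(8 terms by default, hyperspherical angles plus softmax weights), and
minimizes with multi-restart Nelder-Mead. The returned value is therefore
an *upper bound* on \(E_R\).

The first restart is not random: it is assembled from the Schmidt
components of the eigenvectors of \(\rho\), weighted by eigenvalue mass
times Schmidt weight. For a *pure* state this initial mixture is exactly
the known closest separable state, so the optimizer starts at the optimum
and the bound is tight; for mixed states it is a strong warm start. The
remaining restarts draw uniform random angles. Because of this structure, a
handful of restarts already reproduces the pure-state closed form (the
reduced-state von Neumann entropy, available independently as
`entanglement_pure()`) to well below the 5e-3 verification tolerance; the
default of 16 restarts is kept for mixed-state inputs where the landscape
is less forgiving. The test suite and the acceptance script run the
optimizer with 2 restarts and 120 simplex iterations, which keeps 50-state
verification sweeps to a few seconds without affecting the pure-state
result.

When the support of \(\rho\) leaks outside the support of \(\sigma\) the
divergence is infinite; `quantum_relative_entropy()` signals this as a
distinct condition class (`quantmine_infinite_divergence`) rather than
returning a number, while the optimizer's internal objective uses clipped
logarithms so that near-singular candidates are merely penalized.

## Grover search as implemented

The oracle is a diagonal ±1 phase flip on the marked strings and the
diffusion operator is the reflection \(2|s\rangle\langle s| - I\) about the
uniform state — the textbook construction. The iteration count uses the
floor exactly as the formula states, never rounding, even where rounding
would give a marginally higher success mass. The final state is reported as
an exact distribution; `grover_sample()` provides seeded multinomial shots
for demonstrations only. `mine_combinations()` builds the oracle from a
frequency threshold (`min_support`) on the empirical pattern distribution;
the predicate is pluggable because no canonical "disease association
pattern" criterion exists — any total predicate over patterns works. The
marked *set* always equals a classical exhaustive scan; amplification
changes only the probabilities. A rule that marks nothing returns an
explicit empty result rather than an error.

## From moments to the Ising model

No standard recipe maps empirical correlations onto higher-order Ising
coefficients, so the package uses centered moment estimators and documents
them as the (pluggable) default: bits map to spins \(\sigma = 2b-1\), then

* \(h_i = \bar\sigma_i\) (marginal tendency),
* \(J_{ij} = \widehat{\mathrm{cov}}(\sigma_i,\sigma_j)\)
  (population denominator),
* \(K_{ijk} = \widehat E[(\sigma_i-\mu_i)(\sigma_j-\mu_j)
  (\sigma_k-\mu_k)]\).

Centered cross-moments were chosen precisely because a parity dependence
drives every pairwise \(J\) on the triple to zero while \(|K|\) stays
bounded away from zero — they isolate what second-order screens miss. These
are *ranking* statistics, monotone in the underlying coupling strength, not
consistent estimators of generative couplings; the parameter-recovery test
accordingly checks rank agreement on Gibbs-sampled data, not coefficient
equality. Constant (zero-variance) features are flagged with a warning and
their couplings are 0 by the defining moments.

The energy function's sign pattern — minus on \(J\) and \(h\), plus on
\(K\) — is kept exactly as stated. Users should note the asymmetry: a
*positive* third-order coupling penalizes aligned triples. A fourth-order
tensor is accepted for forward energy evaluation (also with a plus sign),
but estimation stops at order 3.

**Annealers.** Both ground-state searchers are classical Monte-Carlo
simulations. The thermal annealer runs Metropolis single-spin-flip sweeps
with a geometric temperature decay. The simulated quantum annealer is
path-integral Monte Carlo: `n_trotter` coupled replicas with inter-replica
ferromagnetic coupling \(J_\perp = -\tfrac12 \log\tanh(\Gamma/(PT))\), the
transverse field \(\Gamma\) decaying geometrically while updates run at the
fixed base temperature. Defaults — 2000 sweeps, \(T: 2.0 \to 0.05\),
\(\Gamma: 2.5 \to 0.01\), 8 Trotter slices, 8 restarts — were chosen so
that random 12-spin instances with dense pairwise and 30 third-order
couplings are solved to the exact (brute-force) ground energy in
essentially every run; the verification criterion requires 18 of 20. Both
annealers return the best-seen configuration, so their energy can never
undercut the exhaustive minimum, and both are deterministic given the
schedule seed (the compiled cores draw from R's RNG stream). Ties in the
brute-force oracle are broken lexicographically with +1 ordered before -1.

## The quantum kernel and its SVM

The default feature map applies a Y-rotation by \(\pi x_j\) per feature and
tensors the results: binary features land on basis states, fractional
values interpolate on the Bloch sphere, and the fidelity kernel has the
closed form \(\prod_j \cos^2(\pi(x_j-y_j)/2)\) — used as the independent
oracle in tests, while the implementation computes overlaps of the actual
simulated states. A kernel written as \(\langle x|U^\dagger U|y\rangle\)
would collapse to the plain inner product because \(U^\dagger U = I\),
making the circuit irrelevant; the package therefore uses the standard
fidelity form \(|\langle 0|U^\dagger(x)U(y)|0\rangle|^2\) by default and
keeps the literal inner-product variant available as
`feature_map = "inner"` for comparison. Inputs must lie in \([0,1]\);
real-valued columns should be min-max scaled (the table reader's
median-binarization handles the fully binary pipeline case).

The dual soft-margin problem is solved by pairwise coordinate optimization
(SMO-style): the scan visits samples in index order, pairs each KKT
violator with partners in decreasing error-gap order until one admits a
non-degenerate analytic update, and stops after full passes produce no
change. All choices are deterministic, so training is exactly reproducible.
The box default is \(C = 10\) with KKT tolerance 1e-3; duplicate-invariance
checks use 1e-8 because the decision function converges at the rate of the
dual gap. The solver is validated in the test suite against an independent
QP solver (`kernlab::ksvm` on the same precomputed Gram matrix): dual
objectives agree to 1e-5 and decision values to the same order.
`sign(0)` is defined as +1.

## The synthetic generator and what it does (not) show

`generate_table()` draws each feature from its Bernoulli marginal using a
dedicated pseudorandom substream derived from the master seed (appending
features never perturbs existing columns), then overwrites effect targets:
a pairwise effect copies its source (or its complement) with probability
\(|strength|\); a triple effect sets the target to XOR or AND of its
sources with probability `strength`; independent bit-flip noise comes last.
Each feature may be the target of at most one effect — contradictory specs
are rejected.

Parity is the canonical planted triple because with balanced marginals it
is invisible to *all* second-order statistics; the spin-mapped third
central moment of an exact parity triple is \(-1\), attenuated by a factor
\((1-2\nu)^3\) under flip noise \(\nu\) and linearly by the mechanism
strength. The reference scenario used across examples and checks —
`demo_scenario()` — plants one parity triple at strength 0.9 with 5% flip
noise in a seven-feature gene/symptom/disease panel of balanced marginals:
a near-deterministic logical interaction observed through imperfect
measurement, with expected \(|K| \approx 0.9 \times 0.9^3 \approx 0.66\)
against a null scale of \(1/\sqrt{n}\). Recovery checks use 2000 patients
and demand the planted triple rank first among third-order terms in at
least 18 of 20 seeded replicates, with no pairwise coupling on the triple
exceeding \(4/\sqrt{n}\).

What passing these checks does *not* show: the generator has independent
features apart from the planted effects, no linkage structure, no
covariate-driven marginals, no missingness, and balanced classes. Real
cohort tables violate all of these; results on synthetic recovery bound
what the method can do under ideal conditions, not what it will do on a
hospital extract.

## Pipeline determinism and reporting

`run_pipeline()` executes load → entanglement → mining → Ising → classify,
any subset of which can be disabled. Stage seeds are derived from the
master seed by fixed offsets, so a report is a pure function of (input,
config, seed); two runs with the same configuration compare `identical()`.
Stage failures carry the stage name; completed sections are retained.
Reports serialize to JSON plus TSV sections, and `write_manifest()` records
md5 checksums of config and artifacts sufficient to replay a run.
Multiple-testing control is off by default — the ranked coefficients are
descriptive — but `permutation_filter()` offers a seeded permutation null
(200 permutations by default) for the top interactions.

Problem sizes in the shipped checks — 4-qubit registers for exhaustive
quantum-identity sweeps, all of \(n \le 8\) for Grover, 12 spins for
annealer-versus-oracle, 2000 x 7 tables for recovery — were chosen as the
smallest instances that still exercise every code path meaningfully
(exhaustive enumeration stays exact, concentration bounds stay sharp).

## Known limitations

* Registers are capped at 20 qubits; there is no sparse or mixed-state
  encoding backend, and no noise/decoherence model.
* The variational \(E_R\) is an upper bound; certified values would need an
  SDP formulation, which is out of scope, as are negativity, concurrence
  and multipartite measures.
* Moment-based Ising estimation is a screening device, not inference;
  pseudo-likelihood or regularized inverse-Ising methods are deliberate
  future work.
* \(M\) (the marked-state count) is computed classically; there is no
  quantum counting, and no fixed-point amplitude amplification.
* The SVM is binary only; one-vs-rest composition is left to the caller.
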