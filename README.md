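# quantmine

Quantum-inspired mining of higher-order associations in binary health data.

`quantmine` is for analysts of patient-by-feature 0/1 tables — gene variants,
symptoms, diagnoses — who need to find dependencies that pairwise statistics
cannot see. Its core observation is that a strictly third-order relation
such as parity (`disease = gene XOR symptom`, with balanced marginals) leaves
every correlation coefficient at zero while remaining near-deterministic.
The package detects such structure with a pipeline of quantum-information
primitives, all simulated exactly on classical hardware for registers of up
to 20 qubits:

- **Amplitude encoding** of the empirical joint distribution,
  `α_x = √P̂(x)`, so measurement probabilities `P(x) = |α_x|²` reproduce the
  data exactly.
- **Entanglement scores**: the von Neumann entropy
  `S(ρ_A) = −Tr(ρ_A log₂ ρ_A)` of the reduced encoded state scores each
  gene–symptom pair (0 bits = independent, 1 bit = perfectly coupled), with
  a variational relative-entropy-of-entanglement
  `E_R(ρ) = min_{σ∈D} S(ρ‖σ)` for density-matrix inputs.
- **Grover amplitude amplification** over the pattern space, with the
  multi-target iteration count `k = ⌊(π/4)√(N/M)⌋`.
- A **higher-order Ising model**
  `E(s) = −Σ_{i<j} J_ij s_i s_j − Σ_i h_i s_i + Σ_{i<j<k} K_ijk s_i s_j s_k`
  estimated from centered spin moments and optimized by simulated annealing
  or path-integral simulated quantum annealing (compiled Monte-Carlo cores,
  fully seeded), with an exact brute-force oracle for validation.
- A **quantum fidelity-kernel SVM**,
  `K(x,y) = |⟨φ(x)|φ(y)⟩|²` over tensored Y-rotation feature maps with the
  dual decision function `f(x) = sign(Σ_i α_i y_i K(x_i,x) + b)`, evaluated
  on a seeded 7:3 train/test split.

A seeded synthetic-data generator with planted pairwise and strictly
third-order (parity / AND) dependencies makes every stage testable without
external data.

## Worked example

```r
library(quantmine)

spec <- demo_scenario(n_patients = 2000, seed = 42)  # plants d1 = g1 XOR s1
tab  <- generate_table(spec)
cfg  <- pipeline_config(input = tab, seed = 42, min_support = 0.02)
rep  <- run_pipeline(cfg)
print(rep)
```

```
<association_report>
  entanglement edges: 9 
  mined combinations: 11 
  top interactions:
    1. [order 3] g1:s1:d1  coef -0.6397
    2. [order 2] g2:s2  coef 0.4370
    3. [order 2] s1:d1  coef -0.0551
  classifier: accuracy 0.832 (train 0.817) on 600 test records
```

Reading the output: the planted parity triple `g1:s1:d1` is the top-ranked
interaction and it is *third-order* — its coefficient is the centered triple
moment of the spin-mapped features (≈ −0.9·(1−2·0.05)³ under the scenario's
strength 0.9 and 5% flip noise), while every pairwise coefficient among
`g1`, `s1`, `d1` stays at noise level (the next order-2 term after the
planted `g2:s2` copy link is only −0.055). The entanglement stage tells the
same story from the quantum side:

```r
head(rep$entanglement, 3)
```

```
  feature_a feature_b       score
5        g2        s2 0.287593334
6        g3        s2 0.003215532
2        g2        s1 0.003082642
```

The pairwise-coupled `g2:s2` carries ~0.29 bits of entanglement in the
encoded joint state; all parity-involved pairs sit at the floor — exactly
the "invisible to second order" signature. The classifier block reports
held-out accuracy of the quantum-kernel SVM predicting `d1` from the other
features on the 1400/600 split.

Individual stages are exported (`encode_joint_distribution`,
`entanglement_matrix`, `mine_combinations`, `estimate_ising`,
`simulated_quantum_annealing`, `train_qsvm`, ...) and a thin CLI wraps them:

```sh
exec/quantmine simulate --out demo --patients 500 --seed 4
exec/quantmine anneal --input demo/table.csv --roles demo/roles.json --seed 4
```

See the vignette (`vignettes/quantum-association-mining.Rmd`) for the
models, conventions, parameter defaults and limitations.

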