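# gbsgraph

Exact, desk-scale simulation of **Gaussian boson sampling (GBS) applied to
graph problems**, for researchers who want to study — classically and
reproducibly — how a programmable squeezed-light sampler solves maximum
weighted clique problems, and how molecular docking and RNA secondary
structure prediction map onto them.

A GBS device prepares squeezed vacua with parameters *r&#8321;…r&#8344;*,
interferes them in a unitary *U*, and detects photons. For a pure state the
probability of a detection pattern *s* is

> Pr(*s*) = |Haf(*B<sub>s</sub>*)|² / (*n*₁!…*n*<sub>N</sub>! √det(σ + 𝕀/2)),  *B* = *U* diag(tanh *r<sub>i</sub>*) *U*ᵀ

where Haf is the matrix hafnian (the perfect-matching sum). A
vertex-weighted graph is programmed onto the device through its rescaled
weighted Laplacian *A′* = Ω(*D* − *A*)Ω with Ω = diag(*c*(1 + α ω<sub>i</sub>)),
Takagi-decomposed as *A′* = *U* diag(λ) *U*ᵀ with λ<sub>i</sub> = tanh
*r<sub>i</sub>* ∈ [0, 1). Collision-free patterns then arrive with
probability ∝ det(Ω<sub>s</sub>)² Haf(*A<sub>s</sub>*)² — dense, heavy
subgraphs light up first — and greedy-shrink / local-search postprocessing
turns samples into cliques. Two front-ends reduce drug-discovery questions
to this machinery:

* **docking** — binding interaction graphs (BIGs): vertices are
  protein–ligand pharmacophore contacts weighted by interaction potential,
  edges join geometrically compatible contacts (|D<sub>L</sub> −
  D<sub>P</sub>| ≤ τ + 2ε); the maximum weighted clique is the predicted
  binding pose.
* **RNA folding** — weighted full stem graphs (WFSGs): vertices are
  candidate stems weighted by length, edges mark co-existence; the maximum
  weighted clique is the predicted secondary structure, scored by the
  Matthews correlation coefficient (MCC).

Everything is exact and seeded: hafnians by matching enumeration, Takagi by
the real symmetric embedding, sampling by inverse CDF over the enumerated
collision-free subspace, cliques by branch-and-bound. Synthetic fixture
generators (planted-clique graphs, rigid pharmacophore complexes, designed
RNA sequences, Haar unitaries) make the whole pipeline testable offline.

## Worked example

Plant a heavy 6-clique in a random 16-vertex graph, program it onto the
simulated sampler, and compare GBS sampling with uniform sampling under
identical postprocessing:

```r
library(gbsgraph)

fx <- planted_clique_graph(N = 16, k_planted = 6, edge_p = 0.4,
                           weight_boost = 2, seed = 7)
G <- fx$graph
fx$planted
#> [1]  1  2  8  9 10 11

circ <- encode_graph(G, scaling_for_weight_gain(G, alpha = 1))
circ
#> Encoded GBS circuit: 16 modes; r_max = 1.8 ; mean photons = 12.52383

dist <- exact_distribution(circ, k_max = 6)
cond <- condition_on_photons(dist, 6)          # six-photon events only
batch <- gbs_sample(circ, 200, seed = 42, dist = cond)
stats <- run_clique_pipeline(G, batch, n_post = 30, seed = 43)
stats
#> Clique statistics over 200 postprocessed samples ( 1 replicate(s) )
#>   max weighted clique: { 1, 2, 8, 9, 10, 11 } weight 9.855061
#>   success probability: 0.805

base <- run_clique_pipeline(G, uniform_baseline(G, c(`6` = 1), 200, seed = 44),
                            n_post = 30, seed = 45)
base$success_probability
#> [1] 0.545
```

The sampler returns the planted maximum weighted clique (weight 9.86) for
80.5% of postprocessed samples versus 54.5% for uniform subsets of the same
size — the weighted encoding is doing the work. `head(stats$table)` lists
every clique found with its weight, size and empirical probability.

The docking and RNA front-ends follow the same pattern
(`build_big()` → graph → clique → `clique_to_pose()`;
`build_wfsg()` → graph → clique → `clique_to_structure()` → `mcc()`), and a
thin command-line launcher (`inst/scripts/gbsgraph.R`) exposes
`encode / sample / cliques / dock / rnafold / fixtures` subcommands.

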