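# phyloerr

Maximum likelihood phylogeny inference that accounts for sequencing error.

Base-calling errors masquerade as singleton polymorphisms. When a
phylogeny is inferred by maximum likelihood under the usual assumption of
error-free data, those miscalls are absorbed into the branch lengths —
inflating them, and at high error rates degrading the topology too.
`phyloerr` implements the classical correction: a declared per-base
miscall rate ε enters the tip likelihoods, so that for an observed base
the conditional vector stored at the tip becomes

    Pr(obs | true base x) = 1 − ε           if x is the observed base
                            ε / 3           otherwise

and, for an IUPAC ambiguity code with resolution set S of size k,

    Pr(obs | x) = 1 − ε + (k − 1) ε / 3     if x ∈ S
                  k ε / 3                   if x ∉ S

(`N`, `-`, `?` give `(1,1,1,1)` at any ε). The pruning algorithm then
proceeds unchanged under the Kimura 2-parameter model (ts/tv ratio R,
default 2; branch lengths in expected substitutions/site), with branch
lengths — or node heights, under a molecular clock — optimized by bounded
1-D search and topology found by seeded stepwise addition plus
nearest-neighbor interchanges.

The package is aimed at anyone who wants to (a) infer trees from data
with a known, appreciable error rate — global or per sequence — or
(b) study how declared-vs-true error mismatches distort inference, using
the included simulation laboratory: clocklike branching-process trees,
K2P sequence evolution, seeded miscall injection, Robinson–Foulds
topology (RF) and branch-length (RFL) metrics, and a replication harness.

## A worked example

Simulate a 10-taxon clocklike tree, evolve 2,000 sites, inject 1%
miscalls, then infer with and without declaring the error:

```r
library(phyloerr)

tree <- simulate_yule_tree(n_taxa = 10, t = 1e-3, seed = 101)
aln  <- evolve_alignment(tree, k2p_model(2), seq_length = 2000, seed = 102)
obs  <- inject_errors(aln, 0.01, seed = 103)

naive     <- infer_tree(obs, inference_config(declared_error = 0,    seed = 104))
corrected <- infer_tree(obs, inference_config(declared_error = 0.01, seed = 104))

c(rfl_naive     = rfl_distance(naive$tree, tree),
  rfl_corrected = rfl_distance(corrected$tree, tree))
#>     rfl_naive rfl_corrected
#>   0.102829494   0.009297725
c(len_ratio_naive     = total_length(naive$tree)     / total_length(tree),
  len_ratio_corrected = total_length(corrected$tree) / total_length(tree))
#>     len_ratio_naive len_ratio_corrected
#>           14.419594            1.087988
```

Uncorrected, the miscalls inflate the total tree length ~14-fold;
declaring the true ε brings the branch-length error (RFL, the sum of
absolute branch-length differences over matched splits) down by an order
of magnitude and the length ratio to ≈ 1.

The same machinery is scriptable from a shell:

```sh
phyloerr simulate --n-taxa 20 --t 1e-3 --length 20000 --error 1e-2 \
                  --replicates 100 --seed 1 --out-dir sims/
phyloerr infer    --alignment sims/alignment_001.phy --error-rate 1e-2 \
                  --seed 1 --out tree.nwk
phyloerr treedist sims/true_tree_001.nwk tree.nwk
phyloerr replicate --config condition.json --out results.csv
```

Every run writes a JSON manifest beside its outputs;
`run_from_manifest()` replays it bit-for-bit.

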