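# rootphylo

Maximum-likelihood rooting of phylogenetic trees **without an outgroup**,
using nonreversible substitution models, with honest statistics about how
much the data actually know about the root.

Under a time-reversible model the likelihood of a tree is the same wherever
the root is placed, so the root must be imposed from outside — usually with
an outgroup, which is not always available and whose long branch is a
classic source of artifacts. The fully general (unrestricted) nonreversible
DNA model gives each of the 12 off-diagonal entries of the rate matrix Q
its own parameter; detailed balance π<sub>i</sub>Q<sub>ij</sub> =
π<sub>j</sub>Q<sub>ji</sub> no longer holds, the likelihood depends on the
root position, and the root becomes an estimable parameter of the model.

`rootphylo` is for molecular phylogeneticists who have a topology (typically
from a reversible, partitioned analysis) and want to know where its root is
and how much to trust that placement. It provides:

- **`ml_root_search()`** — tries every branch of the unrooted topology as
  the root branch, optimizing the root's position along each branch and
  refitting the model per branch (warm-started); branch lengths are
  otherwise held fixed.
- **`bootstrap_root_analysis()` / `rootstrap_support()`** — *rootstrap*
  support: the proportion of nonparametric bootstrap replicates (alignment
  columns resampled with replacement) whose root falls on each branch of
  the ML tree. Replicates rooted on a branch absent from the ML tree are
  reported as unplaced mass, so supports sum to at most 1.
- **`rsed()` / `rbed()`** — root error metrics against a known or assumed
  true root branch: the number of splits between the ML root branch and the
  true one, and the [min, max] branch-length distance from the inferred
  root point to that branch.
- **`au_confidence_set()`** — the approximately unbiased (AU) confidence
  set of root branches, computed by multiscale RELL bootstrap of per-site
  log-likelihoods (`site_ll_for_all_roots()`); always contains the ML
  placement.
- **`delta_sls()` / `delta_gls()`** — site- and locus-wise log-likelihood
  differences between two competing rootings, for finding loci that
  dominate the root signal.
- **`bowker_test()` / `maxsym_filter()`** — matched-pairs symmetry tests
  to flag loci that violate the stationarity/homogeneity assumptions the
  nonreversible model still makes.
- **`generate_scenario()`** — synthetic rooted trees, nonreversible
  models, and partitioned alignments with a recorded truth, so every stage
  is testable end to end.

The likelihood engine (Felsenstein pruning over compressed site patterns,
with rescaling, in C++/Armadillo) is generic over the state-space size K;
DNA (K = 4, 12 free rates) is the primary use.

## A worked example

Simulate a decisive scenario (6 taxa, strongly nonreversible model, 4,000
sites in 8 loci), then infer and interrogate the root:

```r
library(rootphylo)

cfg <- scenario_config(n_taxa = 6, n_loci = 8, locus_length = 500, seed = 42)
sc  <- generate_scenario(cfg)
sc$truth$root_bipartition
#> [1] "t1,t3,t4,t5,t6|t2"

res <- ml_root_search(sc$tree, sc$aln)
res
#> ML root placement search over 9 branches
#>   best branch: t1,t3,t4,t5,t6|t2
#>   split fraction: 0.0980   log-likelihood: -16978.7737

boot <- bootstrap_root_analysis(sc$tree, sc$aln, B = 100, seed = 42)
boot$rootstrap
#> Rootstrap support over 100 bootstrap replicates
#>    96.0%  t1,t3,t4,t5,t6|t2 (ML root branch)
#>     3.0%  t1,t3,t4|t2,t5,t6
#>     1.0%  t1,t2,t3,t4,t6|t5

rsed(res$rooted_tree, sc$truth$root_bipartition)
#> [1] 0
rbed(res$rooted_tree, sc$truth$root_bipartition)
#>       min       max
#> 0.0000000 0.2428426
```

The search found the generating root branch (the tip branch of `t2`), 96%
of bootstrap replicates root there too, the split error distance to the
true branch is 0, and the inferred root point lies on the true branch
(rBED minimum 0; the maximum is the distance to the branch's farther end).

The AU test asks which alternative placements the sites can actually
reject in favor of the ML root:

```r
sllm <- site_ll_for_all_roots(sc$tree, sc$aln, res$model)
au_confidence_set(sllm, alpha = 0.05, seed = 42)
#> AU test over 9 candidate root placements (alpha = 0.05 )
#>   p = 0.9140  t1,t3,t4,t5,t6|t2 ML *
#>   p = 0.1936  t1,t3,t4,t5|t2,t6 *
#>   p = 0.1566  t1,t3,t4|t2,t5,t6 *
#>   p = 0.1283  t1,t2,t3,t4,t6|t5 *
#>   p = 0.0273  t1,t2,t3,t4,t5|t6
#>   p = 0.0000  t1,t2,t3,t5,t6|t4
#>   p = 0.0000  t1,t2,t4,t5,t6|t3
#>   p = 0.0000  t1,t3|t2,t4,t5,t6
#>   p = 0.0000  t1|t2,t3,t4,t5,t6
#> confidence set: 4 placement(s)
```

Four placements survive at α = 0.05 — the data decisively reject five
rootings but cannot distinguish placements adjacent to the ML root, which
is exactly the nuance a single point estimate hides.

A thin command-line front end over the same functions ships in
`inst/cli/rootphylo.R`:

```sh
Rscript inst/cli/rootphylo.R root --tree unrooted.nwk --aln aln.fasta \
    --boot 1000 --seed 42 --out myclade
Rscript inst/cli/rootphylo.R symtest --aln aln.fasta --partitions loci.txt
```

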