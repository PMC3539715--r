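# netpaleo

Evolutionary dating and selection analysis of protein–protein interaction
(PPI) networks from ortholog presence/absence and branch-wise selective
constraint, across a fixed eight-mammal phylogeny (human, chimpanzee,
macaque, mouse, rat, horse, dog, cow).

Interaction catalogs effectively exist for one species at a time, so the
history of an interactome has to be inferred indirectly. netpaleo
implements an integrated analysis of that problem for a human PPI network:

* **Constrained-parsimony dating** — each gene appears exactly once on the
  tree and can only be lost afterwards, so its *latest possible* origin is
  the branch ancestral to the MRCA of the species carrying its ortholog;
  a pair's origin is the younger of its members'. A census over the five
  origin-eligible branches (root, euarchontoglires stem, primate stem,
  human–chimp stem, human terminal) gives the fraction of present-day
  interactions already present at each ancestral node.
* **Ks-calibrated gain/loss rates** — events per exposed pair per unit
  synonymous divergence (Ks), with loss estimated on the two stems that
  contain no human ancestors (mouse–rat, horse–dog) and a steady-state
  correction that discounts the root-presence fraction by the gains a
  loss-derived rate implies.
* **Mirrortree co-evolution** — Spearman correlation of paired branch-wise
  ω = Ka/Ks vectors for interacting proteins (ω < 5 filter, ≥ 6 shared
  branches), with the mean ρ tested against degree-proportional
  pseudo-pair nulls and a clade-removal sensitivity scan.
* **Shared directional selection** — per-branch χ² test of whether both
  members of a pair exceed an ω threshold more often than their marginal
  exceedance frequencies predict.
* **Network weights** — the mean edge weight w = mean |ω_n − ω_m| (or
  |k_n − k_m|) tested against node-weight permutations and
  degree-preserving rewirings: do proteins interact with partners of
  similar selective constraint, or similar degree?
* **Gene-set enrichment** — hypergeometric over/under-representation with
  Bonferroni correction for the primate-specific (PrimPresI, PrimUniqI)
  and shared-selection (AdaptI) gene sets.
* **A synthetic-data generator** that emulates every input file with
  planted, recoverable parameters (origin probabilities, per-Ks loss rate
  λ, target pairwise Spearman ρ*, constraint assortativity strength), so
  the whole pipeline is testable end to end without proprietary data.

All empirical p-values use p = (r + 1)/(n + 1); every null replicate is
seeded deterministically (`seed + i`).

## Worked example

```r
library(netpaleo)

d <- "study"
make_study_fixture(np_sim_config(seed = 7), d)   # writes all input files

net  <- read_network(file.path(d, "network.tsv"))
pres <- read_presence_matrix(file.path(d, "presence.tsv"))
phy  <- read_phylogeny(file.path(d, "tree.nwk"),
                       file.path(d, "branch_roles.tsv"))

origin_census(net, pres, phy)
#> Origin census of 1500 interactions
#>   root                 1352 new  ( 90.1% present at node)
#>   euarchontoglires      135 new  ( 99.1% present at node)
#>   primates                2 new  ( 99.3% present at node)
#>   human-chimp             9 new  ( 99.9% present at node)
#>   human                   2 new  (100.0% present at node)
```

Ninety percent of the simulated interactions date to the basal split —
the generator's default conditions describe a mostly ancient network.
Rates and the steady-state correction:

```r
cen <- origin_census(net, pres, phy)
loss_rate("mouse-rat", net, pres, phy)
#> loss rate on mouse-rat: 169 events / 1487 exposed / Ks 0.1800 = 0.6314 per PPI per unit Ks
gain_rate("primates", cen, phy)
#> gain rate on primates: 2 events / 1489 exposed / Ks 0.0500 = 0.02686 per PPI per unit Ks
steady_state_correction(loss_rate("mouse-rat", net, pres, phy), cen, phy)
#> Steady-state correction (g = 0.6314): raw root fraction 90.1% -> corrected 67.2%
```

Reading: if the true gain rate matched the mouse–rat loss rate, about a
quarter of the pairs called ancient would actually be post-root gains
invisible to ortholog dating, so 90.1% is an upper bound and 67.2% the
corrected estimate. Co-evolution and constraint assortativity:

```r
bo <- read_branch_omega(file.path(d, "branch_omega.tsv"))
mean_rho_test(net, bo, n_null = 1000, cutoff = 5, seed = 7)
#> Mirrortree co-evolution: 1064 eligible pairs (436 excluded)
#>   mean rho 0.0413 vs null mean-of-means 0.0005 (difference +0.0408)
#>   empirical P <0.000999 (1000 pseudo-pair sets)

go <- read_gene_omega(file.path(d, "gene_omega.tsv"))
constraint_assortativity_test(net, go, n_perm = 10000, seed = 7)
#> Network weight test (omega-difference)
#>   observed w = 0.4003 vs null mean 0.7842 (n = 10000)
#>   empirical P <0.0001 (less)
```

Interacting pairs co-evolve (mean ρ above every pseudo-pair mean) and
interacting proteins are under more similar constraint than a random
assignment of the same ω values — both planted by the generator and
recovered by the tests.

The entire pipeline, with TSV reports and a JSON run manifest:

```r
run_all(np_run_config(seed = 7), "reports")
```

or from a shell: `exec/netpaleo run-all --seed 7 --out reports`.

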