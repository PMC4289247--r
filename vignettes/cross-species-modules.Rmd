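---
title: "Cross-species module detection with crossclust: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species module detection with crossclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossclust)
```

## The problem

Co-expression clustering is usually run one species at a time, and the
resulting modules are matched across species only afterwards, through the
orthologs they happen to share. `crossclust` instead clusters several
species *jointly*: each species contributes a co-association network layer,
orthologous genes are linked across layers, and a single optimization
assigns every gene of every species to a module. Modules that recruit genes
from several species through their orthology links are *conserved*; modules
confined to one species are *species-specific*.

## The model

Every gene (node) $i$ carries a label $\sigma_i \in \{1, \dots, q\}$. A
configuration is scored by the Potts-type cost

$$
H(\sigma) \;=\; -\Biggl[\;
\sum_{\ell \in \text{layers}} \sum_{i,j \in S_\ell}
  \Bigl(A^{(\ell)}_{ij} - \lambda \tfrac{k_i k_j}{2m_\ell}\Bigr)\,
  \delta(\sigma_i, \sigma_j)
\;+\; \kappa \sum_{(i,j) \in O} w_{ij}\, \delta(\sigma_i, \sigma_j)
\;+\; \kappa_t \sum_{(i,j,k) \in T} \delta(\sigma_i,\sigma_j,\sigma_k)
\Biggr]
$$

where $A^{(\ell)}$ is layer $\ell$'s adjacency matrix, $k_i$ its degrees,
$m_\ell$ its edge count, $O$ the set of orthologous pairs with weights
$w_{ij}$, and $T$ the optional set of 1-1-1 ortholog triplets (three
species, pairwise one-to-one). The intra-layer part is the familiar
modularity kernel $\Lambda_{ij} = A_{ij} - \lambda k_i k_j / 2m$: pairs
connected more often than a degree-preserving random graph would predict
are rewarded for sharing a label. The coupling term rewards co-labeling
orthologs; $\kappa$ sets the relative importance of orthology against
co-association. Minimizing $H$ — finding the Potts ground state — yields
the joint module assignment.

With expression-derived networks the package can separate positive from
negative correlations (`signed = TRUE`): each sign class is scored with its
own degrees and edge count and the negative class enters with opposite
sign, so co-labeling two anti-correlated genes is penalized. On our
synthetic data signed and unsigned scoring give the same modules; the
option exists because signed networks have a more frustrated energy
landscape and deserve separate scrutiny.

### Ortholog weights

Many orthologs are many-to-many and form bipartite cliques between layers.
Treating every pair equally lets an $s \times s$ clique contribute $s^2$
links, which can out-vote genuine one-to-one evidence and glue unrelated
conserved structures together (the failure mode the `"uniform"` scheme
reproduces). The default weight is therefore the symmetric mean of
reciprocal ortholog counts,

$$ w_{ij} = \tfrac12\Bigl(\tfrac1{a} + \tfrac1{b}\Bigr), $$

where $a$ is the number of orthologs of $i$ in $j$'s species and $b$ the
number of orthologs of $j$ in $i$'s species. One-to-one pairs keep weight
exactly 1; a clique member's total outgoing weight stays bounded near 1
regardless of clique size. `1/(a b)` and `1/sqrt(a b)` are available as
`scheme = "recip_product"` / `"recip_geom"` for sensitivity analysis. The
exact functional form is a design choice of this package, constrained by
two requirements: per-endpoint normalization by ortholog counts, and no
penalty for one-to-one pairs.

### Scaling of the terms

The package evaluates $H$ with raw sums by default
(`normalize_layers = FALSE`). This keeps each intra-layer link and each
orthology link an $O(1)$ contribution, so $\kappa$ of order 1–3 balances
the two kinds of evidence gene by gene; $\kappa = 3$ is the shipped
default. The alternative (`normalize_layers = TRUE`) divides each layer's
term by its own $2m_\ell$ and — to keep the terms commensurate
(`normalize_orthology`, which defaults to `normalize_layers`) — each
orthology map's term by its total weight and the triplet term by the
triplet count. Mixed scaling (normalized layers, raw coupling) is
deliberately not a default anywhere: it puts the coupling four orders of
magnitude above the per-edge modularity scale, and the annealer then
freezes ortholog pairs onto random common labels long before the layer
structure can order. Reported modularities (e.g. in `kappa_scan()`) always
use the conventional normalized $Q \le 1$, independent of how $H$ is
scaled.

## Optimization

`anneal()` runs heat-bath simulated annealing:

* labels start uniformly at random from the run's seed;
* one *sweep* visits every node in a fresh random permutation and resamples
  its label from the Gibbs distribution
  $P(s) \propto \exp(-H(s)/T)$ of the local cost (computed incrementally
  from the node's incident edges, ortholog links and triplets; the
  incremental and full evaluations agree to $10^{-9}$ by contract, and the
  exponent is max-shifted to avoid overflow);
* the initial temperature is calibrated by a doubling/halving search to the
  smallest $T$ whose measured flip rate (fraction of nodes changing label
  per sweep, estimated over 3 sweeps) exceeds $1 - 1/q$ — i.e. the system
  starts effectively randomizing;
* after `sweeps_per_temperature` sweeps (default 20) the temperature is
  multiplied by the cooling factor 0.9; the run stops when the flip rate of
  the last sweep drops below 1% (defaults exposed in `anneal_schedule()`);
* the returned labeling is the best-cost configuration seen, not
  necessarily the final one.

### Collective moves

Single-node moves cannot cross two barriers that both scale with module
size: merging two frozen fragments of one module, and re-labeling an
entire crystallized module so that it joins its orthologous counterpart in
another layer. Without help, whether two counterpart modules end up
co-labeled is decided by luck at the temperature where the layers order
(about half of runs on our planted data). Each temperature therefore also
runs one collective sweep (`group_sweeps_per_temperature`, 0 disables): for
every (layer, label) group, the whole group is offered a heat-bath
relabeling among all $q$ labels, with the group's gain computed exactly
from its boundary edges, null-model term, ortholog links and triplets.
Group moves respect the same Gibbs distribution over a restricted move set
and cost $O(\text{group degree} + q)$ each; with them, restarts agree and
the ensemble consensus is stable. The per-node sweeps, the stop rule, the
cooling factor and the calibration are unchanged by this addition.

`q` only needs to be "large enough": surplus labels die out during
cooling, and the post-consensus module count is identical for
$q \in \{10, 50, 250\}$ on planted data (a property the test suite
asserts). The desk-scale experiments here use $q = 50$; genome-scale
configurations ship with $q = 250$.

## Consensus

Annealing is stochastic, so `run_ensemble()` repeats it $R$ times (seeds
`seed .. seed+R-1`; parallel execution is bitwise-identical to serial
because each run seeds its own stream). The ensemble is summarized by the
co-appearance matrix: entry $(i,j)$ is the fraction of runs in which $i$
and $j$ shared a label. `extract_modules()` thresholds this matrix at 0.95
and takes connected components of the resulting graph; components smaller
than `min_size = 5` are reported as unassigned rather than as modules.
Components, not cliques, implement the transitivity of "ended up in the
same module"; whether stricter clique-like grouping is preferable is
genuinely open, but components are deterministic and monotone (raising the
threshold can only refine the partition, never merge — also asserted as a
property test). We compare co-appearance with `>=` at the threshold; the
distinction from strict `>` matters only when the fraction lands exactly
on the 0.95 grid point, i.e. when $R$ is a multiple of 20.

`classify_modules()` tags a module conserved when it has at least
`min_cross = 3` genes from each of two or more species *and* contains an
internal ortholog pair; otherwise it is specific to its majority species.
`fit_size_distribution()` fits a discrete power law
$P(s) \propto s^{-\alpha}$, $s \ge x_{\min} = $ smallest observed size, by
maximizing the Hurwitz-zeta likelihood with `optimize()`; the zeta function
is evaluated by direct summation to $10^5$ with an Euler–Maclaurin tail.
The fit is flagged low-confidence with fewer than three distinct sizes and
refuses degenerate all-equal input.

## Evaluation machinery

* **GO similarity** (`go_similarity`): terms are weighted by inverse
  document frequency $\mathrm{idf}_j = \log(n / n_j)$ (natural log; a term
  annotating all genes gets weight exactly 0, the extreme of down-weighting
  uninformative high-level terms), and gene-gene similarity is the cosine
  of the weighted annotation vectors. No propagation to ancestor terms is
  performed (a GAF row annotates exactly the listed term); propagate
  upstream of the package if desired.
* **Weighted modularity** (`weighted_modularity`): the standard
  $Q_w = \frac1{2m}\sum_{ij}[W_{ij} - k_ik_j/2m]\,\delta$ on an arbitrary
  weighted network, used with the GO similarity network as an
  annotation-based benchmark: the $\kappa$ whose modules maximize $Q_w$
  separates genes best in annotation space. The degree-product null
  includes the diagonal, which makes the one-module score exactly 0 and
  two clean equal blocks exactly 0.5.
* **kappa_scan**: runs the full pipeline per $\kappa$ and reports each
  layer's (normalized) modularity at the consensus partition, the fraction
  of metagenes recovered intact (a metagene counts as recovered only if
  all its resolvable members share one module; members absent from the
  network are dropped, or fail the metagene in `strict` mode), and the GO
  benchmark modularity. Raising $\kappa$ trades layer modularity for
  cross-species recovery; the recommended $\kappa$ maximizes the GO
  benchmark when present, else the sum of recovery and mean layer
  modularity.
* **Ortholog enrichment** (`ortholog_enrichment`): observed cross-module
  ortholog pairs against the expectation
  $O \cdot (n_w/N_w)(n_f/N_f)$; the upper-tail p-value draws the
  $n_w n_f$ candidate cross pairs from the $N_w N_f$ population containing
  $O$ ortholog pairs. The urn is a package decision (the test only names
  the distribution); it is frozen and documented here.
* **Clustering overlap**: gene pairs co-assigned by at least one of two
  clusterings split into both/only-A/only-B; the overlap is
  $I/(I+II+III)$. Pairs separated by both sides dominate by orders of
  magnitude and are excluded by construction.
* **Regulator coherence** (`regulatory_coherence`): ratio of mean shared
  regulator counts over within- versus between-module pairs; the null
  shuffles module labels preserving sizes, and the p-value uses the +1
  permutation correction.
* **ncRNA mapping** (`map_ncrna`): per ncRNA, Pearson correlations to all
  coding genes; the null pools correlations of 10 condition-shuffled
  copies; the neighbor threshold is the smallest correlation whose
  tail-ratio FDR estimate (null tail fraction over observed tail
  fraction — a plug-in of the Benjamini–Hochberg form) is below 5%;
  neighbor sets are tested per module by upper-tail hypergeometric and
  mapped where $p < 0.01$, possibly to several modules. Raw thresholds are
  used wherever the methodology states them; Benjamini–Hochberg correction
  across modules is available but off by default for fidelity.
* **Cross-layer co-appearance test** (`cross_coappearance_test`): module
  pairs, not gene pairs, are the exchangeable unit — a whole block pair
  either shares a label in a run or does not, so a gene-level permutation
  null is badly mis-calibrated. The test compares matched block-pair cells
  against random cells of the block grid.

## The synthetic-data generator

`generate_planted_multilayer()` plants equal-sized modules per species
(Bernoulli $p_{in}$ within, $p_{out}$ between), designates the first
`n_conserved` modules of every species as cross-species counterparts, and
links their positionally matched genes as orthologs with probability $f$.
`generate_expression_from_truth()` draws one latent profile per module —
shared across species for conserved modules — and emits
$\sqrt{\rho}\,\text{latent} + \sqrt{1-\rho}\,\text{noise}$ per gene, so the
expected within-module Pearson correlation is $\rho$.
`generate_benchmarks_from_truth()` adds GO annotations (module-specific
terms shared across species for conserved pairs, plus near-ubiquitous
background terms that exercise the idf), metagenes sampled from ortholog
groups, regulators targeting single planted modules, and ncRNA profiles
copying module means.

The default scenario — 2 species x 200 genes, 4 modules per species of
which 2 conserved, $p_{in} = 0.3$, $p_{out} = 0.01$, $f = 1$,
$\rho = 0.7$, 30 conditions — is the study condition for the end-to-end
checks: pipeline at $\kappa = 1$, $q = 50$, $R = 16$, threshold 0.95. The
many-to-many clique experiment plants an $8\times8$ bipartite clique from
module-1 genes of species 1 to module-2 genes of species 2 (clique members
take part in no 1-1 pair) and is run at $\kappa = 3$: per-count weighting
resolves the two conserved structures, uniform weighting glues the clique
into one module.

What the generator does **not** emulate: scale (hundreds, not tens of
thousands of genes), heavy-tailed degree distributions, partially
conserved modules, correlated noise between conditions, missing or
mis-assigned orthologs beyond the fidelity parameter, and annotation bias.
Passing tests demonstrate that the machinery behaves as designed under
controlled structure; they do not certify recovery rates on real
compendia.

## Numerical choices and edge cases

* Ties at the top-$d$ rank boundary in `rank_network()` break by
  descending $|r|$ then ascending gene name — bit-reproducible networks.
* "Giant connected network" in `choose_d()` means a single component over
  all genes with defined correlations (strictest reading); a coverage
  fraction (e.g. 0.95) is exposed as an alternative. If no $d \le d_{max}$
  connects the graph, $d_{max}$ is returned with a warning.
* Genes with missing values are dropped before correlation; zero-variance
  genes yield NA correlations and are excluded from the network.
* Layers with no edges are a hard error (the modularity null is undefined
  at $m = 0$); a sign class with no edges contributes 0 in signed mode.
* The brute-force oracle enumerates restricted growth strings (set
  partitions with at most $q$ blocks), i.e. one representative per
  label-permutation orbit, and refuses instances with $q^M > 10^7$.
* All stochastic entry points take explicit seeds; ensembles derive run
  seeds as `seed + 0..R-1`.
* Test problem sizes: unit tests run on instances of 6–60 genes; the
  end-to-end checks use the 400-gene default scenario with $R = 16$ and a
  five-point $\kappa$ grid over three seeds — a few minutes on one core.

## Known limitations

Global modularity-style objectives have a resolution limit: very large
modules can hide finer structure, and the shipped remedy is re-running the
tool on a sub-network (the resolution parameter $\lambda$ is exposed but
conventionally left at 1). Simulated annealing, even with collective
moves, carries no optimality guarantee; the brute-force oracle bounds only
desk-scale instances. Orthology input is consumed as given — no inference
from sequence, no identifier mapping across annotation releases (gene
identifiers match exactly and case-sensitively).
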