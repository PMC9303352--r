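---
title: "Individual semantic networks: models, measures, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual semantic networks: models, measures, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assocnet)
```

`assocnet` analyses free-association protocols collected from *single
individuals*: each participant responds to a large fixed cue list with up to
three associations per cue, a subset of cues is presented twice to measure
response reliability, and the same participant later completes verbal
fluency, episodic free-recall and paired-associate tasks. This vignette
documents the models the package implements, every tunable that matters, the
design decisions taken where the methodology is genuinely open, what the
synthetic cohort generator does and does not emulate, and the package's
numerical conventions.

## 1. From association records to networks

An association record table has one row per cue encounter
(`participant_id`, `encounter_index`, `cue`, `r1`–`r3`, `is_repeat`). Words
are canonicalized by lower-casing, trimming, and collapsing internal
whitespace — deliberately nothing more (no lemmatization, no diacritic
folding), so every network node can be traced verbatim to raw responses.
Canonicalization is idempotent.

`build_individual_network()` places a weighted, undirected edge between a cue
and each of its responses; the weight counts how often the unordered pair
occurred across positions and encounters. Response position carries no
weight discount: the three responses per cue are treated jointly, since
nothing in the elicitation privileges the first slot beyond response
dominance itself, which the counts already reflect. A response identical to
its cue is discarded. Both encounters of a repeated cue contribute by
default (`include_repeats = TRUE`): the repeat block is part of the response
yield, and dropping it discards half the reliability signal; the flag exists
because the opposite convention is defensible.

`build_aggregate_network()` pools all participants' pairs (weights sum), and
`common_subnetworks()` induces each network on the intersection of all node
sets, which equalizes lexicon coverage before structural comparison; nodes
isolated by the induction are retained so all common networks have the same
|V|.

## 2. Macroscopic structure

`macro_stats()` reports |V|, mean degree ⟨k⟩ = 2E/|V|, mean local clustering
C, and mean shortest path length L. All four ignore edge weights: degree
magnitudes in association networks of this design are dominated by the
counting scheme, and unweighted statistics are the convention for
cross-study comparison. Two further conventions matter and are fixed here:

* nodes of degree 0 or 1, whose local clustering is undefined, contribute 0
  to C and stay in the mean (the more common convention; excluding them
  raises C in sparse networks substantially);
* L is averaged over unordered pairs *within the largest connected
  component*, so disconnected pairs contribute no infinities. Individual
  networks built by this package never have isolated nodes (every node
  enters via an edge), but common subnetworks can.

`group_summary()` takes unweighted arithmetic means within groups;
`degree_distribution_similarity()` is the Pearson correlation of two degree
vectors over the shared node set. `detect_communities()` wraps weighted
Louvain modularity maximization with a fixed node ordering (lexicographic
sort) and an explicit seed, so partitions are reproducible.

## 3. Node-level measures

**Scaled PageRank.** `pagerank()` solves
PR_i = (1−d)/|V| + d Σ_j PR_j w_ij/s_j by power iteration on the weighted
undirected graph (dangling mass, which only arises in induced subnetworks,
is redistributed uniformly), iterating to an L1 change below 1e-12 and
erroring with the residual if 10,000 iterations do not suffice (the
contraction rate is d, so ~170 iterations reach 1e-12 at d = 0.85). The raw
stationary probabilities are scaled by |V|, making the mean exactly 1 and
values comparable across differently sized networks. Default d = 0.85, the
classical damping value; centrality always uses raw co-occurrence counts,
not PPMI weights — the frequency de-biasing argument applies to relatedness,
whereas for centrality the frequency signal *is* the construct.

**PPMI.** `ppmi_transform()` maps an edge count w_ij to
max(0, log₂ p(i,j)/(p(i)p(j))) with p(i,j) = w_ij/W and marginals
p(i) = s_i/W, each undirected edge contributing to both endpoints'
marginals. Zero-PPMI edges are removed (they carry no association signal
beyond frequency); nodes are retained and may become isolated, in which case
their similarity row is zero and their cosine to everything is 0.

**Katz walk similarity.** `walk_similarity()` computes
S = Σ_{t≥1} α^t P^t = (I − αP)^{-1} − I, with P the row-normalized
(optionally PPMI-reweighted) adjacency. Because P is row-(sub)stochastic and
α < 1, the series always converges and the linear system is never singular.
The identity is subtracted so that a word's vector encodes its walk profile
through the rest of the lexicon rather than trivial self-walks; cosine of
two rows is the relatedness measure. Defaults: α = 0.75, the value
customary in the walk-similarity literature on association norms, and PPMI
on. Three compute routes agree to 1e-8 where they overlap and are tested for
it: a dense solve (used up to 2,000 nodes), a truncated series iterated
until the largest new term is below 1e-10, and a row-restricted series that
computes only the rows that will actually be compared — the route the
simulator and large-network pipeline use. One analytic point worth recording:
a series truncated at exactly 50 terms carries a geometric tail of
α^51/(1−α) ≈ 9e-7 at α = 0.75, so agreement at 1e-8 is only meaningful for a
*converged* series; the test suite checks the 50-term oracle at its analytic
tail bound and a 100-term oracle at 1e-8.

## 4. Linking networks to behaviour

All behavioural statistics are raw mean differences with support sizes
attached, as effect plots in this literature show them; standardization is
left downstream, where the support sizes make it possible.

* **Fluency retrieval effect**: mean scaled PageRank of retrieved candidate
  words minus that of candidate words present in the network but not
  retrieved. Category candidates come from an explicit word list (never
  inferred); letter candidates default to all network words starting with
  the task letter. The alternative reading of "words starting with any same
  letter" — candidates matching the initials of whatever was retrieved — is
  implemented as `letter_rule = "retrieved_initials"`, since the phrase is
  genuinely ambiguous.
* **Lag similarity**: mean cosine between retrievals ℓ positions apart
  (ℓ = 1..3). Pairs involving out-of-network items are excluded, and the
  sequence is *not* re-spliced around them, which would manufacture
  adjacency that never occurred.
* **Episodic profile**: studied ∪ recalled words (restricted to network
  nodes) are partitioned into retrieved, missing, and intrusions (recalled,
  not studied, in the network); each status gets a mean scaled PageRank and
  a mean cosine to the retrieved words, a retrieved word excluding itself.
  If no retrieved word is in the network the similarity profile is
  undefined but the centrality profile is still returned.
* **Paired-associate effect**: mean cue–target cosine of recalled minus
  unrecalled pairs, on pairs with both words in the network.
* **Individual vs aggregate**: the identical code path evaluates each
  statistic under the participant's own network and under the aggregate
  network's measures applied to the same behavioural data;
  `compare_individual_vs_aggregate()` tabulates per-task means and their
  difference. No significance test is attached — with cohorts of this size
  the comparison is descriptive.

Centrality and similarity values are always taken from the network under
which an effect is evaluated, never mixed across networks.

## 5. Reliability

`repeated_cue_consistency()` is the proportion of second-encounter responses
that already appeared at the first encounter of the same cue (set semantics,
position ignored). The reverse direction is available because the two differ
whenever response counts differ. `repeat_association_profile()` reports the
percentage of distinct cue–response pairs occurring more than once and the
maximum count — the quantities that separate graded aggregate edge weights
from the nearly binary individual ones.
`cross_network_measure_correlation()` correlates centrality vectors over
shared nodes, or the upper triangles of shared-node cosine matrices; for the
cosine variant the matrix-triangle reading was chosen over a per-node mean
cosine (available as the `"vector"` type applied to row means) because it
compares the full relational structure rather than a one-number-per-word
summary. Above 100,000 triangle entries a seeded subsample is used and the
delta-method standard error of the estimated correlation is reported.

## 6. The synthetic cohort generator

The generator exists so every stage of the pipeline can be validated with
known ground truth. Its guiding principle: each participant owns a latent
"truth" network (their semantic memory); the association protocol *samples*
that network noisily; the behavioural tasks are driven by the truth
network's centrality and similarity; and the analysis sees only the sampled
records — so parameter recovery genuinely tests measurement, not
bookkeeping.

**Ground-truth networks.** A Watts–Strogatz-style ring lattice provides the
clustered backbone: `clustering_control` c rewires each lattice edge with
probability 1 − c, monotonically lowering realized clustering at fixed
degree. Two additions make the family behave like real association
lexicons, whose degree and frequency distributions are strongly
heavy-tailed rather than lattice-homogeneous:

* every word has a log-normal *prominence* (sd 2 on the log scale,
  truncated at exp(2.5·sd) so a single extreme draw cannot wire to most of
  the lexicon); edge strengths are ⌈π_i π_j⌉ capped at 50;
* a *hub overlay* adds `hub_overlay` extra edges per word on average, with
  prominence-proportional endpoints, so a few high-frequency words are
  connected to very many others — the "money is a response to many cues"
  phenomenon. Rewired lattice edges also choose prominence-proportional
  targets.

Degree homogeneity is not a cosmetic issue: with a vanilla lattice the
built networks carry essentially no recoverable centrality signal (the
candidate-level correlation between true and rebuilt PageRank is
indistinguishable from zero), and no slope on behaviour can compensate.
Heavy tails are what make node-level measurement possible at realistic
protocol sizes, in the simulation exactly as in real lexicons.

Group defaults encode the young/old contrast of interest: young —
2,000 words, mean degree 12 (overlay 4), clustering control 0.90; old —
2,600 words, mean degree 8 (overlay 2), clustering control 0.30. The old
group's larger lexicon, lower degree and sparser overlay jointly produce
larger rebuilt networks with lower mean degree, lower clustering and longer
paths, and the cohort-level recovery of that ordering is an acceptance
property of the package.

Categories (the first is `"animals"`) are random lexicon subsets of 80
words, not contiguous lattice blocks: real taxonomic categories span the
full word-frequency hierarchy, and confining them to one lattice
neighbourhood would flatten exactly the centrality differences the fluency
analysis measures. `category_cohesion` adds within-category edges (one per
member by default) for the internal density that makes category fluency
semantically chainable.

**Cohort structure.** One lexicon and one cue list are shared by the whole
cohort, as when every participant answers the same experimenter-chosen
cues; each group has a base network, and each participant's truth is derived
from it by degree-preserving rewiring of 10% of edges (idiosyncratic
experience). Shared structure is what makes the aggregate network, the
common subnetworks and cross-participant correlations meaningful.

**Association sampling.** Responses are drawn without replacement from the
cue's truth neighbourhood proportionally to edge strength; with probability
`noise_rate` (0.05) a response is instead a uniform lexicon draw,
emulating idiosyncratic responses that differentiate individual networks. A
repeat encounter copies each first-encounter response with probability
`repeat_fidelity` (default 0.53, a moderate consistency level typical of
repeated free association) and otherwise produces a *different* association
— one not given at the first encounter. That exclusion is a deliberate
reading of "otherwise resample": without it, chance re-overlap inside small
neighbourhoods (~3/k) would inflate measured consistency well above the
fidelity parameter and parameter recovery within a tight band would be
structurally impossible.

**Behaviour.** Fluency retrieves candidates sequentially with softmax
weights exp(β_c·PR + β_s·cos-to-previous) (the first item uses centrality
only); episodic recall of a studied word is Bernoulli with log-odds
β_c·(PR − 1) plus an intercept, with intrusions injected from truth
neighbours of recalled words; paired-associate recall is Bernoulli with
log-odds β_s·cosine plus an intercept, on pairs spanning adjacent, two-step
and random relatedness. Defaults β_c = 0.5 and β_s = 25 were calibrated once
by simulation so that, at the default protocol size, each of the four
behavioural signatures is strongly expressed in rebuilt networks — the
regime the analysis is designed for; the calibration was frozen before the
package's acceptance checks were written. Note the asymmetry: because
scaled PageRank is heavy-tailed (hubs at 10–20), a moderate β_c already
makes hub retrieval nearly certain, while a large β_c would collapse the
fluency chain into pure centrality ordering and erase the lag-similarity
structure. Setting both slopes to 0 yields behaviour unrelated to the
network, the null used in calibration tests.

**Protocol size.** The default desk-scale protocol is 1,200 unique + 240
repeated cues per participant (the study design's 5:1 ratio at 40% of its
cue count) on the 2,000/2,600-word lexicons. This keeps the ratio of
network size to cue count near the real design's; halving the cue count
again leaves networks too sparsely sampled for node-level measurement,
which is a statement about the method's data requirements, not a software
limit. A full eight-participant cohort simulates in seconds and the whole
pipeline runs in well under a minute.

**What the generator does not emulate.** Nodes are synthetic tokens with a
random initial letter, not words: there is no morphology, no polysemy, no
spelling variation, and canonicalization is therefore exercised only
lightly. Truth networks are static (no learning or forgetting between the
association task and the behavioural tasks), response chaining within an
encounter is absent, and the old/young contrast is imposed by parameters
rather than emerging from an experience model. Passing recovery tests on
this cohort shows the *pipeline* measures what it claims to measure at
realistic sizes; it cannot show that real aging lexicons follow the
generator's mechanism.

## 7. Numerical conventions and degenerate inputs

* PageRank: L1 tolerance 1e-12, max 10,000 iterations, error with residual
  on non-convergence; isolated nodes are dangling and receive uniform mass,
  so a single-node network has scaled PageRank exactly 1.
* Walk similarity: dense solve ≤ 2,000 nodes, otherwise truncated series to
  1e-10; cosine returns 0 whenever either row is all-zero, hence 0 across
  components and for PPMI-isolated words; cosine of a connected node with
  itself is exactly 1.
* Effects: empty retrieved or comparison sets raise errors rather than
  returning NaN; out-of-network items are dropped and counted in an
  attribute so the caller can audit coverage.
* Reproducibility: every stochastic function takes an explicit seed; the
  cohort generator and pipeline derive per-stage substreams from one root
  seed, and identical config + seed reproduce byte-identical CSVs. RNG
  state is saved and restored around all seeded code, so library calls do
  not perturb the caller's stream.
* Community detection ties are broken by lexicographically sorted node
  order under a fixed seed.

## 8. Problem sizes used by the test suite

The package's own validation uses reduced scales chosen to exercise the same
regimes: oracle comparisons on graphs of 4–50 nodes; structure recovery on
100 cohorts of six participants at half scale (1,000/1,300-word lexicons,
600 + 120 cues); behavioural recovery on 40 participants at full desk scale
plus a 200-replication null calibration; and reliability recovery at the
full 600-repeat design. These sizes are the package's choices for a
convincing-but-quick validation study of the method's operating regime.

## 9. Known limitations

* The letter-fluency candidate rule and the consistency direction are
  conventions with defensible alternatives; both are exposed as options and
  the defaults are stated above.
* C and L magnitudes of rebuilt synthetic networks are lower than those of
  real full-protocol networks (the synthetic desk protocol samples fewer
  triangles); group *orderings*, not magnitudes, are the validated
  quantity.
* The aggregate-vs-individual comparison inherits the design's confound:
  aggregate networks are effectively weighted, individual ones nearly
  binary, so "aggregate advantage" mixes pooling with weighting.
* Real-data ingestion assumes the documented CSV schemas; the package does
  not parse any platform's native export format, and response cleaning
  beyond canonicalization (spelling correction, multi-word handling) is out
  of scope — multi-word responses are kept as single nodes.
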