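---
title: "Predicting the assembly order of protein complexes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the assembly order of protein complexes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assemblypath)
```

## The problem

A complex of N protein subunits does not form in one step: subunits
associate in a defined order, passing through N - 2 intermediate
subcomplexes before the complete assembly appears. That order matters —
it constrains which subcomplexes can be reconstituted in vitro, which
interfaces are druggable before the complex is complete, and how the
machine evolved. Experiments that resolve it (native mass spectrometry,
co-immunoprecipitation of intermediates, time-resolved EM) are expensive,
so computational predictors are attractive.

`assemblypath` implements two families of predictors and the apparatus to
evaluate them.

**Buried-surface-area (BSA) predictors** require the solved complex.
Thermodynamically, the subcomplexes that form first are those with the
most favourable association free energy, and buried interface area is the
classic structural proxy for it. The *pairwise* variant computes, for
every contacting chain pair,

$$\mathrm{BSA}_{AB} = \mathrm{SASA}_A + \mathrm{SASA}_B - \mathrm{SASA}_{AB},$$

sorts pairs by descending area and assembles a spanning tree, skipping
cycle-closing edges. The *subcomplex* variant evaluates every feasible
merge of the current components,

$$\mathrm{BSA}_{P:Q} = \mathrm{SASA}_P + \mathrm{SASA}_Q - \mathrm{SASA}_{P \cup Q},$$

and greedily performs the largest-area merge until one component remains.
The difference is not cosmetic: a subunit that touches several
already-assembled chains (an apex subunit capping a partial ring) can
bury more area against the subcomplex than any single pair buries, a step
the pairwise ordering cannot express. The package's C5 ring-plus-apex
fixture is built to exhibit exactly this contrast, and the test suite
asserts it.

**Decoy-ensemble prediction** needs only the subunit structures. Pairwise
rigid-body docking poses ("decoys") are combined into candidate complexes
by a genetic algorithm (GA), and the assembly order is read off the
surviving models' score ranks. A model is a spanning tree: nodes are
chains, each edge is one pairwise decoy; realizing the model composes the
edge transforms from a root chain outward.

## The rank argument

For a binding pose $i$ of chains A and B with free energy
$\Delta G^{AB,i}_{\mathrm{bind}}$, the Boltzmann population is

$$p^{AB}_i = \frac{e^{-\Delta G^{AB,i}_{\mathrm{bind}}/kT}}
                 {\sum_n e^{-\Delta G^{AB,n}_{\mathrm{bind}}/kT}},$$

implemented in `pose_probabilities()`. More populated pairwise poses
assemble first. If different pairs have normalisation factors of the same
order and similar score distributions, the ordering of populations across
pairs follows the ordering of the *score ranks* within each pair: the
pair whose surviving decoy ranks best among its own alternatives is the
most populated, hence the first to assemble. `extract_pathway()`
therefore sorts a model's edges by score rank (1 = most favourable), ties
by the more negative Z-score, residual ties by pair label and decoy id,
and replays the edges through a union-find to produce the merge events.

Four strategies choose which model(s) to read:

* *Low-RMSD decoy combination* (non-blind): enumerate all spanning trees
  of the native interface graph, combine the k = 5 lowest-RMSD decoys per
  edge, keep the model with the lowest complex RMSD.
* *Lowest RMSD* (non-blind): the best-RMSD model of the final GA
  generation.
* *Final generation* (blind): every final-generation model votes for its
  extracted pathway; the plurality wins.
* *Consensus* (blind): votes are tallied across generations (from
  generation 1000 at full scale; desk-scale runs start halfway).

Votes are canonicalised before tallying. With a chain-class map (derived
from sequences, so still blind), two pathways whose intermediate
subcomplexes carry the same class-multiset signatures are the same
prediction — forming `AB` before `CD` or `CD` before `AB` when A/C and
B/D are identical copies describes one assembly order — and their votes
pool. This is the same equivalence the step-scoring metric uses; without
it, equivalent-correct votes split across symmetric string variants and
can lose the plurality to a genuinely different pathway.

Scores from several scoring functions can be combined by summing their
per-decoy ranks (`sum_of_ranks()`), which puts heterogeneous scores on a
common scale.

## The genetic algorithm

`run_ga()` follows the standard multimeric-docking protocol: a population
of M spanning-tree models; each generation applies 2M mutations (delete a
random edge, reconnect the cut with a random available pair and decoy),
discards mutants whose realized structure has more than `clash_max`
inter-chain atom pairs closer than 3 Å, pools parents with surviving
mutants (elitism — the best fitness is non-increasing by construction),
leader-clusters the pool by realized-structure RMSD, refills at random
from absorbed members when below M, and keeps the best M by fitness.
Full-scale defaults are M = 200, 400 mutations per generation, 2000
generations plus a 1000-generation extension when the best fitness has
not converged (improvement below `tol` over a trailing window; the
convergence criterion itself is this package's choice).

The shipped fitness is a residue-bead soft-sphere model: repulsion
$\sum (r_0 - d)^2$ over inter-chain atom pairs closer than $r_0 = 4.4$ Å
(about the non-bonded C$\alpha$–C$\alpha$ contact distance in folded
proteins, weight 3) minus the count of inter-chain residue pairs within
5 Å. Interfaces packed tighter than a physical residue contact are
penalised; regular interfaces are rewarded in proportion to their size.
Real docking pipelines use richer molecular-mechanics scores; `run_ga()`
accepts any `structure -> numeric` fitness.

### Desk-scale profile

Published runs of this kind cost hundreds of CPU hours per complex. The
package ships a desk-scale profile, `ga_config_desk()` (M = 20, 40
mutations/generation, 40 + 20 generations, clash cap 20, model-cluster
cutoff 0.5 Å), sized for its synthetic benchmark: subunits are ~25–45
beads, so a clash cap of 200 — calibrated for full-size proteins — would
let chains interpenetrate, and a 10 Å model-cluster cutoff — calibrated
for decoys spread over tens of Å — would collapse the entire near-native
funnel into a single representative and destroy the model diversity that
the voting strategies average over. Both caps scale with the system: the
full-scale defaults remain in `ga_config()`.

## SASA

Solvent-accessible surface area uses the Shrake–Rupley method
(`compute_sasa()`): golden-spiral test points on each probe-inflated
atomic sphere (960 points/atom by default, probe 1.4 Å), with a standard
van der Waals radius table. The two-sphere spherical-cap closed form and
a point-doubling convergence check bound the quadrature error in the test
suite (≤ 2%). Predictions depend only on BSA *orderings*, which are far
coarser than this error; nevertheless, marginal cases could order
differently under other SASA implementations, which is worth remembering
when comparing against published per-case calls.

## The synthetic benchmark

Real benchmarking requires solved complexes and dockings that cost CPU
weeks. The generator (`generate_benchmark()`) builds rigid pseudo-atom
complexes whose interface strengths are *designed exactly*: each designed
interface is a facing pair of bead grids, one bead pair per contact, 4.5
Å apart with 6 × 4.2 Å lateral spacing, so the residue-pair count at the
5 Å criterion equals the designed number; chain cores are open 5 Å
lattices so that random landings make only small accidental interfaces.
The planted assembly order is the greedy largest-transition pathway on
the designed contact counts. Five fixtures span 3–6 chains: a
hetero-trimer, a tetramer of two homodimeric pairs, a five-chain complex
with a small late binder, a C5 ring with an apex subunit that binds a
partial ring, and a dimer-of-dimers plus homodimer. Designed strengths
are strictly separated (gaps of ≥ 2 contact pairs at every decision the
planted pathway depends on) so the planted order is unambiguous.

Decoys per contacting pair: one exact native pose, 6 near poses
(rotation noise 3° about the ligand centroid, translation noise 0.5 Å)
and 36 random-orientation poses slid onto the receptor surface. Scores
emulate a binding energy, lower better. Native and near poses are scored
from their real geometry,
$S = \alpha\,\mathrm{RMSD} - \gamma\,(\mathrm{contacts} - 3\,\mathrm{repulsion}) + \varepsilon$
with $\alpha = 0.05$, $\gamma = 1$ and
$\varepsilon \sim N(0, \sigma_s)$, clamped so the native pose is each
pair's optimum (the synthetic energy surface is defined with its minimum
at the native pose; the RMSD term makes the minimum strict). Far poses
are scored against a common ladder of fake-interface sizes (0–14 contact
pairs, quantile-spaced). The ladder implements the similar-background
assumption of the rank argument directly: the deeper a pair's native
funnel, the fewer background poses outscore it, so native score ranks
order by designed interface strength — strongly bound pairs rank 1,
weak ones sink into the background. The documented score-noise level is
$\sigma_s = 1$, about 7% of the strongest funnel depth; a pure
RMSD-monotone score (`score_model = "rmsd"`) is also available.

What the generator does *not* emulate: conformational change on binding,
scoring functions whose errors correlate across pairs, decoy sets in the
thousands, and interface chemistry (everything is a carbon bead). Passing
the benchmark therefore demonstrates that the machinery — spanning-tree
search, rank extraction, voting, BSA orderings — behaves as designed
under controlled energetics; it is not evidence about accuracy on real
complexes.

### The ring-plus-apex fixture and what it teaches

The C5 fixture plants the pathway ring-dimer → ring-trimer → apex joins →
ring extends → ring closes. Its apex pairwise interfaces (5 contact
pairs) must be weaker than a ring edge (12), otherwise the pairwise-BSA
failure it exists to exhibit would vanish; but then, in any spanning-tree
model, the apex edge carries the weakest rank and always sorts last, so a
rank-ordered tree walk can never interleave the apex between ring steps.
The paper-scale analogue of this case is rescued by knowledge-based
scores detecting beyond-pairwise contact signal; a strictly pairwise
synthetic score cannot plant that signal. The GA recovery guarantees in
the test suite therefore cover the four fixtures whose native contact
graph is a tree, while the ring fixture is asserted on the
pairwise-vs-subcomplex BSA contrast — which is the scientific point of
that case. The ring's cyclic contact graph also admits many native
spanning trees, so final-generation votes fragment across symmetric
variants; both effects are visible in `vote_tally()` output.

## Evaluation metrics

A prediction is scored X/Y against a reference: Y = N - 2 total steps,
X = maximum bipartite matching between predicted and reference
intermediates under class-multiset equality, so homomeric copies are
interchangeable (`AA'` matches `A''A'''`, and starting a C5 ring at `CD`
instead of `BC` is equally correct). Partial references (not every merge
known) keep Y = N - 2 but can never award unlisted steps; with
alternative references the best-matching one counts. "Recovering the
planted pathway" in the tests and the acceptance script means X = Y.

Structural metrics: `complex_rmsd()` is C$\alpha$ RMSD after Kabsch
superposition, minimised exhaustively over class-preserving chain
permutations (tractable to ~7 chains); `largest_assembled()` finds the
largest chain subset placed within 4 Å RMSD of its native counterpart
(1 = not even a pair); `topology_delta()` compares interface graphs at
the 5 Å contact criterion (correct topology = no missing and no extra
interfaces; almost correct = nothing missing, ≤ 2 extra);
`stratify_vote_accuracy()` splits step accuracy at a 75% winner-vote
threshold.

## Numerical choices and tie-breaks

Determinism is enforced everywhere randomness or ties occur: exact score
ties resolve by decoy id; vote ties by the lexicographically smallest
pathway string (flagged); BSA ties by lexicographic component labels;
equal-RMSD models by fitness then index; chain labels sort base letter
first, then primes, then copy numbers. Rotations loaded from files are
re-orthonormalised when within 1e-3 of a proper rotation and rejected
otherwise (reflections always). Ranks and Z-scores are computed on the
clustered decoy set the GA actually searches, since the ranks must index
that set; Z-scores use the convention that more favourable is more
negative regardless of a score's orientation. All seeds flow through
explicit arguments, and a fixed seed reproduces GA records, fixtures and
predictions bit for bit.

## Limitations

* Bound-docking setting only: subunit library coordinates are the native
  ones. Unbound or homology-model inputs degrade pairwise decoys in ways
  the generator does not model.
* The BSA predictors need the solved complex by definition.
* `complex_rmsd()` and `largest_assembled()` enumerate chain
  permutations and subsets exhaustively; beyond ~8 chains they need the
  documented caps.
* Pathway notation covers tree-like merge orders; cyclic assembly graphs
  and kinetic rates are out of scope.
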