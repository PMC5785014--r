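# assemblypath

Predicting the **assembly order** of multimeric protein complexes.

A complex of N subunits assembles through N − 2 intermediate
subcomplexes, and the order of those merges carries biological and
practical information: which subcomplexes are stable enough to
reconstitute, which interfaces form early enough to be drug targets, how
the machine evolved. `assemblypath` implements two complementary
computational predictors of that order, plus everything needed to
evaluate them:

* **Buried-surface-area (BSA) predictors** on a solved complex.
  Pairwise: sort chain pairs by
  `BSA_AB = SASA_A + SASA_B − SASA_AB` and assemble a spanning tree in
  descending order. Subcomplex: greedily perform the merge
  `P + Q → P∪Q` with the largest transition area
  `BSA_{P:Q} = SASA_P + SASA_Q − SASA_{P∪Q}` — which, unlike the
  pairwise ordering, can let a subunit join a partially built
  subassembly it binds cooperatively (the classic ring-plus-apex case).
  SASA is computed with the Shrake–Rupley method.
* **Decoy-ensemble prediction** from subunit structures alone. Pairwise
  docking poses (rigid transforms plus scores) are combined into
  spanning-tree models of the whole complex by a genetic algorithm
  (population M, 2M edge mutations per generation, 3 Å clash filter,
  redundancy clustering, best-M selection). The assembly order of a model
  is read from its edges in ascending score rank — by the Boltzmann
  argument `p_i = exp(−ΔG_i/kT)/Σ_n exp(−ΔG_n/kT)`, the pairwise pose
  ranking best among its own alternatives is the most populated and so
  assembles first. Four strategies select the model(s): low-RMSD decoy
  combination, lowest-RMSD model (both need the native), and the blind
  final-generation and consensus voting strategies.

The package also provides the pathway text notation
(`"AA'> AA'C> AA'CC'"`, with primes/numbers for identical chains), step
scoring (X/Y correct subcomplexes with homomeric copies
interchangeable), permutation-minimised complex RMSD, largest assembled
subcomplex, interface-topology comparison, vote stratification, and a
synthetic benchmark generator with planted assembly orders so the entire
pipeline is testable end to end without downloads.

## A worked example

Build a synthetic hetero-trimer with a planted order (A–B interface 16
contact pairs, B–C 10, A–C none), predict its assembly order from buried
surface area, then blindly from docking decoys:

```r
library(assemblypath)

suite <- generate_benchmark(seed = 7)   # structures + decoys + scores
toy   <- suite$trimer

# native-structure predictor
p <- predict_subcomplex_bsa_path(toy$structure)
p
#> <assembly_pathway> 3 chains: AB> ABC
attr(p, "transitions")
#> # A tibble: 2 x 3
#>   part_a part_b  area
#>   <chr>  <chr>  <dbl>
#> 1 A      B       527.
#> 2 C      AB      330.

# blind predictor: GA over pairwise decoys, final-generation vote
res <- fixture_ga_predictions(toy, ga_config_desk(seed = 7))
res$final
#> <assembly_prediction> [final_generation, score energy]
#> pathway: AB> ABC
#> votes: 14/20 (70.0%)

score_pathway(res$final$pathway, toy$planted)
#> <pathway_score> 1/1 assembly steps correct
```

Both predictors recover the planted order `AB> ABC`: the A–B dimer
buries 527 Å² (vs 330 Å² for C joining AB), and 14 of the 20 final GA
models vote for assembling A–B first. `tidy()`/`glance()`/`autoplot()`
methods summarise GA runs and vote tallies; a thin command-line wrapper
lives at `inst/cli/assembly-path.R` (`synth`, `bsa`, `predict`
subcommands).

The methods vignette (`vignettes/assembly-order-methods.Rmd`) documents
the models, the synthetic benchmark design, every tunable parameter and
tie-break, and the known limitations.

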