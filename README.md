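# equiset

Feature selection on biomedical tabular data rarely has a unique answer:
when measurements are near-deterministic transformations of one another
(duplicated probes, derived clinical scores, co-regulated transcripts),
many different minimal feature sets predict the outcome equally well. A
method that reports a single "signature" silently hides all the
alternatives, which matters whenever the selected features feed
interpretation, biomarker panels or follow-up assays.

`equiset` discovers **all statistically equivalent minimal predictive
feature sets** — multiple Markov blankets — of one outcome variable in a
numeric data matrix, and represents the resulting family compactly.

## The method

A Markov blanket of an outcome *T* over features **F** is a minimal set
**S** with *T* ⊥ **F**∖**S** | **S**. The package provides:

* **Forward–backward selection (FBS)** as an instance of a general
  forward–backward template: candidates are ranked by the p-value of the
  conditional-independence test Test(*T*; *X* | **S**′) (Fisher-z partial
  correlation for continuous outcomes, logistic likelihood-ratio tests for
  binary ones); a backward pass removes false positives. Its output is the
  *reference solution*.
* **TMFBS**, a backtracking search over the selection states of the
  template: every candidate at every step spawns a branch, each tried
  candidate is excluded from all later sibling branches (so no selected set
  is ever visited twice), and each completed candidate solution is kept if
  it is statistically equivalent to the reference. Three sound pruning
  rules, justified by the fact that a dataset with no equivalent solution
  cannot hide one in any of its embedded (feature-excluded) datasets, cut
  the search drastically.
* **Statistical equivalence testing** of feature sets: a paired-swap
  permutation test on the variance of the per-sample log-likelihood ratio
  of the two models (p-value `(1 + Σ I(s_i ≤ s)) / (B + 1)`), followed by an
  information-equivalence check via two nested likelihood-ratio tests
  against the model on the union of the sets. A J-test variant using model
  predictions as proxies is also provided.
* **TIE\*-IGS**, the classic generate-embedded-datasets baseline, sharing
  the same tests, counters and equivalence decision, for head-to-head
  comparison by the number of conditional-independence tests performed.
* A **multiple-solutions graph (MSG)**: a single-root, single-leaf DAG
  whose root-to-leaf paths, choosing one feature set per node, enumerate
  exactly the discovered family. Construction is by forward, backward and
  OR merging, each provably preserving the decoded family.
* A **synthetic-data generator** with planted indispensable features,
  equivalence classes of near-copies, redundant and irrelevant features,
  plus the exact ground-truth solution family — the test bed for
  everything above.

## Worked example

```r
library(equiset)

gen <- generate_synthetic(synth_spec(
  n_samples = 2000, n_indispensable = 2, class_sizes = c(2),
  n_redundant = 1, n_irrelevant = 3, seed = 7))
gen$truth
#> <ground_truth>
#>   indispensable: 4, 6
#>   class 1: 1, 8
#>   redundant: 2
#>   irrelevant: 3, 5, 7

config  <- search_config(alpha = 1e-4, alpha_eq = 0.05, seed = 7)
counter <- new_test_counter()
res <- run_tmfbs(gen$dataset, config, counter = counter)
res$solutions
#> <solution_set> 2 solution(s)
#>   [1] {1, 4, 6} (reference)
#>   [2] {4, 6, 8}
str(res$stats)
#> List of 5
#>  $ nodes_visited  : int 11
#>  $ ci_tests_search: int 72
#>  $ ci_tests_equiv : int 2
#>  $ solutions_found: int 2
#>  $ limit_hit      : logi FALSE
```

The search found both planted blankets: features 4 and 6 are
indispensable, and features 1 and 8 (the planted near-copies) are
interchangeable. The taxonomy and the compressed graph make this explicit:

```r
classify_features(res$solutions, seq_len(ncol(gen$dataset$X)))
#>                       1                       2                       3
#>           "replaceable" "outside_all_solutions" "outside_all_solutions"
#>                       4                       5                       6
#>         "indispensable" "outside_all_solutions"         "indispensable"
#>                       7                       8
#> "outside_all_solutions"           "replaceable"

decode_solutions(build_msg(res$solutions))
#> <solution_set> 2 solution(s)
#>   [1] {1, 4, 6} (reference)
#>   [2] {4, 6, 8}
```

The baseline needs more work for the same answer — 116 search CI tests
versus TMFBS's 72 on this instance:

```r
run_tie_star_igs(gen$dataset, config)$stats$ci_tests_search
#> [1] 116
```

## Command line

A thin wrapper (`exec/equiset`) exposes the same functionality:

```sh
equiset simulate --n 2000 --classes 2,2 --seed 1 --out data.csv
equiset multi    --input data.csv --target outcome --alpha 1e-4 --out sols.json
equiset msg      --solutions sols.json --dot family.dot --decode
equiset benchmark --suite suite.yaml --out bench/
```

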