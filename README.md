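# corrtrait

Likelihood-based comparative phylogenetics for binary characters on rooted
trees and bootstrap tree ensembles. The package is written for studies of
habitat-driven convergent evolution — the motivating system is a
188-taxon cephalopod phylogeny with a pelagic/benthic habitat coding and
six presence/absence morphological characters — but every component is
generic: any rooted, branch-length-bearing tree ensemble plus a
taxon-by-character matrix of binary (or binarizable) states will do.

## What it computes

For a binary character with gain rate `q01` and loss rate `q10`
(a 2-state continuous-time Markov / Mk model), tree likelihoods are
computed with Felsenstein's pruning algorithm over the closed-form
transition probabilities

    P00(t) = (q10 + q01·e^(−λt)) / λ,   λ = q01 + q10,

with missing tips entering as fully ambiguous. On top of that engine:

* **Rate-model choice** — single-rate vs asymmetric-rate fits compared by
  a χ²(1) likelihood-ratio test (`rate_model_lrt`).
* **Marginal ancestral states** — a node's state is fixed
  ("fossilized"), the full likelihood recomputed per state, and the
  normalized proportional likelihoods assessed by either the
  proportional-likelihood ratio rule (threshold 7.4 ≈ e²) or the
  two-log-unit rule; calls are tallied across a bootstrap ensemble with
  nodes tracked by MRCA (`reconstruct_node`, `ensemble_asr`).
* **Pagel's correlation test** — for a trait pair, an 8-rate dependent
  4-state model (dual transitions forbidden) against the 4-rate
  independent model, per tree, with median log-likelihood aggregation
  across the ensemble and a χ²(4) test:
  `statistic = 2·|lnL_dep − lnL_indep|` (`pagel_test`,
  `correlation_table`).
* **Partition-scheme BIC** — `−2·lnL + k·ln(n_sites)` with
  branch-length parameters held constant across schemes so they cancel
  (`modified_bic`, `select_scheme`).
* **Synthetic study systems** — seeded Yule trees, NNI-perturbed
  ensembles, forward-simulated traits, and an event-driven simulator for
  correlated pairs (`simulate_study` and friends), so the full pipeline
  is testable end to end without sequence data.

## Worked example

```r
library(corrtrait)

cfg <- simulation_config(n_tips = 60, ensemble_size = 10,
                         ensemble_perturbation = 2,
                         trait_models = list(
                           habitat = two_state_model(0.5, 0.5, "symmetric"),
                           ANG = two_state_model(0.7, 0.7, "symmetric")),
                         seed = 42)
bundle <- simulate_study(cfg)
res <- run_full_analysis(
  run_config(bundle$ensemble, bundle$matrix, habitat = "habitat",
             n_starts = 5, seed = 42))
res$correlation[, c("trait_pair", "lnl_independent", "lnl_dependent",
                    "statistic", "p_value")]
#>     trait_pair lnl_independent lnl_dependent statistic   p_value
#> 1 habitat x ANG       -34.11205     -33.64015 0.9438078 0.9181935
```

Here the two characters were simulated independently, and the test agrees:
the dependent model gains only 0.47 log-units (median across the 10-tree
ensemble) over the independent one (statistic 0.94, four degrees of
freedom, p = 0.92 — no evidence of correlated evolution). A published-table audit is one call:

```r
tab <- verify_published_pvalues(system.file("extdata",
  "published_correlation_lnl.tsv", package = "corrtrait"))
tab[1, c("trait_pair", "lnl_difference", "p_recomputed")]
#>      trait_pair lnl_difference p_recomputed
#> 1 Habitat x ANG          -6.19   0.01473825
```

i.e. a printed log-likelihood difference of 6.190 corresponds to
χ²(4) upper-tail p = 0.0147.

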