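test_that("node reconstruction matches the cherry enumeration example", {
  tr <- parse_newick("(A:1,B:1);")
  m <- two_state_model(1, 1)
  rec <- reconstruct_node(tr, binary_trait("t", c(A = 0L, B = 0L)), m, 3)
  p <- (1 + exp(-2)) / 2
  expect_equal(exp(rec$fixed_loglik[["state0"]]), 0.5 * p^2,
               tolerance = 1e-9)
  expect_equal(exp(rec$fixed_loglik[["state1"]]), 0.5 * (1 - p)^2,
               tolerance = 1e-9)
  expect_equal(unname(rec$proportional), c(0.6329, 0.3671),
               tolerance = 1e-4)
  expect_equal(rec$ratio, 0.6329 / 0.3671, tolerance = 1e-3)
  expect_error(reconstruct_node(tr, binary_trait("t", c(A = 0L, B = 0L)),
                                m, 1), "tip")
})

test_that("symmetric data on a symmetric tree reconstruct to (0.5, 0.5)", {
  tr <- parse_newick("(A:1,B:1);")
  m <- two_state_model(1, 1)
  rec <- reconstruct_node(tr, binary_trait("t", c(A = 0L, B = 1L)), m, 3)
  expect_equal(unname(rec$proportional), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("fixed-state likelihoods obey the law of total probability on random trees", {
  set.seed(202)
  for (rep in 1:25) {
    tr <- random_tree(sample(4:8, 1))
    n <- length(tr$tip.label)
    x <- setNames(sample(c(0L, 1L, NA), n, TRUE, prob = c(.45, .45, .1)),
                  tr$tip.label)
    m <- random_q2()
    node <- sample((n + 1):(n + tr$Nnode), 1)
    rec <- reconstruct_node(tr, x, m, node)
    expect_equal(sum(rec$proportional), 1, tolerance = 1e-9)
    expect_true(rec$ratio >= 1)
    expect_equal(sum(exp(rec$fixed_loglik)),
                 exp(rec$unconstrained_loglik), tolerance = 1e-9)
    # node fixing agrees with the enumeration oracle
    o0 <- enum_loglik(tr, binary_tip_sets(x), rate_matrix(m), c(.5, .5),
                      fix_node = node, fix_state = 1L)
    expect_equal(rec$fixed_loglik[["state0"]], o0, tolerance = 1e-8)
  }
})

test_that("significance rules agree at the e^2 boundary and behave monotonically", {
  tr <- parse_newick("(A:1,B:1);")
  m <- two_state_model(1, 1)
  rec <- reconstruct_node(tr, binary_trait("t", c(A = 0L, B = 0L)), m, 3)
  expect_equal(decide_significance(rec, "ratio"), "inconclusive")
  # synthetic reconstructions spanning the threshold
  make_rec <- function(p0) {
    structure(list(node = 3L,
                   fixed_loglik = c(state0 = log(p0), state1 = log(1 - p0)),
                   proportional = c(state0 = p0, state1 = 1 - p0),
                   ratio = max(p0, 1 - p0) / min(p0, 1 - p0),
                   unconstrained_loglik = 0),
              class = "node_reconstruction")
  }
  expect_equal(decide_significance(make_rec(0.9), "ratio"), "state0")
  expect_equal(decide_significance(make_rec(0.1), "ratio"), "state1")
  expect_equal(decide_significance(make_rec(0.6), "ratio"), "inconclusive")
  # fixed lnLs two or more units apart -> significant under the 2-unit rule
  rec2 <- make_rec(0.9)
  rec2$fixed_loglik <- c(state0 = -30.0, state1 = -32.5)
  expect_equal(decide_significance(rec2, "two_log_units"), "state0")
  # rules coincide when ratio is away from e^2 (fixed lnLs proportional
  # to marginals)
  for (p0 in c(0.55, 0.7, 0.885, 0.95, 0.995)) {
    r <- make_rec(p0)
    ratio <- r$ratio
    if (abs(ratio - exp(2)) / exp(2) > 0.05)
      expect_equal(decide_significance(r, "ratio"),
                   decide_significance(r, "two_log_units"))
  }
  # monotonicity: a stricter ratio threshold never gains significance
  expect_equal(decide_significance(make_rec(0.9), "ratio",
                                   ratio_threshold = 20),
               "inconclusive")
})

test_that("ensemble ASR tallies fractions that sum to one and respects degenerate ensembles", {
  set.seed(303)
  base <- simulate_yule_tree(24, seed = 41)
  trait <- simulate_trait(base, two_state_model(0.5, 0.5), seed = 42)
  ens <- simulate_ensemble(base, size = 6, k_nni = 0, bl_sigma = 0,
                           seed = 43)
  tips <- base$tip.label[1:3]
  s <- ensemble_asr(ens, trait, clade_tips(base, mrca_node(base, tips)),
                    n_starts = 3, seed = 44)
  expect_equal(s$fraction_state0 + s$fraction_state1 +
                 s$fraction_inconclusive, 1, tolerance = 1e-12)
  expect_equal(s$n_trees, 6)
  # identical trees -> all replicates agree -> fractions are 0/1
  expect_true(all(c(s$fraction_state0, s$fraction_state1,
                    s$fraction_inconclusive) %in% c(0, 1)))
})
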