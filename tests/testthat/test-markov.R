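test_that("two-state transition probabilities match the closed form and its limits", {
  m <- two_state_model(1, 1)
  expect_equal(transition_matrix(m, 0), diag(2), ignore_attr = TRUE)
  P1 <- transition_matrix(m, 1)
  expect_equal(P1[1, 1], (1 + exp(-2)) / 2, tolerance = 1e-12)
  expect_equal(P1[1, 1], 0.5676676, tolerance = 1e-7)
  Pinf <- transition_matrix(m, 500)
  expect_equal(Pinf, matrix(0.5, 2, 2), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(transition_matrix(m, -0.1), "non-negative")

  # asymmetric case against the series oracle
  ma <- two_state_model(0.3, 2.1)
  for (t in c(0.01, 0.5, 3)) {
    expect_equal(transition_matrix(ma, t),
                 taylor_expm(rate_matrix(ma) * t),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("four-state transition matrix matches the series oracle and factorizes when independent", {
  r <- setNames(rep(1, 8), c("q12","q13","q21","q24","q31","q34","q42","q43"))
  m <- four_state_model(r, mode = "dependent")
  P <- transition_matrix(m, 0.7)
  expect_equal(P, taylor_expm(rate_matrix(m) * 0.7), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(transition_matrix(m, 0), diag(4), ignore_attr = TRUE)

  mx <- two_state_model(0.4, 1.3)
  my <- two_state_model(2.0, 0.6)
  ind <- independent_model(mx, my)
  Px <- transition_matrix(mx, 0.9)
  Py <- transition_matrix(my, 0.9)
  expect_equal(transition_matrix(ind, 0.9), kronecker(Px, Py),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("transition matrices are row-stochastic across rate and time ranges", {
  set.seed(3)
  for (i in 1:20) {
    t <- runif(1, 0, 100)
    m2 <- two_state_model(runif(1, 1e-4, 100), runif(1, 1e-4, 100))
    P2 <- transition_matrix(m2, t)
    expect_equal(rowSums(P2), c(1, 1), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_true(all(P2 >= 0 & P2 <= 1 + 1e-12))
    m4 <- random_q4(1e-2, 10)
    P4 <- transition_matrix(m4, runif(1, 0, 20))
    expect_equal(rowSums(P4), rep(1, 4), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_true(all(P4 >= 0))
  }
})

test_that("pruning matches the cherry closed form and handles total ambiguity", {
  tr <- parse_newick("(A:1,B:1);")
  m <- two_state_model(1, 1)
  ll <- prune_loglik(tr, binary_trait("t", c(A = 0L, B = 0L)), m)
  p <- (1 + exp(-2)) / 2
  expect_equal(ll, log(0.5 * (p^2 + (1 - p)^2)), tolerance = 1e-10)
  # all tips missing: probability 1
  ll_na <- prune_loglik(tr, binary_trait("t", c(A = NA, B = NA)), m)
  expect_equal(ll_na, 0, tolerance = 1e-12)
})

test_that("pruning equals brute-force enumeration on random small trees (2- and 4-state)", {
  set.seed(101)
  for (rep in 1:40) {
    tr <- random_tree(sample(3:6, 1))
    n <- length(tr$tip.label)
    # 2-state with occasional missing tips
    x <- sample(c(0L, 1L, NA), n, replace = TRUE, prob = c(.4, .4, .2))
    names(x) <- tr$tip.label
    m2 <- random_q2()
    ll <- prune_loglik(tr, x, m2)
    oracle <- enum_loglik(tr, binary_tip_sets(x), rate_matrix(m2),
                          c(.5, .5))
    expect_equal(ll, oracle, tolerance = 1e-9)
    # 4-state joint with partial missingness
    y <- sample(c(0L, 1L, NA), n, replace = TRUE, prob = c(.4, .4, .2))
    names(y) <- tr$tip.label
    m4 <- random_q4()
    ll4 <- prune_loglik(tr, list(x, y), m4)
    oracle4 <- enum_loglik(tr, joint_tip_sets(x, y), rate_matrix(m4),
                           rep(.25, 4))
    expect_equal(ll4, oracle4, tolerance = 1e-9)
  }
})

test_that("likelihood is invariant to child order, polytomies are accepted, and reparse is neutral", {
  set.seed(5)
  tr <- random_tree(8)
  x <- setNames(sample(0:1, 8, replace = TRUE), tr$tip.label)
  m <- random_q2()
  ll <- prune_loglik(tr, x, m)
  rot <- ape::rotateConstr(tr, rev(tr$tip.label))
  expect_equal(prune_loglik(rot, x, m), ll, tolerance = 1e-10)
  expect_equal(prune_loglik(parse_newick(write_newick(tr)), x, m), ll,
               tolerance = 1e-9)
  # polytomy: likelihood equals enumeration oracle too
  poly <- parse_newick("((A:1,B:1,C:1):0.5,D:1);")
  xs <- c(A = 0L, B = 1L, C = 0L, D = 1L)
  mp <- two_state_model(0.8, 1.5)
  expect_equal(prune_loglik(poly, xs, mp),
               enum_loglik(poly, binary_tip_sets(xs), rate_matrix(mp),
                           c(.5, .5)),
               tolerance = 1e-9)
})

test_that("ML fitting respects nesting and reproduces its optimum when restarted", {
  set.seed(7)
  tr <- simulate_yule_tree(80, seed = 3)
  trait <- simulate_trait(tr, two_state_model(0.6, 1.4), seed = 4)
  fs <- fit_mk2(tr, trait, "symmetric", n_starts = 5, seed = 1)
  fa <- fit_mk2(tr, trait, "asymmetric", n_starts = 5, seed = 1)
  expect_true(fa$log_likelihood >= fs$log_likelihood - 1e-8)
  expect_true(fs$log_likelihood <= 0)
  expect_true(fa$converged)
  # restart from the optimum: log-likelihood reproduced
  obj_ll <- prune_loglik(tr, trait, fa$model)
  expect_equal(obj_ll, fa$log_likelihood, tolerance = 1e-6)
})

test_that("two-state ML fits agree with an independent Mk implementation", {
  skip_if_not_installed("phytools")
  tr <- simulate_yule_tree(50, seed = 91)
  trait <- simulate_trait(tr, two_state_model(0.7, 1.8), seed = 92)
  ours <- fit_mk2(tr, trait, "asymmetric", n_starts = 5, seed = 1)
  x <- setNames(as.character(trait$tip_states), names(trait$tip_states))
  ref <- phytools::fitMk(tr, x, model = "ARD", pi = "equal")
  expect_equal(ours$log_likelihood, ref$logLik, tolerance = 1e-3,
               ignore_attr = TRUE)
  sym <- fit_mk2(tr, trait, "symmetric", n_starts = 5, seed = 2)
  ref_er <- phytools::fitMk(tr, x, model = "ER", pi = "equal")
  expect_equal(sym$log_likelihood, ref_er$logLik, tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("independent 4-state fit decomposes into the two marginal 2-state fits", {
  tr <- simulate_yule_tree(60, seed = 21)
  a <- simulate_trait(tr, two_state_model(0.8, 0.8), seed = 22, name = "a")
  b <- simulate_trait(tr, two_state_model(1.2, 0.4), seed = 23, name = "b")
  fi <- fit_mk4(tr, a, b, "independent", n_starts = 4, seed = 2)
  f1 <- fit_mk2(tr, a, "asymmetric", n_starts = 4, seed = 3)
  f2 <- fit_mk2(tr, b, "asymmetric", n_starts = 4, seed = 4)
  expect_equal(fi$log_likelihood,
               f1$log_likelihood + f2$log_likelihood, tolerance = 1e-4)
})

test_that("rate-model LRT is well-behaved in the degenerate and asymmetric regimes", {
  tr <- simulate_yule_tree(120, seed = 31)
  trait <- simulate_trait(tr, two_state_model(2.0, 0.2), seed = 32)
  res <- rate_model_lrt(tr, trait, n_starts = 5, seed = 5)
  expect_true(res$statistic >= 0)
  expect_equal(res$df, 1L)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  # strongly asymmetric truth: asymmetric model should fit clearly better
  expect_true(res$lnl_asymmetric >= res$lnl_symmetric)
  # degenerate: all tips missing -> both optima are lnL = 0, statistic 0
  tr2 <- parse_newick("((A:1,B:1):1,C:1);")
  res2 <- rate_model_lrt(tr2, binary_trait("t", c(A = NA, B = NA, C = NA)),
                         n_starts = 3, seed = 6)
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)
})
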