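test_that("Yule trees are seeded, binary, and hit the requested depth", {
  t1 <- simulate_yule_tree(5, seed = 1)
  t2 <- simulate_yule_tree(5, seed = 1)
  expect_equal(write_newick(t1), write_newick(t2))
  t3 <- simulate_yule_tree(188, seed = 2)
  expect_equal(length(t3$tip.label), 188)
  expect_equal(t3$Nnode, 187)
  d <- ape::node.depth.edgelength(t3)[1:188]
  expect_equal(mean(d), 1, tolerance = 1e-9)
  t4 <- simulate_yule_tree(50, depth = 2.5, seed = 3)
  expect_equal(mean(ape::node.depth.edgelength(t4)[1:50]), 2.5,
               tolerance = 1e-9)
})

test_that("NNI ensembles preserve the tip set and bound topological distance", {
  base <- simulate_yule_tree(20, seed = 4)
  ens0 <- simulate_ensemble(base, size = 4, k_nni = 0, bl_sigma = 0,
                            seed = 5)
  for (tr in ens0$trees) expect_equal(write_newick(tr),
                                      write_newick(base))
  ens1 <- simulate_ensemble(base, size = 10, k_nni = 1, bl_sigma = 0,
                            seed = 6)
  for (tr in ens1$trees) {
    expect_setequal(tr$tip.label, base$tip.label)
    rf <- ape::dist.topo(ape::unroot(base), ape::unroot(tr))
    expect_lte(as.numeric(rf), 2)
  }
  # jitter preserves expected branch length (mean-1 log-normal)
  ens2 <- simulate_ensemble(base, size = 200, k_nni = 0, bl_sigma = 0.1,
                            seed = 7)
  mean_len <- mean(vapply(ens2$trees,
                          function(tr) sum(tr$edge.length), numeric(1)))
  expect_equal(mean_len, sum(base$edge.length), tolerance = 0.02)
})

test_that("forward trait simulation is seeded and respects degenerate branch lengths", {
  tr <- simulate_yule_tree(30, seed = 8)
  a <- simulate_trait(tr, two_state_model(0.5, 0.5), seed = 9)
  b <- simulate_trait(tr, two_state_model(0.5, 0.5), seed = 9)
  expect_equal(a$tip_states, b$tip_states)
  tr0 <- tr
  tr0$edge.length[] <- 0
  c0 <- simulate_trait(tr0, two_state_model(0.5, 0.5),
                       root_dist = c(0, 1), seed = 10)
  expect_true(all(c0$tip_states == c0$tip_states[1]))
})

test_that("symmetric rates give near-stationary tip frequencies on deep trees", {
  tr <- simulate_yule_tree(1000, depth = 8, seed = 11)
  x <- simulate_trait(tr, two_state_model(1, 1), seed = 12)
  f <- mean(x$tip_states)
  # tips are phylogenetically correlated, so allow a generous band
  expect_gt(f, 0.2)
  expect_lt(f, 0.8)
})

test_that("event-driven pair simulation is seeded and honours structural constraints", {
  tr <- simulate_yule_tree(60, seed = 13)
  m <- random_q4(mode = "independent")
  p1 <- simulate_correlated_traits(tr, m, seed = 14)
  p2 <- simulate_correlated_traits(tr, m, seed = 14)
  expect_equal(p1$habitat$tip_states, p2$habitat$tip_states)
  expect_equal(p1$morph$tip_states, p2$morph$tip_states)
  # a dependent model that forbids morph gains outside habitat 0 and
  # morph losses: any tip with morph=1 must trace to a gain in habitat 0
  r <- c(q12 = 5, q13 = 1, q21 = 1e-8, q24 = 1e-8, q31 = 1,
         q34 = 1e-8, q42 = 1e-8, q43 = 1e-8)
  md <- four_state_model(r, mode = "dependent")
  p3 <- simulate_correlated_traits(tr, md, root_dist = c(1, 0, 0, 0),
                                   seed = 15)
  expect_true(all(p3$morph$tip_states %in% 0:1))
  # state (1,1) is unreachable under these rates: no such tip may exist
  expect_equal(sum(p3$habitat$tip_states == 1 &
                     p3$morph$tip_states == 1), 0)
  # under independence, traits decorrelate across replicates
  set.seed(16)
  cors <- replicate(30, {
    p <- simulate_correlated_traits(tr, m)
    x <- p$habitat$tip_states
    y <- p$morph$tip_states
    if (length(unique(x)) < 2 || length(unique(y)) < 2) 0
    else cor(x, y)
  })
  expect_lt(abs(mean(cors)), 0.15)
})

test_that("simulate_study builds a coherent bundle from one config", {
  cfg <- simulation_config(n_tips = 25, ensemble_size = 4,
                           ensemble_perturbation = 2,
                           trait_models = list(
                             habitat = two_state_model(0.5, 0.5,
                                                       "symmetric"),
                             ANG = two_state_model(0.7, 0.7, "symmetric")),
                           seed = 17)
  bundle <- simulate_study(cfg)
  expect_equal(length(bundle$best_tree$tip.label), 25)
  expect_length(bundle$ensemble$trees, 4)
  expect_s3_class(bundle$matrix, "character_matrix")
  expect_setequal(colnames(bundle$matrix), c("habitat", "ANG"))
  expect_setequal(rownames(bundle$matrix), bundle$best_tree$tip.label)
  # same config, same bundle
  bundle2 <- simulate_study(cfg)
  expect_equal(unclass(bundle$matrix), unclass(bundle2$matrix))
})
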