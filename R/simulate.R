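#' Simulation configuration for the synthetic study system
#'
#' Bundles the generator settings for a tree, an ensemble, and trait
#' evolution. Defaults mirror the shape of the study system the package
#' targets: 188 tips, a 1000-tree bootstrap-like ensemble, mean
#' root-to-tip depth of 1 expected substitution per site, moderate
#' topological perturbation, and moderately labile binary traits.
#'
#' @param n_tips Number of tips (default 188).
#' @param birth_rate Yule speciation rate per lineage per unit time.
#' @param tree_depth_scaling Target mean root-to-tip path length.
#' @param ensemble_size Number of ensemble replicates (default 1000).
#' @param ensemble_perturbation NNI moves per replicate (default 5).
#' @param bl_jitter_sd Log-normal branch-length jitter sigma (default
#'   0.1); jitter is mean-1 so expected lengths are preserved.
#' @param trait_models Named list of `two_state_model` /
#'   `four_state_model` objects used by higher-level drivers; the default
#'   is a symmetric rate-0.5 two-state model per trait.
#' @param seed Master seed recorded in all provenance.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_tips = 188, birth_rate = 1,
                              tree_depth_scaling = 1,
                              ensemble_size = 1000,
                              ensemble_perturbation = 5,
                              bl_jitter_sd = 0.1,
                              trait_models = list(
                                habitat = two_state_model(0.5, 0.5,
                                                          "symmetric")),
                              seed = 1) {
  stopifnot(n_tips >= 2, birth_rate > 0, tree_depth_scaling > 0,
            ensemble_size >= 1, ensemble_perturbation >= 0,
            bl_jitter_sd >= 0)
  structure(list(n_tips = n_tips, birth_rate = birth_rate,
                 tree_depth_scaling = tree_depth_scaling,
                 ensemble_size = ensemble_size,
                 ensemble_perturbation = ensemble_perturbation,
                 bl_jitter_sd = bl_jitter_sd,
                 trait_models = trait_models,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed",
                                   envir = globalenv())))
  set.seed(seed)
  force(expr)
}

#' Simulate a Yule (pure-birth) tree
#'
#' Draws a rooted binary tree with exponential waiting times under a
#' pure-birth process, then rescales all branch lengths so the mean
#' root-to-tip path equals `depth` (for an ultrametric Yule tree every
#' root-to-tip path is then exactly `depth`). Reproducible under `seed`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate.
#' @param depth Target mean root-to-tip path length.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A `phylo` with tips `t1..tn`.
#' @export
simulate_yule_tree <- function(n_tips = 188, birth_rate = 1, depth = 1,
                               seed = NULL) {
  draw <- function() ape::rphylo(n_tips, birth = birth_rate, death = 0)
  tr <- if (is.null(seed)) draw() else with_seed(seed, draw())
  d <- ape::node.depth.edgelength(tr)[seq_len(n_tips)]
  tr$edge.length <- tr$edge.length * depth / mean(d)
  validate_tree(tr)
}

#' Simulate a bootstrap-like tree ensemble by NNI perturbation
#'
#' Each replicate applies `k_nni` random nearest-neighbour-interchange
#' moves to the base tree and jitters every branch length by a mean-1
#' log-normal factor, emulating the topological and branch-length
#' variance of a bootstrap sample while preserving the tip set exactly.
#'
#' @param base_tree A rooted binary `phylo`.
#' @param size Number of replicates.
#' @param k_nni NNI moves per replicate (0 = identical topologies).
#' @param bl_sigma Log-normal sigma for branch-length jitter (0 = none).
#' @param seed Integer seed, or `NULL`.
#' @return A [tree_ensemble()] with `source_tag = "nni_perturbed"`.
#' @export
simulate_ensemble <- function(base_tree, size = 1000, k_nni = 5,
                              bl_sigma = 0.1, seed = NULL) {
  base_tree <- validate_tree(base_tree)
  gen <- function() {
    lapply(seq_len(size), function(i) {
      tr <- if (k_nni > 0) phangorn::rNNI(base_tree, moves = k_nni, n = 1)
            else base_tree
      if (bl_sigma > 0)
        tr$edge.length <- tr$edge.length *
          rlnorm(length(tr$edge.length), -bl_sigma^2 / 2, bl_sigma)
      tr
    })
  }
  trees <- if (is.null(seed)) gen() else with_seed(seed, gen())
  tree_ensemble(trees, source_tag = "nni_perturbed")
}

# Preorder traversal order of edges (parents before children).
preorder_edges <- function(tree) {
  tre <- ape::reorder.phylo(tree, "postorder")
  list(edge = tre$edge[rev(seq_len(nrow(tre$edge))), , drop = FALSE],
       len = rev(tre$edge.length))
}

#' Forward-simulate a binary trait under a two-state Mk model
#'
#' Draws the root state from `root_dist`, then each child's state from
#' the closed-form transition probabilities over its branch, in preorder.
#'
#' @param tree A rooted `phylo`.
#' @param model A `two_state_model`.
#' @param root_dist Probability of root states (0, 1); default uniform.
#' @param seed Integer seed, or `NULL`.
#' @param name Trait name for the returned object.
#' @return A `binary_trait` over the tree's tips.
#' @export
simulate_trait <- function(tree, model, root_dist = c(0.5, 0.5),
                           seed = NULL, name = "trait") {
  tree <- validate_tree(tree)
  run <- function() {
    po <- preorder_edges(tree)
    n_all <- length(tree$tip.label) + tree$Nnode
    state <- integer(n_all)
    root <- po$edge[1L, 1L]
    state[root] <- sample(0:1, 1L, prob = root_dist)
    for (i in seq_len(nrow(po$edge))) {
      P <- transition_matrix(model, po$len[i])
      s <- state[po$edge[i, 1L]]
      state[po$edge[i, 2L]] <- sample(0:1, 1L, prob = P[s + 1L, ])
    }
    state[seq_along(tree$tip.label)]
  }
  tips <- if (is.null(seed)) run() else with_seed(seed, run())
  binary_trait(name, setNames(tips, tree$tip.label),
               binarization_rule = "simulated")
}

# Gillespie simulation of the 4-state pair process along one branch.
# Dual transitions never occur because only single-trait moves are drawn.
gillespie_branch <- function(state, Q, t) {
  time <- 0
  repeat {
    rates <- Q[state, ]
    rates[state] <- 0
    total <- sum(rates)
    if (total <= 0) return(state)
    time <- time + rexp(1L, total)
    if (time > t) return(state)
    state <- sample.int(4L, 1L, prob = rates)
  }
}

#' Forward-simulate a correlated pair of binary traits
#'
#' Event-driven (Gillespie) simulation of the four-state pair process
#' along every branch: waiting times are exponential in the total exit
#' rate and each event changes exactly one trait, so the prohibition on
#' dual transitions is structural rather than approximate.
#'
#' @param tree A rooted `phylo`.
#' @param model A `four_state_model` (independent or dependent mode).
#' @param root_dist Probability over joint root states 1..4; default
#'   uniform.
#' @param seed Integer seed, or `NULL`.
#' @param names Length-2 trait names (X = habitat, Y = morphology).
#' @return List of two `binary_trait`s: `habitat` (X) and `morph` (Y).
#' @export
simulate_correlated_traits <- function(tree, model,
                                       root_dist = rep(0.25, 4),
                                       seed = NULL,
                                       names = c("habitat", "morph")) {
  tree <- validate_tree(tree)
  stopifnot(inherits(model, "four_state_model"))
  Q <- rate_matrix(model)
  run <- function() {
    po <- preorder_edges(tree)
    n_all <- length(tree$tip.label) + tree$Nnode
    state <- integer(n_all)
    root <- po$edge[1L, 1L]
    state[root] <- sample.int(4L, 1L, prob = root_dist)
    for (i in seq_len(nrow(po$edge))) {
      state[po$edge[i, 2L]] <-
        gillespie_branch(state[po$edge[i, 1L]], Q, po$len[i])
    }
    state[seq_along(tree$tip.label)]
  }
  joint <- if (is.null(seed)) run() else with_seed(seed, run())
  # joint index 1=(0,0), 2=(0,1), 3=(1,0), 4=(1,1)
  x <- as.integer(joint >= 3L)
  y <- as.integer(joint %in% c(2L, 4L))
  list(habitat = binary_trait(names[1L], setNames(x, tree$tip.label),
                              "simulated"),
       morph = binary_trait(names[2L], setNames(y, tree$tip.label),
                            "simulated"))
}

#' Generate a full synthetic study bundle
#'
#' Produces a best tree, an ensemble, and a character matrix (habitat
#' plus one column per entry of `trait_models`) from one
#' [simulation_config()], with all randomness derived from its seed.
#'
#' @param config A `simulation_config`.
#' @return List: `best_tree`, `ensemble`, `matrix` (a
#'   `character_matrix`), `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  best <- simulate_yule_tree(config$n_tips, config$birth_rate,
                             config$tree_depth_scaling,
                             seed = config$seed)
  ens <- simulate_ensemble(best, config$ensemble_size,
                           config$ensemble_perturbation,
                           config$bl_jitter_sd,
                           seed = config$seed + 1L)
  cols <- list()
  for (j in seq_along(config$trait_models)) {
    nm <- names(config$trait_models)[j]
    m <- config$trait_models[[j]]
    if (inherits(m, "two_state_model")) {
      tr <- simulate_trait(best, m, seed = config$seed + 10L + j,
                           name = nm)
      cols[[nm]] <- tr$tip_states
    } else {
      pair <- simulate_correlated_traits(best, m,
                                         seed = config$seed + 10L + j,
                                         names = c("habitat", nm))
      cols[["habitat"]] <- pair$habitat$tip_states
      cols[[nm]] <- pair$morph$tip_states
    }
  }
  raw <- do.call(cbind, cols)
  rownames(raw) <- best$tip.label
  list(best_tree = best, ensemble = ens,
       matrix = character_matrix(raw), config = config)
}
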