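# Independent oracles used against the package's likelihood engine.

# Matrix exponential by scaling + truncated Taylor series + squaring.
taylor_expm <- function(A, terms = 30) {
  s <- max(0, ceiling(log2(max(1, norm(A, "O")))))
  B <- A / 2^s
  X <- diag(nrow(A))
  term <- diag(nrow(A))
  for (i in seq_len(terms)) {
    term <- term %*% B / i
    X <- X + term
  }
  for (i in seq_len(s)) X <- X %*% X
  X
}

# Brute-force tree likelihood: explicit sum over every assignment of states
# to internal nodes (and ambiguous tips). tip_sets is a list of 1-based
# allowed-state vectors per tip; fix_node/fix_state restrict one internal
# node. Only for tiny trees.
enum_loglik <- function(tree, tip_sets, Q, prior, fix_node = NULL,
                        fix_state = NULL) {
  k <- nrow(Q)
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  allowed <- vector("list", n_all)
  for (i in seq_len(n_tip)) allowed[[i]] <- tip_sets[[i]]
  for (i in (n_tip + 1L):n_all) allowed[[i]] <- seq_len(k)
  if (!is.null(fix_node)) allowed[[fix_node]] <- fix_state
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    taylor_expm(Q * tree$edge.length[e]))
  root <- n_tip + 1L
  grid <- as.matrix(expand.grid(allowed, KEEP.OUT.ATTRS = FALSE))
  total <- 0
  for (r in seq_len(nrow(grid))) {
    s <- grid[r, ]
    p <- unname(prior[s[root]])
    for (e in seq_len(nrow(tree$edge))) {
      p <- p * P[[e]][s[tree$edge[e, 1L]], s[tree$edge[e, 2L]]]
      if (p == 0) break
    }
    total <- total + p
  }
  unname(log(total))
}

# 1-based allowed-state sets for a binary trait vector (NA = both states).
binary_tip_sets <- function(states) {
  lapply(states, function(s) if (is.na(s)) 1:2 else s + 1L)
}

# Joint-state sets for a pair of binary vectors, index 1=(0,0) .. 4=(1,1).
joint_tip_sets <- function(x, y) {
  lapply(seq_along(x), function(i) {
    xs <- if (is.na(x[i])) 0:1 else x[i]
    ys <- if (is.na(y[i])) 0:1 else y[i]
    as.integer(outer(xs * 2L, ys, "+") + 1L)
  })
}

# Random rooted tree with branch lengths, as a validated phylo.
random_tree <- function(n_tips, min_bl = 0.05, max_bl = 2) {
  tr <- ape::rtree(n_tips, rooted = TRUE)
  tr$edge.length <- runif(nrow(tr$edge), min_bl, max_bl)
  validate_tree(tr)
}

random_q2 <- function(lo = 0.1, hi = 3) {
  two_state_model(runif(1, lo, hi), runif(1, lo, hi))
}

random_q4 <- function(lo = 0.1, hi = 3, mode = "dependent") {
  r <- runif(8, lo, hi)
  names(r) <- c("q12", "q13", "q21", "q24", "q31", "q34", "q42", "q43")
  if (mode == "independent") {
    r["q34"] <- r["q12"]; r["q24"] <- r["q13"]
    r["q43"] <- r["q21"]; r["q42"] <- r["q31"]
  }
  four_state_model(r, mode = mode)
}
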