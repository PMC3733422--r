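#' Marginal ancestral-state reconstruction at one internal node
#'
#' For each state, computes the log-likelihood of the full tip data with
#' the node's state fixed (its partial likelihood conditioned on that
#' state, all other nodes marginalized) and normalizes across states into
#' proportional likelihoods. The exponentiated fixed-state likelihoods sum
#' to the unconstrained likelihood (law of total probability).
#'
#' @param tree A rooted `phylo`.
#' @param trait A `binary_trait` or named 0/1/NA vector.
#' @param model A fitted or supplied `two_state_model`.
#' @param node Internal node id (ape numbering).
#' @param root_prior Root prior; default uniform.
#' @return A `node_reconstruction`: `node`, `fixed_loglik` (per state),
#'   `proportional` (normalized, sums to 1), `ratio`
#'   (favored / other proportional likelihood), `unconstrained_loglik`.
#' @export
reconstruct_node <- function(tree, trait, model, node, root_prior = NULL) {
  stopifnot(inherits(model, "two_state_model"))
  if (node <= length(tree$tip.label))
    stop("node ", node, " is a tip; reconstruction targets internal nodes",
         call. = FALSE)
  fixed <- vapply(0:1, function(s)
    prune_loglik(tree, trait, model, root_prior,
                 fix_node = node, fix_state = s), numeric(1))
  names(fixed) <- c("state0", "state1")
  m <- max(fixed)
  w <- exp(fixed - m)
  prop <- w / sum(w)
  structure(list(node = node,
                 fixed_loglik = fixed,
                 proportional = prop,
                 ratio = max(prop) / min(prop),
                 unconstrained_loglik =
                   prune_loglik(tree, trait, model, root_prior)),
            class = "node_reconstruction")
}

#' @export
print.node_reconstruction <- function(x, ...) {
  cat(sprintf(paste0("Node %d: P(state0) = %.4f, P(state1) = %.4f, ",
                     "ratio = %.3f\n"),
              x$node, x$proportional[1L], x$proportional[2L], x$ratio))
  invisible(x)
}

#' Significance call for a node reconstruction
#'
#' Two rules are supported. The proportional-likelihood ratio rule calls
#' the favored state significant when the favored/unfavored ratio exceeds
#' the threshold (default 7.4, approximately e^2). The two-log-unit rule
#' calls a state significant when its fixed-state log-likelihood is at
#' least `delta` (default 2) natural-log units above the other's. The two
#' rules coincide whenever the threshold equals `exp(delta)`, because
#' fixed-state likelihoods are proportional to the marginals.
#'
#' @param rec A `node_reconstruction`.
#' @param rule `"ratio"` or `"two_log_units"`.
#' @param ratio_threshold Ratio cutoff for the ratio rule.
#' @param delta Log-likelihood difference cutoff for the two-log-unit rule.
#' @return `"state0"`, `"state1"`, or `"inconclusive"`.
#' @export
decide_significance <- function(rec, rule = c("ratio", "two_log_units"),
                                ratio_threshold = 7.4, delta = 2) {
  stopifnot(inherits(rec, "node_reconstruction"))
  rule <- match.arg(rule)
  favored <- if (rec$proportional[1L] >= rec$proportional[2L]) "state0"
             else "state1"
  sig <- if (rule == "ratio") {
    rec$ratio > ratio_threshold
  } else {
    abs(rec$fixed_loglik[1L] - rec$fixed_loglik[2L]) >= delta
  }
  if (sig) favored else "inconclusive"
}

#' Ensemble ancestral-state reconstruction at a node tracked by MRCA
#'
#' For every tree in the ensemble, locates the MRCA of `node_tips`, fits
#' the two-state model (per tree by default, or once on the first tree
#' with `shared_rates = TRUE`), reconstructs the node and applies the
#' significance rule; the calls are tallied into fractions. Trees where
#' the optimizer fails are excluded with a warning and do not enter the
#' denominator.
#'
#' @param ensemble A [tree_ensemble()].
#' @param trait A `binary_trait`.
#' @param node_tips Tip labels defining the node (tracked by MRCA).
#' @param rule,ratio_threshold,delta As in [decide_significance()].
#' @param constraint Rate model used for fitting (`"symmetric"` or
#'   `"asymmetric"`).
#' @param shared_rates Fit once on the first tree and reuse the rates.
#' @param n_starts,seed,root_prior As in [fit_mk2()].
#' @return An `ensemble_asr`: node definition, effective `n_trees`,
#'   `fraction_state0`, `fraction_state1`, `fraction_inconclusive`, the
#'   rule used, and the per-tree table.
#' @export
ensemble_asr <- function(ensemble, trait, node_tips,
                         rule = c("ratio", "two_log_units"),
                         ratio_threshold = 7.4, delta = 2,
                         constraint = c("symmetric", "asymmetric"),
                         shared_rates = FALSE, n_starts = 10, seed = 1,
                         root_prior = NULL) {
  stopifnot(inherits(ensemble, "tree_ensemble"))
  rule <- match.arg(rule)
  constraint <- match.arg(constraint)
  mapping <- map_node_across_ensemble(ensemble, node_tips)
  shared_model <- NULL
  if (shared_rates)
    shared_model <- fit_mk2(ensemble$trees[[1L]], trait, constraint,
                            n_starts, seed, root_prior)$model
  n <- length(ensemble$trees)
  calls <- character(n)
  details <- vector("list", n)
  n_failed <- 0L
  for (i in seq_len(n)) {
    tr <- ensemble$trees[[i]]
    res <- tryCatch({
      model <- shared_model %||%
        fit_mk2(tr, trait, constraint, n_starts, seed + i, root_prior)$model
      rec <- reconstruct_node(tr, trait, model, mapping$node[i], root_prior)
      list(rec = rec,
           call = decide_significance(rec, rule, ratio_threshold, delta))
    }, error = function(e) NULL)
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      calls[i] <- NA_character_
    } else {
      calls[i] <- res$call
      details[[i]] <- data.frame(
        tree = i, node = mapping$node[i], exact = mapping$exact[i],
        p_state0 = res$rec$proportional[1L],
        p_state1 = res$rec$proportional[2L],
        ratio = res$rec$ratio, call = res$call)
    }
  }
  if (n_failed > 0L)
    warning(n_failed, " tree(s) excluded after optimizer failure",
            call. = FALSE)
  ok <- !is.na(calls)
  n_eff <- sum(ok)
  if (n_eff == 0L) stop("reconstruction failed on every tree",
                        call. = FALSE)
  structure(list(node_definition = node_tips,
                 n_trees = n_eff,
                 fraction_state0 = mean(calls[ok] == "state0"),
                 fraction_state1 = mean(calls[ok] == "state1"),
                 fraction_inconclusive = mean(calls[ok] == "inconclusive"),
                 rule = rule,
                 per_tree = do.call(rbind, details[ok])),
            class = "ensemble_asr")
}

#' @export
print.ensemble_asr <- function(x, ...) {
  cat(sprintf(paste0("Ensemble ASR (%d trees, rule = %s):\n",
                     "  state0 significant: %.1f%%\n",
                     "  state1 significant: %.1f%%\n",
                     "  inconclusive:       %.1f%%\n"),
              x$n_trees, x$rule, 100 * x$fraction_state0,
              100 * x$fraction_state1, 100 * x$fraction_inconclusive))
  invisible(x)
}
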