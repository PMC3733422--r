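#' Two-state continuous-time Markov model
#'
#' Rates are per unit branch length (expected substitutions per site on the
#' input tree). `q01` is the gain rate (0 to 1), `q10` the loss rate.
#'
#' @param q01,q10 Strictly positive transition rates.
#' @param constraint `"asymmetric"` (free rates) or `"symmetric"`
#'   (`q01 = q10`).
#' @return A `two_state_model`.
#' @export
two_state_model <- function(q01, q10 = q01,
                            constraint = c("asymmetric", "symmetric")) {
  constraint <- match.arg(constraint)
  if (constraint == "symmetric" && !isTRUE(all.equal(q01, q10)))
    stop("symmetric model requires q01 == q10", call. = FALSE)
  if (!is.finite(q01) || !is.finite(q10) || q01 <= 0 || q10 <= 0)
    stop("rates must be finite and strictly positive", call. = FALSE)
  structure(list(q01 = q01, q10 = q10, constraint = constraint),
            class = "two_state_model")
}

#' Four-state model for a pair of binary traits
#'
#' Joint states are indexed 1 = (0,0), 2 = (0,1), 3 = (1,0), 4 = (1,1) for
#' the pair (X = habitat, Y = morphology). Single-trait transitions have
#' free rates; dual transitions (1<->4, 2<->3) are structurally 0. In
#' independent mode each trait's rates do not depend on the other trait's
#' state (`q12 = q34`, `q13 = q24`, `q21 = q43`, `q31 = q42`; 4 free
#' parameters); in dependent mode all 8 rates are free.
#'
#' @param rates Named numeric vector with elements `q12, q13, q21, q24,
#'   q31, q34, q42, q43`, all strictly positive.
#' @param mode `"dependent"` or `"independent"`.
#' @return A `four_state_model`.
#' @export
four_state_model <- function(rates, mode = c("dependent", "independent")) {
  mode <- match.arg(mode)
  need <- c("q12", "q13", "q21", "q24", "q31", "q34", "q42", "q43")
  if (!all(need %in% names(rates)))
    stop("rates must name all of: ", paste(need, collapse = ", "),
         call. = FALSE)
  rates <- rates[need]
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("rates must be finite and strictly positive", call. = FALSE)
  if (mode == "independent") {
    eq <- c(abs(rates["q12"] - rates["q34"]), abs(rates["q13"] - rates["q24"]),
            abs(rates["q21"] - rates["q43"]), abs(rates["q31"] - rates["q42"]))
    if (any(eq > 1e-12 * (1 + max(rates))))
      stop("independent mode requires q12=q34, q13=q24, q21=q43, q31=q42",
           call. = FALSE)
  }
  structure(list(rates = as.list(rates), mode = mode),
            class = "four_state_model")
}

#' Independent four-state model from two marginal two-state models
#'
#' @param model_x,model_y `two_state_model`s for the two traits.
#' @return A `four_state_model` in independent mode.
#' @export
independent_model <- function(model_x, model_y) {
  four_state_model(c(q12 = model_y$q01, q13 = model_x$q01,
                     q21 = model_y$q10, q24 = model_x$q01,
                     q31 = model_x$q10, q34 = model_y$q01,
                     q42 = model_x$q10, q43 = model_y$q10),
                   mode = "independent")
}

#' Instantaneous rate matrix of a model
#'
#' Off-diagonals hold the transition rates (dual transitions 0 for the
#' four-state model); each diagonal is minus its row sum.
#'
#' @param model A `two_state_model` or `four_state_model`.
#' @return A k x k rate matrix.
#' @export
rate_matrix <- function(model) UseMethod("rate_matrix")

#' @export
rate_matrix.two_state_model <- function(model) {
  matrix(c(-model$q01, model$q01, model$q10, -model$q10),
         2, 2, byrow = TRUE, dimnames = list(0:1, 0:1))
}

#' @export
rate_matrix.four_state_model <- function(model) {
  r <- model$rates
  Q <- matrix(0, 4, 4, dimnames = list(1:4, 1:4))
  Q[1, 2] <- r$q12; Q[1, 3] <- r$q13
  Q[2, 1] <- r$q21; Q[2, 4] <- r$q24
  Q[3, 1] <- r$q31; Q[3, 4] <- r$q34
  Q[4, 2] <- r$q42; Q[4, 3] <- r$q43
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition-probability matrix over a branch
#'
#' For the two-state model the closed form is used: with
#' `lambda = q01 + q10`, `P00 = (q10 + q01 exp(-lambda t)) / lambda` and
#' `P11 = (q01 + q10 exp(-lambda t)) / lambda`. The four-state matrix is
#' the matrix exponential of the rate matrix.
#'
#' @param model A `two_state_model` or `four_state_model`.
#' @param t Branch length, `t >= 0`.
#' @return A row-stochastic k x k matrix.
#' @export
transition_matrix <- function(model, t) {
  if (!is.finite(t) || t < 0)
    stop("branch length must be finite and non-negative", call. = FALSE)
  cpp_ctmc_prob(rate_matrix(model), t)
}

# Joint-state partial-likelihood row for a tip given (x, y) in {0,1,NA}.
joint_tip_partial <- function(x, y) {
  px <- if (is.na(x)) c(1, 1) else as.numeric(0:1 == x)
  py <- if (is.na(y)) c(1, 1) else as.numeric(0:1 == y)
  # state order 1=(0,0), 2=(0,1), 3=(1,0), 4=(1,1)
  c(px[1] * py[1], px[1] * py[2], px[2] * py[1], px[2] * py[2])
}

# Build (n_nodes x k) partial matrix: tip rows from states, internal ones.
build_partials <- function(tree, states, k) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  part <- matrix(1, n_all, k)
  if (k == 2L) {
    for (i in seq_len(n_tip)) {
      s <- states[i]
      if (!is.na(s)) part[i, ] <- as.numeric(0:1 == s)
    }
  } else {
    for (i in seq_len(n_tip)) {
      part[i, ] <- joint_tip_partial(states[[1L]][i], states[[2L]][i])
    }
  }
  part
}

resolve_states <- function(tree, trait) {
  if (inherits(trait, "binary_trait")) {
    suppressWarnings(align_trait_to_tree(trait, tree))
  } else {
    s <- trait[tree$tip.label]
    if (anyNA(names(s)) || length(s) != length(tree$tip.label))
      stop("trait must cover the tree's tips (named 0/1/NA vector)",
           call. = FALSE)
    as.integer(s)
  }
}

#' Pruning-algorithm log-likelihood of tip data under an Mk model
#'
#' Felsenstein's post-order pruning with per-edge rescaling. Missing tip
#' states contribute an all-ones partial; for a trait pair, a tip missing
#' one trait is ambiguous over the two compatible joint states. Optionally
#' one internal node's state can be fixed (conditioning its partial on a
#' single state — the "fossilizing" used for marginal ancestral-state
#' reconstruction).
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param trait A `binary_trait` (or named 0/1/NA vector) for a
#'   `two_state_model`; a list of two of them for a `four_state_model`
#'   (order: X = habitat, Y = morphology).
#' @param model A `two_state_model` or `four_state_model`.
#' @param root_prior Prior over root states; default uniform.
#' @param fix_node Internal node id to fix, or `NULL`.
#' @param fix_state State to fix the node to: 0/1 (two-state) or 1..4
#'   (joint state index, four-state).
#' @return Log-likelihood (natural log).
#' @export
prune_loglik <- function(tree, trait, model, root_prior = NULL,
                         fix_node = NULL, fix_state = NULL) {
  tree <- validate_tree(tree)
  Q <- rate_matrix(model)
  k <- nrow(Q)
  states <- if (k == 2L) resolve_states(tree, trait)
            else lapply(trait, resolve_states, tree = tree)
  part <- build_partials(tree, states, k)
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  if (length(root_prior) != k || any(root_prior < 0) ||
      abs(sum(root_prior) - 1) > 1e-9)
    stop("root prior must be a length-", k, " probability vector",
         call. = FALSE)
  fn <- 0L; fs <- 0L
  if (!is.null(fix_node)) {
    if (fix_node <= length(tree$tip.label))
      stop("cannot fix a tip node; fixing is for internal nodes",
           call. = FALSE)
    fn <- as.integer(fix_node)
    fs <- if (k == 2L) as.integer(fix_state) + 1L else as.integer(fix_state)
    if (fs < 1L || fs > k) stop("fix_state out of range", call. = FALSE)
  }
  tre <- ape::reorder.phylo(tree, "postorder")
  cpp_prune_loglik(tre$edge, tre$edge.length, part, Q, root_prior, fn, fs)
}

# ---- maximum-likelihood fitting -------------------------------------------

rate_bounds <- c(1e-4, 100)

# Deterministic + seeded random starts in log-rate space.
make_starts <- function(n_par, n_starts, seed) {
  starts <- list(rep(log(1), n_par))
  if (n_starts > 1L) {
    rs <- local_seed_runif((n_starts - 1L) * n_par, seed)
    extra <- matrix(log(1e-2) + rs * (log(10) - log(1e-2)),
                    ncol = n_par)
    starts <- c(starts, lapply(seq_len(nrow(extra)),
                               function(i) extra[i, ]))
  }
  starts
}

# runif under a private RNG state so fitting never disturbs the caller's.
local_seed_runif <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  runif(n)
}

optimise_loglik <- function(obj, starts) {
  lb <- log(rate_bounds[1L]); ub <- log(rate_bounds[2L])
  best <- NULL
  n_used <- 0L
  any_conv <- FALSE
  for (st in starts) {
    n_used <- n_used + 1L
    fit <- tryCatch(
      optim(pmin(pmax(st, lb), ub), obj, method = "L-BFGS-B",
            lower = lb, upper = ub, control = list(factr = 1e7)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (fit$convergence == 0L) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("optimizer failed from every start", call. = FALSE)
  list(par = best$par, loglik = -best$value, converged = any_conv,
       n_starts_used = n_used)
}

#' Fit a two-state Mk model by maximum likelihood
#'
#' Maximizes the pruning log-likelihood over log-rates bounded in
#' `[1e-4, 100]` with L-BFGS-B from multiple starts (one at equal rates,
#' the rest drawn log-uniform under the seed). Deterministic given `seed`.
#'
#' @param tree A rooted `phylo` (or a list/`tree_ensemble`, fitted per
#'   tree).
#' @param trait A `binary_trait` or named 0/1/NA vector.
#' @param constraint `"symmetric"` (one rate) or `"asymmetric"` (two).
#' @param n_starts Number of optimizer starts (default 10).
#' @param seed Integer seed for the random starts.
#' @param root_prior Root state prior; default uniform.
#' @return A `mk_fit`: list with `model`, `log_likelihood`, `converged`,
#'   `n_starts_used`. For multiple trees, a list of `mk_fit`.
#' @export
fit_mk2 <- function(tree, trait, constraint = c("asymmetric", "symmetric"),
                    n_starts = 10, seed = 1, root_prior = NULL) {
  constraint <- match.arg(constraint)
  if (inherits(tree, "tree_ensemble")) tree <- tree$trees
  if (is.list(tree) && !inherits(tree, "phylo"))
    return(lapply(seq_along(tree), function(i)
      fit_mk2(tree[[i]], trait, constraint, n_starts, seed + i - 1L,
              root_prior)))
  tree <- validate_tree(tree)
  states <- resolve_states(tree, trait)
  part <- build_partials(tree, states, 2L)
  tre <- ape::reorder.phylo(tree, "postorder")
  prior <- root_prior %||% c(0.5, 0.5)
  n_par <- if (constraint == "symmetric") 1L else 2L
  obj <- function(lp) {
    r <- exp(lp)
    q <- if (n_par == 1L) c(r, r) else r
    Q <- matrix(c(-q[1L], q[1L], q[2L], -q[2L]), 2, 2, byrow = TRUE)
    -cpp_prune_loglik(tre$edge, tre$edge.length, part, Q, prior, 0L, 0L)
  }
  res <- optimise_loglik(obj, make_starts(n_par, n_starts, seed))
  r <- exp(res$par)
  model <- if (n_par == 1L) two_state_model(r, r, "symmetric")
           else two_state_model(r[1L], r[2L], "asymmetric")
  structure(list(model = model, log_likelihood = res$loglik,
                 converged = res$converged,
                 n_starts_used = res$n_starts_used),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  m <- x$model
  if (inherits(m, "two_state_model")) {
    cat(sprintf("Mk fit (%s): q01 = %.4g, q10 = %.4g, lnL = %.4f%s\n",
                m$constraint, m$q01, m$q10, x$log_likelihood,
                if (x$converged) "" else " [NOT CONVERGED]"))
  } else {
    cat(sprintf("Pagel %s model fit: lnL = %.4f%s\n", m$mode,
                x$log_likelihood,
                if (x$converged) "" else " [NOT CONVERGED]"))
    print(round(unlist(m$rates), 4))
  }
  invisible(x)
}

# Map a free-parameter vector to the 8 named rates.
pagel_rates <- function(r, mode) {
  if (mode == "independent") {
    # r = (x gain q13, x loss q31, y gain q12, y loss q21)
    c(q12 = r[3L], q13 = r[1L], q21 = r[4L], q24 = r[1L],
      q31 = r[2L], q34 = r[3L], q42 = r[2L], q43 = r[4L])
  } else {
    c(q12 = r[1L], q13 = r[2L], q21 = r[3L], q24 = r[4L],
      q31 = r[5L], q34 = r[6L], q42 = r[7L], q43 = r[8L])
  }
}

#' Fit the four-state model for a trait pair
#'
#' Independent mode has 4 free rates, dependent mode 8; the two differ by
#' 4 degrees of freedom. In dependent mode one extra start is seeded from
#' the independent-mode optimum, which guarantees the nested-model
#' inequality `lnL_dep >= lnL_indep` up to optimizer tolerance.
#'
#' @param tree A rooted `phylo`.
#' @param trait_x,trait_y `binary_trait`s (X = habitat, Y = morphology).
#' @param mode `"independent"` or `"dependent"`.
#' @param n_starts,seed,root_prior As in [fit_mk2()].
#' @param init Optional `four_state_model` used as an additional start.
#' @return A `mk_fit` whose `model` is a `four_state_model`.
#' @export
fit_mk4 <- function(tree, trait_x, trait_y,
                    mode = c("independent", "dependent"),
                    n_starts = 10, seed = 1, root_prior = NULL,
                    init = NULL) {
  mode <- match.arg(mode)
  tree <- validate_tree(tree)
  states <- list(resolve_states(tree, trait_x),
                 resolve_states(tree, trait_y))
  part <- build_partials(tree, states, 4L)
  tre <- ape::reorder.phylo(tree, "postorder")
  prior <- root_prior %||% rep(0.25, 4)
  n_par <- if (mode == "independent") 4L else 8L
  obj <- function(lp) {
    rates <- pagel_rates(exp(lp), mode)
    Q <- matrix(0, 4, 4)
    Q[1, 2] <- rates["q12"]; Q[1, 3] <- rates["q13"]
    Q[2, 1] <- rates["q21"]; Q[2, 4] <- rates["q24"]
    Q[3, 1] <- rates["q31"]; Q[3, 4] <- rates["q34"]
    Q[4, 2] <- rates["q42"]; Q[4, 3] <- rates["q43"]
    diag(Q) <- -rowSums(Q)
    -cpp_prune_loglik(tre$edge, tre$edge.length, part, Q, prior, 0L, 0L)
  }
  starts <- make_starts(n_par, n_starts, seed)
  if (mode == "dependent" && is.null(init)) {
    ind <- fit_mk4(tree, trait_x, trait_y, "independent",
                   n_starts = max(3L, n_starts %/% 2L), seed = seed,
                   root_prior = root_prior)
    init <- ind$model
  }
  if (!is.null(init)) {
    r <- unlist(init$rates)
    st <- if (mode == "independent")
      log(c(r["q13"], r["q31"], r["q12"], r["q21"]))
    else log(r[c("q12", "q13", "q21", "q24", "q31", "q34", "q42", "q43")])
    starts <- c(list(unname(st)), starts)
  }
  res <- optimise_loglik(obj, starts)
  model <- four_state_model(pagel_rates(exp(res$par), mode), mode = mode)
  structure(list(model = model, log_likelihood = res$loglik,
                 converged = res$converged,
                 n_starts_used = res$n_starts_used),
            class = "mk_fit")
}

#' Single-rate versus asymmetric-rate likelihood-ratio test
#'
#' Fits the symmetric (1-parameter) and asymmetric (2-parameter) two-state
#' models and compares them by a chi-square LRT with 1 degree of freedom.
#' When the two optima differ by less than 1e-6 log-units the statistic is
#' reported as 0 to suppress numerical noise.
#'
#' @inheritParams fit_mk2
#' @return List: `lnl_symmetric`, `lnl_asymmetric`, `statistic`, `df`,
#'   `p_value`, and the two fits.
#' @export
rate_model_lrt <- function(tree, trait, n_starts = 10, seed = 1,
                           root_prior = NULL) {
  fit_sym <- fit_mk2(tree, trait, "symmetric", n_starts, seed, root_prior)
  fit_asym <- fit_mk2(tree, trait, "asymmetric", n_starts, seed, root_prior)
  # the symmetric optimum is a valid asymmetric start; enforce nesting
  if (fit_asym$log_likelihood < fit_sym$log_likelihood) {
    fit_asym$model <- two_state_model(fit_sym$model$q01, fit_sym$model$q10,
                                      "asymmetric")
    fit_asym$log_likelihood <- fit_sym$log_likelihood
  }
  delta <- fit_asym$log_likelihood - fit_sym$log_likelihood
  stat <- if (delta < 1e-6) 0 else 2 * delta
  list(lnl_symmetric = fit_sym$log_likelihood,
       lnl_asymmetric = fit_asym$log_likelihood,
       statistic = stat, df = 1L, p_value = chi2_sf(stat, 1L),
       fit_symmetric = fit_sym, fit_asymmetric = fit_asym)
}
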