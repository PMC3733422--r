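#' Upper-tail chi-square probability
#'
#' The survival function of the chi-square distribution, used for every
#' likelihood-ratio test in the package. For even degrees of freedom it
#' equals the closed form `exp(-x/2) * sum_{k < df/2} (x/2)^k / k!`.
#'
#' @param x Test statistic, `x >= 0`.
#' @param df Positive integer degrees of freedom.
#' @return Upper-tail probability.
#' @export
chi2_sf <- function(x, df) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("chi-square statistic must be finite and non-negative",
         call. = FALSE)
  pchisq(x, df = df, lower.tail = FALSE)
}

#' Pagel's test of correlated evolution for a trait pair
#'
#' Per tree, fits the four-state model in independent (4 free rates) and
#' dependent (8 free rates) mode; the per-model log-likelihoods are then
#' aggregated across trees (median by default) and compared by a
#' chi-square LRT with 4 degrees of freedom:
#' `statistic = 2 |agg(lnL_dep) - agg(lnL_indep)|`. Per tree the nested
#' models satisfy `lnL_dep >= lnL_indep`; median aggregation across trees
#' can in principle reverse the sign, which is recorded as a warning.
#'
#' @param ensemble A [tree_ensemble()], `phylo`, or list of `phylo`.
#' @param habitat_trait,morph_trait `binary_trait`s over the shared tips.
#' @param aggregation `"median"`, `"mean"` or `"best_tree"` (tree 1,
#'   conventionally the best ML tree placed first in the ensemble).
#' @param n_starts,seed,root_prior As in [fit_mk4()].
#' @return A `pagel_result`: aggregated `lnl_independent`,
#'   `lnl_dependent`, signed `lnl_difference` (dependent - independent),
#'   `statistic`, `df = 4`, `p_value`, effective `n_trees`, `aggregation`,
#'   and the per-tree log-likelihoods.
#' @export
pagel_test <- function(ensemble, habitat_trait, morph_trait,
                       aggregation = c("median", "mean", "best_tree"),
                       n_starts = 10, seed = 1, root_prior = NULL) {
  aggregation <- match.arg(aggregation)
  trees <- if (inherits(ensemble, "tree_ensemble")) ensemble$trees
           else if (inherits(ensemble, "phylo")) list(ensemble)
           else lapply(ensemble, identity)
  n <- length(trees)
  lnl_ind <- lnl_dep <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fits <- tryCatch({
      fi <- fit_mk4(trees[[i]], habitat_trait, morph_trait, "independent",
                    n_starts, seed + i, root_prior)
      fd <- fit_mk4(trees[[i]], habitat_trait, morph_trait, "dependent",
                    n_starts, seed + i, root_prior, init = fi$model)
      list(fi = fi, fd = fd)
    }, error = function(e) NULL)
    if (is.null(fits)) next
    lnl_ind[i] <- fits$fi$log_likelihood
    lnl_dep[i] <- fits$fd$log_likelihood
  }
  ok <- is.finite(lnl_ind) & is.finite(lnl_dep)
  if (!any(ok)) stop("model fitting failed on every tree", call. = FALSE)
  if (any(!ok))
    warning(sum(!ok), " tree(s) excluded after fit failure", call. = FALSE)
  agg <- switch(aggregation,
                median = stats::median,
                mean = mean,
                best_tree = function(v) v[1L])
  a_ind <- agg(lnl_ind[ok])
  a_dep <- agg(lnl_dep[ok])
  diff <- a_dep - a_ind
  if (diff < -1e-6)
    warning("aggregated dependent lnL below independent lnL (median ",
            "aggregation across trees)", call. = FALSE)
  stat <- 2 * abs(diff)
  structure(list(lnl_independent = a_ind,
                 lnl_dependent = a_dep,
                 lnl_difference = diff,
                 statistic = stat,
                 df = 4L,
                 p_value = chi2_sf(stat, 4L),
                 n_trees = sum(ok),
                 aggregation = aggregation,
                 per_tree = data.frame(tree = which(ok),
                                       lnl_independent = lnl_ind[ok],
                                       lnl_dependent = lnl_dep[ok])),
            class = "pagel_result")
}

#' @export
print.pagel_result <- function(x, ...) {
  cat(sprintf(paste0("Pagel correlation test (%d tree%s, %s lnL):\n",
                     "  lnL independent: %.4f\n",
                     "  lnL dependent:   %.4f\n",
                     "  LRT statistic:   %.4f (df = 4), p = %.4f\n"),
              x$n_trees, if (x$n_trees > 1L) "s" else "", x$aggregation,
              x$lnl_independent, x$lnl_dependent, x$statistic, x$p_value))
  invisible(x)
}

#' Habitat-by-trait correlation table
#'
#' Runs [pagel_test()] for habitat against each listed morphological
#' character and assembles the results into one table (trait pair,
#' aggregated log-likelihoods, difference, chi-square p). A character that
#' is constant across scored taxa carries no signal: its row is flagged
#' degenerate and reported with p = 1 under a warning.
#'
#' @param ensemble A [tree_ensemble()] or `phylo`.
#' @param matrix A `character_matrix`.
#' @param habitat Name of the habitat character (default `"habitat"`).
#' @param traits Character names to test; default all non-habitat columns.
#' @param aggregation,n_starts,seed,root_prior As in [pagel_test()].
#' @return Data frame with one row per trait and attribute `results`
#'   holding the full `pagel_result` objects.
#' @export
correlation_table <- function(ensemble, matrix, habitat = "habitat",
                              traits = NULL,
                              aggregation = "median",
                              n_starts = 10, seed = 1, root_prior = NULL) {
  stopifnot(inherits(matrix, "character_matrix"))
  if (!habitat %in% colnames(matrix))
    stop("habitat character '", habitat, "' not in matrix", call. = FALSE)
  traits <- traits %||% setdiff(colnames(matrix), habitat)
  missing_tr <- setdiff(traits, colnames(matrix))
  if (length(missing_tr))
    stop("character(s) not in matrix: ", paste(missing_tr, collapse = ", "),
         call. = FALSE)
  hab <- binarize(matrix, habitat)
  rows <- list()
  results <- list()
  for (j in seq_along(traits)) {
    tr <- binarize(matrix, traits[j])
    obs <- tr$tip_states[!is.na(tr$tip_states)]
    if (length(unique(obs)) < 2L) {
      warning("character '", traits[j],
              "' is constant; no correlation signal, p reported as 1",
              call. = FALSE)
      rows[[j]] <- data.frame(trait_pair = paste(habitat, "x", traits[j]),
                              lnl_independent = NA_real_,
                              lnl_dependent = NA_real_,
                              lnl_difference = NA_real_,
                              statistic = 0, df = 4L, p_value = 1,
                              n_trees = 0L, degenerate = TRUE)
      next
    }
    res <- pagel_test(ensemble, hab, tr, aggregation, n_starts,
                      seed + 1000L * j, root_prior)
    results[[traits[j]]] <- res
    rows[[j]] <- data.frame(trait_pair = paste(habitat, "x", traits[j]),
                            lnl_independent = res$lnl_independent,
                            lnl_dependent = res$lnl_dependent,
                            lnl_difference = res$lnl_difference,
                            statistic = res$statistic, df = 4L,
                            p_value = res$p_value, n_trees = res$n_trees,
                            degenerate = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}

#' Recompute chi-square p-values from printed log-likelihood differences
#'
#' Given a table of independent/dependent model log-likelihood differences
#' (as published in correlation analyses of this kind), recomputes the
#' p-value for each row as `chi2_sf(2 |difference|, df = 4)`. Useful for
#' auditing published tables without refitting anything.
#'
#' @param x A data frame with a `lnl_difference` column (and optionally a
#'   `trait_pair` column), or a path to a TSV with those columns.
#' @return The input with a `p_recomputed` column (and a `p_printed_4dp`
#'   convenience column rounded to 4 decimals).
#' @export
verify_published_pvalues <- function(x) {
  if (is.character(x)) x <- read.delim(x, check.names = FALSE)
  if (!"lnl_difference" %in% names(x))
    stop("need a 'lnl_difference' column", call. = FALSE)
  x$p_recomputed <- chi2_sf(2 * abs(x$lnl_difference), 4L)
  x$p_printed_4dp <- round(x$p_recomputed, 4)
  x
}
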