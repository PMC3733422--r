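#' Describe a data-partitioning scheme for BIC comparison
#'
#' Holds the quantities needed to score a partitioning strategy whose tree
#' search was run elsewhere: the scheme's log-likelihood, its count of
#' free substitution-model parameters, the alignment length, and the
#' number of branch-length parameters (which must be identical across the
#' schemes being compared, so that branch lengths cancel from every
#' pairwise BIC difference).
#'
#' @param name Scheme label, e.g. `"16-part"`.
#' @param log_likelihood Log-likelihood (natural log) from the external
#'   analysis.
#' @param n_free_parameters Free substitution-model parameters (>= 1).
#'   With one GTR+GAMMA model per partition the conventional count is 9
#'   per partition (5 exchangeabilities + 3 free base frequencies + 1
#'   gamma shape).
#' @param n_sites Alignment columns (>= 1).
#' @param n_branch_lengths Branch-length parameter count, recorded for the
#'   comparability check.
#' @return A `partition_scheme`.
#' @export
partition_scheme <- function(name, log_likelihood, n_free_parameters,
                             n_sites, n_branch_lengths = 0L) {
  stopifnot(is.finite(log_likelihood), n_free_parameters >= 1,
            n_sites >= 1)
  structure(list(name = as.character(name),
                 log_likelihood = log_likelihood,
                 n_free_parameters = as.integer(n_free_parameters),
                 n_sites = as.integer(n_sites),
                 n_branch_lengths = as.integer(n_branch_lengths)),
            class = "partition_scheme")
}

#' Modified BIC of a partitioning scheme
#'
#' `BIC = -2 lnL + k ln(n_sites)` with `k` the free substitution-model
#' parameters only. Branch-length parameters are excluded: holding their
#' number constant across the compared schemes makes them cancel from all
#' BIC differences, so the ranking is identical to standard BIC.
#'
#' @param scheme A `partition_scheme`.
#' @return The BIC score.
#' @export
modified_bic <- function(scheme) {
  stopifnot(inherits(scheme, "partition_scheme"))
  -2 * scheme$log_likelihood +
    scheme$n_free_parameters * log(scheme$n_sites)
}

#' Rank partitioning schemes by modified BIC
#'
#' All schemes must share the same `n_sites` and `n_branch_lengths`
#' (otherwise the branch-length cancellation does not hold and the call
#' errors). Ties are broken by fewer parameters, then by name.
#'
#' @param schemes A list of [partition_scheme()]s, length >= 2.
#' @return Data frame sorted by ascending BIC with a `delta_bic` column
#'   relative to the best scheme.
#' @export
select_scheme <- function(schemes) {
  if (length(schemes) < 2L)
    stop("need at least two schemes to compare", call. = FALSE)
  stopifnot(all(vapply(schemes, inherits, logical(1), "partition_scheme")))
  nbl <- vapply(schemes, `[[`, integer(1), "n_branch_lengths")
  ns <- vapply(schemes, `[[`, integer(1), "n_sites")
  if (length(unique(nbl)) != 1L)
    stop("schemes differ in n_branch_lengths; comparison is invalid",
         call. = FALSE)
  if (length(unique(ns)) != 1L)
    stop("schemes differ in n_sites; comparison is invalid", call. = FALSE)
  df <- data.frame(
    scheme = vapply(schemes, `[[`, character(1), "name"),
    log_likelihood = vapply(schemes, `[[`, numeric(1), "log_likelihood"),
    n_free_parameters = vapply(schemes, `[[`, integer(1),
                               "n_free_parameters"),
    n_sites = ns,
    bic = vapply(schemes, modified_bic, numeric(1)))
  ord <- order(df$bic, df$n_free_parameters, df$scheme)
  df <- df[ord, , drop = FALSE]
  df$delta_bic <- df$bic - df$bic[1L]
  rownames(df) <- NULL
  df
}

#' Read partitioning schemes from CSV
#'
#' Expects columns `scheme`, `lnl`, `k`, `n_sites` and optionally
#' `n_branch_lengths`.
#'
#' @param path CSV path.
#' @return List of [partition_scheme()]s.
#' @export
read_partition_schemes <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  need <- c("scheme", "lnl", "k", "n_sites")
  if (!all(need %in% names(df)))
    stop("CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  nbl <- if ("n_branch_lengths" %in% names(df)) df$n_branch_lengths
         else rep(0L, nrow(df))
  lapply(seq_len(nrow(df)), function(i)
    partition_scheme(df$scheme[i], df$lnl[i], df$k[i], df$n_sites[i],
                     nbl[i]))
}
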