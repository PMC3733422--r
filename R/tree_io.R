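#' Parse a newick string into a validated rooted tree
#'
#' Wraps [ape::read.tree()] and enforces the invariants every downstream
#' likelihood computation relies on: a single root, unique non-empty tip
#' labels, at least two tips, and finite non-negative branch lengths.
#' Branches without a stated length (including the whole tree when no
#' lengths are given) are set to 0; polytomies are accepted.
#'
#' @param text A newick string (one tree).
#' @return An object of class `phylo`.
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("newick parse error: empty input", call. = FALSE)
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("newick parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(tr))
    stop("newick parse error: no tree could be read from input",
         call. = FALSE)
  validate_tree(tr)
}

#' Validate a phylo object against the package's tree invariants
#'
#' @param tree A `phylo` object.
#' @return The tree, with missing branch lengths replaced by 0.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  n_tip <- length(tree$tip.label)
  if (n_tip < 2L) stop("tree must have at least 2 tips", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(tree$tip.label)))
    stop("empty tip label", call. = FALSE)
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else {
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  bad <- !is.finite(tree$edge.length) | tree$edge.length < 0
  if (any(bad))
    stop("non-finite or negative branch length on ", sum(bad), " edge(s)",
         call. = FALSE)
  parents <- unique(tree$edge[, 1])
  roots <- setdiff(parents, tree$edge[, 2])
  if (length(roots) != 1L)
    stop("tree must have exactly one root", call. = FALSE)
  tab <- tabulate(tree$edge[, 2])
  if (any(tab > 1L))
    stop("a node has more than one parent", call. = FALSE)
  tree
}

#' Serialize a tree to newick
#'
#' Round-trips with [parse_newick()]: topology, labels and branch lengths
#' are preserved to 10 significant digits.
#'
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths.
#' @return A newick string.
#' @export
write_newick <- function(tree, digits = 10) {
  ape::write.tree(tree, digits = digits)
}

#' Read a tree ensemble from a newick file (one tree per line)
#'
#' All member trees must share an identical tip-label set; each tree is
#' validated as in [parse_newick()].
#'
#' @param x Path to a newick file, a `multiPhylo`, or a list of `phylo`.
#' @param source_tag Free-text provenance tag, e.g. `"bootstrap"`.
#' @return A `tree_ensemble`: list with elements `trees` (list of `phylo`)
#'   and `source_tag`.
#' @export
tree_ensemble <- function(x, source_tag = "bootstrap") {
  if (is.character(x)) {
    x <- ape::read.tree(x, keep.multi = TRUE)
  }
  if (inherits(x, "phylo")) x <- list(x)
  trees <- lapply(unclass(x), validate_tree)
  if (length(trees) < 1L) stop("ensemble must contain at least one tree",
                               call. = FALSE)
  tips <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), tips))
      stop("tree ", i, " does not share the ensemble tip-label set",
           call. = FALSE)
  }
  structure(list(trees = trees, source_tag = source_tag),
            class = "tree_ensemble")
}

#' @export
print.tree_ensemble <- function(x, ...) {
  cat("Tree ensemble (", x$source_tag, "): ", length(x$trees),
      " trees over ", length(x$trees[[1L]]$tip.label), " tips\n", sep = "")
  invisible(x)
}

#' @export
length.tree_ensemble <- function(x) length(x$trees)

#' Most recent common ancestor of a set of tips
#'
#' @param tree A `phylo` object.
#' @param tips Character vector of at least two tip labels.
#' @return The MRCA node id (ape numbering: tips are `1..n`, internal nodes
#'   `n+1..`).
#' @export
mrca_node <- function(tree, tips) {
  tips <- unique(as.character(tips))
  if (length(tips) < 2L)
    stop("need at least two tip labels to define an MRCA", call. = FALSE)
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  ape::getMRCA(tree, tips)
}

#' Tip labels subtended by a node
#' @param tree A `phylo` object.
#' @param node Node id.
#' @return Character vector of tip labels in the node's clade.
#' @export
clade_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  idx <- phangorn::Descendants(tree, node, type = "tips")[[1L]]
  tree$tip.label[idx]
}

#' Track a node across a tree ensemble by its defining tip set
#'
#' For every ensemble tree, finds the MRCA of `defining_tips`. When the
#' clade is non-monophyletic in a replicate the MRCA subtends extra tips;
#' this is recorded in the `exact` flag rather than treated as an error.
#'
#' @param ensemble A [tree_ensemble()].
#' @param defining_tips Tip labels defining the node (length >= 2).
#' @return Data frame with one row per tree: `tree`, `node`, `n_subtended`,
#'   `exact` (TRUE when the MRCA subtends exactly the defining tips).
#' @export
map_node_across_ensemble <- function(ensemble, defining_tips) {
  stopifnot(inherits(ensemble, "tree_ensemble"))
  defining_tips <- unique(as.character(defining_tips))
  if (length(defining_tips) < 2L)
    stop("need at least two defining tips", call. = FALSE)
  rows <- lapply(seq_along(ensemble$trees), function(i) {
    tr <- ensemble$trees[[i]]
    nd <- mrca_node(tr, defining_tips)
    ct <- clade_tips(tr, nd)
    data.frame(tree = i, node = nd, n_subtended = length(ct),
               exact = setequal(ct, defining_tips))
  })
  do.call(rbind, rows)
}

#' Structural diagnostics for a tree or ensemble
#'
#' Reports tip counts, polytomy counts and zero-length branch counts —
#' the checks a user runs before trusting a bootstrap file.
#'
#' @param x A `phylo` or a [tree_ensemble()].
#' @return Data frame with one row per tree.
#' @export
tree_diagnostics <- function(x) {
  trees <- if (inherits(x, "tree_ensemble")) x$trees else list(x)
  rows <- lapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    deg <- tabulate(tr$edge[, 1])
    data.frame(tree = i,
               n_tips = length(tr$tip.label),
               n_polytomies = sum(deg > 2L),
               n_zero_branches = sum(tr$edge.length == 0))
  })
  do.call(rbind, rows)
}
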