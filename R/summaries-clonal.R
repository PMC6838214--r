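# Clonal-family and phylogenetic summaries.

#' Cluster size distribution
#'
#' Multiset of clonal-family sizes; the values sum to the number of records
#' carrying a `clone_id`.
#'
#' @param x repertoire data frame with a `clone_id` column.
#' @export
cluster_size_distribution <- function(x) {
  if (!"clone_id" %in% names(x)) abort("clone_id column is absent")
  ids <- x$clone_id[!is.na(x$clone_id)]
  if (length(ids) == 0) abort("clone_id is missing for all records")
  sizes <- as.numeric(table(ids))
  new_rep_dist(sizes, "cluster_size", length(ids))
}

#' Hill diversity numbers
#'
#' With `p_i` the normalized clone frequencies, the Hill number of order `q`
#' is `(sum p_i^q)^(1/(1-q))`; `q = 1` is the exponential Shannon entropy
#' `exp(-sum p_i log p_i)` and `q = 0` is the richness.
#'
#' @param counts a `rep_counts` tibble, a named numeric vector of counts, or
#'   a repertoire data frame with `clone_id` (counted internally).
#' @param q nonnegative diversity order.
#' @return scalar Hill number.
#' @export
#' @examples
#' hill_diversity(c(a = 3, b = 1), q = 2)  # 1.6
hill_diversity <- function(counts, q) {
  if (q < 0) abort("q must be nonnegative")
  if (is.data.frame(counts) && !"count" %in% names(counts)) {
    counts <- setNames(dist_values(cluster_size_distribution(counts)), NULL)
  } else {
    counts <- unname(counts_vector(counts))
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0) abort("need at least one nonzero count")
  p <- counts / sum(counts)
  if (q == 0) return(length(p))
  if (q == 1) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

# --- tree shape indices -----------------------------------------------------

# depths (edge counts from the root) of all nodes of a rooted ape tree
node_depths <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  depth <- rep(NA_real_, n_all)
  root <- n_tip + 1L
  depth[root] <- 0
  # edges are not guaranteed ordered root-down; iterate until resolved
  edges <- tree$edge
  remaining <- rep(TRUE, nrow(edges))
  while (any(remaining)) {
    ready <- remaining & !is.na(depth[edges[, 1]])
    if (!any(ready)) abort("tree is not a rooted connected tree")
    depth[edges[ready, 2]] <- depth[edges[ready, 1]] + 1
    remaining[ready] <- FALSE
  }
  depth
}

sackin_index <- function(tree) {
  n_tip <- length(tree$tip.label)
  sum(node_depths(tree)[seq_len(n_tip)])
}

# cophenetic index: sum over unordered leaf pairs of the depth of their MRCA
cophenetic_index <- function(tree) {
  n_tip <- length(tree$tip.label)
  if (n_tip < 2) return(0)
  depth <- node_depths(tree)
  mrca <- ape::mrca(tree)
  total <- 0
  for (i in seq_len(n_tip - 1)) {
    for (j in (i + 1):n_tip) total <- total + depth[mrca[i, j]]
  }
  total
}

# Colless-like balance index (Mir, Rossello & Rotger) for arbitrary trees:
# sum over internal nodes of the mean deviation of the f-sizes of their child
# subtrees, with f(n) = log(n + e) by default.
colless_like_index <- function(tree, f = function(n) log(n + exp(1)),
                               dissim = c("mdm", "sd", "var")) {
  dissim <- arg_match(dissim)
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  children <- split(tree$edge[, 2], tree$edge[, 1])
  # Mir et al.: delta(v) = sum over nodes u in subtree(v) of f(kappa(u)),
  # where kappa(u) = number of leaves under u; the index is the sum over
  # internal nodes of the dissimilarity of their children's deltas.
  kappa <- rep(0, n_all)
  for (v in postorder_nodes(tree)) {
    kids <- children[[as.character(v)]]
    kappa[v] <- if (is.null(kids)) 1 else sum(kappa[kids])
  }
  delta <- rep(0, n_all)
  for (v in postorder_nodes(tree)) {
    kids <- children[[as.character(v)]]
    delta[v] <- f(kappa[v]) + if (is.null(kids)) 0 else sum(delta[kids])
  }
  dis <- switch(dissim,
    mdm = function(x) mean(abs(x - mean(x))),
    sd = stats::sd,
    var = stats::var
  )
  internal <- (n_tip + 1L):n_all
  sum(vapply(internal, function(v) {
    kids <- children[[as.character(v)]]
    if (length(kids) < 2) return(0)
    dis(delta[kids])
  }, numeric(1)))
}

# nodes in child-before-parent order
postorder_nodes <- function(tree) {
  e <- ape::reorder.phylo(tree, "postorder")$edge
  unique(c(e[, 2], e[nrow(e), 1]))
}

#' Tree shape index distribution
#'
#' One imbalance index per clonal-family tree with at least two leaves (trees
#' below the minimum are skipped):
#' * `sackin` — sum of leaf depths (edge counts from the root);
#' * `colless_like` — Mir et al. Colless-like index with `f(n) = ln(n + e)`
#'   and mean-deviation dissimilarity (both configurable);
#' * `cophenetic` — sum over unordered leaf pairs of the depth of their most
#'   recent common ancestor.
#'
#' @param trees a `clone_trees` list (see [read_clone_trees()]) or a plain
#'   list of `phylo` objects.
#' @param index which index to compute.
#' @param f,dissim Colless-like options: node-size transform and child
#'   dissimilarity (`"mdm"` mean deviation, `"sd"`, `"var"`).
#' @export
tree_shape_indices <- function(trees, index = c("sackin", "colless_like", "cophenetic"),
                               f = function(n) log(n + exp(1)),
                               dissim = "mdm") {
  index <- arg_match(index)
  if (length(trees) == 0) abort("empty tree set")
  trees <- keep(trees, function(t) length(t$tip.label) >= 2)
  if (length(trees) == 0) abort("no tree with >= 2 leaves")
  vals <- vapply(trees, function(t) {
    switch(index,
      sackin = sackin_index(t),
      colless_like = colless_like_index(t, f = f, dissim = dissim),
      cophenetic = cophenetic_index(t)
    )
  }, numeric(1))
  new_rep_dist(unname(vals), paste0(index, "_index"), length(trees))
}
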