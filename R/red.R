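#' Relative evolutionary divergence of every node of a rooted tree
#'
#' RED normalizes node depth on a rooted tree to `[0, 1]`: the root has
#' RED 0, every leaf has RED 1, and an internal node `n` with parent `p`
#' has `red(n) = red(p) + (1 - red(p)) * d / u`, where `d` is the
#' branch length from `p` to `n` and `u` is the mean branch length from
#' `p` to all leaves descending through `n`. RED is invariant under
#' global rescaling of branch lengths and non-decreasing along every
#' root-to-leaf path. A zero-length internal branch gives the child its
#' parent's RED; an internal node whose entire subtree (including its
#' own branch) has zero length makes the recursion undefined and raises
#' an error naming the node.
#'
#' @param tree Rooted `phylo` tree with branch lengths (>= 2 leaves,
#'   all branch lengths finite and non-negative).
#' @return Object of class `red_map`: list with `red` (numeric vector
#'   indexed by ape node number, named), and `tree`.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1)X:1,C:2);")
#' compute_red(tr)$red
compute_red <- function(tree) {
  nt <- n_tips(tree)
  if (nt < 2) stop("RED needs a tree with at least 2 leaves")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and non-negative")
  }
  n_nodes <- nt + tree$Nnode
  parent <- rep(NA_integer_, n_nodes)
  blen <- rep(0, n_nodes)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  blen[tree$edge[, 2]] <- tree$edge.length

  # postorder accumulation of leaf counts and summed node-to-leaf
  # distances below each node
  n_leaves <- rep(0, n_nodes)
  sum_dist <- rep(0, n_nodes)   # sum over leaves below of dist(node, leaf)
  n_leaves[seq_len(nt)] <- 1
  po_edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(po_edges))) {
    p <- po_edges[k, 1]; ch <- po_edges[k, 2]
    n_leaves[p] <- n_leaves[p] + n_leaves[ch]
    sum_dist[p] <- sum_dist[p] + sum_dist[ch] + n_leaves[ch] * blen[ch]
  }

  red <- rep(NA_real_, n_nodes)
  red[root_node(tree)] <- 0
  # preorder: parents before children
  pre <- rev(seq_len(nrow(po_edges)))
  for (k in pre) {
    ch <- po_edges[k, 2]
    p <- po_edges[k, 1]
    if (ch <= nt) {
      red[ch] <- 1          # leaves are 1 by definition
      next
    }
    d <- blen[ch]
    u <- d + sum_dist[ch] / n_leaves[ch]  # mean parent-to-leaf distance
    if (u == 0) {
      stop("RED undefined at node ", node_name(tree, ch),
           ": all branch lengths from its parent to its leaves are zero")
    }
    red[ch] <- red[p] + (1 - red[p]) * d / u
  }
  names(red) <- vapply(seq_len(n_nodes), function(nd) node_name(tree, nd),
                       character(1))
  structure(list(red = red, tree = tree), class = "red_map")
}

#' @export
print.red_map <- function(x, ...) {
  cat("<red_map> over", length(x$red), "nodes;",
      n_tips(x$tree), "leaves at RED 1, root at 0\n")
  invisible(x)
}

#' RED of the node circumscribing a taxon
#'
#' The RED of a taxon is the RED of the most recent common ancestor of
#' its member tips. For a singleton taxon the RED of the leaf's parent
#' node is returned, flagged via the `"singleton"` attribute (the
#' pendant edge is not interpolated).
#'
#' @param redmap A `red_map` from [compute_red()].
#' @param tips Character vector of tip labels.
#' @return Numeric RED value with attributes `node` (ape node number)
#'   and `singleton`.
#' @export
taxon_red <- function(redmap, tips) {
  tree <- redmap$tree
  tips <- unique(as.character(tips))
  node <- mrca_node(tree, tips)
  singleton <- length(tips) == 1
  if (singleton) {
    node <- parent_node(tree, node)
    if (is.na(node)) stop("singleton taxon at the root")
  }
  structure(unname(redmap$red[node]), node = node,
            singleton = singleton)
}

#' Median RED over the taxa of one rank
#'
#' @param redmap A `red_map` from [compute_red()].
#' @param taxa Named list: taxon name -> character vector of member
#'   tips.
#' @param rank Label for the rank (e.g. `"genus"`).
#' @return Object of class `rank_summary`: list with `rank`, `values`
#'   (named numeric, one RED per taxon) and `median`.
#' @export
rank_summary <- function(redmap, taxa, rank = "genus") {
  if (length(taxa) < 1) stop("need at least one taxon")
  values <- vapply(taxa, function(tips) as.numeric(taxon_red(redmap, tips)),
                   numeric(1))
  structure(list(rank = rank, values = values,
                 median = median(values)),
            class = "rank_summary")
}

#' @export
print.rank_summary <- function(x, ...) {
  cat(sprintf("<rank_summary> %s: median RED %.3f over %d taxa\n",
              x$rank, x$median, length(x$values)))
  invisible(x)
}

#' RED of a core clade
#'
#' The core clade of a group is the smallest clade encompassing a named
#' subset of its members (e.g. the validly published species of a
#' proposed genus); its RED is the RED of the MRCA of the named tips,
#' and is at least the RED of the full group's node because the MRCA of
#' a subset is never shallower than that of a superset.
#'
#' @inheritParams taxon_red
#' @param named_tips Tips defining the core clade.
#' @return As [taxon_red()].
#' @export
core_clade_red <- function(redmap, named_tips) {
  taxon_red(redmap, named_tips)
}

#' Extract the genus field from GTDB-style taxonomy strings
#'
#' Convenience splitter for strings like
#' `"d__Bacteria;...;g__Bacteroides;s__..."`.
#'
#' @param taxonomy Character vector of semicolon-delimited taxonomy
#'   strings with `g__` genus fields.
#' @return Character vector of genus names (`NA` where no `g__` field).
#' @export
gtdb_genus <- function(taxonomy) {
  m <- regmatches(taxonomy, regexpr("g__[^;]*", taxonomy))
  out <- rep(NA_character_, length(taxonomy))
  has <- grepl("g__", taxonomy)
  out[has] <- sub("^g__", "", m)
  out
}
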