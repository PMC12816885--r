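#' Read a rooted tree from Newick text
#'
#' Parses Newick with branch lengths into an [ape::read.tree()] `phylo`
#' object after validating the string (balanced parentheses, terminal
#' semicolon). The outermost node of the Newick string is taken as the
#' root; multifurcations, including at the root, are permitted. Internal
#' node labels are preserved verbatim.
#'
#' @param text Newick string, or a path to a file containing one tree.
#' @return A `phylo` object.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
read_newick <- function(text) {
  if (length(text) == 1 && !grepl("[();]", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  if (!nzchar(text)) stop("empty Newick string")
  check_newick_syntax(text)
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("Newick parse error")
  if (!is.null(tr$edge.length)) {
    if (any(!is.finite(tr$edge.length))) {
      stop("non-finite branch length in tree")
    }
    if (any(tr$edge.length < 0)) stop("negative branch length in tree")
  }
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
               collapse = ", "))
  }
  tr
}

check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (k in seq_along(chars)) {
    if (chars[k] == "(") depth <- depth + 1L
    if (chars[k] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("Newick parse error: unbalanced ')' at offset ", k)
      }
    }
  }
  if (depth != 0L) {
    stop("Newick parse error: ", depth, " unclosed '(' at end of string")
  }
  if (!endsWith(text, ";")) {
    stop("Newick parse error: missing terminal ';' at offset ",
         nchar(text))
  }
  invisible(TRUE)
}

#' Write a tree to Newick text
#'
#' Inverse of [read_newick()]; topology and branch lengths round-trip
#' (branch lengths to the 10 significant digits written by
#' [ape::write.tree()]).
#'
#' @param tree A `phylo` object.
#' @param path Optional file path; if `NULL`, the Newick string is
#'   returned.
#' @return Newick string (invisibly, when `path` is given).
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# --- internal tree helpers -------------------------------------------------

n_tips <- function(tree) length(tree$tip.label)

root_node <- function(tree) n_tips(tree) + 1L

# node number of the MRCA of a set of tip labels (tip itself for a
# singleton set); errors on unknown labels, naming them
mrca_node <- function(tree, tips) {
  tips <- unique(as.character(tips))
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown) > 0) {
    stop("tip label(s) not in tree: ", paste(unknown, collapse = ", "))
  }
  if (length(tips) == 0) stop("empty tip set")
  if (length(tips) == 1) return(match(tips, tree$tip.label))
  ape::getMRCA(tree, tips)
}

# tip labels descending from a node (the label itself for a tip node)
tips_under <- function(tree, node) {
  if (node <= n_tips(tree)) return(tree$tip.label[node])
  tree$tip.label[phangorn::Descendants(tree, node, type = "tips")[[1]]]
}

# parent node number (NA for the root)
parent_node <- function(tree, node) {
  hit <- tree$edge[, 2] == node
  if (!any(hit)) return(NA_integer_)
  tree$edge[hit, 1]
}

node_name <- function(tree, node) {
  if (node <= n_tips(tree)) return(tree$tip.label[node])
  lab <- tree$node.label[node - n_tips(tree)]
  if (!is.null(lab) && !is.na(lab) && nzchar(lab)) lab
  else paste0("node", node)
}
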