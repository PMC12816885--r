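#' Build the joint AAI/POCP criterion graph
#'
#' Vertices are all genomes appearing in the metrics table; an edge
#' joins an unordered pair iff `aai >= aai_threshold` and
#' `pocp >= pocp_threshold` (inclusive comparisons). Pairs with an
#' undefined AAI contribute no edge.
#'
#' @param metrics Pair-metrics data frame ([pair_metrics()]), one row
#'   per unordered pair.
#' @param aai_threshold AAI threshold in percent (e.g. the detected
#'   boundary).
#' @param pocp_threshold POCP threshold in percent; 50 is the commonly
#'   used genus-level criterion.
#' @return Object of class `criterion_graph`: list with `vertices`,
#'   `edges` (two-column character matrix) and the thresholds.
#' @export
build_graph <- function(metrics, aai_threshold, pocp_threshold = 50) {
  stopifnot(is.finite(aai_threshold), is.finite(pocp_threshold))
  key <- paste(pmin(metrics$genome_a, metrics$genome_b),
               pmax(metrics$genome_a, metrics$genome_b), sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate pair row(s): ",
         paste(unique(gsub("\r", " / ", key[duplicated(key)])),
               collapse = ", "))
  }
  vertices <- sort(unique(c(metrics$genome_a, metrics$genome_b)))
  pass <- !is.na(metrics$aai) &
    metrics$aai >= aai_threshold & metrics$pocp >= pocp_threshold
  edges <- cbind(pmin(metrics$genome_a, metrics$genome_b),
                 pmax(metrics$genome_a, metrics$genome_b))[pass, ,
                                                           drop = FALSE]
  structure(list(vertices = vertices, edges = edges,
                 aai_threshold = aai_threshold,
                 pocp_threshold = pocp_threshold),
            class = "criterion_graph")
}

#' Connected components of a criterion graph
#'
#' @param graph A `criterion_graph` from [build_graph()].
#' @return List of character vectors (sorted genome ids), one per
#'   component, including singletons, ordered by smallest member id.
#' @export
graph_components <- function(graph) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(graph$vertices),
                            name = graph$vertices)
  if (nrow(graph$edges) > 0) {
    g <- igraph::add_edges(g, t(graph$edges))
  }
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  groups <- lapply(groups, function(x) sort(unname(x)))
  unname(groups[order(vapply(groups, `[`, character(1), 1))])
}

# connected components of the subgraph induced by `members`
induced_components <- function(graph, members) {
  keep <- graph$edges[, 1] %in% members & graph$edges[, 2] %in% members
  sub <- structure(list(vertices = sort(members),
                        edges = graph$edges[keep, , drop = FALSE],
                        aai_threshold = graph$aai_threshold,
                        pocp_threshold = graph$pocp_threshold),
                   class = "criterion_graph")
  graph_components(sub)
}

#' Test a tip set for monophyly on a rooted tree
#'
#' A set of tips is monophyletic iff the leaves descending from its most
#' recent common ancestor are exactly the set. Singleton sets are
#' monophyletic by definition.
#'
#' @param tree Rooted `phylo` tree whose tip labels include all of
#'   `tips`.
#' @param tips Character vector of tip labels.
#' @return List with `is_monophyletic`, `mrca` (node number) and
#'   `intruders` (leaf labels under the MRCA that are not in `tips`).
#' @export
monophyly_test <- function(tree, tips) {
  tips <- unique(as.character(tips))
  node <- mrca_node(tree, tips)   # errors on unknown tips, naming them
  under <- tips_under(tree, node)
  intruders <- setdiff(under, tips)
  list(is_monophyletic = length(intruders) == 0,
       mrca = node,
       intruders = sort(intruders))
}

#' Delineate genus-level groups from a criterion graph and a tree
#'
#' Computes connected components of the joint-criterion graph and tests
#' each against the rooted phylogenomic tree. A non-monophyletic
#' component is resolved by iteratively removing the member whose
#' removal most reduces the intruder count (ties broken by removing the
#' lexicographically last id) until the remainder is monophyletic or a
#' single genome remains. Removed genomes are reported as excluded with
#' a reason code, keeping the exclusion auditable.
#'
#' @param tree Rooted `phylo` tree; its tip labels must include all
#'   graph vertices.
#' @param graph A `criterion_graph` from [build_graph()].
#' @return Object of class `genus_partition`: list with `groups` (list
#'   of character vectors), `excluded` (data frame `genome_id`,
#'   `reason`), `monophyly` (per-group test results) and the thresholds.
#' @export
delineate <- function(tree, graph) {
  missing <- setdiff(graph$vertices, tree$tip.label)
  if (length(missing) > 0) {
    stop("graph vertices absent from tree: ",
         paste(missing, collapse = ", "))
  }
  groups <- list()
  verdicts <- list()
  excluded <- data.frame(genome_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  queue <- graph_components(graph)
  while (length(queue) > 0) {
    members <- queue[[1]]
    queue <- queue[-1]
    test <- monophyly_test(tree, members)
    if (test$is_monophyletic || length(members) == 1) {
      groups[[length(groups) + 1]] <- sort(members)
      verdicts[[length(groups)]] <- test
      next
    }
    # greedy removal: candidate whose removal minimizes intruders
    n_intr <- vapply(members, function(v) {
      length(monophyly_test(tree, setdiff(members, v))$intruders)
    }, numeric(1))
    # ties -> lexicographically last id
    best <- min(n_intr)
    drop_id <- max(members[n_intr == best])
    members <- setdiff(members, drop_id)
    excluded <- rbind(excluded, data.frame(
      genome_id = drop_id, reason = "breaks_monophyly",
      stringsAsFactors = FALSE))
    # a removal can disconnect the criterion subgraph; re-split the
    # survivors so reported groups stay criterion-connected
    queue <- c(induced_components(graph, members), queue)
  }
  ord <- order(vapply(groups, `[`, character(1), 1))
  groups <- groups[ord]
  verdicts <- verdicts[ord]
  names(groups) <- paste0("group", seq_along(groups))
  names(verdicts) <- names(groups)
  structure(list(groups = groups, excluded = excluded,
                 monophyly = verdicts,
                 aai_threshold = graph$aai_threshold,
                 pocp_threshold = graph$pocp_threshold),
            class = "genus_partition")
}

#' @export
print.genus_partition <- function(x, ...) {
  cat(sprintf("<genus_partition> %d group(s), %d excluded (AAI >= %.4g, POCP >= %.4g)\n",
              length(x$groups), nrow(x$excluded),
              x$aai_threshold, x$pocp_threshold))
  for (g in names(x$groups)) {
    cat("  ", g, ": ", paste(x$groups[[g]], collapse = ", "), "\n",
        sep = "")
  }
  if (nrow(x$excluded) > 0) {
    cat("  excluded: ",
        paste(x$excluded$genome_id, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Write a genus partition as TSV
#'
#' One row per genome: `genome_id`, `group_id`, `status`
#' (`grouped`/`excluded`), `reason`.
#'
#' @param partition A `genus_partition` from [delineate()].
#' @param path File path.
#' @export
write_partition <- function(partition, path) {
  rows <- do.call(rbind, lapply(names(partition$groups), function(g) {
    data.frame(genome_id = partition$groups[[g]], group_id = g,
               status = "grouped", reason = "",
               stringsAsFactors = FALSE)
  }))
  if (nrow(partition$excluded) > 0) {
    rows <- rbind(rows, data.frame(
      genome_id = partition$excluded$genome_id, group_id = "",
      status = "excluded", reason = partition$excluded$reason,
      stringsAsFactors = FALSE))
  }
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
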