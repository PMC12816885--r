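#' Gene-tree container for marker-clade analysis
#'
#' A rooted gene tree whose leaves are gene ids, with a mapping from
#' gene id to source genome and a set of reference gene ids with
#' experimentally validated function (e.g. tryptophanase genes with
#' demonstrated indole production).
#'
#' @param tree Rooted `phylo` tree of gene sequences.
#' @param gene_to_genome Named character vector mapping gene id ->
#'   genome id; reference genes map to `"reference"`.
#' @param reference_ids Gene ids of the experimentally validated
#'   sequences (must be leaves of `tree`).
#' @return Object of class `gene_tree`.
#' @export
gene_tree <- function(tree, gene_to_genome, reference_ids) {
  stopifnot(inherits(tree, "phylo"))
  missing_ref <- setdiff(reference_ids, tree$tip.label)
  if (length(missing_ref) > 0) {
    stop("reference id(s) absent from gene tree: ",
         paste(missing_ref, collapse = ", "))
  }
  unmapped <- setdiff(tree$tip.label, names(gene_to_genome))
  if (length(unmapped) > 0) {
    stop("gene tree leaves with no genome mapping: ",
         paste(unmapped, collapse = ", "))
  }
  structure(list(tree = tree,
                 gene_to_genome = gene_to_genome[tree$tip.label],
                 reference_ids = as.character(reference_ids)),
            class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("<gene_tree>", n_tips(x$tree), "genes,",
      length(x$reference_ids), "reference sequence(s)\n")
  invisible(x)
}

#' Clade anchored by the validated reference sequences
#'
#' The validated clade is the most recent common ancestor of all
#' reference gene ids. With a single reference the leaf's parent node
#' is used (flagged via the `"singleton"` attribute); references
#' spanning the root give the root itself, with a warning, since the
#' clade is then degenerate (it contains every gene).
#'
#' @param gtree A [gene_tree()].
#' @return Node number with attribute `singleton`.
#' @export
validated_clade <- function(gtree) {
  refs <- gtree$reference_ids
  if (length(refs) < 1) stop("need at least one reference id")
  tree <- gtree$tree
  singleton <- length(refs) == 1
  node <- mrca_node(tree, refs)
  if (singleton) {
    node <- parent_node(tree, node)
    if (is.na(node)) stop("single reference at the root of the gene tree")
  }
  if (node == root_node(tree)) {
    warning("validated clade is the entire gene tree ",
            "(references span the root)")
  }
  structure(node, singleton = singleton)
}

#' Per-genome membership in a gene-tree clade
#'
#' A genome is a member iff at least one of its genes is a leaf under
#' the clade node. Genomes mapped in the gene tree but with all genes
#' outside the clade are `FALSE`; genomes with no gene in the tree are
#' absent from the result (absence of the marker is distinct from
#' presence outside the clade). Reference sequences are ignored.
#'
#' @param gtree A [gene_tree()].
#' @param clade Node number (e.g. from [validated_clade()]).
#' @return Named logical vector over genomes with >= 1 gene in the
#'   tree.
#' @export
genome_membership <- function(gtree, clade) {
  tree <- gtree$tree
  in_clade_genes <- tips_under(tree, as.integer(clade))
  map <- gtree$gene_to_genome
  genomes <- sort(unique(unname(map[map != "reference"])))
  member <- vapply(genomes, function(g) {
    any(names(map)[map == g] %in% in_clade_genes)
  }, logical(1))
  setNames(member, genomes)
}

#' Concordance between clade membership and a binary phenotype
#'
#' Cross-tabulates marker-clade membership against a phenotype (e.g.
#' indole production). Counts are over genomes present in both maps;
#' agreement is `(n11 + n00) / total`. Genomes with a phenotype call
#' but no marker gene in the tree are tallied separately
#' (`absent_negative` / `absent_positive`), since marker absence in a
#' phenotype-negative genome is corroborating rather than discordant.
#' Phenotypes may be logical, or three-valued character
#' (`"positive"`/`"negative"`/`"variable"`); `"variable"` genomes are
#' excluded from the counts.
#'
#' @param membership Named logical vector from [genome_membership()].
#' @param phenotype Named logical or character vector over genomes.
#' @return Object of class `concordance_table`: list with `n11`, `n10`,
#'   `n01`, `n00`, `total`, `agreement`, `absent_negative`,
#'   `absent_positive`, `excluded_variable`.
#' @export
concordance <- function(membership, phenotype) {
  if (is.character(phenotype)) {
    bad <- setdiff(unique(phenotype),
                   c("positive", "negative", "variable"))
    if (length(bad) > 0) {
      stop("phenotype values must be positive/negative/variable; got: ",
           paste(bad, collapse = ", "))
    }
    variable <- names(phenotype)[phenotype == "variable"]
    phenotype <- setNames(phenotype == "positive", names(phenotype))
    phenotype <- phenotype[setdiff(names(phenotype), variable)]
  } else {
    variable <- character()
  }
  shared <- intersect(names(membership), names(phenotype))
  m <- membership[shared]
  p <- phenotype[shared]
  n11 <- sum(m & p); n10 <- sum(m & !p)
  n01 <- sum(!m & p); n00 <- sum(!m & !p)
  total <- length(shared)
  no_marker <- setdiff(names(phenotype), names(membership))
  structure(list(
    n11 = n11, n10 = n10, n01 = n01, n00 = n00, total = total,
    agreement = if (total > 0) (n11 + n00) / total else NA_real_,
    absent_negative = sum(!phenotype[no_marker]),
    absent_positive = sum(phenotype[no_marker]),
    excluded_variable = length(variable)
  ), class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat(sprintf(
    "<concordance_table> agreement %.3f over %d genomes (n11=%d n10=%d n01=%d n00=%d; absent/neg=%d absent/pos=%d)\n",
    x$agreement, x$total, x$n11, x$n10, x$n01, x$n00,
    x$absent_negative, x$absent_positive))
  invisible(x)
}

#' Neighbour-joining gene tree from global identities
#'
#' Simple fallback for synthetic tests when no externally inferred gene
#' tree is available: pairwise global identities are converted to
#' distances `(100 - identity) / 100` and passed to neighbour joining,
#' then the tree is midpoint-rooted.
#'
#' @param genes Sequence table (`id`, `seq`) of aligned-length gene
#'   sequences.
#' @param params [align_params()] (affine gap penalties for the global
#'   alignment).
#' @return Rooted `phylo` tree.
#' @export
marker_nj_tree <- function(genes, params = align_params()) {
  n <- nrow(genes)
  d <- matrix(0, n, n, dimnames = list(genes$id, genes$id))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      r <- .align_one_cpp(genes$seq[i], genes$seq[j],
                          local = FALSE, dna = FALSE,
                          gopen = params$gap_open,
                          gext = params$gap_extend)
      d[i, j] <- d[j, i] <- (100 - 100 * r$matches / r$cols) / 100
    }
  }
  tr <- ape::nj(as.dist(d))
  phangorn::midpoint(tr)
}
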