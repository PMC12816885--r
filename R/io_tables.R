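#' Read tabular pipeline inputs
#'
#' Small readers for the TSV formats used around the pipeline:
#'
#' * `read_marker_map()`: columns `genome_id`, `marker_name`,
#'   `protein_id` (at most one protein per marker per genome) ->
#'   the nested map consumed by [marker_aai()].
#' * `read_taxon_map()`: columns `taxon`, `tip_id` -> named list of
#'   tip sets for [rank_summary()].
#' * `read_phenotype()`: columns `genome_id`, `phenotype`
#'   (`positive`/`negative`/`variable`, or `TRUE`/`FALSE`) -> named
#'   vector for [concordance()].
#' * `read_gene_tree()`: gene tree Newick + gene-to-genome TSV
#'   (columns `gene_id`, `genome_id`) + reference-id file (one id per
#'   line) -> a [gene_tree()].
#'
#' @param path Path to a TSV file with a header row.
#' @return See above.
#' @name read_tables
NULL

#' @rdname read_tables
#' @export
read_marker_map <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  stopifnot(all(c("genome_id", "marker_name", "protein_id") %in%
                  names(tab)))
  if (anyDuplicated(tab[, c("genome_id", "marker_name")])) {
    stop("more than one protein per marker per genome in ", path)
  }
  lapply(split(tab, tab$genome_id), function(d) {
    setNames(d$protein_id, d$marker_name)
  })
}

#' @rdname read_tables
#' @export
read_taxon_map <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  stopifnot(all(c("taxon", "tip_id") %in% names(tab)))
  lapply(split(tab, tab$taxon), function(d) unique(d$tip_id))
}

#' @rdname read_tables
#' @export
read_phenotype <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  stopifnot(all(c("genome_id", "phenotype") %in% names(tab)))
  ph <- tab$phenotype
  if (is.logical(ph)) {
    return(setNames(ph, tab$genome_id))
  }
  ph <- tolower(as.character(ph))
  if (all(ph %in% c("true", "false"))) {
    return(setNames(ph == "true", tab$genome_id))
  }
  setNames(ph, tab$genome_id)
}

#' @rdname read_tables
#' @param tree_path Newick file for the gene tree.
#' @param map_path Gene-to-genome TSV.
#' @param refs Reference gene ids, or a path to a file with one id per
#'   line.
#' @export
read_gene_tree <- function(tree_path, map_path, refs) {
  tr <- read_newick(tree_path)
  tab <- read.table(map_path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "genome_id") %in% names(tab)))
  if (length(refs) == 1 && file.exists(refs)) {
    refs <- readLines(refs, warn = FALSE)
    refs <- refs[nzchar(refs)]
  }
  gene_tree(tr, setNames(tab$genome_id, tab$gene_id), refs)
}
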