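#' Configuration for an end-to-end demarcation run
#'
#' @param proteomes Either a named list of [proteome()] objects or a
#'   directory of per-genome amino acid FASTA files (`*.faa`/`*.fasta`,
#'   genome id = file name without extension).
#' @param tree A `phylo` object or a Newick file path (rooted species
#'   tree covering the genomes).
#' @param aai_threshold `"auto"` (detect the boundary from the pooled
#'   AAI distribution; requires >= 10 defined pairwise values) or a
#'   fixed percentage.
#' @param pocp_threshold POCP threshold (percent); 50 by default.
#' @param sweep_lo,sweep_hi Search range for the boundary.
#' @param adjusts Bandwidth multipliers for the sensitivity sweep.
#' @param marker Optional list with components `gtree` (a
#'   [gene_tree()]) and `phenotype` (named logical or
#'   positive/negative/variable character vector), enabling the
#'   marker-concordance stage.
#' @param taxa Optional named list (taxon -> tips) for an additional
#'   RED rank summary (e.g. reference genera, or core clades of named
#'   species).
#' @param params [align_params()].
#' @param out_dir Optional directory; when given, all intermediate
#'   tables and the report are written there.
#' @param seed Integer seed recorded in the provenance block (the
#'   pipeline itself is deterministic given its inputs).
#' @return A list of class `run_config`.
#' @export
run_config <- function(proteomes, tree, aai_threshold = "auto",
                       pocp_threshold = 50,
                       sweep_lo = 60, sweep_hi = 80,
                       adjusts = seq(0.5, 2.0, by = 0.1),
                       marker = NULL, taxa = NULL,
                       params = align_params(),
                       out_dir = NULL, seed = 1L) {
  structure(list(proteomes = proteomes, tree = tree,
                 aai_threshold = aai_threshold,
                 pocp_threshold = pocp_threshold,
                 sweep_lo = sweep_lo, sweep_hi = sweep_hi,
                 adjusts = adjusts, marker = marker, taxa = taxa,
                 params = params, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the genus-demarcation pipeline end to end
#'
#' Stages, in order: load proteomes; all-pairs AAI/POCP metrics;
#' boundary detection on the pooled AAI values (bandwidth sweep, with
#' the `adjust = 1` local minimum as the working threshold when
#' `aai_threshold = "auto"`); joint-criterion graph and
#' monophyly-constrained delineation on the species tree; RED
#' computation with per-group and rank summaries; and, when marker
#' inputs are supplied, marker-clade membership and phenotype
#' concordance. A stage failure aborts the run naming the stage;
#' intermediate results computed before the failure are written to
#' `out_dir` if one is configured.
#'
#' @param config A [run_config()].
#' @param verbose Print per-stage progress.
#' @return Object of class `run_report` with elements `metrics`,
#'   `threshold`, `partition`, `red` (red map, group summary, optional
#'   taxa summary), `concordance` (or `NULL`), and `provenance`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(...)

  proteomes <- stage("load_proteomes", {
    p <- config$proteomes
    if (is.character(p) && length(p) == 1) {
      if (!dir.exists(p)) stop("proteome directory not found: ", p)
      files <- sort(list.files(p, pattern = "\\.(faa|fasta|fa)$",
                               full.names = TRUE))
      if (length(files) < 2) stop("need >= 2 proteome FASTA files")
      setNames(lapply(files, read_proteome),
               vapply(files, function(f) sub("\\.[^.]*$", "", basename(f)),
                      character(1)))
    } else p
  })
  say("loaded ", length(proteomes), " proteomes")

  metrics <- stage("pair_metrics", {
    pair_metrics(proteomes, config$params)
  })
  say("computed ", nrow(metrics), " pairwise metrics")

  threshold <- stage("boundary_detection", {
    values <- metrics$aai[!is.na(metrics$aai)]
    if (identical(config$aai_threshold, "auto")) {
      if (length(values) < 10) {
        stop("'auto' AAI threshold needs >= 10 defined pairwise values")
      }
      est <- bandwidth_sweep(values, config$adjusts,
                             config$sweep_lo, config$sweep_hi)
      if (est$no_boundary || is.na(est$minimum_at)) {
        stop("no AAI boundary detected in [", config$sweep_lo, ", ",
             config$sweep_hi, "]; supply a fixed aai_threshold")
      }
      est
    } else {
      structure(list(minimum_at = config$aai_threshold,
                     search_lo = config$sweep_lo,
                     search_hi = config$sweep_hi,
                     sweep_interval = c(config$aai_threshold,
                                        config$aai_threshold),
                     n_modes_in_range = NA_integer_,
                     adjusts = numeric(), minima = numeric(),
                     bandwidth = NA_real_, no_boundary = FALSE,
                     fixed = TRUE),
                class = "threshold_estimate")
    }
  })
  say(sprintf("AAI threshold: %.2f", threshold$minimum_at))

  tree <- stage("delineation", {
    tr <- config$tree
    if (is.character(tr)) {
      if (!file.exists(tr)) stop("tree file not found: ", tr)
      tr <- read_newick(tr)
    }
    tr
  })
  partition <- stage("delineation", {
    graph <- build_graph(metrics, threshold$minimum_at,
                         config$pocp_threshold)
    delineate(tree, graph)
  })
  say(length(partition$groups), " group(s), ",
      nrow(partition$excluded), " excluded")

  red <- stage("red", {
    redmap <- compute_red(tree)
    multi <- partition$groups[vapply(partition$groups, length,
                                     integer(1)) >= 1]
    group_summary <- rank_summary(redmap, multi, rank = "proposed_genus")
    taxa_summary <- if (!is.null(config$taxa)) {
      rank_summary(redmap, config$taxa, rank = "reference")
    }
    list(redmap = redmap, groups = group_summary, taxa = taxa_summary)
  })

  conc <- if (!is.null(config$marker)) {
    stage("marker_concordance", {
      clade <- validated_clade(config$marker$gtree)
      membership <- genome_membership(config$marker$gtree, clade)
      list(clade = clade, membership = membership,
           table = concordance(membership, config$marker$phenotype))
    })
  }

  report <- structure(list(
    metrics = metrics, threshold = threshold, partition = partition,
    red = red, concordance = conc,
    provenance = list(
      package = as.character(packageVersion("genusdemarc")),
      seed = config$seed,
      n_genomes = length(proteomes),
      aai_threshold = config$aai_threshold,
      pocp_threshold = config$pocp_threshold,
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )), class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  print(x$threshold)
  print(x$partition)
  cat(sprintf("  median group RED: %.3f\n", x$red$groups$median))
  if (!is.null(x$concordance)) print(x$concordance$table)
  invisible(x)
}

#' Write a run report to a directory
#'
#' Persists the pair-metrics TSV, partition TSV, per-node RED TSV and a
#' JSON summary (threshold, groups, RED medians, concordance counts,
#' provenance). Timestamps are excluded so that re-running an identical
#' configuration reproduces byte-identical files.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pair_metrics(report$metrics, file.path(dir, "pair_metrics.tsv"))
  write_partition(report$partition, file.path(dir, "partition.tsv"))
  red <- report$red$redmap$red
  write.table(data.frame(node = names(red), red = unname(red)),
              file.path(dir, "red.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    schema = "genusdemarc_report_v1",
    threshold = list(
      minimum_at = report$threshold$minimum_at,
      sweep_interval = report$threshold$sweep_interval,
      n_modes_in_range = report$threshold$n_modes_in_range,
      bandwidth = report$threshold$bandwidth),
    groups = report$partition$groups,
    excluded = report$partition$excluded,
    red_group_values = as.list(report$red$groups$values),
    red_group_median = report$red$groups$median,
    concordance = if (!is.null(report$concordance)) {
      unclass(report$concordance$table)
    },
    provenance = report$provenance[setdiff(names(report$provenance),
                                           "elapsed_s")]
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Rank references by 16S-like global identity to a query
#'
#' Computes the global percent identity ([global_identity()]) of a
#' query sequence against each reference, sorted descending, flagging
#' values below the commonly accepted genus-level similarity band
#' (92-95%).
#'
#' @param query Nucleotide sequence string or single-row sequence
#'   table.
#' @param references Sequence table of reference sequences.
#' @param genus_band Lower edge of the genus-level similarity band.
#' @return Data frame with columns `ref_id`, `identity`,
#'   `below_genus_band`, sorted by decreasing identity.
#' @export
validate_16s <- function(query, references, genus_band = 92) {
  if (!is.data.frame(references) || nrow(references) == 0) {
    stop("empty reference set")
  }
  ident <- vapply(references$seq, function(r) {
    global_identity(query, r)
  }, numeric(1))
  out <- data.frame(ref_id = references$id, identity = unname(ident),
                    below_genus_band = unname(ident) < genus_band,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$identity, out$ref_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
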