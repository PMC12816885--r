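#' Alignment and hit-filter parameters
#'
#' Parameters for the built-in Smith-Waterman protein search and the
#' hit filters applied when computing AAI and POCP. Defaults follow the
#' conventions of the standard AAI/POCP tooling: BLOSUM62 with gap open
#' 11 / extend 1; AAI reciprocal-best-hit filters identity >= 40%,
#' query coverage >= 50%, e-value <= 1e-5 (inclusive comparisons); POCP
#' conserved-protein filters e-value < 1e-5, identity > 40%, alignable
#' region > 50% of the query length (strict comparisons, following the
#' published POCP definition). E-values use the Karlin-Altschul form
#' `E = K * m * n * exp(-lambda * S)` on the gapped raw score, with the
#' ungapped lambda = 0.3176, K = 0.134 as a documented approximation.
#'
#' @param gap_open,gap_extend Affine gap penalties (a gap of length L
#'   costs `gap_open + gap_extend * L`).
#' @param lambda,K Karlin-Altschul parameters for e-values/bit scores.
#' @param aai_min_identity,aai_min_coverage,aai_max_evalue AAI filters
#'   (inclusive).
#' @param pocp_min_identity,pocp_min_coverage,pocp_max_evalue POCP
#'   filters (strict).
#' @return A list of class `align_params`.
#' @export
align_params <- function(gap_open = 11, gap_extend = 1,
                         lambda = 0.3176, K = 0.134,
                         aai_min_identity = 40, aai_min_coverage = 50,
                         aai_max_evalue = 1e-5,
                         pocp_min_identity = 40, pocp_min_coverage = 50,
                         pocp_max_evalue = 1e-5) {
  if (gap_open %% 1 != 0 || gap_extend %% 1 != 0) {
    stop("gap penalties must be whole numbers")
  }
  structure(list(gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K,
                 aai_min_identity = aai_min_identity,
                 aai_min_coverage = aai_min_coverage,
                 aai_max_evalue = aai_max_evalue,
                 pocp_min_identity = pocp_min_identity,
                 pocp_min_coverage = pocp_min_coverage,
                 pocp_max_evalue = pocp_max_evalue),
            class = "align_params")
}

#' Proteome container
#'
#' Bundles a genome id with its predicted protein sequences; the unit
#' of all pairwise genome comparisons.
#'
#' @param genome_id Genome identifier.
#' @param proteins Amino acid sequence table with columns `id`, `seq`
#'   (optionally `desc`), e.g. from [read_fasta()].
#' @return An object of class `proteome`.
#' @export
proteome <- function(genome_id, proteins) {
  stopifnot(is.character(genome_id), length(genome_id) == 1,
            nzchar(genome_id))
  if (!is.data.frame(proteins) ||
      !all(c("id", "seq") %in% names(proteins))) {
    stop("proteins must be a data frame with columns id, seq")
  }
  if (nrow(proteins) < 1) stop("proteome must contain >= 1 protein")
  if (anyDuplicated(proteins$id)) {
    stop("duplicate protein id(s) in proteome ", genome_id)
  }
  if (is.null(proteins$desc)) proteins$desc <- ""
  structure(list(genome_id = genome_id,
                 proteins = proteins[, c("id", "desc", "seq")],
                 n_proteins = nrow(proteins)),
            class = "proteome")
}

#' @export
print.proteome <- function(x, ...) {
  cat("<proteome>", x$genome_id, "-", x$n_proteins, "proteins\n")
  invisible(x)
}

#' Read a proteome FASTA file
#'
#' @param path Path to an amino acid FASTA file.
#' @param genome_id Genome id; defaults to the file name without
#'   extension.
#' @return A [proteome()] object.
#' @export
read_proteome <- function(path, genome_id = NULL) {
  if (is.null(genome_id)) {
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  }
  proteome(genome_id, read_fasta(path, "aa"))
}

hit_evalue <- function(score, m, n, params) {
  params$K * m * n * exp(-params$lambda * score)
}

hit_bitscore <- function(score, params) {
  (params$lambda * score - log(params$K)) / log(2)
}

#' Locally align one protein pair
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gaps.
#' Returns `NULL` when the optimal local score is not positive (no
#' alignable region).
#'
#' @param query,subject Amino acid sequence strings, or single-row
#'   sequence tables.
#' @param params [align_params()].
#' @return `NULL`, or a one-row data frame with columns `identity`
#'   (percent over alignment columns), `aligned_length` (columns,
#'   including gap columns), `query_coverage` (percent of query residues
#'   inside the aligned region), `score`, `bit_score` and `e_value`.
#' @export
align_pair <- function(query, subject, params = align_params()) {
  q <- as_seq_string(query)
  s <- as_seq_string(subject)
  if (nchar(q) == 0 || nchar(s) == 0) stop("empty sequence")
  r <- .align_one_cpp(q, s, local = TRUE, dna = FALSE,
                      gopen = params$gap_open, gext = params$gap_extend)
  if (!r$hit) return(NULL)
  data.frame(
    identity = 100 * r$matches / r$cols,
    aligned_length = r$cols,
    query_coverage = 100 * r$qres / nchar(q),
    score = r$score,
    bit_score = hit_bitscore(r$score, params),
    e_value = hit_evalue(r$score, nchar(q), nchar(s), params)
  )
}

# All-vs-all local alignments between two proteomes. Returns matrices
# (rows = a's proteins, cols = b's proteins) of raw score and, where the
# e-value passes `emax_full`, matches/cols/qres/sres. Used once per
# unordered pair: scores and alignment columns are symmetric, so both
# search directions derive from the same matrices.
pair_alignments <- function(a, b, params = align_params(),
                            emax_full = Inf) {
  res <- .sw_batch_cpp(a$proteins$seq, b$proteins$seq,
                       params$gap_open, params$gap_extend,
                       params$lambda, params$K, emax_full)
  res$qlen <- nchar(a$proteins$seq)
  res$slen <- nchar(b$proteins$seq)
  res$evalue <- params$K * outer(res$qlen, res$slen) *
    exp(-params$lambda * res$score)
  res$identity <- 100 * res$matches / res$cols
  res
}

# best hit per row of a score matrix; ties broken toward the
# lexicographically smallest subject id; rows with no positive score
# are dropped
best_by_score <- function(score, subject_ids) {
  ord <- order(subject_ids, method = "radix")
  apply(score[, ord, drop = FALSE], 1, function(row) {
    if (all(row <= 0)) return(NA_integer_)
    ord[which.max(row)]
  })
}

#' Best hits of one proteome against another
#'
#' For each protein of `a`, the highest-bit-score local alignment
#' against `b` (ties broken toward the lexicographically smallest
#' subject id). Proteins with no positive-scoring alignment are absent
#' from the result.
#'
#' @param a,b [proteome()] objects (queries come from `a`).
#' @param params [align_params()].
#' @return Data frame with one row per query that has a hit: columns
#'   `query_id`, `subject_id`, `identity`, `aligned_length`,
#'   `query_coverage`, `score`, `bit_score`, `e_value`.
#' @export
best_hits <- function(a, b, params = align_params()) {
  aln <- pair_alignments(a, b, params, emax_full = Inf)
  best_hits_from(aln, a, b, params, direction = "ab")
}

best_hits_from <- function(aln, a, b, params, direction = c("ab", "ba")) {
  direction <- match.arg(direction)
  if (direction == "ab") {
    score <- aln$score
    identity <- aln$identity
    cols <- aln$cols
    cov_res <- aln$qres
    qlen <- aln$qlen
    qids <- a$proteins$id
    sids <- b$proteins$id
  } else {
    score <- t(aln$score)
    identity <- t(aln$identity)
    cols <- t(aln$cols)
    cov_res <- t(aln$sres)
    qlen <- aln$slen
    qids <- b$proteins$id
    sids <- a$proteins$id
  }
  j <- best_by_score(score, sids)
  keep <- which(!is.na(j))
  if (length(keep) == 0) {
    return(data.frame(query_id = character(), subject_id = character(),
                      identity = numeric(), aligned_length = numeric(),
                      query_coverage = numeric(), score = numeric(),
                      bit_score = numeric(), e_value = numeric()))
  }
  idx <- cbind(keep, j[keep])
  sc <- score[idx]
  data.frame(
    query_id = qids[keep],
    subject_id = sids[j[keep]],
    identity = identity[idx],
    aligned_length = cols[idx],
    query_coverage = 100 * cov_res[idx] / qlen[keep],
    score = sc,
    bit_score = hit_bitscore(sc, params),
    e_value = hit_evalue(sc, qlen[keep],
                         nchar(if (direction == "ab") b$proteins$seq
                               else a$proteins$seq)[j[keep]], params)
  )
}

#' Reciprocal best hits between two best-hit tables
#'
#' Pairs `(x, y)` such that `y` is `x`'s best hit in one direction and
#' `x` is `y`'s best hit in the other. The pair identity is the
#' arithmetic mean of the two directional identities.
#'
#' @param ab Best hits of proteome a against b ([best_hits()]).
#' @param ba Best hits of proteome b against a.
#' @return Data frame with columns `a_id`, `b_id`, `identity`, plus the
#'   two directional hit tables' columns prefixed `ab_` / `ba_`.
#' @export
reciprocal_best_hits <- function(ab, ba) {
  m <- merge(ab, ba, by.x = c("query_id", "subject_id"),
             by.y = c("subject_id", "query_id"),
             suffixes = c("_ab", "_ba"))
  out <- data.frame(
    a_id = m$query_id,
    b_id = m$subject_id,
    identity = (m$identity_ab + m$identity_ba) / 2,
    ab_coverage = m$query_coverage_ab,
    ba_coverage = m$query_coverage_ba,
    ab_evalue = m$e_value_ab,
    ba_evalue = m$e_value_ba
  )
  out[order(out$a_id), , drop = FALSE]
}

rbh_passing <- function(rbh, params) {
  rbh[rbh$identity >= params$aai_min_identity &
        rbh$ab_coverage >= params$aai_min_coverage &
        rbh$ba_coverage >= params$aai_min_coverage &
        rbh$ab_evalue <= params$aai_max_evalue &
        rbh$ba_evalue <= params$aai_max_evalue, , drop = FALSE]
}

#' Average amino acid identity between two proteomes
#'
#' Mean percent identity over reciprocal best hit pairs passing the AAI
#' filters (identity >= 40%, coverage >= 50% of the query in both
#' directions, e-value <= 1e-5 in both directions, by default). When no
#' pair passes, the AAI is undefined and flagged (`defined = FALSE`,
#' `aai = NA`) rather than returned as a silent `NaN`.
#'
#' @param a,b [proteome()] objects.
#' @param params [align_params()].
#' @return List with elements `aai`, `n_rbh` and `defined`.
#' @export
aai <- function(a, b, params = align_params()) {
  aln <- pair_alignments(a, b, params,
                         emax_full = max(params$aai_max_evalue,
                                         params$pocp_max_evalue))
  aai_from(aln, a, b, params)
}

aai_from <- function(aln, a, b, params) {
  ab <- best_hits_from(aln, a, b, params, "ab")
  ba <- best_hits_from(aln, a, b, params, "ba")
  rbh <- reciprocal_best_hits(ab, ba)
  pass <- rbh_passing(rbh, params)
  n <- nrow(pass)
  list(aai = if (n > 0) mean(pass$identity) else NA_real_,
       n_rbh = n, defined = n > 0)
}

#' Percentage of conserved proteins between two proteomes
#'
#' `POCP = 100 * (C1 + C2) / (T1 + T2)`, where `T` is the proteome size
#' and `C` the number of proteins with at least one hit in the other
#' proteome satisfying e-value < 1e-5, identity > 40% and an alignable
#' region covering > 50% of the query length (strict inequalities, per
#' the published definition).
#'
#' @param a,b [proteome()] objects.
#' @param params [align_params()].
#' @return List with elements `pocp`, `c_a`, `c_b`, `t_a`, `t_b`.
#' @export
pocp <- function(a, b, params = align_params()) {
  aln <- pair_alignments(a, b, params,
                         emax_full = max(params$aai_max_evalue,
                                         params$pocp_max_evalue))
  pocp_from(aln, a, b, params)
}

pocp_from <- function(aln, a, b, params) {
  qualifies <- !is.na(aln$identity) &
    aln$evalue < params$pocp_max_evalue &
    aln$identity > params$pocp_min_identity
  cov_a <- 100 * aln$qres / aln$qlen          # region / query length
  cov_b <- 100 * sweep_cols(aln$sres, aln$slen)
  qa <- qualifies & !is.na(cov_a) & cov_a > params$pocp_min_coverage
  qb <- qualifies & !is.na(cov_b) & cov_b > params$pocp_min_coverage
  c_a <- sum(apply(qa, 1, any))
  c_b <- sum(apply(qb, 2, any))
  list(pocp = 100 * (c_a + c_b) / (a$n_proteins + b$n_proteins),
       c_a = c_a, c_b = c_b,
       t_a = a$n_proteins, t_b = b$n_proteins)
}

# divide each column j of matrix m by len[j], elementwise
sweep_cols <- function(m, len) {
  sweep(m, 2, len, "/")
}

#' All pairwise AAI/POCP metrics for a set of proteomes
#'
#' Runs the alignment search once per unordered genome pair (scores and
#' alignments are symmetric) and assembles the pair-metrics table that
#' downstream boundary detection and clade delineation consume.
#'
#' @param proteomes List of [proteome()] objects.
#' @param params [align_params()].
#' @param verbose Print one line per pair.
#' @return Data frame with one row per unordered pair: `genome_a`,
#'   `genome_b`, `aai`, `n_rbh`, `pocp`, `c_a`, `c_b`, `t_a`, `t_b`.
#' @export
pair_metrics <- function(proteomes, params = align_params(),
                         verbose = FALSE) {
  ids <- vapply(proteomes, function(p) p$genome_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate genome ids")
  n <- length(proteomes)
  rows <- list()
  emax <- max(params$aai_max_evalue, params$pocp_max_evalue)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- proteomes[[i]]; b <- proteomes[[j]]
      aln <- pair_alignments(a, b, params, emax_full = emax)
      av <- aai_from(aln, a, b, params)
      pv <- pocp_from(aln, a, b, params)
      rows[[length(rows) + 1]] <- data.frame(
        genome_a = a$genome_id, genome_b = b$genome_id,
        aai = av$aai, n_rbh = av$n_rbh,
        pocp = pv$pocp, c_a = pv$c_a, c_b = pv$c_b,
        t_a = pv$t_a, t_b = pv$t_b)
      if (verbose) {
        message(sprintf("%s vs %s: AAI %.2f (n=%d), POCP %.2f",
                        a$genome_id, b$genome_id,
                        av$aai, av$n_rbh, pv$pocp))
      }
    }
  }
  do.call(rbind, rows)
}

#' Write / read a pair-metrics table as TSV
#'
#' @param metrics Data frame from [pair_metrics()].
#' @param path File path.
#' @return `path` (write) or the metrics data frame (read).
#' @export
write_pair_metrics <- function(metrics, path) {
  write.table(metrics, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_metrics
#' @export
read_pair_metrics <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Marker-subset AAI between two genomes
#'
#' Mean pairwise global percent identity over marker genes present as
#' single copies in both genomes, mirroring AAI recalculated from a
#' fixed panel of conserved single-copy genes. Global alignment uses
#' BLOSUM62 with the affine gap penalties from `params`; identity is
#' matches over all alignment columns.
#'
#' @param a,b [proteome()] objects.
#' @param marker_map Named list: `marker_map[[genome_id]]` is a named
#'   character vector mapping marker name -> protein id (at most one
#'   protein per marker per genome).
#' @param params [align_params()].
#' @return List with `aai` (mean identity; `NA` if no shared markers),
#'   `n_markers` and `defined`.
#' @export
marker_aai <- function(a, b, marker_map, params = align_params()) {
  ma <- marker_map[[a$genome_id]]
  mb <- marker_map[[b$genome_id]]
  shared <- intersect(names(ma), names(mb))
  if (length(shared) == 0) {
    return(list(aai = NA_real_, n_markers = 0L, defined = FALSE))
  }
  seq_a <- a$proteins$seq[match(ma[shared], a$proteins$id)]
  seq_b <- b$proteins$seq[match(mb[shared], b$proteins$id)]
  if (anyNA(seq_a) || anyNA(seq_b)) {
    stop("marker map points at protein ids absent from the proteome")
  }
  ident <- mapply(function(x, y) {
    r <- .align_one_cpp(x, y, local = FALSE, dna = FALSE,
                        gopen = params$gap_open,
                        gext = params$gap_extend)
    100 * r$matches / r$cols
  }, seq_a, seq_b)
  list(aai = mean(ident), n_markers = length(shared), defined = TRUE)
}
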