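#' Read a FASTA file into a sequence table
#'
#' Parses a (possibly line-wrapped) FASTA file and validates the records
#' against the declared alphabet. Sequences are uppercased on read; for
#' nucleotide input, `U` is mapped to `T`. Record order is preserved.
#'
#' Validation is strict: record ids must be unique within a file, and
#' sequences may contain only the unambiguous residue characters of the
#' declared alphabet plus the ambiguity code (`X` for amino acids, `N`
#' for nucleotides). Gap characters (`-`, `.`) are rejected for amino
#' acid input with a dedicated message, since proteome FASTA files must
#' be unaligned.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"aa"` (amino acid) or `"nt"` (nucleotide).
#' @return A data frame with columns `id`, `desc`, `seq`, one row per
#'   record (zero rows for an empty file), with an `alphabet` attribute.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".faa")
#' writeLines(c(">p1 a protein", "MKV", ">p2", "MA"), tf)
#' read_fasta(tf, "aa")
read_fasta <- function(path, alphabet = c("aa", "nt")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) {
    return(empty_records(alphabet))
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers),
                  sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  names(seqs) <- NULL
  if (alphabet == "nt") seqs <- gsub("U", "T", seqs, fixed = TRUE)
  validate_records(ids, seqs, alphabet, path)
  structure(
    data.frame(id = ids, desc = descs, seq = seqs,
               stringsAsFactors = FALSE),
    alphabet = alphabet
  )
}

empty_records <- function(alphabet) {
  structure(
    data.frame(id = character(), desc = character(), seq = character(),
               stringsAsFactors = FALSE),
    alphabet = alphabet
  )
}

alphabet_chars <- function(alphabet) {
  if (alphabet == "aa") c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
  else c("A", "C", "G", "T", "N")
}

validate_records <- function(ids, seqs, alphabet, path = "<records>") {
  if (any(ids == "")) stop("empty record id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for record ",
         ids[which(nchar(seqs) == 0L)[1]], " in ", path)
  }
  ok <- alphabet_chars(alphabet)
  for (k in seq_along(seqs)) {
    chars <- strsplit(seqs[k], "")[[1]]
    bad <- which(!chars %in% ok)
    if (length(bad) > 0) {
      ch <- chars[bad[1]]
      if (alphabet == "aa" && ch %in% c("-", ".")) {
        stop("gap character '", ch, "' at position ", bad[1],
             " in record ", ids[k],
             ": proteome input must be unaligned")
      }
      stop("illegal character '", ch, "' at position ", bad[1],
           " in record ", ids[k], " (alphabet ", alphabet, ")")
    }
  }
  invisible(TRUE)
}

#' Write a sequence table to FASTA
#'
#' @param records Data frame with columns `id`, `desc`, `seq`, as
#'   returned by [read_fasta()].
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  headers <- ifelse(nchar(records$desc) > 0,
                    paste(records$id, records$desc), records$id)
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Pooled G+C content of nucleotide records
#'
#' Computes 100 * (G + C) / (A + C + G + T) pooled over all records.
#' Ambiguity characters (`N`) are excluded from both numerator and
#' denominator. Reported in mol%, as customary for genomic G+C.
#'
#' @param records Sequence table (nucleotide).
#' @return Percentage (numeric scalar).
#' @export
gc_content <- function(records) {
  counts <- pooled_base_counts(records)
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0) stop("G+C content undefined: no unambiguous bases")
  100 * sum(counts[c("G", "C")]) / denom
}

pooled_base_counts <- function(records) {
  all <- paste(records$seq, collapse = "")
  chars <- strsplit(all, "")[[1]]
  vapply(c("A", "C", "G", "T", "N"),
         function(b) sum(chars == b), integer(1))
}

#' Total assembly length in bp
#'
#' Sum of record lengths over all contigs of a nucleotide FASTA.
#'
#' @param records Sequence table (nucleotide).
#' @return Integer number of base pairs.
#' @export
genome_size <- function(records) {
  sum(nchar(records$seq))
}

#' Global percent identity between two nucleotide sequences
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1 and a
#' linear gap cost of 2 per gap column (no free terminal gaps). Identity
#' is 100 * matches / alignment columns, with gap columns counted in the
#' denominator, which makes the value symmetric in its arguments.
#' Different aligners use different identity conventions, so values from
#' other tools on the same pair of sequences can differ by a few tenths
#' of a percent.
#'
#' @param a,b Nucleotide sequence strings (or single-row sequence
#'   tables from [read_fasta()]).
#' @return Percent identity in `[0, 100]`.
#' @export
#' @examples
#' global_identity("ACGT", "ACGA") # 75
global_identity <- function(a, b) {
  a <- as_seq_string(a)
  b <- as_seq_string(b)
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  r <- .align_one_cpp(a, b, local = FALSE, dna = TRUE,
                      gopen = 0, gext = 2)
  100 * r$matches / r$cols
}

as_seq_string <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- x$seq
  }
  toupper(as.character(x))
}
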