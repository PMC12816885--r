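# Independent pure-R reference implementations used as oracles.

BLOSUM62_TXT <- "
   A  R  N  D  C  Q  E  G  H  I  L  K  M  F  P  S  T  W  Y  V  X
A  4 -1 -2 -2  0 -1 -1  0 -2 -1 -1 -1 -1 -2 -1  1  0 -3 -2  0  0
R -1  5  0 -2 -3  1  0 -2  0 -3 -2  2 -1 -3 -2 -1 -1 -3 -2 -3 -1
N -2  0  6  1 -3  0  0  0  1 -3 -3  0 -2 -3 -2  1  0 -4 -2 -3 -1
D -2 -2  1  6 -3  0  2 -1 -1 -3 -4 -1 -3 -3 -1  0 -1 -4 -3 -3 -1
C  0 -3 -3 -3  9 -3 -4 -3 -3 -1 -1 -3 -1 -2 -3 -1 -1 -2 -2 -1 -2
Q -1  1  0  0 -3  5  2 -2  0 -3 -2  1  0 -3 -1  0 -1 -2 -1 -2 -1
E -1  0  0  2 -4  2  5 -2  0 -3 -3  1 -2 -3 -1  0 -1 -3 -2 -2 -1
G  0 -2  0 -1 -3 -2 -2  6 -2 -4 -4 -2 -3 -3 -2  0 -2 -2 -3 -3 -1
H -2  0  1 -1 -3  0  0 -2  8 -3 -3 -1 -2 -1 -2 -1 -2 -2  2 -3 -1
I -1 -3 -3 -3 -1 -3 -3 -4 -3  4  2 -3  1  0 -3 -2 -1 -3 -1  3 -1
L -1 -2 -3 -4 -1 -2 -3 -4 -3  2  4 -2  2  0 -3 -2 -1 -2 -1  1 -1
K -1  2  0 -1 -3  1  1 -2 -1 -3 -2  5 -1 -3 -1  0 -1 -3 -2 -2 -1
M -1 -1 -2 -3 -1  0 -2 -3 -2  1  2 -1  5  0 -2 -1 -1 -1 -1  1 -1
F -2 -3 -3 -3 -2 -3 -3 -3 -1  0  0 -3  0  6 -4 -2 -2  1  3 -1 -1
P -1 -2 -2 -1 -3 -1 -1 -2 -2 -3 -3 -1 -2 -4  7 -1 -1 -4 -3 -2 -2
S  1 -1  1  0 -1  0  0  0 -1 -2 -2  0 -1 -2 -1  4  1 -3 -2 -2  0
T  0 -1  0 -1 -1 -1 -1 -2 -2 -1 -1 -1 -1 -2 -1  1  5 -2 -2  0  0
W -3 -3 -4 -4 -2 -2 -3 -2 -2 -3 -2 -3 -1  1 -4 -3 -2 11  2 -3 -2
Y -2 -2 -2 -3 -2 -1 -2 -3  2 -1 -1 -2 -1  3 -3 -2 -2  2  7 -1 -1
V  0 -3 -3 -3 -1 -2 -2 -3 -3  3  1 -2  1 -1 -2 -2  0 -3 -1  4 -1
X  0 -1 -1 -1 -2 -1 -1 -1 -1 -1 -1 -1 -1 -1 -2  0  0 -2 -1 -1 -1
"

oracle_blosum62 <- local({
  m <- as.matrix(read.table(text = BLOSUM62_TXT, header = TRUE,
                            row.names = 1, check.names = FALSE))
  colnames(m) <- rownames(m)
  m
})

oracle_sub <- function(a, b, dna) {
  if (dna) {
    if (a == b && a %in% c("A", "C", "G", "T")) 1 else -1
  } else {
    oracle_blosum62[a, b]
  }
}

# Reference Gotoh DP sharing the package's documented conventions
# (gap of length L costs open + ext*L; tie preference diag > gap in
# query > gap in subject; local best cell = first maximum row-major;
# local traceback stops at an H cell of value 0).
oracle_align <- function(q, s, local = TRUE, dna = FALSE,
                         open = 11, ext = 1) {
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  NEG <- -1e18
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  pH <- matrix(0L, n + 1, m + 1)  # 0 stop, 1 diag, 2 E, 3 F
  pE <- matrix(0L, n + 1, m + 1)  # 1 from H, 2 extend
  pF <- matrix(0L, n + 1, m + 1)
  if (!local) {
    for (j in seq_len(m)) {
      E[1, j + 1] <- -(open + ext * j)
      pE[1, j + 1] <- if (j == 1) 1L else 2L
      H[1, j + 1] <- E[1, j + 1]; pH[1, j + 1] <- 2L
    }
    for (i in seq_len(n)) {
      F[i + 1, 1] <- -(open + ext * i)
      pF[i + 1, 1] <- if (i == 1) 1L else 2L
      H[i + 1, 1] <- F[i + 1, 1]; pH[i + 1, 1] <- 3L
    }
  }
  best <- 0; bi <- 0; bj <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      eo <- H[i + 1, j] - open - ext; ee <- E[i + 1, j] - ext
      E[i + 1, j + 1] <- max(eo, ee)
      pE[i + 1, j + 1] <- if (eo >= ee) 1L else 2L
      fo <- H[i, j + 1] - open - ext; fe <- F[i, j + 1] - ext
      F[i + 1, j + 1] <- max(fo, fe)
      pF[i + 1, j + 1] <- if (fo >= fe) 1L else 2L
      d <- H[i, j] + oracle_sub(qc[i], sc[j], dna)
      h <- d; p <- 1L
      if (E[i + 1, j + 1] > h) { h <- E[i + 1, j + 1]; p <- 2L }
      if (F[i + 1, j + 1] > h) { h <- F[i + 1, j + 1]; p <- 3L }
      if (local && h <= 0) { h <- 0; p <- 0L }
      H[i + 1, j + 1] <- h; pH[i + 1, j + 1] <- p
      if (local && h > best) { best <- h; bi <- i; bj <- j }
    }
  }
  if (local) {
    if (best <= 0) return(NULL)
    score <- best; i <- bi; j <- bj
  } else {
    score <- H[n + 1, m + 1]; i <- n; j <- m
  }
  matches <- 0L; cols <- 0L; qres <- 0L; sres <- 0L
  state <- 1L
  while (i > 0 || j > 0) {
    if (state == 1L) {
      p <- pH[i + 1, j + 1]
      if (local && p == 0L) break
      if (p == 1L) {
        cols <- cols + 1L; qres <- qres + 1L; sres <- sres + 1L
        if (qc[i] == sc[j]) matches <- matches + 1L
        i <- i - 1L; j <- j - 1L
      } else if (p == 2L) state <- 2L
      else if (p == 3L) state <- 3L
      else break
    } else if (state == 2L) {
      p <- pE[i + 1, j + 1]
      cols <- cols + 1L; sres <- sres + 1L; j <- j - 1L
      if (p == 1L) state <- 1L
    } else {
      p <- pF[i + 1, j + 1]
      cols <- cols + 1L; qres <- qres + 1L; i <- i - 1L
      if (p == 1L) state <- 1L
    }
  }
  list(score = score, matches = matches, cols = cols,
       qres = qres, sres = sres,
       identity = 100 * matches / cols,
       qcov = 100 * qres / n)
}

# random protein sequence
rand_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# plant k substitutions into a protein sequence (never to the original
# residue)
plant_subs <- function(seq, k) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(aas, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# oracle e-value / filters shared with the package's documented
# constants
oracle_evalue <- function(score, m, n, lambda = 0.3176, K = 0.134) {
  K * m * n * exp(-lambda * score)
}

make_proteome <- function(genome_id, seqs) {
  proteome(genome_id,
           data.frame(id = sprintf("%s_p%02d", genome_id,
                                   seq_along(seqs)),
                      seq = seqs, stringsAsFactors = FALSE))
}
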