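test_that("align_pair agrees with the reference DP on score and identity", {
  withr::local_seed(101)
  for (k in 1:30) {
    q <- rand_protein(sample(5:60, 1))
    s <- if (k %% 3 == 0) plant_subs(q, sample(1:5, 1))
         else rand_protein(sample(5:60, 1))
    ref <- oracle_align(q, s, local = TRUE)
    hit <- align_pair(q, s)
    if (is.null(ref)) {
      expect_null(hit)
    } else {
      expect_equal(hit$score, ref$score)
      expect_equal(hit$identity, ref$identity)
      expect_equal(hit$aligned_length, ref$cols)
      expect_equal(hit$query_coverage, ref$qcov)
    }
  }
})

test_that("align_pair handles identity, no-hit and planted-substitution cases", {
  withr::local_seed(42)
  self <- rand_protein(100)
  hit <- align_pair(self, self)
  expect_equal(hit$identity, 100)
  expect_equal(hit$query_coverage, 100)
  expect_equal(hit$aligned_length, 100)

  # no positive-scoring alignment under BLOSUM62
  expect_null(align_pair("MKV", "AAAA"))

  # 50-aa pair with 5 planted substitutions: full-length gap-free
  # alignment at 90% identity
  base <- rand_protein(50)
  mut <- plant_subs(base, 5)
  hit <- align_pair(base, mut)
  expect_equal(hit$identity, 90)
  expect_equal(hit$aligned_length, 50)
  expect_error(align_pair("", "MKV"), "empty")
})

test_that("best_hits finds exact copies and applies the tie-break", {
  withr::local_seed(7)
  seqs <- vapply(rep(40, 5), rand_protein, character(1))
  a <- make_proteome("a", seqs)
  b <- make_proteome("b", seqs)
  bh <- best_hits(a, b)
  expect_equal(nrow(bh), 5L)
  expect_equal(sub("^a", "b", bh$query_id), bh$subject_id)
  expect_true(all(bh$identity == 100))

  # two equal-score subjects: lexicographically smaller id wins
  dup <- proteome("d", data.frame(
    id = c("z_copy", "a_copy"), seq = c(seqs[1], seqs[1])))
  bh2 <- best_hits(make_proteome("q", seqs[1]), dup)
  expect_equal(bh2$subject_id, "a_copy")

  # query with no positive-scoring partner is absent
  weird <- proteome("w", data.frame(id = "w1", seq = "MKV"))
  poly <- proteome("p", data.frame(id = "p1", seq = "AAAAAAA"))
  expect_equal(nrow(best_hits(weird, poly)), 0L)
})

test_that("reciprocal best hits require mutual best and average identities", {
  ab <- data.frame(query_id = c("a1", "a2"), subject_id = c("b1", "b2"),
                   identity = c(80, 75), aligned_length = c(50, 50),
                   query_coverage = c(100, 100), score = c(100, 90),
                   bit_score = c(40, 38), e_value = c(1e-20, 1e-18))
  ba <- data.frame(query_id = c("b1", "b2"), subject_id = c("a1", "a9"),
                   identity = c(82, 75), aligned_length = c(50, 50),
                   query_coverage = c(100, 100), score = c(100, 90),
                   bit_score = c(40, 38), e_value = c(1e-20, 1e-18))
  rbh <- reciprocal_best_hits(ab, ba)
  expect_equal(nrow(rbh), 1L)           # a2/b2 not reciprocal
  expect_equal(rbh$a_id, "a1")
  expect_equal(rbh$identity, 81)        # mean of 80 and 82
})

test_that("aai matches a filter-then-average oracle on planted identities", {
  withr::local_seed(202)
  # orthologous families with substitution loads spanning the filters,
  # from identical to effectively random
  n_sub <- c(0, 2, 5, 10, 20, 30, 42, 50)  # of 60 aa
  base <- vapply(rep(60, 8), rand_protein, character(1))
  mut <- unname(mapply(plant_subs, base, n_sub))
  a <- make_proteome("ga", base)
  b <- make_proteome("gb", mut)
  res <- aai(a, b)

  # oracle: all-vs-all pure-R DP, reciprocal best hits, then the
  # documented filter-then-average rule
  sc <- id <- qc <- sv <- ev <- matrix(NA_real_, 8, 8)
  for (i in 1:8) {
    for (j in 1:8) {
      r <- oracle_align(base[i], mut[j], local = TRUE)
      if (!is.null(r)) {
        sc[i, j] <- r$score; id[i, j] <- r$identity
        qc[i, j] <- 100 * r$qres / 60
        sv[i, j] <- 100 * r$sres / 60
        ev[i, j] <- oracle_evalue(r$score, 60, 60)
      }
    }
  }
  pick <- function(x) if (all(is.na(x) | x <= 0)) NA_integer_
                      else which.max(x)
  ab <- apply(sc, 1, pick); ba <- apply(sc, 2, pick)
  rbh_ident <- c()
  for (i in 1:8) {
    j <- ab[i]
    if (!is.na(j) && !is.na(ba[j]) && ba[j] == i &&
        id[i, j] >= 40 && qc[i, j] >= 50 && sv[i, j] >= 50 &&
        ev[i, j] <= 1e-5) {
      rbh_ident <- c(rbh_ident, id[i, j])
    }
  }
  expect_gt(length(rbh_ident), 0)
  expect_lt(length(rbh_ident), 8)       # filters actually bite
  expect_equal(res$n_rbh, length(rbh_ident))
  expect_equal(res$aai, mean(rbh_ident))
})

test_that("aai of identical proteomes is 100 and symmetric", {
  withr::local_seed(9)
  a <- make_proteome("a", vapply(rep(50, 6), rand_protein, character(1)))
  b <- make_proteome("b", vapply(rep(50, 7), rand_protein, character(1)))
  expect_equal(aai(a, a)$aai, 100)
  ab <- aai(a, b); ba <- aai(b, a)
  expect_identical(ab$aai, ba$aai)
  expect_identical(ab$n_rbh, ba$n_rbh)
})

test_that("aai is flagged undefined when no pair passes", {
  a <- proteome("a", data.frame(id = "a1", seq = "MKVMKVMKV"))
  b <- proteome("b", data.frame(id = "b1", seq = "WWDDCCHHGG"))
  res <- aai(a, b)
  expect_false(res$defined)
  expect_true(is.na(res$aai))
  expect_equal(res$n_rbh, 0L)
})

test_that("pocp matches the published formula on a worked case", {
  withr::local_seed(303)
  shared <- vapply(rep(60, 3), rand_protein, character(1))
  a <- proteome("a", data.frame(
    id = paste0("a", 1:4), seq = c(shared, rand_protein(60))))
  b <- proteome("b", data.frame(
    id = paste0("b", 1:6),
    seq = c(shared, vapply(rep(60, 3), rand_protein, character(1)))))
  res <- pocp(a, b)
  expect_equal(res$c_a, 3L); expect_equal(res$c_b, 3L)
  expect_equal(res$t_a, 4L); expect_equal(res$t_b, 6L)
  expect_identical(res$pocp, 60)   # 100 * (3+3) / (4+6), exactly

  expect_equal(pocp(a, a)$pocp, 100)
  # completely unrelated short proteomes: no qualifying hits
  u <- make_proteome("u", vapply(rep(30, 3), rand_protein, character(1)))
  v <- make_proteome("v", vapply(rep(30, 3), rand_protein, character(1)))
  expect_equal(pocp(u, v)$pocp, 0)
})

test_that("pocp agrees with a per-hit oracle and is symmetric", {
  withr::local_seed(404)
  a <- make_proteome("a", c(vapply(rep(50, 4), rand_protein, character(1))))
  bseqs <- c(plant_subs(a$proteins$seq[1], 5),
             plant_subs(a$proteins$seq[2], 25),
             rand_protein(50), rand_protein(50), rand_protein(50))
  b <- make_proteome("b", bseqs)
  res <- pocp(a, b)

  count_conserved <- function(qs, ss) {
    sum(vapply(qs, function(q) {
      any(vapply(ss, function(s) {
        r <- oracle_align(q, s, local = TRUE)
        !is.null(r) &&
          oracle_evalue(r$score, nchar(q), nchar(s)) < 1e-5 &&
          r$identity > 40 && (100 * r$qres / nchar(q)) > 50
      }, logical(1)))
    }, logical(1)))
  }
  expect_equal(res$c_a, count_conserved(a$proteins$seq, b$proteins$seq))
  expect_equal(res$c_b, count_conserved(b$proteins$seq, a$proteins$seq))
  ba <- pocp(b, a)
  expect_identical(res$pocp, ba$pocp)
  expect_identical(res$c_a, ba$c_b)
})

test_that("marker-subset AAI averages global identities of shared markers", {
  withr::local_seed(21)
  m1 <- rand_protein(60); m2 <- rand_protein(60); m3 <- rand_protein(60)
  a <- proteome("a", data.frame(id = c("a1", "a2", "a3"),
                                seq = c(m1, m2, m3)))
  b <- proteome("b", data.frame(id = c("b1", "b2"),
                                seq = c(m1, plant_subs(m2, 12))))
  map <- list(a = c(mk1 = "a1", mk2 = "a2", mk3 = "a3"),
              b = c(mk1 = "b1", mk2 = "b2"))
  res <- marker_aai(a, b, map)
  expect_equal(res$n_markers, 2L)
  expect_equal(res$aai, mean(c(100, 100 * 48 / 60)))

  expect_equal(marker_aai(a, a, list(a = map$a))$aai, 100)
  no_shared <- marker_aai(a, b, list(a = c(mk9 = "a1"),
                                     b = c(mk8 = "b1")))
  expect_false(no_shared$defined)
})

test_that("increasing planted divergence never increases mean AAI", {
  withr::local_seed(77)
  base <- vapply(rep(50, 10), rand_protein, character(1))
  a <- make_proteome("a", base)
  rates <- c(2, 6, 10, 15, 20)
  means <- vapply(rates, function(k) {
    b <- make_proteome("b", vapply(base, plant_subs, character(1), k))
    aai(a, b)$aai
  }, numeric(1))
  expect_true(all(diff(means) <= 1))  # tolerance one point
})
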