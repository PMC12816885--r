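pm_row <- function(a, b, aai, pocp) {
  data.frame(genome_a = a, genome_b = b, aai = aai, n_rbh = 10L,
              pocp = pocp, c_a = 5L, c_b = 5L, t_a = 10L, t_b = 10L)
}

test_that("build_graph applies joint thresholds inclusively", {
  m <- rbind(pm_row("a", "b", 75, 55),    # both pass
             pm_row("a", "c", 75, 45),    # POCP fails
             pm_row("b", "c", 71.9, 90),  # AAI below boundary
             pm_row("a", "d", 72, 50))    # exactly at both thresholds
  g <- build_graph(m, aai_threshold = 72, pocp_threshold = 50)
  expect_setequal(g$vertices, c("a", "b", "c", "d"))
  expect_equal(nrow(g$edges), 2L)
  expect_true(any(g$edges[, 1] == "a" & g$edges[, 2] == "b"))
  expect_true(any(g$edges[, 1] == "a" & g$edges[, 2] == "d"))

  # undefined AAI contributes no edge
  m2 <- rbind(pm_row("a", "b", NA, 90))
  expect_equal(nrow(build_graph(m2, 72)$edges), 0L)

  # duplicate pair rows (either orientation) are rejected
  m3 <- rbind(pm_row("a", "b", 75, 55), pm_row("b", "a", 60, 20))
  expect_error(build_graph(m3, 72), "duplicate pair")
})

test_that("graph_components returns sorted components incl. singletons", {
  m <- rbind(pm_row("a", "b", 90, 90), pm_row("b", "c", 90, 90),
             pm_row("c", "d", 10, 10), pm_row("a", "d", 10, 10),
             pm_row("b", "d", 10, 10), pm_row("a", "c", 10, 10))
  g <- build_graph(m, 50)
  comps <- graph_components(g)
  expect_equal(comps, list(c("a", "b", "c"), "d"))

  # empty edge set: all singletons
  g0 <- build_graph(m, 99)
  expect_equal(graph_components(g0), list("a", "b", "c", "d"))

  # complete graph: one component
  gc <- build_graph(m, 5, 5)
  expect_equal(graph_components(gc), list(c("a", "b", "c", "d")))
})

test_that("monophyly_test identifies intruders via the MRCA", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  t1 <- monophyly_test(tr, c("A", "B"))
  expect_true(t1$is_monophyletic)
  expect_equal(t1$intruders, character(0))

  t2 <- monophyly_test(tr, c("A", "C"))
  expect_false(t2$is_monophyletic)
  expect_equal(t2$intruders, c("B", "D"))
  expect_equal(t2$mrca, 5L)  # the root

  expect_true(monophyly_test(tr, "A")$is_monophyletic)
  expect_error(monophyly_test(tr, c("A", "Z")), "Z")
})

test_that("delineate keeps clean clades and excludes monophyly breakers", {
  tr <- read_newick("(((A:1,B:1):1,X:2):1,((C:1,D:1):1,Y:2):1);")
  # two criterion components matching the two planted clades
  m <- rbind(pm_row("A", "B", 90, 90), pm_row("C", "D", 90, 90),
             pm_row("A", "C", 60, 40), pm_row("A", "D", 60, 40),
             pm_row("B", "C", 60, 40), pm_row("B", "D", 60, 40))
  part <- delineate(tr, build_graph(m, 72))
  expect_equal(unname(part$groups), list(c("A", "B"), c("C", "D")))
  expect_equal(nrow(part$excluded), 0L)

  # component {A, B, Y} where Y sits outside the (A,B) clade
  m2 <- rbind(pm_row("A", "B", 90, 90), pm_row("A", "Y", 80, 80),
              pm_row("B", "Y", 80, 80))
  part2 <- delineate(tr, build_graph(m2, 72))
  expect_equal(unname(part2$groups), list(c("A", "B")))
  expect_equal(part2$excluded$genome_id, "Y")
  expect_equal(part2$excluded$reason, "breaks_monophyly")

  # isolated vertices stay as singleton groups, not exclusions
  m3 <- rbind(pm_row("A", "B", 10, 10), pm_row("C", "D", 10, 10))
  part3 <- delineate(tr, build_graph(m3, 72))
  expect_equal(length(part3$groups), 4L)
  expect_equal(nrow(part3$excluded), 0L)

  expect_error(delineate(read_newick("(A:1,B:1);"),
                         build_graph(m2, 72)), "absent from tree")
})

test_that("every genome lands exactly once in groups or excluded", {
  withr::local_seed(61)
  for (k in 1:5) {
    tr <- ape::rtree(8)
    tr$tip.label <- sort(tr$tip.label)
    ids <- tr$tip.label
    pairs <- t(combn(ids, 2))
    m <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
      pm_row(pairs[r, 1], pairs[r, 2],
             sample(c(60, 90), 1), sample(c(40, 90), 1))
    }))
    part <- delineate(tr, build_graph(m, 72))
    all_ids <- c(unlist(part$groups), part$excluded$genome_id)
    expect_setequal(all_ids, ids)
    expect_equal(anyDuplicated(all_ids), 0L)
    # exhaustive check: every reported group is monophyletic
    for (g in part$groups) {
      expect_true(monophyly_test(tr, g)$is_monophyletic)
    }
  }
})

test_that("delineate is idempotent on its own groups", {
  withr::local_seed(62)
  tr <- ape::rtree(10)
  ids <- tr$tip.label
  pairs <- t(combn(ids, 2))
  m <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    pm_row(pairs[r, 1], pairs[r, 2],
           sample(c(60, 90), 1), 90)
  }))
  part <- delineate(tr, build_graph(m, 72))
  for (g in part$groups) {
    keep <- m$genome_a %in% g & m$genome_b %in% g
    if (!any(keep)) next
    sub <- delineate(tr, build_graph(m[keep, , drop = FALSE], 72))
    regrouped <- sub$groups[vapply(sub$groups, length, 1L) > 0]
    expect_true(any(vapply(regrouped, setequal, logical(1), g)))
    expect_equal(nrow(sub$excluded), 0L)
  }
})
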