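test_that("sim_config validates its fields and lists all violations", {
  cfg <- sim_config()
  expect_s3_class(cfg, "sim_config")
  err <- tryCatch(sim_config(n_genera = 1, intra_depth = 0.5,
                             inter_depth = 0.2),
                  error = function(e) conditionMessage(e))
  expect_match(err, "n_genera")
  expect_match(err, "inter_depth")
  expect_error(sim_config(marker_genera = "g9"), "marker_genera")
  expect_error(sim_config(loss_prob_per_branch = 1), "loss_prob")
})

test_that("simulate_tree plants monophyletic, ultrametric genus clades", {
  cfg <- sim_config(n_genera = 2, genomes_per_genus = 3, seed = 5)
  st <- simulate_tree(cfg)
  expect_equal(length(st$tree$tip.label), 6L)
  expect_equal(sort(unique(unname(st$truth$genus))), c("g1", "g2"))
  for (g in c("g1", "g2")) {
    tips <- names(st$truth$genus)[st$truth$genus == g]
    expect_true(monophyly_test(st$tree, tips)$is_monophyletic)
  }
  # ultrametric: all leaves at depth inter_depth / 2
  depths <- ape::node.depth.edgelength(st$tree)[1:6]
  expect_equal(depths, rep(cfg$inter_depth / 2, 6), tolerance = 1e-9)
  # between-genus pairs at distance inter_depth exactly; crown pairs at
  # intra_depth
  d <- stats::cophenetic(st$tree)
  inter <- d[paste0("g1_s0", 1:3), paste0("g2_s0", 1:3)]
  expect_equal(unname(inter), matrix(cfg$inter_depth, 3, 3),
               tolerance = 1e-9)
  intra <- d[paste0("g1_s0", 1:3), paste0("g1_s0", 1:3)]
  expect_equal(max(intra), cfg$intra_depth, tolerance = 1e-9)
})

test_that("identical configurations yield byte-identical outputs", {
  cfg <- sim_config(genomes_per_genus = 3, n_families = 20, seed = 11)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(write_newick(d1$tree), write_newick(d2$tree))
  expect_identical(d1$proteomes, d2$proteomes)
  expect_identical(d1$marker$genes, d2$marker$genes)
  expect_identical(d1$marker$phenotype, d2$marker$phenotype)
  # a different seed changes the data
  d3 <- simulate_dataset(sim_config(genomes_per_genus = 3,
                                    n_families = 20, seed = 12))
  expect_false(identical(d1$proteomes, d3$proteomes))
})

test_that("a zero-length tree yields identical proteomes with AAI 100", {
  cfg <- sim_config(genomes_per_genus = 2, n_families = 10,
                    loss_prob_per_branch = 0, seed = 3)
  st <- simulate_tree(cfg)
  tr0 <- st$tree
  tr0$edge.length[] <- 0
  pr <- simulate_proteomes(tr0, cfg)
  seqs <- lapply(pr$proteomes, function(p) unname(p$proteins$seq))
  for (k in 2:length(seqs)) expect_identical(seqs[[k]], seqs[[1]])
  res <- aai(pr$proteomes[[1]], pr$proteomes[[2]])
  expect_equal(res$aai, 100)
})

test_that("without gene loss POCP is 100 between related proteomes", {
  cfg <- sim_config(genomes_per_genus = 2, n_families = 30,
                    loss_prob_per_branch = 0, seed = 13)
  st <- simulate_tree(cfg)
  pr <- simulate_proteomes(st$tree, cfg)
  p <- pr$proteomes
  g1 <- names(which(st$truth$genus == "g1"))
  res <- pocp(p[[g1[1]]], p[[g1[2]]])
  expect_equal(res$pocp, 100)
  expect_true(all(pr$truth$presence))
})

test_that("realized identities track the truth-table expectation", {
  cfg <- sim_config(genomes_per_genus = 3, n_families = 120,
                    loss_prob_per_branch = 0, seed = 21)
  st <- simulate_tree(cfg)
  pr <- simulate_proteomes(st$tree, cfg)
  genomes <- names(pr$proteomes)
  # raw per-site identity (equal-length families, no alignment) vs the
  # closed-form expectation, per pair
  for (pair in list(c(1, 2), c(1, 4), c(2, 5))) {
    a <- pr$proteomes[[genomes[pair[1]]]]$proteins$seq
    b <- pr$proteomes[[genomes[pair[2]]]]$proteins$seq
    ach <- strsplit(paste(a, collapse = ""), "")[[1]]
    bch <- strsplit(paste(b, collapse = ""), "")[[1]]
    realized <- 100 * mean(ach == bch)
    expected <- pr$truth$expected_identity[genomes[pair[1]],
                                           genomes[pair[2]]]
    expect_lt(abs(realized - expected), 2)
  }
})

test_that("gene loss is irreversible along paths", {
  cfg <- sim_config(genomes_per_genus = 4, n_families = 60,
                    loss_prob_per_branch = 0.15, seed = 31)
  st <- simulate_tree(cfg)
  pr <- simulate_proteomes(st$tree, cfg)
  pres <- pr$truth$presence
  expect_true(any(!pres))          # losses happened
  # every retained protein id is mapped in marker_map and exists
  for (g in rownames(pres)) {
    p <- pr$proteomes[[g]]
    expect_equal(sum(pres[g, ]), p$n_proteins)
    expect_setequal(unname(pr$marker_map[[g]]), p$proteins$id)
  }
})

test_that("the planted marker tracks genus membership and phenotype", {
  cfg <- sim_config(seed = 41)
  st <- simulate_tree(cfg)
  mk <- simulate_marker(st$tree, cfg)
  clade <- validated_clade(mk$gtree)
  mem <- genome_membership(mk$gtree, clade)
  g1 <- names(st$truth$genus)[st$truth$genus == "g1"]
  expect_setequal(names(mem), st$tree$tip.label)   # paralogs present
  expect_true(all(mem[g1]))
  expect_false(any(mem[setdiff(names(mem), g1)]))
  ct <- concordance(mem, mk$phenotype)
  expect_equal(ct$agreement, 1)

  # all genera carrying: membership all true (the validated clade is
  # then the whole gene tree, which warns about degeneracy)
  cfg2 <- sim_config(marker_genera = c("g1", "g2"), seed = 41)
  mk2 <- simulate_marker(st$tree, cfg2)
  expect_warning(clade2 <- validated_clade(mk2$gtree), "root")
  mem2 <- genome_membership(mk2$gtree, clade2)
  expect_true(all(mem2))

  # planted discordance lowers agreement accordingly
  cfg3 <- sim_config(n_discordant = 1, seed = 41)
  mk3 <- simulate_marker(st$tree, cfg3)
  mem3 <- genome_membership(mk3$gtree, validated_clade(mk3$gtree))
  expect_equal(concordance(mem3, mk3$phenotype)$agreement, 0.9)
})

test_that("simulate_dataset writes a complete, reloadable run directory", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(genomes_per_genus = 2, n_families = 15, seed = 51)
  ds <- simulate_dataset(cfg, dir = dir)
  faa <- list.files(file.path(dir, "proteomes"), pattern = "\\.faa$")
  expect_equal(length(faa), 4L)
  back <- read_proteome(file.path(dir, "proteomes", faa[1]))
  expect_identical(back$proteins$seq,
                   ds$proteomes[[back$genome_id]]$proteins$seq)
  tr <- read_newick(file.path(dir, "tree.nwk"))
  expect_setequal(tr$tip.label, ds$tree$tip.label)
  expect_true(file.exists(file.path(dir, "phenotype.tsv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
})

test_that("file-based marker and phenotype inputs reload into working objects", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(genomes_per_genus = 2, n_families = 12, seed = 91)
  ds <- simulate_dataset(cfg, dir = dir)
  gt <- read_gene_tree(file.path(dir, "gene_tree.nwk"),
                       file.path(dir, "gene_to_genome.tsv"),
                       file.path(dir, "reference_ids.txt"))
  ph <- read_phenotype(file.path(dir, "phenotype.tsv"))
  mem <- genome_membership(gt, validated_clade(gt))
  ct <- concordance(mem, ph)
  expect_equal(ct$agreement, 1)
  expect_equal(ct$total, 4L)

  # marker map round trip for marker-subset AAI
  map_rows <- do.call(rbind, lapply(names(ds$marker_map), function(g) {
    data.frame(genome_id = g,
               marker_name = names(ds$marker_map[[g]]),
               protein_id = unname(ds$marker_map[[g]]))
  }))
  tf <- file.path(dir, "marker_map.tsv")
  write.table(map_rows, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  map <- read_marker_map(tf)
  g12 <- names(ds$proteomes)[1:2]
  res <- marker_aai(ds$proteomes[[g12[1]]], ds$proteomes[[g12[2]]], map)
  expect_true(res$defined)
  expect_gt(res$aai, 50)

  # taxon map reader
  tax_rows <- data.frame(taxon = unname(ds$truth$genus),
                         tip_id = names(ds$truth$genus))
  tf2 <- file.path(dir, "taxa.tsv")
  write.table(tax_rows, tf2, sep = "\t", quote = FALSE, row.names = FALSE)
  taxa <- read_taxon_map(tf2)
  rs <- rank_summary(compute_red(ds$tree), taxa)
  expect_equal(length(rs$values), 2L)
})
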