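AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Configuration for the synthetic genome set
#'
#' Defines the study conditions emulated by the generator: a balanced
#' set of genera whose proteomes diverge with tree distance under a
#' uniform 20-state (Poisson) substitution model, branch-wise
#' irreversible gene loss, and a marker gene restricted to a subset of
#' genera with a matched phenotype.
#'
#' `intra_depth` is the within-genus crown divergence: the pairwise
#' distance (expected substitutions per site, summed over both
#' lineages) between the two deepest-diverging genomes of a genus.
#' `inter_depth` is the pairwise distance between genomes of different
#' genera (the tree is ultrametric, so this is the same for every
#' between-genus pair). Under the uniform model the expected percent
#' identity at pairwise distance `d` is
#' `floor + (100 - floor) * exp(-d * 20/19)` with `floor = 5` (the
#' random-alignment baseline of a 20-letter alphabet). The defaults
#' place the deepest within-genus pairs near 85% identity (shallower
#' pairs higher) and every between-genus pair near 70%, so the pooled
#' AAI distribution is bimodal with a planted valley between roughly
#' 70 and 85%.
#'
#' @param n_genera Number of genera (>= 2).
#' @param genomes_per_genus Genomes per genus (>= 2).
#' @param intra_depth Within-genus crown pairwise divergence
#'   (substitutions/site).
#' @param inter_depth Between-genus pairwise divergence; must exceed
#'   `intra_depth`. The default is calibrated so that the realized AAI
#'   (which sits slightly above the raw expected site identity because
#'   local alignments trim poorly matching ends) is close to 70%.
#' @param crown_shape Exponent in `(0, 1]` applied to relative
#'   within-genus coalescence depths; values below 1 pull coalescence
#'   events toward the genus crown, concentrating within-genus pairwise
#'   identities near the planted crown identity (1 leaves the raw
#'   coalescent depths unchanged).
#' @param n_families Number of protein families.
#' @param family_length Family length in amino acids (no indels are
#'   simulated, so family length is constant across genomes).
#' @param loss_prob_per_branch Probability that a family is lost on any
#'   given branch (irreversible; drives POCP below 100).
#' @param identity_floor Random-alignment identity baseline used in the
#'   truth table (percent; 5 under the uniform 20-state model).
#' @param marker_genera Genus labels whose genomes carry the validated
#'   marker lineage.
#' @param n_reference Number of reference (validated) marker sequences.
#' @param marker_length Marker gene length (aa).
#' @param n_discordant Number of genomes whose phenotype is flipped
#'   relative to marker carriage (planted discordance).
#' @param seed Integer seed; identical configurations produce
#'   byte-identical outputs.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_genera = 2, genomes_per_genus = 5,
                       intra_depth = 0.1633, inter_depth = 0.3812,
                       crown_shape = 0.2,
                       n_families = 150, family_length = 50,
                       loss_prob_per_branch = 0.02,
                       identity_floor = 5,
                       marker_genera = "g1",
                       n_reference = 3, marker_length = 120,
                       n_discordant = 0,
                       seed = 1) {
  cfg <- list(n_genera = as.integer(n_genera),
              genomes_per_genus = as.integer(genomes_per_genus),
              intra_depth = intra_depth, inter_depth = inter_depth,
              crown_shape = crown_shape,
              n_families = as.integer(n_families),
              family_length = as.integer(family_length),
              loss_prob_per_branch = loss_prob_per_branch,
              identity_floor = identity_floor,
              marker_genera = marker_genera,
              n_reference = as.integer(n_reference),
              marker_length = as.integer(marker_length),
              n_discordant = as.integer(n_discordant),
              seed = as.integer(seed))
  problems <- character()
  if (cfg$n_genera < 2) problems <- c(problems, "n_genera must be >= 2")
  if (cfg$genomes_per_genus < 2) {
    problems <- c(problems, "genomes_per_genus must be >= 2")
  }
  if (!(cfg$inter_depth > cfg$intra_depth)) {
    problems <- c(problems, "inter_depth must exceed intra_depth")
  }
  if (cfg$intra_depth <= 0) {
    problems <- c(problems, "intra_depth must be positive")
  }
  if (cfg$identity_floor < 0 || cfg$identity_floor >= 100) {
    problems <- c(problems, "identity_floor must be in [0, 100)")
  }
  if (cfg$loss_prob_per_branch < 0 || cfg$loss_prob_per_branch >= 1) {
    problems <- c(problems, "loss_prob_per_branch must be in [0, 1)")
  }
  if (cfg$crown_shape <= 0 || cfg$crown_shape > 1) {
    problems <- c(problems, "crown_shape must be in (0, 1]")
  }
  if (!all(cfg$marker_genera %in% paste0("g", seq_len(cfg$n_genera)))) {
    problems <- c(problems, "marker_genera must be genus labels g1..gN")
  }
  if (length(problems) > 0) {
    stop("invalid simulation config:\n  ",
         paste(problems, collapse = "\n  "))
  }
  structure(cfg, class = "sim_config")
}

#' Expected percent identity at a given pairwise distance
#'
#' Closed form for the uniform 20-state substitution model:
#' `floor + (100 - floor) * exp(-d * 20/19)`.
#'
#' @param d Pairwise distance (expected substitutions/site).
#' @param floor Random-alignment baseline (percent).
#' @return Expected percent identity.
#' @export
expected_identity <- function(d, floor = 5) {
  floor + (100 - floor) * exp(-d * 20 / 19)
}

#' Simulate a species tree with planted genus structure
#'
#' Builds an ultrametric tree: each genus is a random coalescent
#' subtree rescaled to height `intra_depth / 2` (so the deepest
#' within-genus pair is at distance exactly `intra_depth`), and all
#' genus subtrees hang from the root at total leaf depth
#' `inter_depth / 2`, so that every between-genus pair is at distance
#' exactly `inter_depth`. Genus clades are monophyletic by
#' construction. Tip labels are `g<genus>_s<index>`.
#'
#' @param cfg A [sim_config()].
#' @return List with `tree` (`phylo`) and `truth` (list with `genus`,
#'   the genome -> genus map; `distances`; `expected_identity`).
#' @export
simulate_tree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    m <- cfg$genomes_per_genus
    subtrees <- lapply(seq_len(cfg$n_genera), function(g) {
      tr <- ape::rcoal(m, tip.label = sprintf("g%d_s%02d", g, seq_len(m)))
      # concentrate coalescences toward the genus crown, then rescale
      # the crown to height intra_depth / 2
      bt <- ape::branching.times(tr)
      height <- max(bt)
      bt <- height * (bt / height)^cfg$crown_shape
      h <- numeric(m + tr$Nnode)
      h[as.integer(names(bt))] <- bt
      tr$edge.length <- (h[tr$edge[, 1]] - h[tr$edge[, 2]]) *
        (cfg$intra_depth / 2) / height
      tr
    })
  })
  heights <- vapply(subtrees, function(tr) {
    max(ape::node.depth.edgelength(tr))
  }, numeric(1))
  stems <- cfg$inter_depth / 2 - heights
  if (any(stems <= 0)) {
    stop("genus subtrees deeper than inter_depth/2; ",
         "increase inter_depth or decrease intra_depth")
  }
  cores <- vapply(subtrees, function(tr) {
    sub(";$", "", ape::write.tree(tr))
  }, character(1))
  nwk <- paste0("(", paste0(cores, ":", sprintf("%.12g", stems),
                            collapse = ","), ");")
  tree <- read_newick(nwk)
  genus <- setNames(sub("_.*$", "", tree$tip.label), tree$tip.label)
  dmat <- stats::cophenetic(tree)
  list(tree = tree,
       truth = list(genus = genus, distances = dmat,
                    expected_identity =
                      expected_identity(dmat, cfg$identity_floor)))
}

# one substitution round: sites with pending events jump uniformly to
# one of the other 19 states
mutate_states <- function(s, expected_subs) {
  k <- rpois(length(s), expected_subs)
  active <- which(k > 0)
  while (length(active) > 0) {
    shift <- sample.int(19, length(active), replace = TRUE)
    s[active] <- ((s[active] - 1 + shift) %% 20) + 1
    k[active] <- k[active] - 1
    active <- active[k[active] > 0]
  }
  s
}

states_to_seq <- function(s) {
  paste(AA_LETTERS[s], collapse = "")
}

# evolve integer state matrices (rows = families or one marker) down a
# phylo tree; returns per-leaf state matrices and per-leaf family
# presence (loss applied branch-wise, irreversibly)
evolve_on_tree <- function(tree, root_states, loss_prob) {
  nt <- n_tips(tree)
  n_nodes <- nt + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  states <- vector("list", n_nodes)
  present <- vector("list", n_nodes)
  rt <- root_node(tree)
  states[[rt]] <- root_states
  present[[rt]] <- rep(TRUE, nrow(root_states))
  for (k in rev(seq_len(nrow(po$edge)))) {   # preorder
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    bl <- po$edge.length[k]
    st <- states[[p]]
    st[] <- mutate_states(as.vector(st), bl)
    lost <- runif(nrow(st)) < loss_prob
    states[[ch]] <- st
    present[[ch]] <- present[[p]] & !lost
  }
  list(states = states[seq_len(nt)], present = present[seq_len(nt)],
       labels = tree$tip.label)
}

#' Simulate proteomes along a species tree
#'
#' Each protein family starts from a uniformly random root sequence and
#' evolves along the tree by per-site Poisson substitutions (uniform
#' replacement among the other 19 amino acids) at the branch's expected
#' substitutions/site; families are lost independently on each branch
#' with probability `loss_prob_per_branch`, and a loss is inherited by
#' the whole subtree. No indels are simulated, so orthologous family
#' members stay equal-length.
#'
#' @param tree Species tree from [simulate_tree()] (`phylo`).
#' @param cfg A [sim_config()].
#' @return List with `proteomes` (named list of [proteome()]),
#'   `marker_map` (per-genome named vector: family -> protein id, for
#'   marker-subset AAI), and `truth` (family presence matrix and the
#'   per-pair expected identities).
#' @export
simulate_proteomes <- function(tree, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 1L, {
    root <- matrix(sample.int(20, cfg$n_families * cfg$family_length,
                              replace = TRUE),
                   nrow = cfg$n_families)
    ev <- evolve_on_tree(tree, root, cfg$loss_prob_per_branch)
  })
  fam_names <- sprintf("fam%03d", seq_len(cfg$n_families))
  proteomes <- list()
  marker_map <- list()
  presence <- matrix(FALSE, length(ev$labels), cfg$n_families,
                     dimnames = list(ev$labels, fam_names))
  for (i in seq_along(ev$labels)) {
    genome <- ev$labels[i]
    keep <- which(ev$present[[i]])
    if (length(keep) == 0) {
      stop("genome ", genome, " lost every family; ",
           "lower loss_prob_per_branch")
    }
    presence[i, keep] <- TRUE
    ids <- sprintf("%s_%s", genome, fam_names[keep])
    seqs <- vapply(keep, function(f) states_to_seq(ev$states[[i]][f, ]),
                   character(1))
    proteomes[[genome]] <- proteome(
      genome, data.frame(id = ids, desc = "", seq = seqs,
                         stringsAsFactors = FALSE))
    marker_map[[genome]] <- setNames(ids, fam_names[keep])
  }
  dmat <- stats::cophenetic(tree)
  list(proteomes = proteomes, marker_map = marker_map,
       truth = list(presence = presence, distances = dmat,
                    expected_identity =
                      expected_identity(dmat, cfg$identity_floor)))
}

#' Simulate a clade-restricted marker gene with phenotype labels
#'
#' Genomes of the genera in `marker_genera` carry the validated marker
#' lineage; reference sequences (standing in for experimentally
#' validated genes) branch from the root of the carrier clade, so their
#' MRCA circumscribes exactly the carriers. All remaining genomes carry
#' a distant paralog in a sister clade, so their clade membership is
#' `FALSE` rather than missing. The phenotype equals marker carriage,
#' with `n_discordant` genomes flipped.
#'
#' @param tree Species tree (`phylo`).
#' @param cfg A [sim_config()].
#' @return List with `genes` (sequence table), `gtree`
#'   ([gene_tree()]), `phenotype` (named logical), `carriers`
#'   (character vector) and `discordant` (flipped genomes).
#' @export
simulate_marker <- function(tree, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  genus <- sub("_.*$", "", tree$tip.label)
  carriers <- tree$tip.label[genus %in% cfg$marker_genera]
  others <- setdiff(tree$tip.label, carriers)
  if (length(carriers) < 2) stop("need >= 2 carrier genomes")

  ref_ids <- sprintf("ref%02d", seq_len(cfg$n_reference))
  ref_bl <- 0.03
  carrier_tr <- ape::keep.tip(tree, carriers)
  carrier_tr$tip.label <- paste0(carrier_tr$tip.label, "_tnaA")
  core <- sub(";$", "", ape::write.tree(carrier_tr))
  grafted <- paste0(substr(core, 1, nchar(core) - 1), ",",
                    paste0(ref_ids, ":", ref_bl, collapse = ","), ")")
  if (length(others) > 0) {
    par_tr <- ape::keep.tip(tree, others)
    par_tr$tip.label <- paste0(par_tr$tip.label, "_tnaX")
    par_core <- sub(";$", "", ape::write.tree(par_tr))
    nwk <- paste0("(", grafted, ":0.4,", par_core, ":0.4);")
  } else {
    nwk <- paste0(grafted, ";")
  }
  gtr <- read_newick(nwk)

  withr::with_seed(cfg$seed + 2L, {
    root <- matrix(sample.int(20, cfg$marker_length, replace = TRUE),
                   nrow = 1)
    ev <- evolve_on_tree(gtr, root, 0)
    flipped <- if (cfg$n_discordant > 0) {
      sort(sample(tree$tip.label, cfg$n_discordant))
    } else character()
  })
  genes <- data.frame(
    id = ev$labels, desc = "",
    seq = vapply(ev$states, function(st) states_to_seq(st[1, ]),
                 character(1)),
    stringsAsFactors = FALSE)

  gene_genome <- sub("_tna[AX]$", "", ev$labels)
  gene_genome[ev$labels %in% ref_ids] <- "reference"
  gtree <- gene_tree(gtr, setNames(gene_genome, ev$labels), ref_ids)

  phenotype <- setNames(tree$tip.label %in% carriers, tree$tip.label)
  phenotype[flipped] <- !phenotype[flipped]
  list(genes = genes, gtree = gtree, phenotype = phenotype,
       carriers = carriers, discordant = flipped)
}

#' Generate a complete synthetic data set
#'
#' Runs [simulate_tree()], [simulate_proteomes()] and
#' [simulate_marker()] under one configuration and, optionally, writes
#' all inputs to a run directory (per-genome proteome FASTA, species
#' tree Newick, marker FASTA, gene tree Newick, gene-to-genome TSV,
#' phenotype TSV, truth JSON).
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory (created if needed).
#' @return List with `tree`, `proteomes`, `marker_map`, `marker`,
#'   `truth` and `cfg`.
#' @export
simulate_dataset <- function(cfg = sim_config(), dir = NULL) {
  st <- simulate_tree(cfg)
  pr <- simulate_proteomes(st$tree, cfg)
  mk <- simulate_marker(st$tree, cfg)
  truth <- list(genus = st$truth$genus,
                distances = pr$truth$distances,
                expected_identity = pr$truth$expected_identity,
                presence = pr$truth$presence,
                carriers = mk$carriers,
                discordant = mk$discordant)
  out <- list(tree = st$tree, proteomes = pr$proteomes,
              marker_map = pr$marker_map, marker = mk,
              truth = truth, cfg = cfg)
  if (!is.null(dir)) write_dataset(out, dir)
  out
}

write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "proteomes"), recursive = TRUE,
             showWarnings = FALSE)
  for (g in names(dataset$proteomes)) {
    write_fasta(dataset$proteomes[[g]]$proteins,
                file.path(dir, "proteomes", paste0(g, ".faa")))
  }
  write_newick(dataset$tree, file.path(dir, "tree.nwk"))
  write_fasta(dataset$marker$genes, file.path(dir, "marker_genes.faa"))
  write_newick(dataset$marker$gtree$tree,
               file.path(dir, "gene_tree.nwk"))
  map <- dataset$marker$gtree$gene_to_genome
  write.table(data.frame(gene_id = names(map), genome_id = unname(map)),
              file.path(dir, "gene_to_genome.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ph <- dataset$marker$phenotype
  write.table(data.frame(genome_id = names(ph),
                         phenotype = ifelse(ph, "positive", "negative")),
              file.path(dir, "phenotype.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(dataset$marker$gtree$reference_ids,
             file.path(dir, "reference_ids.txt"))
  truth <- dataset$truth
  jsonlite::write_json(
    list(genus = as.list(truth$genus),
         carriers = truth$carriers,
         discordant = truth$discordant,
         expected_identity =
           as.data.frame(as.table(truth$expected_identity))),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
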