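#' Configure an alignment simulation with planted synapomorphies
#'
#' Describes a synthetic dataset: a rooted tree over `n_taxa` taxa in which
#' `planted_clade` is constrained to be monophyletic, exon loci evolved
#' along that tree, `n_planted` clade-diagnostic substitutions overwritten
#' into the alignment as exact ground truth, and per-cell missingness and
#' negative-binomial sequencing coverage.
#'
#' @param seed Integer seed; all randomness derives from it (per-locus
#'   streams use `seed + locus index`).
#' @param n_taxa Number of taxa.
#' @param planted_clade Character vector of taxa forming the ground-truth
#'   clade; must be a proper, non-empty subset of the taxon set.
#' @param taxa Taxon names; defaults to NVG-style specimen codes.
#' @param n_loci Number of exon loci (excluding the optional barcode).
#' @param locus_length Length of each exon locus in bp.
#' @param tree_source Either a newick string (fixed topology) or a list
#'   `list(birth_rate = )` for a pure-birth (Yule) tree, rate per lineage
#'   per unit time.
#' @param subst_model `list(model = "JC69")` or `list(model = "GTR",
#'   rates = <6 exchangeabilities>, base_freq = <4 frequencies>)`.
#' @param subst_rate Multiplier applied to branch lengths before evolving
#'   sequences (expected substitutions per site per unit branch length).
#'   Zero evolves an invariant alignment, isolating planted characters.
#' @param n_planted Number of synapomorphies planted for the clade across
#'   the exon loci.
#' @param n_planted_barcode Synapomorphies planted on the COI barcode.
#' @param missing_fraction Per-cell probability that a state is masked to
#'   `N`; in `[0, 1)`.
#' @param coverage_mean,coverage_dispersion Mean and dispersion (negative
#'   binomial `size`) of per-cell read depth; unmasked cells draw
#'   `1 + NB(mu = coverage_mean - 1, size = dispersion)` so depth is at
#'   least 1 with mean exactly `coverage_mean`; masked cells have depth 0.
#' @param include_barcode Add a 658-bp COI barcode locus
#'   (partition `coi_barcode`).
#' @param prefix Reference-genome tag used in locus ids.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed, n_taxa, planted_clade,
                              taxa = default_taxa(n_taxa),
                              n_loci = 20, locus_length = 300,
                              tree_source = list(birth_rate = 1),
                              subst_model = list(model = "JC69"),
                              subst_rate = 0.1,
                              n_planted = 10, n_planted_barcode = 0,
                              missing_fraction = 0,
                              coverage_mean = 20, coverage_dispersion = 5,
                              include_barcode = TRUE, prefix = "aly") {
  stopifnot(is.numeric(seed), length(seed) == 1,
            n_taxa >= 2, n_loci >= 1, locus_length >= 1)
  stopifnot(length(taxa) == n_taxa, !anyDuplicated(taxa))
  if (!length(planted_clade) || !all(planted_clade %in% taxa) ||
      length(planted_clade) >= n_taxa) {
    abort("planted_clade must be a proper non-empty subset of the taxon set")
  }
  if (missing_fraction < 0 || missing_fraction >= 1) {
    abort("missing_fraction must lie in [0, 1)")
  }
  if (coverage_mean < 1) abort("coverage_mean must be at least 1")
  total <- n_loci * locus_length
  if (n_planted > total) abort("n_planted exceeds the total alignment length")
  if (n_planted_barcode > 0 && !include_barcode) {
    abort("n_planted_barcode > 0 requires include_barcode = TRUE")
  }
  if (n_planted_barcode > 658) abort("n_planted_barcode exceeds the 658-bp barcode")
  if (!subst_model$model %in% c("JC69", "GTR")) {
    abort(paste0("unknown substitution model: ", subst_model$model))
  }
  if (subst_model$model == "GTR") {
    stopifnot(length(subst_model$rates) == 6, length(subst_model$base_freq) == 4,
              all(subst_model$rates > 0), all(subst_model$base_freq > 0))
  }
  structure(list(seed = as.integer(seed), n_taxa = as.integer(n_taxa),
                 taxa = taxa, planted_clade = planted_clade,
                 n_loci = as.integer(n_loci),
                 locus_length = as.integer(locus_length),
                 tree_source = tree_source, subst_model = subst_model,
                 subst_rate = subst_rate,
                 n_planted = as.integer(n_planted),
                 n_planted_barcode = as.integer(n_planted_barcode),
                 missing_fraction = missing_fraction,
                 coverage_mean = coverage_mean,
                 coverage_dispersion = coverage_dispersion,
                 include_barcode = include_barcode, prefix = prefix),
            class = "simulation_config")
}

#' @noRd
default_taxa <- function(n) sprintf("NVG-18%03dC%02d", seq_len(n), seq_len(n))

#' Simulate a rooted tree with the planted clade monophyletic
#'
#' With a birth-process `tree_source`, a Yule backbone is drawn over the
#' non-clade taxa plus one placeholder tip, a Yule subtree is drawn over
#' the clade taxa, and the subtree is grafted at the placeholder, which
#' guarantees monophyly of the planted clade. A fixed newick `tree_source`
#' is read and checked instead.
#'
#' @param config A [simulation_config()].
#' @return A rooted binary `phylo` tree with positive branch lengths in
#'   which `planted_clade` is monophyletic.
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  taxa <- config$taxa
  clade <- config$planted_clade
  if (is.character(config$tree_source)) {
    tr <- ape::read.tree(text = config$tree_source)
    if (is.null(tr)) abort("tree_source newick string failed to parse")
    if (!setequal(tr$tip.label, taxa)) abort("tree_source tips do not match the configured taxa")
    if (!ape::is.rooted(tr) || !ape::is.binary(tr)) abort("tree_source must be a rooted binary tree")
    if (!ape::is.monophyletic(tr, clade)) {
      abort("planted_clade is not monophyletic in the supplied tree")
    }
    return(tr)
  }
  rate <- config$tree_source$birth_rate
  stopifnot(is.numeric(rate), rate > 0)
  others <- setdiff(taxa, clade)
  set.seed(config$seed)
  if (length(clade) == 1) {
    tr <- ape::rphylo(length(taxa), birth = rate, death = 0)
    tr$tip.label <- sample(taxa)
  } else {
    # graft an ultrametric clade subtree into a Yule backbone at a
    # placeholder tip, keeping the whole tree clock-like: the clade crown
    # sits at 40% of the placeholder's terminal edge, its stem takes the
    # remaining 60%
    backbone <- ape::rphylo(length(others) + 1, birth = rate, death = 0)
    backbone$tip.label <- sample(c(others, ".__clade__."))
    w <- which(backbone$tip.label == ".__clade__.")
    e <- backbone$edge.length[backbone$edge[, 2] == w]
    sub <- ape::rphylo(length(clade), birth = rate, death = 0)
    sub$tip.label <- sample(clade)
    crown <- 0.4 * e
    sub$edge.length <- sub$edge.length * crown / max(ape::node.depth.edgelength(sub))
    sub$root.edge <- crown
    tr <- ape::bind.tree(backbone, sub, where = w, position = 2 * crown)
    tr <- ape::drop.tip(tr, ".__clade__.")
  }
  tr$edge.length <- pmax(tr$edge.length, 1e-8)
  stopifnot(ape::is.monophyletic(tr, clade))
  tr
}

#' Evolve a partitioned alignment along a tree
#'
#' Simulates each locus independently along `tree` under JC69 or GTR
#' (via [phangorn::simSeq()]), with branch lengths scaled by
#' `config$subst_rate`. Loci are assigned deterministic
#' `prefix<scaffold>.<gene>.<exon>` ids and split across the `nuclear`,
#' `Z` and `mito` partitions (roughly 60/20/20); with
#' `include_barcode = TRUE` a final 658-bp `COI` locus is added to the
#' `coi_barcode` partition.
#'
#' @param tree A rooted `phylo` whose tips match the configured taxa.
#' @param config A [simulation_config()].
#' @return An [alignment_set()] (no coverage yet).
#' @export
evolve_alignment <- function(tree, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!setequal(tree$tip.label, config$taxa)) {
    abort("tree tips do not match the configured taxa")
  }
  manifest <- sim_manifest(config)
  scaled <- tree
  scaled$edge.length <- scaled$edge.length * config$subst_rate
  loci <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    set.seed(config$seed + i)
    sq <- if (config$subst_model$model == "GTR") {
      phangorn::simSeq(scaled, l = manifest$length[i], type = "DNA",
                       Q = config$subst_model$rates,
                       bf = config$subst_model$base_freq)
    } else {
      phangorn::simSeq(scaled, l = manifest$length[i], type = "DNA")
    }
    m <- toupper(as.character(sq))
    loci[[i]] <- m[config$taxa, , drop = FALSE]
  }
  names(loci) <- manifest$locus_id
  alignment_set(loci, manifest)
}

# deterministic locus addressing and partition split
#' @noRd
sim_manifest <- function(config) {
  n <- config$n_loci
  if (n >= 3) {
    nz <- max(1L, floor(n * 0.2))
    nm <- max(1L, floor(n * 0.2))
    part <- c(rep("nuclear", n - nz - nm), rep("Z", nz), rep("mito", nm))
  } else {
    part <- rep("nuclear", n)
  }
  i <- seq_len(n)
  manifest <- tibble(
    locus_id = NA_character_,
    prefix = config$prefix,
    scaffold = as.integer(100 + 7 * i),
    gene = as.integer(1 + (3 * i) %% 97),
    exon = as.integer(1 + (i %% 5)),
    partition = part,
    length = config$locus_length
  )
  manifest$locus_id <- paste0(manifest$prefix, manifest$scaffold, ".",
                              manifest$gene, ".", manifest$exon)
  if (config$include_barcode) {
    manifest <- dplyr::bind_rows(manifest, tibble(
      locus_id = "COI", prefix = NA_character_, scaffold = NA_integer_,
      gene = NA_integer_, exon = NA_integer_, partition = "coi_barcode",
      length = 658L))
  }
  manifest
}

#' Plant clade synapomorphies into an alignment
#'
#' Overwrites the states at `n` randomly chosen positions so that every
#' clade taxon carries a derived state and every other taxon carries a
#' different ancestral state, and returns the positions as exact ground
#' truth. Overwriting (rather than constraining the simulator) keeps the
#' ground truth exact.
#'
#' @param aln An [alignment_set()].
#' @param tree The tree the alignment evolved along; the clade must be
#'   monophyletic in it.
#' @param clade Character vector of clade taxa.
#' @param n Number of positions to plant.
#' @param seed Integer seed for position and state choice.
#' @param partitions Partitions eligible for planting (default: all but
#'   `coi_barcode`).
#' @return A list with `alignment` (the modified set) and `truth`
#'   (a `synapo_chars` tibble of the planted characters, in locus order).
#' @export
plant_synapomorphies <- function(aln, tree, clade, n, seed,
                                 partitions = setdiff(PARTITION_LABELS, "coi_barcode")) {
  stopifnot(all(clade %in% taxa_names(aln)))
  if (!ape::is.monophyletic(tree, clade)) {
    abort("clade is not monophyletic in the supplied tree")
  }
  keep <- aln$manifest$partition %in% partitions
  if (!any(keep)) abort("no loci in the requested partitions")
  lens <- ifelse(keep, aln$manifest$length, 0L)
  total <- sum(lens)
  if (n > total) abort(sprintf("cannot plant %d characters into %d eligible positions", n, total))
  if (n == 0) {
    truth <- diag_characters()
    return(list(alignment = aln, truth = truth))
  }
  set.seed(seed)
  cols <- sort(sample.int(total, n))
  starts <- cumsum(c(1L, lens[-length(lens)]))
  li <- findInterval(cols, starts)
  pos <- cols - starts[li] + 1L
  # skip zero-length (ineligible) entries findInterval may land on
  stopifnot(all(lens[li] > 0))
  focal_rows <- match(clade, taxa_names(aln))
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    st <- sample(BASES, 2)
    a <- st[1]; d <- st[2]
    m <- aln$loci[[li[k]]]
    m[focal_rows, pos[k]] <- d
    m[-focal_rows, pos[k]] <- a
    aln$loci[[li[k]]] <- m
    mf <- aln$manifest[li[k], ]
    rows[[k]] <- diag_characters(prefix = mf$prefix, scaffold = mf$scaffold,
                                 gene = mf$gene, exon = mf$exon,
                                 position = pos[k], kind = "derived",
                                 ancestral = a, derived = d,
                                 missing_count = 0L)
  }
  truth <- dplyr::bind_rows(rows)
  class(truth) <- c("synapo_chars", class(tibble()))
  list(alignment = aln, truth = truth)
}

#' Apply missing-data masks and sequencing coverage
#'
#' Masks each cell independently to `N` with probability
#' `missing_fraction` and draws per-cell read depth from a shifted
#' negative binomial (`1 + NB(mu = coverage_mean - 1, size =
#' coverage_dispersion)`), so unmasked cells always have depth at least 1
#' and mean depth exactly `coverage_mean`; masked cells get depth 0.
#'
#' @param aln An [alignment_set()].
#' @param config A [simulation_config()].
#' @return The alignment set with masks applied and coverage attached.
#' @export
apply_missingness_and_coverage <- function(aln, config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 100003L)
  cov <- vector("list", length(aln$loci))
  for (i in seq_along(aln$loci)) {
    m <- aln$loci[[i]]
    mask <- matrix(runif(length(m)) < config$missing_fraction,
                   nrow = nrow(m))
    m[mask] <- "N"
    depth <- matrix(as.integer(1L + rnbinom(length(m),
                                            mu = config$coverage_mean - 1,
                                            size = config$coverage_dispersion)),
                    nrow = nrow(m))
    depth[mask] <- 0L
    dimnames(depth) <- dimnames(m)
    aln$loci[[i]] <- m
    cov[[i]] <- depth
  }
  names(cov) <- names(aln$loci)
  alignment_set(aln$loci, aln$manifest, cov)
}

#' Simulate a complete benchmark dataset
#'
#' Runs the full generator: tree, evolved loci, planted synapomorphies
#' (exon partitions and optionally the barcode), then missingness and
#' coverage. All stages are driven by `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A list with `tree`, `alignment`, `truth` (planted characters,
#'   barcode rows included), `clades` (a [clade_partition()]: planted clade
#'   vs all other taxa) and `config`.
#' @export
simulate_dataset <- function(config) {
  tree <- simulate_tree(config)
  aln <- evolve_alignment(tree, config)
  planted <- plant_synapomorphies(aln, tree, config$planted_clade,
                                  config$n_planted, seed = config$seed + 50021L)
  truth <- planted$truth
  aln <- planted$alignment
  if (config$n_planted_barcode > 0) {
    pb <- plant_synapomorphies(aln, tree, config$planted_clade,
                               config$n_planted_barcode,
                               seed = config$seed + 50023L,
                               partitions = "coi_barcode")
    aln <- pb$alignment
    truth <- dplyr::bind_rows(truth, pb$truth)
    class(truth) <- c("synapo_chars", class(tibble()))
  }
  aln <- apply_missingness_and_coverage(aln, config)
  clades <- clade_partition(focal = config$planted_clade,
                            outgroups = setdiff(config$taxa, config$planted_clade))
  list(tree = tree, alignment = aln, truth = truth, clades = clades,
       config = config)
}

#' Write a simulated dataset to disk
#'
#' Writes the per-locus FASTA alignments, manifest and coverage tables
#' (see [write_alignment_set()]), the ground-truth characters in notation
#' format (`truth_characters.txt`), the true tree (`true_tree.nwk`) and
#' the clade definitions (`clades.yml`).
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_alignment_set(sim$alignment, dir)
  write_characters(sim$truth, file.path(dir, "truth_characters.txt"))
  ape::write.tree(sim$tree, file.path(dir, "true_tree.nwk"))
  write_clades(sim$clades, file.path(dir, "clades.yml"))
  invisible(dir)
}
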