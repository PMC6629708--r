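test_that("configuration invariants are enforced", {
  taxa <- paste0("t", 1:6)
  ok <- simulation_config(seed = 1, n_taxa = 6, planted_clade = taxa[1:2],
                          taxa = taxa, n_loci = 2, locus_length = 10,
                          n_planted = 5)
  expect_s3_class(ok, "simulation_config")
  expect_error(simulation_config(seed = 1, n_taxa = 6, planted_clade = taxa,
                                 taxa = taxa), "proper non-empty subset")
  expect_error(simulation_config(seed = 1, n_taxa = 6, planted_clade = "zz",
                                 taxa = taxa), "proper non-empty subset")
  expect_error(simulation_config(seed = 1, n_taxa = 6, planted_clade = taxa[1:2],
                                 taxa = taxa, missing_fraction = 1),
               "missing_fraction")
  expect_error(simulation_config(seed = 1, n_taxa = 6, planted_clade = taxa[1:2],
                                 taxa = taxa, n_loci = 2, locus_length = 5,
                                 n_planted = 11), "exceeds")
  expect_error(simulation_config(seed = 1, n_taxa = 6, planted_clade = taxa[1:2],
                                 taxa = taxa,
                                 subst_model = list(model = "HKY")),
               "unknown substitution model")
})

test_that("simulated trees are rooted, binary, and keep the planted clade monophyletic", {
  taxa2 <- c("A", "B")
  cfg <- simulation_config(seed = 3, n_taxa = 2, planted_clade = "A",
                           taxa = taxa2, n_loci = 1, locus_length = 10,
                           n_planted = 0)
  tr <- simulate_tree(cfg)
  expect_setequal(tr$tip.label, taxa2)
  expect_equal(ape::Ntip(tr), 2)

  taxa4 <- c("A", "B", "C", "D")
  cfg4 <- simulation_config(seed = 9, n_taxa = 4, planted_clade = c("A", "B"),
                            taxa = taxa4, n_loci = 1, locus_length = 10,
                            n_planted = 0)
  tr4 <- simulate_tree(cfg4)
  expect_true(ape::is.rooted(tr4))
  expect_true(ape::is.binary(tr4))
  expect_true(is_monophyletic(tr4, c("A", "B")))
  expect_true(all(tr4$edge.length > 0))

  for (seed in c(7, 8)) {
    cfg8 <- simulation_config(seed = seed, n_taxa = 8,
                              planted_clade = paste0("t", 1:3),
                              taxa = paste0("t", 1:8), n_loci = 1,
                              locus_length = 10, n_planted = 0,
                              tree_source = list(birth_rate = 1))
    expect_identical(ape::write.tree(simulate_tree(cfg8)),
                     ape::write.tree(simulate_tree(cfg8)))
    expect_true(is_monophyletic(simulate_tree(cfg8), paste0("t", 1:3)))
  }
})

test_that("a fixed newick tree source is validated against the clade", {
  taxa <- c("A", "B", "C", "D")
  good <- simulation_config(seed = 1, n_taxa = 4, planted_clade = c("A", "B"),
                            taxa = taxa, n_loci = 1, locus_length = 10,
                            n_planted = 0,
                            tree_source = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(is_monophyletic(simulate_tree(good), c("A", "B")))
  bad <- simulation_config(seed = 1, n_taxa = 4, planted_clade = c("A", "C"),
                           taxa = taxa, n_loci = 1, locus_length = 10,
                           n_planted = 0,
                           tree_source = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_error(simulate_tree(bad), "not monophyletic")
})

test_that("zero branch lengths evolve identical sequences; saturation approaches 3/4 differences", {
  taxa <- c("A", "B", "C")
  cfg <- simulation_config(seed = 2, n_taxa = 3, planted_clade = "A",
                           taxa = taxa, n_loci = 2, locus_length = 50,
                           n_planted = 0, include_barcode = FALSE,
                           subst_rate = 1,
                           tree_source = "((A:0,B:0):0,C:0);")
  aln <- evolve_alignment(simulate_tree(cfg), cfg)
  for (m in aln$loci) {
    expect_equal(length(unique(apply(m, 1, paste0, collapse = ""))), 1)
  }

  # two taxa separated by total branch length 10: JC69 saturation gives
  # expected per-site identity 1/4 + 3/4 exp(-4*10/3) ~ 0.25
  cfg2 <- simulation_config(seed = 4, n_taxa = 2, planted_clade = "A",
                            taxa = c("A", "B"), n_loci = 1,
                            locus_length = 10000, n_planted = 0,
                            include_barcode = FALSE, subst_rate = 1,
                            tree_source = "(A:5,B:5);")
  m <- evolve_alignment(simulate_tree(cfg2), cfg2)$loci[[1]]
  p <- mean(m["A", ] != m["B", ])
  se <- sqrt(0.75 * 0.25 / 10000)
  expect_lt(abs(p - 0.75), 4 * se)
})

test_that("the JC69 expected distance matches its closed form at moderate divergence", {
  t <- 0.3   # total path length between the two tips
  cfg <- simulation_config(seed = 6, n_taxa = 2, planted_clade = "A",
                           taxa = c("A", "B"), n_loci = 1,
                           locus_length = 20000, n_planted = 0,
                           include_barcode = FALSE, subst_rate = 1,
                           tree_source = sprintf("(A:%f,B:%f);", t / 2, t / 2))
  m <- evolve_alignment(simulate_tree(cfg), cfg)$loci[[1]]
  p_obs <- mean(m["A", ] != m["B", ])
  p_exp <- 0.75 * (1 - exp(-4 * t / 3))
  expect_lt(abs(p_obs - p_exp), 4 * sqrt(p_exp * (1 - p_exp) / 20000))
})

test_that("the whole generator is bit-deterministic in its seed", {
  cfg <- simulation_config(seed = 13, n_taxa = 6,
                           planted_clade = paste0("t", 1:2),
                           taxa = paste0("t", 1:6), n_loci = 3,
                           locus_length = 40, n_planted = 4,
                           n_planted_barcode = 2, missing_fraction = 0.1)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$alignment$loci, s2$alignment$loci)
  expect_identical(s1$alignment$coverage, s2$alignment$coverage)
  expect_identical(s1$truth$notation, s2$truth$notation)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
})

test_that("planting overwrites exactly n positions and records exact ground truth", {
  taxa <- paste0("t", 1:10)
  cfg <- simulation_config(seed = 21, n_taxa = 10, planted_clade = taxa[1:3],
                           taxa = taxa, n_loci = 3, locus_length = 60,
                           n_planted = 0, include_barcode = FALSE,
                           subst_rate = 0)
  tree <- simulate_tree(cfg)
  aln <- evolve_alignment(tree, cfg)

  p0 <- plant_synapomorphies(aln, tree, taxa[1:3], n = 0, seed = 1)
  expect_identical(p0$alignment$loci, aln$loci)
  expect_equal(nrow(p0$truth), 0)

  p5 <- plant_synapomorphies(aln, tree, taxa[1:3], n = 5, seed = 1)
  expect_equal(nrow(p5$truth), 5)
  clades <- clade_partition(focal = taxa[1:3], outgroups = taxa[4:10])
  found <- scan_clade(p5$alignment, clades,
                      scan_params(outgroup_majority_threshold = 1,
                                  forbid_derived_in_outgroup = TRUE,
                                  top_k = Inf))
  expect_setequal(found$notation, p5$truth$notation)
  expect_equal(nrow(found), 5)

  # masking one clade taxon at a planted site keeps the character but
  # records the missing taxon
  masked <- p5$alignment
  li <- match(p5$truth$locus_id[1], masked$manifest$locus_id)
  masked$loci[[li]][taxa[1], p5$truth$position[1]] <- "N"
  found2 <- scan_clade(masked, clades,
                       scan_params(outgroup_majority_threshold = 1, top_k = Inf))
  hit <- found2[found2$locus_id == p5$truth$locus_id[1] &
                  found2$position == p5$truth$position[1], ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$missing_count, 1L)

  expect_error(plant_synapomorphies(aln, tree, taxa[1:3], n = 10000, seed = 1),
               "cannot plant")
})

test_that("missingness and coverage match their configured distributions", {
  taxa <- paste0("t", 1:5)
  base <- function(mf, cm = 20) {
    simulation_config(seed = 31, n_taxa = 5, planted_clade = taxa[1:2],
                      taxa = taxa, n_loci = 2, locus_length = 1000,
                      n_planted = 0, include_barcode = FALSE,
                      missing_fraction = mf, coverage_mean = cm,
                      coverage_dispersion = 5)
  }
  cfg0 <- base(0)
  aln0 <- apply_missingness_and_coverage(evolve_alignment(simulate_tree(cfg0), cfg0), cfg0)
  expect_false(any(unlist(aln0$loci) == "N"))
  expect_true(all(unlist(aln0$coverage) >= 1))

  cfg1 <- base(0.1)
  aln1 <- apply_missingness_and_coverage(evolve_alignment(simulate_tree(cfg1), cfg1), cfg1)
  cells <- unlist(aln1$loci)
  frac <- mean(cells == "N")
  expect_gte(frac, 0.091)   # 3-sigma binomial band around 0.1 at 10,000 cells
  expect_lte(frac, 0.109)
  cov <- unlist(aln1$coverage)
  expect_true(all(cov[cells != "N"] >= 1))
  expect_true(all(cov[cells == "N"] == 0))
  obs <- cov[cells != "N"]
  se <- sqrt(stats::var(obs) / length(obs))
  expect_lt(abs(mean(obs) - 20), 3 * se)
})
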