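#' Assemble a run configuration for the full pipeline
#'
#' Bundles the generator settings with the scan, distance, bootstrap and
#' rank parameters. Every randomized stage derives its stream from the
#' single `seed`.
#'
#' @param seed Integer master seed (required).
#' @param sim A [simulation_config()]; built from `seed` and the defaults
#'   of [demo_config()] if omitted.
#' @param scan A [scan_params()].
#' @param n_replicates Bootstrap replicates per partition tree.
#' @param conspecific_threshold Barcode p-distance threshold for
#'   [associate_specimens()].
#' @param strong_threshold Bootstrap percentage treated as strong support
#'   in [rank_decision()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed, sim, scan = scan_params(),
                       n_replicates = 100, conspecific_threshold = 0.02,
                       strong_threshold = 95) {
  if (missing(seed) || is.null(seed)) abort("run_config requires a seed")
  stopifnot(inherits(sim, "simulation_config"), inherits(scan, "scan_params"),
            n_replicates >= 1)
  structure(list(seed = as.integer(seed), sim = sim, scan = scan,
                 n_replicates = as.integer(n_replicates),
                 conspecific_threshold = conspecific_threshold,
                 strong_threshold = strong_threshold),
            class = "run_config")
}

#' Demonstration configuration
#'
#' A desk-scale benchmark: 12 taxa with a 4-taxon planted clade, 20 exon
#' loci of 300 bp plus the 658-bp barcode, 10 planted exon synapomorphies
#' and 3 barcode ones, 5% missing data, mean coverage 20.
#'
#' @param seed Integer master seed.
#' @param ... Overrides passed to [simulation_config()].
#' @return A [run_config()].
#' @export
demo_config <- function(seed = 1, ...) {
  taxa <- default_taxa(12)
  sim <- simulation_config(seed = seed, n_taxa = 12,
                           planted_clade = taxa[1:4], taxa = taxa,
                           n_loci = 20, locus_length = 300,
                           n_planted = 10, n_planted_barcode = 3,
                           missing_fraction = 0.05,
                           coverage_mean = 20, coverage_dispersion = 5,
                           subst_rate = 0.1, ...)
  run_config(seed = seed, sim = sim)
}

#' Read / write a run configuration
#'
#' Flat YAML round-trip of all [run_config()] fields. A file without a
#' `seed` is rejected.
#'
#' @param path File path.
#' @return `read_run_config()` returns a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) abort("run configuration lacks a seed")
  sim_args <- y$sim
  for (f in c("taxa", "planted_clade")) {
    if (!is.null(sim_args[[f]])) sim_args[[f]] <- unlist(sim_args[[f]])
  }
  if (is.list(sim_args$tree_source) && is.null(sim_args$tree_source$birth_rate)) {
    sim_args$tree_source <- unlist(sim_args$tree_source)
  }
  sim <- do.call(simulation_config, c(sim_args, list(seed = y$seed)))
  run_config(seed = y$seed, sim = sim,
             scan = do.call(scan_params, y$scan %||% list()),
             n_replicates = y$n_replicates %||% 100,
             conspecific_threshold = y$conspecific_threshold %||% 0.02,
             strong_threshold = y$strong_threshold %||% 95)
}

#' @param config A [run_config()].
#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  sim <- unclass(config$sim)
  sim$seed <- NULL
  y <- list(seed = config$seed, sim = sim,
            scan = unclass(config$scan),
            n_replicates = config$n_replicates,
            conspecific_threshold = config$conspecific_threshold,
            strong_threshold = config$strong_threshold)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the full diagnostic pipeline
#'
#' Simulate a benchmark dataset, scan the exon partitions and the barcode
#' for diagnostic characters, compute barcode p-distances and specimen
#' groups, build bootstrapped NJ trees for the nuclear, Z and mitogenome
#' partitions, assemble the clade-support report, and apply the rank rule.
#' All outputs are written under `out_dir`; reruns with the same
#' configuration are byte-identical.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created; existing files overwritten).
#' @return Invisibly, a list with the in-memory results (`sim`, `chars`,
#'   `barcode_chars`, `distances`, `groups`, `trees`, `report`,
#'   `decision`) and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
  }
  cat(sprintf("synapodiag %s | seed %d\n",
              as.character(utils::packageVersion("synapodiag")), config$seed),
      file = log_path)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  logf("stage simulate: %d taxa, %d loci x %d bp, %d + %d planted, missing %.3f",
       config$sim$n_taxa, config$sim$n_loci, config$sim$locus_length,
       config$sim$n_planted, config$sim$n_planted_barcode,
       config$sim$missing_fraction)
  sim <- stage("simulate", simulate_dataset(config$sim))
  write_dataset(sim, file.path(out_dir, "dataset"))
  write_run_config(config, file.path(out_dir, "config.yml"))

  logf("stage scan: threshold %.2f, forbid %s, top_k %s",
       config$scan$outgroup_majority_threshold,
       config$scan$forbid_derived_in_outgroup, config$scan$top_k)
  chars <- stage("scan", scan_clade(sim$alignment, sim$clades, config$scan))
  write_scan(chars, file.path(out_dir, "characters.txt"))
  bchars <- stage("scan_barcode", scan_barcode(sim$alignment, sim$clades, config$scan))
  write_scan(bchars, file.path(out_dir, "barcode_characters.txt"))

  logf("stage distance: barcode p-distances, threshold %.3f",
       config$conspecific_threshold)
  bc <- concatenate(sim$alignment, "coi_barcode")
  dm <- stage("distance", p_distance_matrix(bc$matrix))
  readr::write_tsv(tibble::as_tibble(dm, rownames = "specimen"),
                   file.path(out_dir, "barcode_distances.tsv"))
  groups <- stage("associate", associate_specimens(dm, config$conspecific_threshold))
  readr::write_tsv(groups, file.path(out_dir, "specimen_groups.tsv"))

  ref <- reference_clades_from_tree(sim$tree, config$sim$planted_clade)
  outgroup <- ref$outgroup
  trees <- list()
  for (p in c("nuclear", "Z", "mito")) {
    logf("stage tree (%s): NJ + %d bootstrap replicates, outgroup %s",
         p, config$n_replicates, outgroup)
    mat <- concatenate(sim$alignment, p)$matrix
    trees[[p]] <- stage(paste0("tree_", p),
                        bootstrap_support(mat, config$n_replicates,
                                          seed = config$seed + match(p, c("nuclear", "Z", "mito")),
                                          outgroup = outgroup))
    ape::write.tree(trees[[p]], file.path(out_dir, paste0("tree_", p, ".nwk")))
  }

  report <- stage("support", support_report(trees, ref$clades, ref$roles,
                                            config$sim$planted_clade))
  readr::write_tsv(report, file.path(out_dir, "support_report.tsv"))
  decision <- stage("rank", rank_decision(report, config$strong_threshold))
  logf("stage rank: %s (%s)", decision$recommendation, decision$rationale)

  # recovery is measured against untruncated scans: top_k limits the
  # published diagnosis, not what the rule can find
  all_params <- scan_params(config$scan$outgroup_majority_threshold,
                            config$scan$forbid_derived_in_outgroup,
                            config$scan$max_focal_missing, top_k = Inf)
  full <- scan_clade(sim$alignment, sim$clades, all_params)
  full_bc <- scan_barcode(sim$alignment, sim$clades, all_params)
  recovered <- sum(sim$truth$notation %in% c(full$notation, full_bc$notation))
  summary <- list(
    seed = config$seed,
    n_taxa = config$sim$n_taxa,
    n_loci = config$sim$n_loci,
    planted = nrow(sim$truth),
    reported_characters = nrow(chars),
    reported_barcode_characters = nrow(bchars),
    planted_recovered = recovered,
    n_specimen_groups = max(groups$group),
    supports = setNames(lapply(trees, function(t) {
      clade_support(t, config$sim$planted_clade)
    }), names(trees)),
    recommendation = decision$recommendation
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(sim = sim, chars = chars, barcode_chars = bchars,
                 distances = dm, groups = groups, trees = trees,
                 report = report, decision = decision, out_dir = out_dir))
}

# pick the rooting taxon and the inclusion/exclusion reference clades off
# the true tree. The exclusion clade is a cherry of two non-focal taxa in
# the unrooted topology (one always exists when >= 3 non-focal taxa are
# present, since an unrooted binary tree has at least two cherries); the
# rooting outgroup is a non-focal taxon outside both the cherry and the
# focal clade; the inclusion clade is the focal clade's parent clade in
# the rooted tree.
#' @noRd
reference_clades_from_tree <- function(tree, focal) {
  un <- ape::unroot(tree)
  ntip <- ape::Ntip(un)
  tip_children <- split(un$edge[, 2][un$edge[, 2] <= ntip],
                        un$edge[, 1][un$edge[, 2] <= ntip])
  # among non-focal cherries, prefer the one with the longest stem edge:
  # the reference clade should be the best-separated one available
  cherry <- NULL
  best_stem <- -Inf
  for (node in names(tip_children)) {
    kids <- tip_children[[node]]
    labs <- un$tip.label[kids]
    if (length(labs) != 2 || any(labs %in% focal)) next
    stem <- un$edge.length[un$edge[, 2] == as.integer(node)]
    if (length(stem) == 0) stem <- 0  # cherry at the unrooted basal node
    if (stem > best_stem) {
      best_stem <- stem
      cherry <- sort(labs)
    }
  }
  if (is.null(cherry)) abort("no non-focal cherry exists in the true tree")
  outgroup <- setdiff(tree$tip.label, c(focal, cherry))[1]
  if (is.na(outgroup)) abort("too few non-focal taxa to pick a rooting outgroup")
  rooted <- root_tree(tree, outgroup)
  ntip_r <- ape::Ntip(rooted)
  mrca <- ape::getMRCA(rooted, focal)
  parent <- rooted$edge[rooted$edge[, 2] == mrca, 1]
  inclusion <- if (parent == ntip_r + 1L) {
    setdiff(rooted$tip.label, outgroup)
  } else {
    ape::extract.clade(rooted, parent)$tip.label
  }
  list(outgroup = outgroup,
       clades = list(inclusion_clade = inclusion, exclusion_clade = cherry),
       roles = c(inclusion_clade = "inclusion", exclusion_clade = "exclusion"))
}
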