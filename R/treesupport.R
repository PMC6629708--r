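#' Neighbor-joining tree from a distance matrix
#'
#' Thin validated wrapper around [ape::nj()]. On an additive distance
#' matrix the path lengths of the returned tree reproduce the input
#' exactly, so NJ recovers the generating topology.
#'
#' @param d Symmetric distance matrix with zero diagonal over at least
#'   three taxa.
#' @return An unrooted `phylo` tree; root it with [root_tree()].
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 3) abort("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-10)) abort("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) abort("distance matrix diagonal must be zero")
  ape::nj(d)
}

#' Root a tree on a named outgroup
#'
#' @param tree A `phylo`.
#' @param outgroup Taxon name (or vector of names) to root with.
#' @return A rooted `phylo`.
#' @export
root_tree <- function(tree, outgroup) {
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing)) abort(paste0("outgroup taxa not in tree: ", paste(missing, collapse = ", ")))
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Test whether a taxon set is monophyletic
#'
#' @param tree A rooted `phylo`.
#' @param taxa Character vector of tip labels.
#' @return `TRUE` iff `taxa` form an exact clade of the tree.
#' @export
is_monophyletic <- function(tree, taxa) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing)) abort(paste0("unknown taxa: ", paste(missing, collapse = ", ")))
  ape::is.monophyletic(tree, taxa)
}

#' Neighbor-joining tree with column-bootstrap clade support
#'
#' Builds the NJ tree from uncorrected p-distances on an alignment
#' matrix, then resamples alignment columns with replacement
#' `n_replicates` times, rebuilds the NJ tree on each replicate, and
#' records for every internal node of the reference tree the percentage
#' of replicate trees containing its clade. Reproducible bit-exactly for
#' a given `seed`.
#'
#' @param mat Character matrix (taxa in rows, alignment columns in
#'   columns), e.g. `concatenate(aln, "nuclear")$matrix`.
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed for the resampling.
#' @param outgroup Optional taxon to root the reference and replicate
#'   trees; when given, clades are counted on the rooted trees.
#' @return The reference `phylo` with `node.label` holding bootstrap
#'   support percentages (0-100; the root label is empty).
#' @export
bootstrap_support <- function(mat, n_replicates, seed, outgroup = NULL) {
  stopifnot(is.matrix(mat), nrow(mat) >= 3, n_replicates >= 1)
  ref <- nj_tree(p_distance_matrix(mat))
  if (!is.null(outgroup)) ref <- root_tree(ref, outgroup)
  set.seed(seed)
  reps <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol(mat), replace = TRUE)
    t_b <- nj_tree(p_distance_matrix(mat[, cols, drop = FALSE]))
    if (!is.null(outgroup)) t_b <- root_tree(t_b, outgroup)
    reps[[b]] <- t_b
  }
  counts <- ape::prop.clades(ref, reps, rooted = !is.null(outgroup))
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_replicates, 1)
  ref$node.label <- as.character(support)
  if (!is.null(outgroup)) ref$node.label[1] <- ""
  ref
}

#' Bootstrap support of one clade in a tree
#'
#' @param tree A `phylo` with `node.label` support values (as written by
#'   [bootstrap_support()] or read from newick internal-node labels).
#' @param taxa Clade taxon set.
#' @return The numeric support of the clade's stem node, or `NA` if the
#'   taxa are not monophyletic in the tree.
#' @export
clade_support <- function(tree, taxa) {
  if (!is_monophyletic(tree, taxa)) return(NA_real_)
  if (length(taxa) == 1) return(NA_real_)
  node <- ape::getMRCA(tree, taxa)
  lab <- tree$node.label[node - ape::Ntip(tree)]
  suppressWarnings(as.numeric(lab))
}

#' Build a clade-support report across several trees
#'
#' Collects, for a focal clade and a set of named reference clades, the
#' bootstrap support of each reference clade in each tree together with
#' whether the reference clade's taxon set contains the focal clade.
#' This is the input of [rank_decision()].
#'
#' @param trees Named list of `phylo` trees with support `node.label`s
#'   (e.g. nuclear / Z / mitogenome).
#' @param reference_clades Named list of taxon sets; names are clade
#'   labels.
#' @param roles Named character vector mapping each reference clade label
#'   to `"inclusion"` (a well-supported clade the focal belongs to) or
#'   `"exclusion"` (a well-supported clade the focal falls outside of).
#' @param focal Focal-clade taxon set.
#' @return Tibble with `clade`, `role`, `tree`, `support`,
#'   `contains_focal`, plus rows `role = "focal_placement"` giving the
#'   focal clade's own (possibly weak) support in each tree.
#' @export
support_report <- function(trees, reference_clades, roles, focal) {
  stopifnot(length(names(trees)) == length(trees),
            all(names(reference_clades) %in% names(roles)))
  sup0 <- function(tree, taxa) {
    s <- clade_support(tree, taxa)
    if (is.na(s)) 0 else s  # a clade absent from a tree has no support
  }
  rows <- list()
  for (cl in names(reference_clades)) {
    for (tn in names(trees)) {
      rows[[length(rows) + 1]] <- tibble(
        clade = cl, role = unname(roles[cl]), tree = tn,
        support = sup0(trees[[tn]], reference_clades[[cl]]),
        contains_focal = all(focal %in% reference_clades[[cl]]))
    }
  }
  for (tn in names(trees)) {
    rows[[length(rows) + 1]] <- tibble(
      clade = "focal", role = "focal_placement", tree = tn,
      support = sup0(trees[[tn]], focal), contains_focal = TRUE)
  }
  dplyr::bind_rows(rows)
}

#' Decide whether a lineage merits its own rank from multi-tree support
#'
#' Classification needs a clade to be well supported and separate from
#' other clades of the same rank, not a fully resolved placement. The rule:
#' recommend the higher (subfamily) rank iff (a) every *inclusion* clade
#' (a clade the focal lineage belongs to) reaches `strong_threshold`
#' bootstrap in every tree, and (b) every *exclusion* clade reaches
#' `strong_threshold` in every tree while not containing the focal
#' lineage. The focal lineage's own placement support is irrelevant:
#' whichever of the possible placement scenarios holds, the lineage sits
#' inside the inclusion clade and outside the exclusion clade, so it is
#' its own deep lineage.
#'
#' @param report Tibble as produced by [support_report()] (columns
#'   `clade`, `role`, `tree`, `support`, `contains_focal`).
#' @param strong_threshold Bootstrap percentage counted as strong support;
#'   default 95.
#' @param scenario Optional label for the placement scenario under
#'   consideration, recorded in the output.
#' @return A one-row tibble of class `rank_decision` with `scenario`,
#'   `recommendation` (`"subfamily"` or `"insufficient_support"`) and
#'   `rationale` (the rule trace); attribute `clauses` holds the per-clause
#'   outcomes.
#' @export
rank_decision <- function(report, strong_threshold = 95, scenario = NA_character_) {
  need <- c("clade", "role", "tree", "support", "contains_focal")
  missing_cols <- setdiff(need, names(report))
  if (length(missing_cols)) {
    abort(paste0("report lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  inc <- report[report$role == "inclusion", ]
  exc <- report[report$role == "exclusion", ]
  if (!nrow(inc)) abort("report has no inclusion clade")
  if (!nrow(exc)) abort("report has no exclusion clade")
  if (anyNA(inc$support) || anyNA(exc$support)) {
    abort("reference clades must be monophyletic with support in every tree")
  }
  clauses <- tibble(
    clause = c("inclusion_supported", "inclusion_contains_focal",
               "exclusion_supported", "exclusion_excludes_focal"),
    holds = c(all(inc$support >= strong_threshold),
              all(inc$contains_focal),
              all(exc$support >= strong_threshold),
              all(!exc$contains_focal)))
  ok <- all(clauses$holds)
  rationale <- if (ok) {
    sprintf(paste0("inclusion clade(s) supported >= %s%% in all trees and contain ",
                   "the focal lineage; exclusion clade(s) supported >= %s%% in all ",
                   "trees and exclude it; placement support among the remaining ",
                   "scenarios does not affect the rank"),
            strong_threshold, strong_threshold)
  } else {
    paste0("failing clause(s): ",
           paste(clauses$clause[!clauses$holds], collapse = ", "))
  }
  out <- tibble(scenario = scenario,
                recommendation = if (ok) "subfamily" else "insufficient_support",
                rationale = rationale)
  attr(out, "clauses") <- clauses
  attr(out, "strong_threshold") <- strong_threshold
  class(out) <- c("rank_decision", class(tibble()))
  out
}
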