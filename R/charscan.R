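#' Parameters of the diagnostic-character scan
#'
#' @param outgroup_majority_threshold Minimum frequency, among non-missing
#'   outgroup states, that the modal outgroup state must reach to count as
#'   the "mostly invariant" ancestral state; in `(0.5, 1]`. Default 0.9.
#' @param forbid_derived_in_outgroup If `TRUE` (default), a column is
#'   rejected when any outgroup taxon carries the focal (derived) state,
#'   even if the outgroup majority state differs.
#' @param max_focal_missing Maximum number of focal-clade taxa allowed to
#'   have missing data at a reported position. `NULL` (default) means
#'   one fewer than the focal clade size (at least one observed state).
#' @param top_k Number of top-ranked characters to report; published
#'   diagnoses list five to seven, so the default is 6. Use `Inf` to keep
#'   all candidates.
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(outgroup_majority_threshold = 0.9,
                        forbid_derived_in_outgroup = TRUE,
                        max_focal_missing = NULL,
                        top_k = 6) {
  stopifnot(outgroup_majority_threshold > 0.5, outgroup_majority_threshold <= 1,
            is.logical(forbid_derived_in_outgroup), top_k >= 1)
  if (!is.null(max_focal_missing)) stopifnot(max_focal_missing >= 0)
  structure(list(outgroup_majority_threshold = outgroup_majority_threshold,
                 forbid_derived_in_outgroup = forbid_derived_in_outgroup,
                 max_focal_missing = max_focal_missing, top_k = top_k),
            class = "scan_params")
}

#' Classify one alignment column against the synapomorphy rule
#'
#' A column is a candidate diagnostic character when (i) all non-missing
#' focal states equal some state `d`; (ii) the outgroup has a majority
#' state `a` with frequency at least `outgroup_majority_threshold` among
#' non-missing outgroup states; (iii) `a != d`; and (iv) when
#' `forbid_derived_in_outgroup`, no outgroup taxon carries `d`. When the
#' focal clade is invariant and its state is absent from every observed
#' outgroup state but no outgroup majority qualifies, the column is a
#' `state_only` candidate (the ancestral state cannot be polarized).
#' Missing states (`N`, `-`, `?`, IUPAC ambiguity codes) never break focal
#' invariance but are counted in `missing_count`.
#'
#' @param focal_states,outgroup_states Character vectors of single-letter
#'   states for the focal clade and outgroup taxa at one column.
#' @param params A [scan_params()].
#' @return A list with `status` (`"candidate"`, `"rejected"` or
#'   `"uninformative"` when either side is all-missing), and for
#'   candidates `kind`, `ancestral`, `derived`, `missing_count`; rejected
#'   columns carry a `reason`.
#' @export
#' @examples
#' classify_column(c("C", "C", "C"), c("G", "G", "G", "G"), scan_params())
classify_column <- function(focal_states, outgroup_states, params = scan_params()) {
  fm <- is_missing_state(focal_states)
  om <- is_missing_state(outgroup_states)
  f <- focal_states[!fm]
  o <- outgroup_states[!om]
  if (!length(f) || !length(o)) {
    return(list(status = "uninformative",
                reason = if (!length(f)) "focal_all_missing" else "outgroup_all_missing",
                missing_count = sum(fm)))
  }
  miss <- sum(fm)
  rejected <- function(reason) list(status = "rejected", reason = reason,
                                    missing_count = miss)
  if (length(unique(f)) > 1) return(rejected("focal_variable"))
  d <- f[1]
  max_miss <- params$max_focal_missing %||% (length(focal_states) - 1L)
  if (miss > max_miss) return(rejected("too_much_focal_missing"))
  tab <- table(o)
  a <- names(tab)[which.max(tab)]
  if (a == d && max(tab) == length(o)) {
    return(rejected("outgroup_majority_equals_focal"))
  }
  if (params$forbid_derived_in_outgroup && d %in% o && a != d) {
    # the derived state leaking into the outgroup trumps the majority test
    return(rejected("derived_state_in_outgroup"))
  }
  if (max(tab) / length(o) >= params$outgroup_majority_threshold) {
    if (a == d) return(rejected("outgroup_majority_equals_focal"))
    return(list(status = "candidate", kind = "derived", ancestral = a,
                derived = d, missing_count = miss,
                outgroup_missing = sum(om)))
  }
  # no qualifying outgroup majority: diagnosable only as a bare state
  if (!d %in% o) {
    return(list(status = "candidate", kind = "state_only",
                ancestral = NA_character_, derived = d, missing_count = miss,
                outgroup_missing = sum(om)))
  }
  rejected("no_outgroup_majority")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scan an alignment for clade-diagnostic characters
#'
#' Applies [classify_column()] to every column of the requested partitions
#' and ranks the candidates the way published diagnoses were selected:
#' fewest focal taxa with missing data first, then highest minimum focal
#' coverage (weakest-link depth; ties when no coverage table is present),
#' then manifest locus order and position. The top `top_k` are reported.
#'
#' @param aln An [alignment_set()].
#' @param clades A [clade_partition()]; `focal` and `outgroups` must be
#'   taxa of `aln`.
#' @param params A [scan_params()].
#' @param partitions Partitions to scan; default all except `coi_barcode`
#'   (use [scan_barcode()] for barcode coordinates).
#' @return A `synapo_scan` tibble of diagnostic characters (columns as in
#'   [diag_characters()]) with attributes `audit` (per-column rule
#'   outcomes for all focal-invariant columns that reached the outgroup
#'   clauses), `params` and `clades`.
#' @export
scan_clade <- function(aln, clades, params = scan_params(),
                       partitions = setdiff(PARTITION_LABELS, "coi_barcode")) {
  stopifnot(inherits(clades, "clade_partition"))
  check_taxa(aln, c(clades$focal, clades$outgroups))
  keep <- which(aln$manifest$partition %in% partitions)
  if (!length(keep)) abort("no loci in the requested partitions")
  scan_loci(aln, keep, clades$focal, clades$outgroups, params)
}

# shared scanning core over a set of locus indices
#' @noRd
scan_loci <- function(aln, locus_idx, focal, outgroups, params,
                      barcode_coords = FALSE) {
  focal_rows <- match(focal, taxa_names(aln))
  out_rows <- match(outgroups, taxa_names(aln))
  cand <- list()
  audit <- list()
  for (i in locus_idx) {
    m <- aln$loci[[i]]
    Fm <- m[focal_rows, , drop = FALSE]
    Om <- m[out_rows, , drop = FALSE]
    # prefilter: columns where all non-missing focal states agree
    fmiss <- matrix(is_missing_state(Fm), nrow = nrow(Fm))
    Fm2 <- Fm
    Fm2[fmiss] <- NA
    nstates <- apply(Fm2, 2, function(x) length(unique(x[!is.na(x)])))
    cols <- which(nstates == 1)
    for (j in cols) {
      cl <- classify_column(Fm[, j], Om[, j], params)
      if (cl$status == "uninformative") next
      if (cl$status == "rejected" &&
          cl$reason %in% c("focal_variable", "outgroup_majority_equals_focal")) next
      mf <- aln$manifest[i, ]
      mc <- NA_real_
      if (!is.null(aln$coverage)) {
        depth <- aln$coverage[[i]][focal_rows, j]
        obs <- !is_missing_state(Fm[, j])
        mc <- if (any(obs)) min(depth[obs]) else NA_real_
      }
      row <- tibble(locus_index = i,
                    locus_id = mf$locus_id, prefix = mf$prefix,
                    scaffold = mf$scaffold, gene = mf$gene, exon = mf$exon,
                    position = j,
                    focal_state = Fm[!is_missing_state(Fm[, j]), j][1],
                    status = cl$status,
                    reason = if (cl$status == "rejected") cl$reason else NA_character_,
                    kind = if (cl$status == "candidate") cl$kind else NA_character_,
                    ancestral = if (cl$status == "candidate") cl$ancestral else NA_character_,
                    missing_count = cl$missing_count,
                    outgroup_missing = sum(is_missing_state(Om[, j])),
                    min_coverage = mc)
      audit[[length(audit) + 1]] <- row
      if (cl$status == "candidate") {
        cand[[length(cand) + 1]] <- tibble(
          locus_index = i,
          prefix = if (barcode_coords) NA_character_ else mf$prefix,
          scaffold = mf$scaffold, gene = mf$gene, exon = mf$exon,
          position = j, kind = cl$kind, ancestral = cl$ancestral,
          derived = cl$derived, missing_count = cl$missing_count,
          min_coverage = mc)
      }
    }
  }
  finish_scan(cand, audit, params, focal, outgroups)
}

#' @noRd
finish_scan <- function(cand, audit, params, focal, outgroups,
                        offsets = NULL) {
  audit <- if (length(audit)) dplyr::bind_rows(audit) else tibble()
  if (!length(cand)) {
    out <- diag_characters()
  } else {
    tab <- dplyr::bind_rows(cand)
    tab <- dplyr::arrange(tab, .data$missing_count,
                          dplyr::desc(dplyr::coalesce(.data$min_coverage, -Inf)),
                          .data$locus_index, .data$position)
    if (is.finite(params$top_k)) tab <- head(tab, params$top_k)
    out <- diag_characters(prefix = tab$prefix, scaffold = tab$scaffold,
                           gene = tab$gene, exon = tab$exon,
                           position = tab$position, kind = tab$kind,
                           ancestral = tab$ancestral, derived = tab$derived,
                           missing_count = tab$missing_count,
                           min_coverage = tab$min_coverage)
  }
  attr(out, "audit") <- audit
  attr(out, "params") <- params
  attr(out, "clades") <- list(focal = focal, outgroups = outgroups)
  class(out) <- c("synapo_scan", "synapo_chars", class(tibble()))
  out
}

#' @noRd
check_taxa <- function(aln, taxa) {
  missing <- setdiff(taxa, taxa_names(aln))
  if (length(missing)) {
    abort(paste0("taxa absent from the alignment: ", paste(missing, collapse = ", ")))
  }
}

#' Diagnostic characters for a clade with a single sequenced member
#'
#' When only one member of the focal clade is sequenced, its diagnosis
#' combines two sources: (a) positions where the *sister* clade carries a
#' synapomorphy `a -> d` but the focal taxon retains the ancestral state
#' `a`, reported as retained characters "`a` (not `d`)"; and (b) derived
#' synapomorphies of the parent clade (focal plus sister) against a wider
#' outgroup. Positions where the focal taxon is missing, shares the
#' sister's derived state, or carries a third state contribute nothing.
#'
#' @param aln An [alignment_set()].
#' @param clades A [clade_partition()] with a single `focal` taxon and
#'   non-empty `sister` and `parent_outgroup` sets.
#' @param params A [scan_params()].
#' @param partitions Partitions to scan (default: all but `coi_barcode`).
#' @return A ranked `synapo_scan` tibble (union of both character sources).
#' @export
scan_singleton <- function(aln, clades, params = scan_params(),
                           partitions = setdiff(PARTITION_LABELS, "coi_barcode")) {
  stopifnot(inherits(clades, "clade_partition"))
  if (length(clades$focal) != 1) abort("scan_singleton needs exactly one focal taxon")
  if (is.null(clades$sister)) abort("scan_singleton needs a sister clade")
  if (is.null(clades$parent_outgroup)) abort("scan_singleton needs a parent_outgroup set")
  check_taxa(aln, c(clades$focal, clades$sister, clades$parent_outgroup,
                    clades$outgroups))
  all_params <- scan_params(params$outgroup_majority_threshold,
                            params$forbid_derived_in_outgroup,
                            params$max_focal_missing, top_k = Inf)
  # (a) sister synapomorphies where the focal taxon retains the ancestor
  sis <- scan_clade(aln, clade_partition(focal = clades$sister,
                                         outgroups = clades$outgroups),
                    all_params, partitions)
  retained <- list()
  focal_row <- match(clades$focal, taxa_names(aln))
  sis_derived <- sis[sis$kind == "derived", ]
  for (k in seq_len(nrow(sis_derived))) {
    li <- match(sis_derived$locus_id[k], aln$manifest$locus_id)
    st <- aln$loci[[li]][focal_row, sis_derived$position[k]]
    if (is_missing_state(st) || st != sis_derived$ancestral[k]) next
    mc <- NA_real_
    if (!is.null(aln$coverage)) mc <- aln$coverage[[li]][focal_row, sis_derived$position[k]]
    retained[[length(retained) + 1]] <- tibble(
      locus_index = li, prefix = sis_derived$prefix[k],
      scaffold = sis_derived$scaffold[k], gene = sis_derived$gene[k],
      exon = sis_derived$exon[k], position = sis_derived$position[k],
      kind = "retained_not", ancestral = sis_derived$ancestral[k],
      derived = sis_derived$derived[k], missing_count = 0L,
      min_coverage = mc)
  }
  # (b) synapomorphies of the parent clade (focal + sister)
  par <- scan_clade(aln, clade_partition(focal = c(clades$focal, clades$sister),
                                         outgroups = clades$parent_outgroup),
                    all_params, partitions)
  parent_rows <- list()
  for (k in seq_len(nrow(par))) {
    parent_rows[[length(parent_rows) + 1]] <- tibble(
      locus_index = match(par$locus_id[k], aln$manifest$locus_id),
      prefix = par$prefix[k], scaffold = par$scaffold[k], gene = par$gene[k],
      exon = par$exon[k], position = par$position[k], kind = par$kind[k],
      ancestral = par$ancestral[k], derived = par$derived[k],
      missing_count = par$missing_count[k], min_coverage = par$min_coverage[k])
  }
  cand <- c(retained, parent_rows)
  audit <- dplyr::bind_rows(attr(sis, "audit"), attr(par, "audit"))
  finish_scan(cand, list(audit), params, clades$focal, clades$outgroups)
}

#' Scan the COI barcode for diagnostic characters
#'
#' Applies the [scan_clade()] rule to the `coi_barcode` partition in
#' barcode coordinates: positions run 1-658 over the concatenated
#' barcode and characters carry the `COI` marker instead of a locus
#' address (rendered without prefix, e.g. `C235T`).
#'
#' @inheritParams scan_clade
#' @return A ranked `synapo_scan` tibble of barcode characters.
#' @export
scan_barcode <- function(aln, clades, params = scan_params()) {
  stopifnot(inherits(clades, "clade_partition"))
  check_taxa(aln, c(clades$focal, clades$outgroups))
  bc <- concatenate(aln, "coi_barcode")
  if (ncol(bc$matrix) != 658) {
    abort(sprintf("the COI barcode region must have 658 positions, found %d",
                  ncol(bc$matrix)))
  }
  manifest <- tibble(locus_id = "COI", prefix = NA_character_,
                     scaffold = NA_integer_, gene = NA_integer_,
                     exon = NA_integer_, partition = "coi_barcode",
                     length = 658L)
  sub <- alignment_set(list(COI = bc$matrix), manifest,
                       if (is.null(bc$coverage)) NULL else list(COI = bc$coverage))
  scan_loci(sub, 1L, clades$focal, clades$outgroups, params,
            barcode_coords = TRUE)
}

#' Write a scan result and its audit table
#'
#' Writes the reported characters one per line in notation format and,
#' alongside it, a tab-separated audit table of every column that reached
#' the outgroup clauses (locus, position, states, missing counts,
#' coverage, rule outcome).
#'
#' @param scan A `synapo_scan` result.
#' @param path Output path for the character list; the audit table goes to
#'   `<path>` with extension replaced by `_audit.tsv`.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  write_characters(scan, path)
  audit <- attr(scan, "audit")
  if (!is.null(audit) && nrow(audit)) {
    audit_path <- paste0(sub("\\.[^.]*$", "", path), "_audit.tsv")
    readr::write_tsv(audit, audit_path)
  }
  invisible(path)
}
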