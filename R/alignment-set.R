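#' Partitioned alignment container
#'
#' Bundles per-locus nucleotide alignments with their genome-partition
#' metadata and an optional per-taxon, per-position coverage table. Each
#' locus is a character matrix (taxa in rows, 1-based positions in columns)
#' over the alphabet `A C G T` plus the missing/ambiguity symbols
#' `N - ?` and IUPAC codes. All loci share the same taxon set and row
#' order; a taxon without data at a locus is an all-`N` row.
#'
#' @param loci Named list of character matrices; names are locus ids such as
#'   `"aly728.44.1"` (reference-genome prefix, scaffold, gene, exon) or
#'   `"COI"` for the barcode.
#' @param manifest Tibble with columns `locus_id`, `prefix`, `scaffold`,
#'   `gene`, `exon`, `partition` (one of `nuclear`, `Z`, `mito`,
#'   `coi_barcode`) and `length`, one row per locus, in locus order.
#' @param coverage Optional named list of integer matrices, parallel to
#'   `loci`, giving read depth per cell (0 where masked).
#' @return An object of class `alignment_set`.
#' @export
alignment_set <- function(loci, manifest, coverage = NULL) {
  stopifnot(is.list(loci), length(loci) == nrow(manifest))
  need <- c("locus_id", "prefix", "scaffold", "gene", "exon", "partition", "length")
  missing_cols <- setdiff(need, names(manifest))
  if (length(missing_cols)) {
    abort(paste0("manifest lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(manifest$partition %in% PARTITION_LABELS)) {
    bad <- unique(setdiff(manifest$partition, PARTITION_LABELS))
    abort(paste0("unknown partition label(s): ", paste(bad, collapse = ", ")))
  }
  if (is.null(names(loci))) names(loci) <- manifest$locus_id
  stopifnot(identical(names(loci), manifest$locus_id))
  taxa <- rownames(loci[[1]])
  for (i in seq_along(loci)) {
    m <- loci[[i]]
    stopifnot(is.matrix(m), is.character(m))
    if (ncol(m) != manifest$length[i]) {
      abort(sprintf("locus %s: matrix has %d columns but manifest says %d",
                    manifest$locus_id[i], ncol(m), manifest$length[i]))
    }
    if (!identical(rownames(m), taxa)) {
      abort(sprintf("locus %s: taxon rows differ from the first locus", manifest$locus_id[i]))
    }
  }
  if (!is.null(coverage)) {
    stopifnot(identical(names(coverage), manifest$locus_id))
    for (i in seq_along(coverage)) {
      stopifnot(identical(dim(coverage[[i]]), dim(loci[[i]])))
    }
  }
  structure(list(loci = loci, manifest = as_tibble(manifest), coverage = coverage),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("<alignment_set> %d taxa, %d loci (%s), %s coverage\n",
              length(taxa_names(x)), length(x$loci),
              paste(sprintf("%s: %d", names(table(x$manifest$partition)),
                            table(x$manifest$partition)), collapse = ", "),
              if (is.null(x$coverage)) "no" else "with"))
  invisible(x)
}

#' Taxon names of an alignment set
#' @param aln An `alignment_set`.
#' @return Character vector of taxon names (row order).
#' @export
taxa_names <- function(aln) rownames(aln$loci[[1]])

#' Extract one genome partition
#'
#' Keeps only the loci assigned to a partition (`nuclear`, `Z`, `mito` or
#' `coi_barcode`), preserving locus order and coverage.
#'
#' @param aln An `alignment_set`.
#' @param partition Partition label.
#' @return An `alignment_set` restricted to the partition.
#' @export
extract_region <- function(aln, partition) {
  if (!partition %in% PARTITION_LABELS) {
    abort(paste0("unknown partition label: ", partition))
  }
  keep <- aln$manifest$partition == partition
  if (!any(keep)) abort(paste0("no loci in partition ", dQuote(partition, q = "\"")))
  alignment_set(aln$loci[keep], aln$manifest[keep, , drop = FALSE],
                if (is.null(aln$coverage)) NULL else aln$coverage[keep])
}

#' Concatenate the loci of a partition into one matrix
#'
#' Binds locus matrices column-wise and returns the offset table needed to
#' map concatenated columns back to 1-based within-exon positions.
#'
#' @param aln An `alignment_set`.
#' @param partition Optional partition label; default concatenates all loci.
#' @return A list with `matrix` (taxa x total columns), `offsets` (tibble
#'   `locus_id`, `start`, `length`) and, when coverage is present,
#'   `coverage` (matching matrix of depths).
#' @seealso [column_to_locus()], [locus_to_column()]
#' @export
concatenate <- function(aln, partition = NULL) {
  if (!is.null(partition)) aln <- extract_region(aln, partition)
  lens <- aln$manifest$length
  offsets <- tibble(locus_id = aln$manifest$locus_id,
                    start = cumsum(c(1L, lens[-length(lens)])),
                    length = lens)
  out <- list(matrix = do.call(cbind, unname(aln$loci)), offsets = offsets)
  if (!is.null(aln$coverage)) {
    out$coverage <- do.call(cbind, unname(aln$coverage))
  }
  out
}

#' Map a concatenated column to its locus and within-exon position
#'
#' @param offsets Offset tibble from [concatenate()].
#' @param column Integer vector of concatenated column indices (1-based).
#' @return Tibble with `locus_id` and `position` (1-based within the exon).
#' @export
column_to_locus <- function(offsets, column) {
  total <- sum(offsets$length)
  stopifnot(all(column >= 1), all(column <= total))
  idx <- findInterval(column, offsets$start)
  tibble(locus_id = offsets$locus_id[idx],
         position = as.integer(column - offsets$start[idx] + 1L))
}

#' @param locus_id,position Locus id and 1-based within-exon position.
#' @rdname column_to_locus
#' @return `locus_to_column()` returns the integer concatenated column.
#' @export
locus_to_column <- function(offsets, locus_id, position) {
  i <- match(locus_id, offsets$locus_id)
  if (anyNA(i)) abort("unknown locus_id in offset map")
  stopifnot(all(position >= 1), all(position <= offsets$length[i]))
  as.integer(offsets$start[i] + position - 1L)
}
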