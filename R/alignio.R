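#' Read a partitioned alignment from FASTA files and a manifest
#'
#' The manifest is tab-separated with columns `locus_id`, `prefix`,
#' `scaffold`, `gene`, `exon`, `partition`, `length` and optionally `file`
#' (defaults to `<locus_id>.fasta` under `fasta_dir`). Sequences are
#' uppercased on read; `-`, `?`, `N` and IUPAC ambiguity codes are kept
#' verbatim (they round-trip on write) but are all treated as missing by
#' the character scan. Taxa absent from a locus become all-`N` rows so
#' every locus shares one taxon set.
#'
#' @param manifest_path Path to the manifest TSV.
#' @param fasta_dir Directory holding one FASTA file per locus.
#' @return An [alignment_set()].
#' @export
read_alignments <- function(manifest_path, fasta_dir) {
  manifest <- readr::read_tsv(manifest_path, show_col_types = FALSE,
                              col_types = readr::cols(
                                locus_id = "c", prefix = "c", scaffold = "i",
                                gene = "i", exon = "i", partition = "c",
                                length = "i", .default = "c"))
  if (!all(manifest$partition %in% PARTITION_LABELS)) {
    bad <- unique(setdiff(manifest$partition, PARTITION_LABELS))
    abort(paste0("unknown partition label(s) in manifest: ",
                 paste(bad, collapse = ", ")))
  }
  files <- if ("file" %in% names(manifest)) manifest$file else paste0(manifest$locus_id, ".fasta")
  raw <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    path <- file.path(fasta_dir, files[i])
    if (!file.exists(path)) abort(paste0("missing FASTA file for locus ", manifest$locus_id[i], ": ", path))
    ss <- Biostrings::readBStringSet(path)
    nm <- sub("\\s.*$", "", names(ss))
    if (anyDuplicated(nm)) {
      abort(sprintf("locus %s: duplicate taxon %s", manifest$locus_id[i],
                    nm[duplicated(nm)][1]))
    }
    w <- Biostrings::width(ss)
    if (any(w != manifest$length[i])) {
      j <- which(w != manifest$length[i])[1]
      abort(sprintf("locus %s: sequence for taxon %s has length %d, manifest says %d",
                    manifest$locus_id[i], nm[j], w[j], manifest$length[i]))
    }
    m <- do.call(rbind, strsplit(toupper(as.character(ss)), ""))
    rownames(m) <- nm
    bad <- setdiff(unique(as.vector(m)), c(BASES, MISSING_STATES))
    if (length(bad)) {
      abort(sprintf("locus %s: unknown state(s) %s", manifest$locus_id[i],
                    paste(bad, collapse = " ")))
    }
    raw[[i]] <- m
  }
  taxa <- unique(unlist(lapply(raw, rownames)))
  loci <- lapply(seq_along(raw), function(i) {
    m <- raw[[i]]
    full <- matrix("N", nrow = length(taxa), ncol = ncol(m),
                   dimnames = list(taxa, NULL))
    full[rownames(m), ] <- m
    full
  })
  names(loci) <- manifest$locus_id
  alignment_set(loci, manifest[names(manifest) != "file"])
}

#' Write an alignment set as FASTA files plus manifest and coverage tables
#'
#' Writes one FASTA per locus (named `<locus_id>.fasta`), `manifest.tsv`,
#' and, when coverage is present, a long-format `coverage.tsv` with columns
#' `taxon`, `locus_id`, `position`, `depth`.
#'
#' @param aln An [alignment_set()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_alignment_set <- function(aln, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(aln$manifest, file.path(dir, "manifest.tsv"))
  for (i in seq_along(aln$loci)) {
    m <- aln$loci[[i]]
    seqs <- Biostrings::BStringSet(apply(m, 1, paste0, collapse = ""))
    names(seqs) <- rownames(m)
    Biostrings::writeXStringSet(seqs, file.path(dir, paste0(names(aln$loci)[i], ".fasta")))
  }
  if (!is.null(aln$coverage)) {
    readr::write_tsv(coverage_table(aln), file.path(dir, "coverage.tsv"))
  }
  invisible(dir)
}

#' Coverage as a long table
#'
#' @param aln An [alignment_set()] with coverage.
#' @return Tibble with `taxon`, `locus_id`, `position`, `depth`.
#' @export
coverage_table <- function(aln) {
  if (is.null(aln$coverage)) abort("alignment set has no coverage")
  purrr::map2_dfr(aln$coverage, names(aln$coverage), function(m, id) {
    tibble(taxon = rep(rownames(m), times = ncol(m)),
           locus_id = id,
           position = rep(seq_len(ncol(m)), each = nrow(m)),
           depth = as.integer(m))
  })
}

#' Attach a coverage table read from disk
#'
#' @param aln An [alignment_set()].
#' @param path Path to a long-format coverage TSV (`taxon`, `locus_id`,
#'   `position`, `depth`). Cells absent from the table get depth 0.
#' @return The alignment set with coverage matrices attached.
#' @export
read_coverage <- function(aln, path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(taxon = "c", locus_id = "c",
                                                 position = "i", depth = "i"))
  cov <- lapply(seq_along(aln$loci), function(i) {
    m <- matrix(0L, nrow = nrow(aln$loci[[i]]), ncol = ncol(aln$loci[[i]]),
                dimnames = dimnames(aln$loci[[i]]))
    sub <- tab[tab$locus_id == names(aln$loci)[i], ]
    if (nrow(sub)) {
      m[cbind(match(sub$taxon, rownames(m)), sub$position)] <- sub$depth
    }
    m
  })
  names(cov) <- names(aln$loci)
  alignment_set(aln$loci, aln$manifest, cov)
}

#' Define the taxon sets of one clade diagnosis
#'
#' A diagnosis compares a focal clade against outgroup taxa; when the focal
#' clade has a single sequenced member, characters are also sought for its
#' sister clade (the focal taxon retaining the ancestral state) and for the
#' parent clade (focal plus sister) against a wider outgroup.
#'
#' @param focal Character vector of focal-clade taxa.
#' @param outgroups Taxa used to polarize ancestral vs derived states.
#' @param sister Optional sister-clade taxa (singleton strategy).
#' @param parent_outgroup Optional outgroup taxa for the parent clade
#'   (focal plus sister).
#' @return An object of class `clade_partition`.
#' @export
clade_partition <- function(focal, outgroups, sister = NULL, parent_outgroup = NULL) {
  stopifnot(length(focal) > 0, length(outgroups) > 0)
  if (length(intersect(focal, outgroups))) abort("focal and outgroup sets overlap")
  if (!is.null(sister)) {
    stopifnot(length(sister) > 0)
    if (length(intersect(focal, sister))) abort("focal and sister sets overlap")
  }
  if (!is.null(parent_outgroup)) {
    stopifnot(length(parent_outgroup) > 0)
    if (length(intersect(parent_outgroup, union(focal, sister)))) {
      abort("parent_outgroup overlaps the focal/sister clades")
    }
  }
  structure(list(focal = focal, sister = sister,
                 parent_outgroup = parent_outgroup, outgroups = outgroups),
            class = "clade_partition")
}

#' Read / write clade definitions
#'
#' Clade definitions live in a YAML file with keys `focal`, `outgroups` and
#' optionally `sister` and `parent_outgroup`, each a list of taxon names.
#'
#' @param path File path.
#' @return `read_clades()` returns a [clade_partition()].
#' @export
read_clades <- function(path) {
  y <- yaml::read_yaml(path)
  clade_partition(focal = unlist(y$focal), outgroups = unlist(y$outgroups),
                  sister = if (!is.null(y$sister)) unlist(y$sister),
                  parent_outgroup = if (!is.null(y$parent_outgroup)) unlist(y$parent_outgroup))
}

#' @param clades A [clade_partition()].
#' @rdname read_clades
#' @export
write_clades <- function(clades, path) {
  yaml::write_yaml(lapply(unclass(clades), as.list), path)
  invisible(path)
}
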