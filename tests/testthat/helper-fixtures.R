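# small in-code fixtures shared across tests

MISS <- c("N", "-", "?", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

# a single-locus alignment_set from a character matrix
one_locus_aln <- function(m, partition = "nuclear", locus_id = "aly101.1.1",
                          coverage = NULL) {
  manifest <- tibble::tibble(
    locus_id = locus_id,
    prefix = if (partition == "coi_barcode") NA_character_ else "aly",
    scaffold = if (partition == "coi_barcode") NA_integer_ else 101L,
    gene = if (partition == "coi_barcode") NA_integer_ else 1L,
    exon = if (partition == "coi_barcode") NA_integer_ else 1L,
    partition = partition, length = ncol(m))
  cov <- if (is.null(coverage)) NULL else setNames(list(coverage), locus_id)
  alignment_set(setNames(list(m), locus_id), manifest, cov)
}

# matrix from per-taxon strings
seq_matrix <- function(...) {
  seqs <- c(...)
  do.call(rbind, lapply(setNames(strsplit(seqs, ""), names(seqs)), identity))
}

# random small alignment + clade split for property tests; columns draw
# from a per-column pool of 1-2 bases (plus occasional missing symbols) so
# candidate columns actually occur
random_case <- function(seed) {
  set.seed(seed)
  nt <- sample(4:8, 1)
  nc <- sample(5:50, 1)
  taxa <- paste0("t", seq_len(nt))
  m <- matrix("A", nt, nc, dimnames = list(taxa, NULL))
  for (j in seq_len(nc)) {
    pool <- sample(c("A", "C", "G", "T"), sample(1:2, 1))
    col <- sample(pool, nt, replace = TRUE)
    mask <- runif(nt) < 0.12
    col[mask] <- sample(c("N", "-", "?"), sum(mask), replace = TRUE)
    m[, j] <- col
  }
  nf <- sample(seq_len(nt - 1), 1)
  list(aln = one_locus_aln(m),
       clades = clade_partition(focal = taxa[seq_len(nf)],
                                outgroups = taxa[(nf + 1):nt]))
}
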