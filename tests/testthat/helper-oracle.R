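# literal brute-force implementation of the synapomorphy rule, kept
# independent of the package internals: every clause is re-stated here
# from first principles and applied column by column

oracle_scan <- function(aln, clades, threshold = 0.9, forbid = TRUE,
                        max_missing = NULL) {
  res <- list()
  for (li in seq_along(aln$loci)) {
    m <- aln$loci[[li]]
    for (j in seq_len(ncol(m))) {
      fs <- m[clades$focal, j]
      os <- m[clades$outgroups, j]
      fobs <- fs[!fs %in% MISS]
      oobs <- os[!os %in% MISS]
      if (length(fobs) == 0 || length(oobs) == 0) next
      if (length(unique(fobs)) != 1) next            # clade must be invariant
      d <- unique(fobs)
      n_miss <- sum(fs %in% MISS)
      mm <- if (is.null(max_missing)) length(fs) - 1 else max_missing
      if (n_miss > mm) next
      counts <- vapply(c("A", "C", "G", "T"), function(b) sum(oobs == b), 0L)
      a <- names(counts)[which.max(counts)]
      if (max(counts) / length(oobs) >= threshold) { # "mostly invariant" outgroup
        if (a == d) next                             # must differ from ancestor
        if (forbid && d %in% oobs) next              # derived leaked into outgroup
        kind <- "derived"; anc <- a
      } else if (!d %in% oobs) {                     # unpolarized but diagnostic
        kind <- "state_only"; anc <- NA_character_
      } else next
      res[[length(res) + 1]] <- data.frame(
        locus_id = aln$manifest$locus_id[li], position = j, kind = kind,
        ancestral = anc, derived = d, missing_count = n_miss,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(locus_id = character(), position = integer(),
                      kind = character(), ancestral = character(),
                      derived = character(), missing_count = integer()))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$locus_id, out$position), ]
}

# normalize a scan result to the oracle's frame for comparison
scan_as_frame <- function(scan) {
  df <- as.data.frame(scan)[, c("locus_id", "position", "kind", "ancestral",
                                "derived", "missing_count")]
  df <- df[order(df$locus_id, df$position), ]
  rownames(df) <- NULL
  df
}
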