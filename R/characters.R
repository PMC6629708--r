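#' Construct a tibble of diagnostic characters
#'
#' A diagnostic character is one alignment position whose state separates a
#' focal clade from its outgroups. Characters come in three kinds:
#'
#' * `"derived"` — the clade carries a state changed from the ancestral
#'   (outgroup) state, e.g. `aly728.44.1:G672C`;
#' * `"retained_not"` — the clade retains the ancestral state while its
#'   sister clade changed it, e.g. `aly5294.20.2:A548A (not C)`;
#' * `"state_only"` — the clade state is diagnostic but the ancestral state
#'   could not be polarized, e.g. `474C`.
#'
#' Characters on the 658-bp COI barcode carry `locus_id = "COI"` and no
#' scaffold/gene/exon address; their rendered form never contains a colon.
#'
#' @param prefix Reference-genome tag (e.g. `"aly"`); `NA` for barcode
#'   characters.
#' @param scaffold,gene,exon Integer address of the exon in the reference
#'   genome; `NA` for barcode characters.
#' @param position 1-based position within the exon (or within the 658-bp
#'   barcode).
#' @param kind One of `"derived"`, `"retained_not"`, `"state_only"`.
#' @param ancestral Ancestral state (`NA` for `state_only`).
#' @param derived Derived state for `kind = "derived"`; the *excluded*
#'   (sister-clade) state for `kind = "retained_not"`; the observed clade
#'   state for `kind = "state_only"`.
#' @param missing_count Number of focal-clade taxa with missing data at the
#'   position (`NA` when unknown).
#' @param min_coverage Minimum read depth over focal-clade taxa with data at
#'   the position (`NA` when no coverage table was supplied).
#'
#' @return A tibble of class `synapo_chars` with one row per character and a
#'   `notation` column holding the rendered string.
#' @seealso [render_characters()], [parse_characters()]
#' @export
#' @examples
#' diag_characters(prefix = "aly", scaffold = 728, gene = 44, exon = 1,
#'                 position = 672, kind = "derived",
#'                 ancestral = "G", derived = "C")
diag_characters <- function(prefix = NA_character_, scaffold = NA_integer_,
                            gene = NA_integer_, exon = NA_integer_,
                            position = integer(), kind = character(),
                            ancestral = NA_character_, derived = character(),
                            missing_count = NA_integer_,
                            min_coverage = NA_real_) {
  out <- tibble(
    prefix = as.character(prefix),
    scaffold = as.integer(scaffold),
    gene = as.integer(gene),
    exon = as.integer(exon),
    locus_id = ifelse(is.na(as.character(prefix)), "COI",
                      paste0(prefix, scaffold, ".", gene, ".", exon)),
    position = as.integer(position),
    kind = as.character(kind),
    ancestral = as.character(ancestral),
    derived = as.character(derived),
    missing_count = as.integer(missing_count),
    min_coverage = as.numeric(min_coverage)
  )
  validate_characters(out)
  out$notation <- render_characters(out)
  class(out) <- c("synapo_chars", class(tibble()))
  out
}

#' @noRd
validate_characters <- function(x) {
  stopifnot(all(x$kind %in% c("derived", "retained_not", "state_only")))
  bad <- x$kind == "derived" &
    (is.na(x$ancestral) | !(x$ancestral %in% BASES) |
       !(x$derived %in% BASES) | x$ancestral == x$derived)
  if (any(bad)) abort("derived characters need distinct A/C/G/T ancestral and derived states")
  bad <- x$kind == "retained_not" &
    (is.na(x$ancestral) | x$ancestral == x$derived)
  if (any(bad)) abort("retained_not characters need an ancestral state distinct from the excluded state")
  bad <- x$kind == "state_only" & !is.na(x$ancestral)
  if (any(bad)) abort("state_only characters cannot carry an ancestral state")
  if (any(!is.na(x$position) & x$position < 1)) abort("positions are 1-based")
  barcode <- is.na(x$prefix)
  if (any(barcode & x$position > 658)) {
    abort("barcode characters cannot exceed position 658")
  }
  invisible(x)
}

#' Render diagnostic characters as notation strings
#'
#' Produces the compact strings used in published diagnoses:
#' `aly728.44.1:G672C` (position 672 in exon 1 of gene 44 from scaffold 728
#' changed from G to C), `aly5294.20.2:A548A (not C)` (ancestral A retained
#' where the sister clade changed to C), and prefix-free barcode forms such
#' as `C235T` or `474C` (COI barcode coordinates, 1-658).
#'
#' @param chars A `synapo_chars` tibble (see [diag_characters()]).
#' @return A character vector, one rendered string per row.
#' @export
#' @examples
#' ch <- diag_characters(prefix = "aly", scaffold = 528, gene = 10, exon = 2,
#'                       position = 940, kind = "derived",
#'                       ancestral = "G", derived = "C")
#' render_characters(ch)
render_characters <- function(chars) {
  loc <- ifelse(is.na(chars$prefix), "",
                paste0(chars$prefix, chars$scaffold, ".", chars$gene, ".",
                       chars$exon, ":"))
  body <- character(nrow(chars))
  k <- chars$kind
  body[k == "derived"] <- paste0(chars$ancestral[k == "derived"],
                                 chars$position[k == "derived"],
                                 chars$derived[k == "derived"])
  body[k == "retained_not"] <- paste0(chars$ancestral[k == "retained_not"],
                                      chars$position[k == "retained_not"],
                                      chars$ancestral[k == "retained_not"],
                                      " (not ", chars$derived[k == "retained_not"], ")")
  body[k == "state_only"] <- paste0(chars$position[k == "state_only"],
                                    chars$derived[k == "state_only"])
  paste0(loc, body)
}

# parse one notation string; `s` is assumed trimmed
#' @noRd
parse_one_character <- function(s) {
  fail <- function(at, why) {
    abort(sprintf("malformed character string %s at position %d: %s",
                  dQuote(s, q = "\""), at, why))
  }
  m <- stringr::str_match(s, "^([a-z]+)(\\d+)\\.(\\d+)\\.(\\d+):")
  if (!is.na(m[1, 1])) {
    prefix <- m[1, 2]
    scaffold <- as.integer(m[1, 3])
    gene <- as.integer(m[1, 4])
    exon <- as.integer(m[1, 5])
    offset <- nchar(m[1, 1])
    body <- substr(s, offset + 1L, nchar(s))
  } else {
    if (grepl("^[a-z]", s)) fail(1L, "locus address must be prefix<scaffold>.<gene>.<exon>:")
    prefix <- NA_character_
    scaffold <- gene <- exon <- NA_integer_
    offset <- 0L
    body <- s
  }
  mk <- function(kind, position, ancestral, derived) {
    if (is.na(prefix) && position > 658L) {
      fail(offset + 2L, "barcode positions run 1-658")
    }
    diag_characters(prefix = prefix, scaffold = scaffold, gene = gene,
                    exon = exon, position = position, kind = kind,
                    ancestral = ancestral, derived = derived)
  }

  m <- stringr::str_match(body, "^([ACGT])(\\d+)([ACGT])(.*)$")
  if (!is.na(m[1, 1])) {
    anc <- m[1, 2]; pos <- as.integer(m[1, 3]); der <- m[1, 4]
    tail <- m[1, 5]
    if (tail == "") {
      if (anc == der) {
        fail(offset + 1L, "ancestral state equals derived state (retained characters need '(not X)')")
      }
      return(mk("derived", pos, anc, der))
    }
    mn <- stringr::str_match(tail, "^\\s*\\(\\s*not\\s+([ACGT])\\s*\\)$")
    if (is.na(mn[1, 1])) {
      fail(offset + nchar(m[1, 2]) + nchar(m[1, 3]) + nchar(m[1, 4]) + 1L,
           "expected end of string or ' (not X)'")
    }
    if (anc != der) {
      fail(offset + 1L, "a '(not X)' character must repeat the retained state")
    }
    excl <- mn[1, 2]
    if (excl == anc) {
      fail(offset + 1L, "excluded state equals the retained state")
    }
    return(mk("retained_not", pos, anc, excl))
  }
  m <- stringr::str_match(body, "^(\\d+)([ACGT])$")
  if (!is.na(m[1, 1])) {
    return(mk("state_only", as.integer(m[1, 2]), NA_character_, m[1, 3]))
  }
  # locate the first offending character for the error message
  ok <- c(BASES, as.character(0:9))
  chars_in <- strsplit(body, "")[[1]]
  at <- which(!chars_in %in% ok)
  fail(offset + if (length(at)) at[1] else nchar(body) + 1L,
       "not a recognized character dialect")
}

#' Parse diagnostic-character notation strings
#'
#' Inverse of [render_characters()]. Accepts the four printed dialects:
#' locus-addressed derived characters (`aly528.10.2:G940C`), retained
#' characters (`aly499.37.1:G77G (not A)`), barcode characters without a
#' locus prefix (`A79T`), and unpolarized states (`59C`, `474C`), which
#' parse to `kind = "state_only"`. Prefix-free strings are barcode
#' characters and must fall within positions 1-658.
#'
#' @param x Character vector of notation strings.
#' @return A `synapo_chars` tibble with one row per string.
#' @export
#' @examples
#' parse_characters(c("aly528.10.2:G940C", "C235T", "474C",
#'                    "aly499.37.1:G77G (not A)"))
parse_characters <- function(x) {
  if (!length(x)) {
    return(diag_characters())
  }
  out <- purrr::map(stringr::str_trim(x), parse_one_character)
  out <- dplyr::bind_rows(out)
  class(out) <- c("synapo_chars", class(tibble()))
  out
}

#' Parse a printed diagnosis list
#'
#' Published diagnoses list characters separated by commas and a final
#' "and" ("aly528.10.2:G940C, aly925.27.5:A3610T, ... and T349A"). This
#' splits such a list (tolerating Oxford commas, "and", and a trailing
#' period) and parses every item.
#'
#' @param text A single string holding the list; the empty string yields an
#'   empty result.
#' @return A `synapo_chars` tibble in list order.
#' @export
#' @examples
#' parse_diagnosis_list("G38A, A81C, A307G, C347T, T349A, A430T, A604C")
parse_diagnosis_list <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- stringr::str_trim(text)
  if (text == "") {
    return(parse_characters(character()))
  }
  text <- stringr::str_replace_all(text, ",?\\s+and\\s+", ", ")
  items <- stringr::str_trim(strsplit(text, ",")[[1]])
  items <- stringr::str_remove(items, "\\.$")
  items <- items[items != ""]
  out <- vector("list", length(items))
  for (i in seq_along(items)) {
    out[[i]] <- tryCatch(
      parse_one_character(items[i]),
      error = function(e) {
        abort(sprintf("item %d of the diagnosis list failed to parse: %s",
                      i, conditionMessage(e)))
      }
    )
  }
  out <- dplyr::bind_rows(out)
  class(out) <- c("synapo_chars", class(tibble()))
  out
}

#' Read / write plain-text character files
#'
#' One rendered character per line; blank lines and lines starting with `#`
#' are ignored. This is the ground-truth format written by
#' [plant_synapomorphies()] and the output format of [scan_clade()].
#'
#' @param path File path.
#' @return `read_characters()` returns a `synapo_chars` tibble.
#' @export
read_characters <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- stringr::str_trim(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  parse_characters(lines)
}

#' @param chars A `synapo_chars` tibble.
#' @rdname read_characters
#' @return `write_characters()` returns `path` invisibly.
#' @export
write_characters <- function(chars, path) {
  writeLines(render_characters(chars), path)
  invisible(path)
}
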