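# seqio: readers/writers for the external formats the pipeline touches
# (FASTA sequences and alignments, Newick trees, TSV tables). All coordinates
# exposed by this module are 0-based, half-open; conversion to 1-based
# happens only at report time.

VALID_SOURCES <- c("genome", "transcriptome", "synthetic")

#' Construct a set of protein records
#'
#' A protein-record set is a plain `data.frame` with one row per sequence and
#' columns `id`, `residues`, `taxon`, `species`, `source`. Residues are
#' uppercase letters over the 20 amino acids plus `X`; gap characters are not
#' allowed here (gapped rows live in alignments, see [read_alignment()]).
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param residues character vector of sequences (no gaps, length >= 1 each).
#' @param taxon,species optional per-record labels (`NA` when unknown).
#' @param source one of `"genome"`, `"transcriptome"`, `"synthetic"`.
#' @return a `data.frame` of protein records.
#' @export
protein_records <- function(id, residues, taxon = NA_character_,
                            species = NA_character_, source = "synthetic") {
  rec <- data.frame(
    id = as.character(id),
    residues = toupper(as.character(residues)),
    taxon = as.character(taxon),
    species = as.character(species),
    source = as.character(source),
    stringsAsFactors = FALSE
  )
  validate_records(rec)
  rec
}

validate_records <- function(rec) {
  if (any(!nzchar(rec$id))) stop2("protein record with empty id")
  dup <- rec$id[duplicated(rec$id)]
  if (length(dup) > 0L) {
    stop2("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (any(!nzchar(rec$residues))) {
    bad <- rec$id[!nzchar(rec$residues)]
    stop2("empty sequence for id(s): ", paste(bad, collapse = ", "))
  }
  allowed <- c(AA_ALPHABET20, "X")
  letters_used <- unique(unlist(strsplit(rec$residues, "", fixed = TRUE)))
  offending <- setdiff(letters_used, allowed)
  if (length(offending) > 0L) {
    stop2(
      "non-amino-acid letter(s) in sequences: ",
      paste(sort(offending), collapse = ", ")
    )
  }
  src <- rec$source[!is.na(rec$source)]
  if (any(!src %in% VALID_SOURCES)) {
    stop2("source must be one of: ", paste(VALID_SOURCES, collapse = ", "))
  }
  invisible(rec)
}

parse_description_tags <- function(desc) {
  out <- list(taxon = NA_character_, species = NA_character_,
              source = NA_character_)
  if (!nzchar(desc)) return(out)
  toks <- strsplit(desc, "[[:space:]]+")[[1L]]
  for (tok in toks) {
    m <- regmatches(tok, regexec("^(taxon|species|source)=(.+)$", tok))[[1L]]
    if (length(m) == 3L) out[[m[2L]]] <- m[3L]
  }
  out
}

#' Read protein sequences from a FASTA file
#'
#' The header token before the first whitespace becomes the record id; the
#' remaining description is scanned for `taxon=`, `species=` and `source=`
#' key=value tags. Duplicate ids, empty sequences and letters outside the
#' amino-acid alphabet (plus `X`) are hard errors.
#'
#' @param path FASTA file path.
#' @return a protein-record `data.frame`, see [protein_records()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop2("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("[[:space:]].*$", "", headers)
  descs <- ifelse(
    grepl("[[:space:]]", headers),
    sub("^[^[:space:]]+[[:space:]]+", "", headers),
    ""
  )
  tags <- lapply(descs, parse_description_tags)
  rec <- data.frame(
    id = unname(ids),
    residues = unname(toupper(as.character(set))),
    taxon = vapply(tags, `[[`, "", "taxon"),
    species = vapply(tags, `[[`, "", "species"),
    source = vapply(tags, `[[`, "", "source"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  validate_records(rec)
  rec
}

#' Write protein records to FASTA
#'
#' Sequences are wrapped at `width` columns; non-`NA` metadata is emitted as
#' `taxon=` / `species=` / `source=` tags so that
#' `write_fasta(read_fasta(f))` is byte-identical for files in this canonical
#' form.
#'
#' @param records protein-record `data.frame`.
#' @param path output path.
#' @param width line-wrap column (default 60).
#' @export
write_fasta <- function(records, path, width = 60L) {
  validate_records(records)
  lines <- character(0L)
  for (i in seq_len(nrow(records))) {
    tags <- character(0L)
    for (f in c("taxon", "species", "source")) {
      v <- records[[f]][i]
      if (!is.na(v)) tags <- c(tags, paste0(f, "=", v))
    }
    header <- paste0(">", records$id[i],
                     if (length(tags)) paste0(" ", paste(tags, collapse = " ")) else "")
    s <- records$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    body <- substring(s, starts, pmin(starts + width - 1L, nchar(s)))
    lines <- c(lines, header, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA protein alignment
#'
#' Rows may contain `-` gap characters; all rows must have equal length
#' (ragged input is a hard error reporting ids and lengths). Gap-only columns
#' are retained; use [ungap()] to recover the source residues of a row.
#'
#' @param path aligned FASTA path.
#' @return named character vector of aligned rows (class `fmo_alignment`).
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop2("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("[[:space:]].*$", "", names(set))
  rows <- toupper(as.character(set))
  names(rows) <- ids
  as_alignment(rows)
}

#' Build an alignment object from named rows
#'
#' @param rows named character vector; equal-length strings over the residue
#'   alphabet plus `-`.
#' @return the validated rows with class `fmo_alignment`.
#' @export
as_alignment <- function(rows) {
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    stop2("alignment rows must be named by sequence id")
  }
  dup <- names(rows)[duplicated(names(rows))]
  if (length(dup) > 0L) {
    stop2("duplicate alignment id(s): ", paste(unique(dup), collapse = ", "))
  }
  widths <- nchar(rows)
  if (length(unique(widths)) > 1L) {
    stop2(
      "ragged alignment rows: ",
      paste(sprintf("%s(%d)", names(rows), widths), collapse = ", ")
    )
  }
  structure(rows, class = "fmo_alignment")
}

#' Alignment width (number of columns)
#' @param aln an `fmo_alignment`.
#' @export
alignment_width <- function(aln) {
  if (length(aln) == 0L) return(0L)
  nchar(aln[[1L]])
}

#' Remove gap characters from an aligned row
#' @param row character string possibly containing `-` gaps.
#' @export
ungap <- function(row) gsub("-", "", row, fixed = TRUE)

#' Write an alignment to FASTA
#' @param aln an `fmo_alignment`.
#' @param path output path.
#' @param width line-wrap column.
#' @export
write_alignment <- function(aln, path, width = 60L) {
  lines <- character(0L)
  for (i in seq_along(aln)) {
    s <- unclass(aln)[[i]]
    starts <- seq(1L, nchar(s), by = width)
    body <- substring(s, starts, pmin(starts + width - 1L, nchar(s)))
    lines <- c(lines, paste0(">", names(aln)[i]), body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a taxonomy sidecar TSV
#'
#' Columns `id`, `species`, `taxon`; each id at most once. Metadata from a
#' sidecar table overrides FASTA header tags, see [apply_taxonomy()].
#'
#' @param path TSV path.
#' @export
read_taxonomy <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "species", "taxon")
  if (!all(need %in% names(tab))) {
    stop2("taxonomy table needs columns: ", paste(need, collapse = ", "))
  }
  dup <- tab$id[duplicated(tab$id)]
  if (length(dup) > 0L) {
    stop2("duplicate taxonomy id(s): ", paste(unique(dup), collapse = ", "))
  }
  tab[, need]
}

#' Overlay taxonomy metadata onto records (sidecar wins on conflict)
#'
#' @param records protein-record `data.frame`.
#' @param taxonomy table from [read_taxonomy()].
#' @export
apply_taxonomy <- function(records, taxonomy) {
  m <- match(records$id, taxonomy$id)
  hit <- !is.na(m)
  records$species[hit] <- taxonomy$species[m[hit]]
  records$taxon[hit] <- taxonomy$taxon[m[hit]]
  records
}

#' Read a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] with an upfront bracket-balance check
#' that reports the character offset of the first mismatch.
#'
#' @param path Newick file path.
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  check_parens(txt)
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop2("could not parse Newick in ", path)
  tr
}

check_parens <- function(txt) {
  chars <- seq_chars(txt)
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop2("malformed Newick: unmatched ')' at character offset ", i - 1L)
      }
    }
  }
  if (depth != 0L) {
    stop2("malformed Newick: ", depth, " unclosed '(' at end of input")
  }
  invisible(TRUE)
}

#' Write a tree to Newick
#'
#' Branch lengths are written at full double precision; unlabeled leaves are
#' a hard error. `read_newick(write_newick(t))` preserves topology, labels
#' and lengths to within 1e-9.
#'
#' @param tree an `ape::phylo` tree.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  if (is.null(tree$tip.label) || any(is.na(tree$tip.label)) ||
      any(!nzchar(tree$tip.label))) {
    stop2("tree has unlabeled leaves")
  }
  ape::write.tree(tree, file = path, digits = 17)
  invisible(path)
}

#' Format a homolog/species count cell
#'
#' Renders `n` homologs over `m` species as `"n(m)"`; a zero homolog count is
#' printed bare as `"0"` (or as `zero` when a different convention, such as
#' `"-"`, is requested).
#'
#' @param n homolog count.
#' @param m species count (optional).
#' @param zero string used when `n == 0`.
#' @export
format_count_cell <- function(n, m = NULL, zero = "0") {
  out <- character(length(n))
  for (i in seq_along(n)) {
    if (n[i] == 0L) {
      out[i] <- zero
    } else if (is.null(m) || is.na(m[i])) {
      out[i] <- as.character(n[i])
    } else {
      out[i] <- sprintf("%d(%d)", n[i], m[i])
    }
  }
  out
}

#' Write a report table as UTF-8 TSV
#'
#' Column order is taken from the data frame and is therefore deterministic
#' across runs; row names are never written.
#'
#' @param rows a `data.frame`.
#' @param path output path.
#' @export
write_table <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
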