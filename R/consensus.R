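# consensus: per-group position frequency matrices over the three motifs
# and consensus-string statistics (the sequence-logo stage).

MOTIF_LENGTHS <- c(FAD = 6L, FMO = 12L, NADPH = 6L)

#' Build a position frequency matrix for one motif and group
#'
#' Tallies, per motif position, the residues observed across the group's
#' sequences. Sequences lacking the requested motif are excluded rather than
#' padded, so each column sums to the number of contributing sequences.
#'
#' @param annotations [annotate_all()] output.
#' @param records the protein-record `data.frame` the annotations refer to.
#' @param ids record ids forming the group (e.g. all ids called `typeIIb`).
#' @param kind one of `"FAD"`, `"FMO"`, `"NADPH"`.
#' @param group label stored on the result.
#' @return integer matrix (positions x 21 residues, `X` included) of class
#'   `fmo_pfm`, with attributes `group`, `kind`, `n`.
#' @export
build_pfm <- function(annotations, records, ids, kind = "FMO",
                      group = "group") {
  kind <- match.arg(kind, names(MOTIF_LENGTHS))
  width <- MOTIF_LENGTHS[[kind]]
  start_col <- switch(kind, FAD = "fad_start", FMO = "fmo_start",
                      NADPH = "nadph_start")
  ann <- annotations[annotations$id %in% ids, ]
  ann <- ann[!is.na(ann[[start_col]]), ]
  if (kind == "FMO") ann <- ann[!is.na(ann$fmo_kind) & ann$fmo_kind == "FMO", ]
  if (nrow(ann) == 0L) {
    stop2("no sequences in group '", group, "' carry a ", kind, " motif")
  }
  residue_set <- c(AA_ALPHABET20, "X")
  counts <- matrix(0L, nrow = width, ncol = length(residue_set),
                   dimnames = list(position = seq_len(width),
                                   residue = residue_set))
  seqs <- records$residues[match(ann$id, records$id)]
  starts <- ann[[start_col]]
  for (i in seq_along(seqs)) {
    frag <- seq_chars(substring(seqs[i], starts[i] + 1L, starts[i] + width))
    for (p in seq_len(width)) {
      counts[p, frag[p]] <- counts[p, frag[p]] + 1L
    }
  }
  structure(counts, class = "fmo_pfm", group = group, kind = kind,
            n = nrow(ann))
}

#' Frequencies of a PFM column
#' @param pfm an `fmo_pfm`.
#' @param position 1-based motif position.
#' @export
pfm_frequencies <- function(pfm, position) {
  row <- unclass(pfm)[position, ]
  row / sum(row)
}

#' Consensus string of a position frequency matrix
#'
#' Per column: the majority residue is rendered uppercase when its frequency
#' is at least `major`, lowercase when at least `minor`; otherwise the
#' column renders as `x` -- unless `slash = TRUE`, in which case columns
#' whose top residues each reach `(1 - major) / 2` render as an alternative
#' set like `(H/y/f)`.
#'
#' @param pfm an `fmo_pfm`.
#' @param major,minor case thresholds (defaults 0.9 / 0.5).
#' @param slash render near-ties as slash sets.
#' @export
consensus_string <- function(pfm, major = 0.9, minor = 0.5, slash = FALSE) {
  width <- nrow(pfm)
  out <- character(width)
  for (p in seq_len(width)) {
    f <- sort(pfm_frequencies(pfm, p), decreasing = TRUE)
    top <- f[1L]
    if (top >= major) {
      out[p] <- names(f)[1L]
    } else if (slash) {
      members <- names(f)[f >= (1 - major) / 2 & f > 0]
      if (length(members) > 1L) {
        rendered <- c(
          if (top >= minor) names(f)[1L] else tolower(names(f)[1L]),
          tolower(members[-1L])
        )
        out[p] <- paste0("(", paste(rendered, collapse = "/"), ")")
      } else if (top >= minor) {
        out[p] <- tolower(names(f)[1L])
      } else {
        out[p] <- "x"
      }
    } else if (top >= minor) {
      out[p] <- tolower(names(f)[1L])
    } else {
      out[p] <- "x"
    }
  }
  paste(out, collapse = "")
}

#' Diagnostic motif-residue statistics across groups
#'
#' Emits the family-diagnostic fractions: the type IIb FMO-motif
#' penultimate-H fraction, the type IIb NADPH-motif second-position-N
#' fraction, and the per-group count (and fraction) of penultimate-H
#' sequences for every group with an FMO-motif PFM in the set. Fractions
#' are reported in `[0, 1]`; `percent` is the round-half-up display value.
#'
#' @param pfms list of `fmo_pfm` objects (mixed groups and kinds).
#' @param require_groups group labels that must be present (their absence is
#'   a hard error naming the group); default `"typeIIb"`.
#' @return `data.frame` with columns `statistic`, `group`, `value`,
#'   `percent`, `count`, `n`.
#' @export
diagnostic_fractions <- function(pfms, require_groups = "typeIIb") {
  groups <- vapply(pfms, attr, "", "group")
  kinds <- vapply(pfms, attr, "", "kind")
  for (g in require_groups) {
    if (!g %in% groups) stop2("group '", g, "' absent from the PFM set")
  }
  rows <- list()
  add <- function(statistic, group, count, n) {
    rows[[length(rows) + 1L]] <<- data.frame(
      statistic = statistic, group = group, value = count / n,
      percent = round_half_up(100 * count / n), count = count, n = n,
      stringsAsFactors = FALSE
    )
  }
  for (i in seq_along(pfms)) {
    pfm <- pfms[[i]]
    if (kinds[i] == "FMO") {
      n <- attr(pfm, "n")
      h <- unclass(pfm)[nrow(pfm) - 1L, "H"]
      add("fmo_penultimate_H", groups[i], h, n)
    }
    if (kinds[i] == "NADPH") {
      n <- attr(pfm, "n")
      nn <- unclass(pfm)[2L + 1L, "N"]
      add("nadph_second_N", groups[i], nn, n)
    }
  }
  do.call(rbind, rows)
}

#' Export a PFM as a TSV matrix
#' @param pfm an `fmo_pfm`.
#' @param path output path.
#' @export
write_pfm <- function(pfm, path) {
  df <- data.frame(position = seq_len(nrow(pfm)), unclass(pfm),
                   check.names = FALSE)
  write_table(df, path)
}
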